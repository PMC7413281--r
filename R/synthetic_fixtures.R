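# Seeded generators for toy knowledge graphs, claim batches with planted
# FWA events, and a typo model over the fixture vocabulary — plus the
# planted-truth evaluation harness. Everything is deterministic given
# (params, seed) and needs no external language resources: the packaged
# attribute maps and unit lexicons cover every character the generators can
# emit.

# fixture vocabulary pools (all characters covered by the packaged
# pronunciation/radical tables where a homophone/radical sibling exists)
POOL_ORGAN <- c("糖", "肝", "肺", "心", "胃", "肠", "肾", "脑", "血", "骨",
                "皮", "目")
POOL_QUALITY <- c("风", "热", "寒", "湿", "瘀", "郁", "亏", "滞")
POOL_SUFFIX <- c("病", "炎", "症")
POOL_BODY <- c("手部", "足部", "头部", "肩部", "腰部", "颈部", "背部",
               "膝部", "肘部", "腕部")
POOL_INJURY <- c("擦伤", "挫伤", "扭伤", "脱位", "劳损")
POOL_DRUG_SYL <- c("氨", "苯", "地", "平", "洛", "伐", "他", "汀", "西",
                   "林", "沙", "星", "康", "唑", "米", "辛", "多", "韦",
                   "尼", "布")

organ_disease_name <- function(i) {
  paste0(POOL_ORGAN[(i - 1L) %% 12L + 1L],
         POOL_QUALITY[((i - 1L) %/% 12L) %% 8L + 1L],
         POOL_SUFFIX[((i - 1L) %/% 96L) %% 3L + 1L])
}

injury_disease_name <- function(i) {
  paste0(POOL_BODY[(i - 1L) %% 10L + 1L],
         POOL_INJURY[((i - 1L) %/% 10L) %% 5L + 1L])
}

drug_name <- function(i) {
  paste0(POOL_DRUG_SYL[(i - 1L) %% 20L + 1L],
         POOL_DRUG_SYL[((i - 1L) %/% 20L) %% 20L + 1L],
         POOL_DRUG_SYL[((i - 1L) %/% 400L) %% 20L + 1L])
}

#' Generator parameters
#'
#' Defaults emulate claim statistics reported for large claim corpora:
#' 1.5 diagnoses and 2.3 drugs per claim on average; counts are drawn as
#' `1 + Poisson(mean - 1)` so every claim has at least one of each.
#'
#' @param seed RNG seed (all generators are bit-reproducible given it)
#' @param n_diseases,n_drugs leaf disease / generic drug counts
#' @param atc_depth,atc_branching shape of the ATC taxonomy below its root
#' @param indication_density Bernoulli rate per (drug, disease) pair
#' @param contraindication_rate Bernoulli rate per (drug, disease) pair
#' @param interaction_rate Bernoulli rate per ATC node pair
#' @param n_claims claims per batch
#' @param mean_diagnoses,mean_drugs average terms per claim
#' @param event_rates per-claim planting probability per scenario
#' @param typo_rates per-term probability of each corruption mode
#' @return a `generator_params` list
#' @export
generator_params <- function(seed = 1L, n_diseases = 90L, n_drugs = 85L,
                             atc_depth = 2L, atc_branching = 4L,
                             indication_density = 0.04,
                             contraindication_rate = 0.01,
                             interaction_rate = 0.10,
                             n_claims = 100L,
                             mean_diagnoses = 1.5, mean_drugs = 2.3,
                             event_rates = list(fraud_diagnosis = 0,
                                                excess_prescription = 0,
                                                irrational_prescription = 0),
                             typo_rates = list(homophone = 0, radical = 0,
                                               drop = 0)) {
  rates <- c(indication_density, contraindication_rate, interaction_rate,
             unlist(event_rates), unlist(typo_rates))
  if (any(rates < 0 | rates > 1))
    abort_mkg("all rates must lie in [0, 1]", "mkg_argument_error")
  ints <- c(n_diseases, n_drugs, atc_depth, atc_branching, n_claims)
  if (any(ints < 1))
    abort_mkg("sizes must be positive integers", "mkg_argument_error")
  if (mean_diagnoses < 1 || mean_drugs < 1)
    abort_mkg("per-claim means must be >= 1", "mkg_argument_error")
  structure(list(seed = as.integer(seed), n_diseases = as.integer(n_diseases),
                 n_drugs = as.integer(n_drugs), atc_depth = as.integer(atc_depth),
                 atc_branching = as.integer(atc_branching),
                 indication_density = indication_density,
                 contraindication_rate = contraindication_rate,
                 interaction_rate = interaction_rate,
                 n_claims = as.integer(n_claims),
                 mean_diagnoses = mean_diagnoses, mean_drugs = mean_drugs,
                 event_rates = event_rates, typo_rates = typo_rates),
            class = "generator_params")
}

#' Generate a toy medical knowledge graph
#'
#' Builds an ATC taxonomy of the requested depth/branching with generic
#' drugs attached round-robin to its leaves, a two-level disease taxonomy
#' (organ-pattern and body-injury families under family parents), sampled
#' indication/contraindication edges (every drug is guaranteed at least one
#' indication), and interaction edges between ATC classes with subtypes
#' promotion/contraindication/none. A few ATC leaves are guaranteed to hold
#' two drugs sharing an indication so that excess-prescription events can be
#' planted. Schema-valid by construction and deterministic given the seed.
#'
#' @param params a [generator_params()]
#' @return an `mkg` object
#' @export
generate_toy_kg <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  n_leaves <- params$atc_branching^params$atc_depth
  if (params$n_diseases > 288L + 50L)
    abort_mkg("fixture vocabulary supports at most 338 diseases",
              "mkg_argument_error")
  if (params$n_drugs > 8000L)
    abort_mkg("fixture vocabulary supports at most 8000 drugs",
              "mkg_argument_error")
  with_seed(params$seed, {
    graph <- kg_new()
    # ---- ATC taxonomy --------------------------------------------------
    root_id <- "A_ROOT"
    graph <- add_node(graph, concept_node(root_id, "药物分类根", "atc",
                                          code = "ATC"))
    level_ids <- list(root_id)
    codes <- list("")
    counter <- 0L
    for (depth in seq_len(params$atc_depth)) {
      prev <- level_ids[[depth]]
      cur <- character(0)
      for (p in seq_along(prev)) {
        for (b in seq_len(params$atc_branching)) {
          counter <- counter + 1L
          code <- if (depth == 1L) LETTERS[(p - 1L) * params$atc_branching + b]
                  else paste0(codes[[depth]][p], sprintf("%02d", b))
          id <- sprintf("A%d", counter)
          graph <- add_node(graph, concept_node(
            id, paste0(code, "类药物"), "atc", code = code))
          graph <- add_edge(graph, relation_edge(id, prev[p], "is_a"))
          cur <- c(cur, id)
          codes[[depth + 1L]] <- c(if (length(codes) > depth)
            codes[[depth + 1L]] else character(0), code)
        }
      }
      level_ids[[depth + 1L]] <- cur
    }
    leaves <- level_ids[[params$atc_depth + 1L]]
    # ---- diseases ------------------------------------------------------
    n_inj <- min(50L, params$n_diseases %/% 3L)
    n_org <- params$n_diseases - n_inj
    disease_ids <- character(0)
    parents_seen <- character(0)
    ensure_parent <- function(graph, pid, pname, code) {
      if (!pid %in% parents_seen) {
        graph <- add_node(graph, concept_node(pid, pname, "disease",
                                              code = code))
        parents_seen <<- c(parents_seen, pid)
      }
      graph
    }
    for (i in seq_len(n_org)) {
      id <- sprintf("D%d", i)
      organ_idx <- (i - 1L) %% 12L + 1L
      pid <- sprintf("DP_org%d", organ_idx)
      graph <- ensure_parent(graph, pid,
                             paste0(POOL_ORGAN[organ_idx], "系统疾病"),
                             sprintf("P%02d", organ_idx))
      graph <- add_node(graph, concept_node(
        id, organ_disease_name(i), "disease", code = sprintf("C%03d", i)))
      graph <- add_edge(graph, relation_edge(id, pid, "is_a"))
      disease_ids <- c(disease_ids, id)
    }
    for (j in seq_len(n_inj)) {
      id <- sprintf("D%d", n_org + j)
      body_idx <- (j - 1L) %% 10L + 1L
      pid <- sprintf("DP_inj%d", body_idx)
      graph <- ensure_parent(graph, pid,
                             paste0(POOL_BODY[body_idx], "损伤"),
                             sprintf("P%02d", 12L + body_idx))
      graph <- add_node(graph, concept_node(
        id, injury_disease_name(j), "disease",
        code = sprintf("C%03d", n_org + j)))
      graph <- add_edge(graph, relation_edge(id, pid, "is_a"))
      disease_ids <- c(disease_ids, id)
    }
    # ---- drugs (generic level), round-robin over ATC leaves ------------
    drug_ids <- character(0)
    for (i in seq_len(params$n_drugs)) {
      id <- sprintf("G%d", i)
      graph <- add_node(graph, concept_node(id, drug_name(i), "drug_generic"))
      graph <- add_edge(graph, relation_edge(
        id, leaves[(i - 1L) %% n_leaves + 1L], "is_a"))
      drug_ids <- c(drug_ids, id)
    }
    # ---- indications ---------------------------------------------------
    ind <- matrix(stats::runif(params$n_drugs * params$n_diseases) <
                    params$indication_density,
                  nrow = params$n_drugs)
    for (i in seq_len(params$n_drugs))
      if (!any(ind[i, ])) ind[i, sample.int(params$n_diseases, 1L)] <- TRUE
    # guarantee excess-prescription structure: on the first few leaves, the
    # two first drugs share one indication
    for (leaf_idx in seq_len(min(3L, n_leaves))) {
      members <- which((seq_len(params$n_drugs) - 1L) %% n_leaves + 1L ==
                         leaf_idx)
      if (length(members) >= 2L) {
        d <- sample.int(params$n_diseases, 1L)
        ind[members[1L], d] <- TRUE
        ind[members[2L], d] <- TRUE
      }
    }
    for (i in seq_len(params$n_drugs))
      for (j in which(ind[i, ]))
        graph <- add_edge(graph, relation_edge(
          drug_ids[i], disease_ids[j], "indication",
          provenance = "generator", confidence = 1.0))
    # ---- contraindications (never where an indication exists) ----------
    contra <- matrix(stats::runif(params$n_drugs * params$n_diseases) <
                       params$contraindication_rate,
                     nrow = params$n_drugs) & !ind
    for (i in seq_len(params$n_drugs))
      for (j in which(contra[i, ]))
        graph <- add_edge(graph, relation_edge(
          drug_ids[i], disease_ids[j], "contraindication",
          provenance = "generator", confidence = 1.0))
    # ---- ATC-level interactions ----------------------------------------
    atc_ids <- setdiff(unlist(level_ids), root_id)
    n_inter <- 0L
    if (length(atc_ids) >= 2L && params$interaction_rate > 0) {
      pairs <- utils::combn(atc_ids, 2L, simplify = FALSE)
      for (p in pairs) {
        if (stats::runif(1) >= params$interaction_rate) next
        subtype <- sample(INTERACTION_SUBTYPES, 1L, prob = c(0.4, 0.4, 0.2))
        graph <- add_edge(graph, relation_edge(
          p[1], p[2], "interaction", subtype = subtype,
          provenance = "generator", confidence = 1.0))
        if (subtype != "none") n_inter <- n_inter + 1L
      }
      if (n_inter == 0L && length(leaves) >= 2L) {
        graph <- add_edge(graph, relation_edge(
          leaves[1L], leaves[length(leaves)], "interaction",
          subtype = "contraindication", provenance = "generator",
          confidence = 1.0))
      }
    }
    validate_graph(graph)
    graph
  })
}

#' Corrupt an entity name with the fixture typo model
#'
#' Applies exactly one corruption drawn according to `rates`: homophone
#' substitution (replace a character by another sharing its pronunciation
#' attribute), radical-sibling substitution (same radical), or component
#' drop (shorten a non-core semantic unit to a lexicon-listed prefix, e.g.
#' a two-character body-structure term to its one-character form). When the
#' drawn mode is impossible for the name, the other non-zero modes are
#' tried; if none applies, the name is returned unchanged with a warning.
#'
#' @param name entity name
#' @param rates named numeric: homophone, radical, drop (relative odds)
#' @param maps attribute maps supplying homophones/radical siblings
#' @param lexicons unit lexicons for component drops
#' @param seed optional seed for a reproducible single draw
#' @return corrupted variant (differs from `name` whenever possible)
#' @export
corrupt_name <- function(name, rates = c(homophone = 1, radical = 0, drop = 0),
                         maps = default_attribute_maps(),
                         lexicons = load_unit_lexicons(), seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, corrupt_name(name, rates, maps,
                                                          lexicons)))
  rates <- rates[c("homophone", "radical", "drop")]
  rates[is.na(rates)] <- 0
  if (sum(rates) <= 0) {
    warning("all typo rates are zero; returning name unchanged")
    return(name)
  }
  map_by_name <- stats::setNames(maps, vapply(maps, `[[`, character(1), "name"))
  substitute_via <- function(map) {
    if (is.null(map)) return(NULL)
    cs <- chars(name)
    pos_ok <- which(vapply(cs, function(c1) {
      v <- map$table[c1]
      !is.na(v) && any(map$table == v & names(map$table) != c1)
    }, logical(1)))
    if (length(pos_ok) == 0) return(NULL)
    pos <- if (length(pos_ok) == 1L) pos_ok else sample(pos_ok, 1L)
    v <- map$table[cs[pos]]
    alts <- names(map$table)[map$table == v & names(map$table) != cs[pos]]
    cs[pos] <- if (length(alts) == 1L) alts else sample(alts, 1L)
    paste(cs, collapse = "")
  }
  drop_component <- function() {
    units <- decompose(name, lexicons)
    for (k in seq_along(units)) {
      u <- units[[k]]
      if (u$ucat == "core_term" || nchar(u$text) < 2L) next
      for (len in seq(nchar(u$text) - 1L, 1L)) {
        short <- substr(u$text, 1L, len)
        if (short %in% lexicons[[u$ucat]]) {
          units[[k]]$text <- short
          return(paste(vapply(units, `[[`, character(1), "text"),
                       collapse = ""))
        }
      }
    }
    NULL
  }
  apply_mode <- function(mode) {
    switch(mode,
           homophone = substitute_via(map_by_name[["pronunciation"]]),
           radical = substitute_via(map_by_name[["radical"]]),
           drop = drop_component())
  }
  order_modes <- sample(names(rates), 3L, prob = pmax(rates, 1e-12))
  # drawn mode first, then remaining non-zero modes as fallbacks
  for (mode in order_modes) {
    if (rates[mode] <= 0) next
    variant <- apply_mode(mode)
    if (!is.null(variant) && variant != name) return(variant)
  }
  warning(sprintf("no applicable corruption for '%s'; returned unchanged",
                  name))
  name
}

# shifted-Poisson count with mean m >= 1
draw_count <- function(m) 1L + stats::rpois(1L, m - 1)

# detector-premise checks used to keep unplanted claims clean; these mirror
# the rule premises (coverage, shared ATC parent, expanded interaction)
claim_conflicts <- function(graph, diag_ids, drug_ids, anc_cache) {
  e <- graph$edges
  conflicts <- character(0)
  # shared direct ATC parent
  parents <- lapply(drug_ids, function(g)
    e$target[e$rel_type == "is_a" & e$source == g])
  if (anyDuplicated(unlist(parents)))
    conflicts <- c(conflicts, "shared_atc_parent")
  # interactions between expanded ATC sets (or direct)
  if (length(drug_ids) >= 2L) {
    for (p in utils::combn(drug_ids, 2L, simplify = FALSE)) {
      a1 <- anc_cache[[p[1]]]$node; a2 <- anc_cache[[p[2]]]$node
      rows <- which(e$rel_type == "interaction" & e$subtype != "none" &
                      ((e$source %in% c(a1, p[1]) & e$target %in% c(a2, p[2])) |
                         (e$source %in% c(a2, p[2]) & e$target %in% c(a1, p[1]))))
      if (length(rows)) {
        conflicts <- c(conflicts, "interacting_pair")
        break
      }
    }
  }
  # contraindications drug (expanded) vs claimed diseases (adjacency)
  for (g in drug_ids) {
    contra <- drug_disease_links(graph, g, "contraindication")
    if (length(contra) == 0) next
    contra_d <- vapply(contra, `[[`, character(1), "disease")
    for (d in diag_ids) {
      adj <- disease_neighbourhood(graph, d)$node
      if (any(contra_d %in% adj)) {
        conflicts <- c(conflicts, "contraindicated_pair")
        break
      }
    }
    if ("contraindicated_pair" %in% conflicts) break
  }
  unique(conflicts)
}

# full detector-style coverage test: is disease d covered by drug g?
covers <- function(graph, g, d) {
  links <- drug_disease_links(graph, g, "indication")
  if (length(links) == 0) return(FALSE)
  targets <- vapply(links, `[[`, character(1), "disease")
  any(targets %in% disease_neighbourhood(graph, d)$node)
}

#' Generate a claim batch with planted FWA events
#'
#' Unplanted claims are consistent by construction: every claimed disease is
#' directly indicated by a claimed drug, every claimed drug covers a claimed
#' disease, no two drugs share an ATC parent, no drug pair interacts (after
#' ATC expansion), and no claimed drug is contraindicated for a claimed
#' disease. Planted events then inject, per scenario and at the configured
#' rates: an uncovered diagnosis (fraud), a same-ATC drug duplication for
#' one diagnosis (excess), or an interacting drug pair (irrational), and the
#' planted truth is recorded. Surface terms are the node names, optionally
#' corrupted by the typo model.
#'
#' @param graph graph from [generate_toy_kg()]
#' @param params a [generator_params()] (uses n_claims, means, event and
#'   typo rates, and `seed + 1` so graph and claims draws are decoupled)
#' @return list with `claims` (claim documents), `truth` (claim_id ->
#'   list of planted events), and `params`
#' @export
generate_claims <- function(graph, params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  e <- graph$edges
  disease_ids <- nodes_of_category(graph, "disease")
  leaf_diseases <- disease_ids[!disease_ids %in%
                                 e$target[e$rel_type == "is_a"]]
  drug_ids <- nodes_of_category(graph, DRUG_CATEGORIES)
  ind_rows <- which(e$rel_type == "indication")
  drugs_for <- split(e$source[ind_rows], e$target[ind_rows])
  covered_diseases <- intersect(leaf_diseases, names(drugs_for))
  if (length(covered_diseases) == 0)
    abort_mkg("graph has no indicated disease to build claims from",
              "mkg_generation_error")
  anc_cache <- stats::setNames(
    lapply(drug_ids, function(g) atc_ancestry(graph, g)), drug_ids)
  rates <- params$event_rates
  # planting inventories
  need <- function(r) !is.null(r) && r > 0
  excess_triples <- list()
  if (need(rates$excess_prescription)) {
    parents <- split(e$source[e$rel_type == "is_a" & e$source %in% drug_ids],
                     e$target[e$rel_type == "is_a" & e$source %in% drug_ids])
    for (a in names(parents)) {
      gs <- parents[[a]]
      if (length(gs) < 2L) next
      for (p in utils::combn(gs, 2L, simplify = FALSE)) {
        d1 <- e$target[ind_rows][e$source[ind_rows] == p[1]]
        d2 <- e$target[ind_rows][e$source[ind_rows] == p[2]]
        common <- intersect(d1, d2)
        for (d in common)
          excess_triples[[length(excess_triples) + 1L]] <- c(p, d)
      }
    }
    if (length(excess_triples) == 0)
      abort_mkg(paste("cannot plant excess-prescription events: no ATC class",
                      "holds two drugs sharing an indication"),
                "mkg_generation_error")
  }
  irrational_pairs <- list()
  if (need(rates$irrational_prescription)) {
    inter_rows <- which(e$rel_type == "interaction" & e$subtype != "none")
    if (length(inter_rows) == 0)
      abort_mkg("cannot plant irrational-prescription events: graph has no non-none interaction edges",
                "mkg_generation_error")
    for (i in seq_along(drug_ids)) {
      for (j in seq_len(i - 1L)) {
        g1 <- drug_ids[i]; g2 <- drug_ids[j]
        a1 <- c(anc_cache[[g1]]$node, g1); a2 <- c(anc_cache[[g2]]$node, g2)
        hit <- any((e$source[inter_rows] %in% a1 &
                      e$target[inter_rows] %in% a2) |
                     (e$source[inter_rows] %in% a2 &
                        e$target[inter_rows] %in% a1))
        if (hit)
          irrational_pairs[[length(irrational_pairs) + 1L]] <- c(g1, g2)
      }
    }
    if (length(irrational_pairs) == 0)
      abort_mkg("cannot plant irrational-prescription events: no drug pair reaches an interaction edge",
                "mkg_generation_error")
  }
  maps <- default_attribute_maps()
  lexicons <- load_unit_lexicons()
  typo_rates <- unlist(params$typo_rates)[c("homophone", "radical", "drop")]
  typo_rates[is.na(typo_rates)] <- 0
  typo_total <- sum(typo_rates)
  surface <- function(id) graph$nodes[[id]]$name
  maybe_corrupt <- function(term) {
    if (typo_total <= 0 || stats::runif(1) >= typo_total) return(term)
    suppressWarnings(corrupt_name(term, typo_rates, maps, lexicons))
  }
  # per-drug caches for the compatibility checks below
  inter_rows <- which(e$rel_type == "interaction" & e$subtype != "none")
  parent_of <- stats::setNames(lapply(drug_ids, function(g)
    e$target[e$rel_type == "is_a" & e$source == g]), drug_ids)
  contra_of <- stats::setNames(lapply(drug_ids, function(g) {
    links <- drug_disease_links(graph, g, "contraindication")
    unique(vapply(links, `[[`, character(1), "disease"))
  }), drug_ids)
  adj_of <- new.env(parent = emptyenv())
  adjacency <- function(d) {
    hit <- adj_of[[d]]
    if (is.null(hit)) {
      hit <- disease_neighbourhood(graph, d)$node
      adj_of[[d]] <- hit
    }
    hit
  }
  # can drug `cand` join `cur` drugs for diagnoses `diag_all` without
  # creating any detector premise?
  compatible <- function(cand, cur, diag_all) {
    for (g0 in cur) {
      if (any(parent_of[[cand]] %in% parent_of[[g0]])) return(FALSE)
      a1 <- c(anc_cache[[cand]]$node, cand)
      a2 <- c(anc_cache[[g0]]$node, g0)
      if (any((e$source[inter_rows] %in% a1 & e$target[inter_rows] %in% a2) |
                (e$source[inter_rows] %in% a2 & e$target[inter_rows] %in% a1)))
        return(FALSE)
    }
    if (length(contra_of[[cand]]))
      for (d in diag_all)
        if (any(contra_of[[cand]] %in% adjacency(d))) return(FALSE)
    TRUE
  }
  with_seed(params$seed + 1L, {
    claims <- vector("list", params$n_claims)
    truth <- list()
    for (ci in seq_len(params$n_claims)) {
      cid <- sprintf("CL%05d", ci)
      # clean base claim: drugs are chosen per diagnosis, each candidate
      # screened for compatibility, so the drawn counts survive intact
      base <- NULL
      for (attempt in seq_len(60L)) {
        nd <- min(draw_count(params$mean_diagnoses), length(covered_diseases))
        ng <- draw_count(params$mean_drugs)
        # draw diagnoses one by one; a disease whose every indicating drug is
        # incompatible with the current selection is redrawn, not the whole
        # claim, so the per-claim counts keep their target distribution
        diag_ids <- character(0)
        dr <- character(0)
        pool_d <- sample(covered_diseases)
        pi <- 1L
        while (length(diag_ids) < nd && pi <= length(pool_d)) {
          d <- pool_d[pi]; pi <- pi + 1L
          if (any(vapply(dr, function(g)
            any(contra_of[[g]] %in% adjacency(d)), logical(1)))) next
          if (any(dr %in% drugs_for[[d]])) {  # already covered
            diag_ids <- c(diag_ids, d)
            next
          }
          picked <- FALSE
          for (cand in sample(drugs_for[[d]])) {
            if (compatible(cand, dr, c(diag_ids, d))) {
              dr <- c(dr, cand); picked <- TRUE; break
            }
          }
          if (picked) diag_ids <- c(diag_ids, d)
        }
        if (length(diag_ids) < nd) next
        extra_pool <- setdiff(unique(unlist(drugs_for[diag_ids])), dr)
        for (cand in sample(extra_pool)) {
          if (length(dr) >= ng) break
          if (compatible(cand, dr, diag_ids)) dr <- c(dr, cand)
        }
        if (length(claim_conflicts(graph, diag_ids, dr, anc_cache)) == 0L) {
          base <- list(diagnoses = diag_ids, drugs = dr)
          break
        }
      }
      if (is.null(base))
        abort_mkg(sprintf("could not build a clean claim after 60 attempts (%s)",
                          cid), "mkg_generation_error")
      events <- list()
      # at most one planted event per claim, drawn by the scenario rates,
      # so planted structures cannot interfere with one another
      u <- stats::runif(1)
      r_fraud <- if (need(rates$fraud_diagnosis)) rates$fraud_diagnosis else 0
      r_excess <- if (need(rates$excess_prescription))
        rates$excess_prescription else 0
      r_irr <- if (need(rates$irrational_prescription))
        rates$irrational_prescription else 0
      plant <- if (u < r_fraud) "fraud"
               else if (u < r_fraud + r_excess) "excess"
               else if (u < r_fraud + r_excess + r_irr) "irrational"
               else "none"
      # fraud: add a diagnosis covered by none of the claim's drugs
      if (plant == "fraud") {
        pool <- sample(setdiff(leaf_diseases, base$diagnoses))
        for (d in pool) {
          if (!any(vapply(base$drugs, covers, logical(1), graph = graph,
                          d = d)) &&
              length(claim_conflicts(graph, d, base$drugs, anc_cache)) == 0L) {
            base$diagnoses <- c(base$diagnoses, d)
            events[[length(events) + 1L]] <- list(
              scenario = "fraud_diagnosis", involved = d)
            break
          }
        }
      }
      # excess: add a same-ATC drug pair indicated for one added diagnosis
      if (plant == "excess") {
        for (tri in sample(excess_triples)) {
          gs <- tri[1:2]; d <- tri[3]
          if (any(gs %in% base$drugs)) next
          cand_drugs <- c(base$drugs, gs)
          # the planted pair shares an ATC parent by construction; any other
          # conflict (interaction, contraindication) rejects the triple
          confl <- claim_conflicts(graph, c(base$diagnoses, d), cand_drugs,
                                   anc_cache)
          if (length(setdiff(confl, "shared_atc_parent"))) next
          base$diagnoses <- unique(c(base$diagnoses, d))
          base$drugs <- cand_drugs
          events[[length(events) + 1L]] <- list(
            scenario = "excess_prescription", involved = c(d, gs))
          break
        }
      }
      # irrational: add an interacting drug pair (plus a covered diagnosis
      # for each so the addition stays otherwise clean)
      if (plant == "irrational") {
        has_interaction <- function(x, y) {
          a1 <- c(anc_cache[[x]]$node, x); a2 <- c(anc_cache[[y]]$node, y)
          rows <- which(e$rel_type == "interaction" & e$subtype != "none")
          any((e$source[rows] %in% a1 & e$target[rows] %in% a2) |
                (e$source[rows] %in% a2 & e$target[rows] %in% a1))
        }
        for (pr in sample(irrational_pairs)) {
          if (any(pr %in% base$drugs)) next
          ds <- character(0)
          ok <- TRUE
          for (g in pr) {
            dg <- e$target[ind_rows][e$source[ind_rows] == g]
            dg <- intersect(dg, leaf_diseases)
            if (length(dg) == 0) { ok <- FALSE; break }
            ds <- c(ds, dg[1])
          }
          if (!ok) next
          # the planted pair must be the only interacting pair, and the
          # addition must create no other conflict
          for (x in pr) for (y in base$drugs)
            if (has_interaction(x, y)) { ok <- FALSE; break }
          if (!ok) next
          diag_all <- unique(c(base$diagnoses, ds))
          drugs_all <- c(base$drugs, pr)
          parents_all <- unlist(lapply(drugs_all, function(g)
            e$target[e$rel_type == "is_a" & e$source == g]))
          if (anyDuplicated(parents_all)) next
          confl <- claim_conflicts(graph, diag_all, drugs_all, anc_cache)
          if (length(setdiff(confl, "interacting_pair"))) next
          base$diagnoses <- diag_all
          base$drugs <- drugs_all
          events[[length(events) + 1L]] <- list(
            scenario = "irrational_prescription", involved = pr)
          break
        }
      }
      claims[[ci]] <- structure(list(
        claim_id = cid,
        diagnoses = vapply(base$diagnoses, function(d)
          maybe_corrupt(surface(d)), character(1), USE.NAMES = FALSE),
        drugs = vapply(base$drugs, function(g)
          maybe_corrupt(surface(g)), character(1), USE.NAMES = FALSE),
        examinations = character(0),
        age = sample(1:90, 1L),
        sex = sample(c("F", "M"), 1L)), class = "claim_document")
      if (length(events)) truth[[cid]] <- events
    }
    list(claims = claims, truth = truth, params = params)
  })
}

#' Write / read planted truth as JSON
#'
#' @param truth truth list from [generate_claims()]
#' @param path file path
#' @return invisibly the path / the truth list
#' @export
write_truth <- function(truth, path) {
  payload <- lapply(truth, function(events) lapply(events, function(ev)
    list(scenario = jsonlite::unbox(ev$scenario), involved = ev$involved)))
  con <- file(path, open = "w", encoding = "UTF-8")
  writeLines(jsonlite::toJSON(payload, null = "null"), con, useBytes = TRUE)
  close(con)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::fromJSON(readLines(file(path, encoding = "UTF-8"),
                                      warn = FALSE),
                            simplifyVector = FALSE)
  lapply(raw, function(events) lapply(events, function(ev)
    list(scenario = ev$scenario, involved = unlist(ev$involved))))
}

#' Evaluate a screening report against planted truth
#'
#' A planted event counts as detected when the report holds a finding of the
#' same scenario in the same claim whose involved entities overlap the
#' planted ones. Precision counts findings matched by some planted event.
#' An empty-truth/empty-findings scenario scores 1.0 by convention.
#'
#' @param report a `screening_report`
#' @param truth truth list from [generate_claims()]
#' @return data.frame with per-scenario and overall events, detected,
#'   findings, precision, recall
#' @export
evaluate_detectors <- function(report, truth) {
  report_ids <- vapply(report$claims, `[[`, character(1), "claim_id")
  missing <- setdiff(names(truth), report_ids)
  if (length(missing))
    abort_mkg(sprintf("truth claims not in report: %s",
                      paste(missing, collapse = ", ")), "mkg_argument_error")
  scenarios <- c("fraud_diagnosis", "excess_prescription",
                 "irrational_prescription")
  findings_by_claim <- stats::setNames(
    lapply(report$claims, `[[`, "findings"), report_ids)
  res <- data.frame(scenario = scenarios, events = 0L, detected = 0L,
                    findings = 0L, matched_findings = 0L,
                    stringsAsFactors = FALSE)
  matched_flag <- list()
  for (cid in names(truth)) {
    for (ev in truth[[cid]]) {
      i <- match(ev$scenario, scenarios)
      res$events[i] <- res$events[i] + 1L
      hit <- FALSE
      for (k in seq_along(findings_by_claim[[cid]])) {
        f <- findings_by_claim[[cid]][[k]]
        if (f$scenario != ev$scenario) next
        if (length(ev$involved) == 0 ||
            length(intersect(f$involved, ev$involved)) > 0) {
          hit <- TRUE
          matched_flag[[paste(cid, k)]] <- TRUE
        }
      }
      if (hit) res$detected[i] <- res$detected[i] + 1L
    }
  }
  for (cid in report_ids) {
    for (k in seq_along(findings_by_claim[[cid]])) {
      f <- findings_by_claim[[cid]][[k]]
      i <- match(f$scenario, scenarios)
      res$findings[i] <- res$findings[i] + 1L
      if (!is.null(matched_flag[[paste(cid, k)]]))
        res$matched_findings[i] <- res$matched_findings[i] + 1L
    }
  }
  res$recall <- ifelse(res$events == 0, 1, res$detected / res$events)
  res$precision <- ifelse(res$findings == 0, 1,
                          res$matched_findings / res$findings)
  overall <- data.frame(scenario = "overall", events = sum(res$events),
                        detected = sum(res$detected),
                        findings = sum(res$findings),
                        matched_findings = sum(res$matched_findings),
                        recall = if (sum(res$events) == 0) 1 else
                          sum(res$detected) / sum(res$events),
                        precision = if (sum(res$findings) == 0) 1 else
                          sum(res$matched_findings) / sum(res$findings))
  rbind(res, overall)
}
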