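# Multilevel fuzzy entity linking: a weighted edit distance whose
# substitution cost is discounted when two characters share an attribute
# (same pronunciation -> homophone typos, same radical -> visually/semantically
# sibling characters), combined with semantic-unit decomposition of entity
# names (body structure, type/stage, negation, ... , core term) so that
# clinically critical differences (type 1 vs type 2) are never smoothed away
# by high surface similarity. Candidates are retrieved from an inverted
# index and reranked by the composite score; mentions whose best score stays
# below the linking threshold are declared unknown and queued for curation.

#' Construct an edit-cost scheme
#'
#' @param insert,delete costs of inserting/deleting one character (> 0)
#' @param sub_full substitution cost for unrelated characters (> 0)
#' @param discounts named numeric vector of discounted substitution costs,
#'   one per attribute level (names must match attribute-map names); each
#'   must lie strictly between 0 and `sub_full`. The effective substitution
#'   cost of a character pair is the minimum over applicable levels.
#' @return a `cost_scheme` object
#' @export
cost_scheme <- function(insert = 1, delete = 1, sub_full = 1,
                        discounts = c(pronunciation = 0.2, radical = 0.5)) {
  if (any(c(insert, delete, sub_full) <= 0))
    abort_mkg("insert, delete, and sub_full costs must be positive",
              "mkg_argument_error")
  if (length(discounts) && (is.null(names(discounts)) ||
                            any(!nzchar(names(discounts)))))
    abort_mkg("discounts must be named by attribute level",
              "mkg_argument_error")
  if (any(discounts <= 0) || any(discounts >= sub_full))
    abort_mkg("discounted substitution costs must satisfy 0 < cost < sub_full",
              "mkg_argument_error")
  structure(list(insert = insert, delete = delete, sub_full = sub_full,
                 discounts = discounts), class = "cost_scheme")
}

# substitution cost of two characters under the maps/costs
char_sub_cost <- function(ca, cb, maps, costs) {
  if (ca == cb) return(0)
  best <- costs$sub_full
  for (m in maps) {
    d <- costs$discounts[m$name]
    if (is.na(d)) next
    va <- m$table[ca]; vb <- m$table[cb]
    if (!is.na(va) && !is.na(vb) && va == vb && d < best) best <- unname(d)
  }
  best
}

#' Multilevel weighted edit distance
#'
#' Standard dynamic-programming edit distance over characters, except that
#' substituting two characters that share an attribute on some level (e.g.
#' the same pronunciation, so one is a homophone typo of the other) costs
#' that level's discounted cost instead of the full substitution cost. With
#' no maps this reduces to plain weighted edit distance, and the multilevel
#' distance never exceeds it.
#'
#' @param a,b strings
#' @param maps list of [attribute_map()] objects (may be empty)
#' @param costs a [cost_scheme()]
#' @return non-negative real distance; 0 iff `a == b`
#' @export
#' @examples
#' maps <- default_attribute_maps()
#' multilevel_distance("唐尿病", "糖尿病", maps)  # 0.2: homophone discount
#' multilevel_distance("唐尿病", "糖尿病")        # 1.0: plain edit distance
multilevel_distance <- function(a, b, maps = list(), costs = cost_scheme()) {
  stopifnot(inherits(costs, "cost_scheme"))
  ca <- chars(a); cb <- chars(b)
  la <- length(ca); lb <- length(cb)
  if (la == 0) return(lb * costs$insert)
  if (lb == 0) return(la * costs$delete)
  prev <- (0:lb) * costs$insert
  for (i in seq_len(la)) {
    cur <- numeric(lb + 1L)
    cur[1] <- i * costs$delete
    for (j in seq_len(lb)) {
      cur[j + 1L] <- min(
        prev[j + 1L] + costs$delete,
        cur[j] + costs$insert,
        prev[j] + char_sub_cost(ca[i], cb[j], maps, costs))
    }
    prev <- cur
  }
  prev[lb + 1L]
}

#' Normalized string similarity
#'
#' `1 - distance / (max(len(a), len(b)) * max_unit_cost)` where
#' `max_unit_cost = max(insert, delete, sub_full)`; equals 1 iff the
#' distance is 0, lies in `[0, 1]`, and two empty strings compare as 1.
#'
#' @inheritParams multilevel_distance
#' @return similarity in `[0, 1]`
#' @export
string_similarity <- function(a, b, maps = list(), costs = cost_scheme()) {
  la <- length(chars(a)); lb <- length(chars(b))
  if (la == 0 && lb == 0) return(1)
  d <- multilevel_distance(a, b, maps, costs)
  max_unit <- max(costs$insert, costs$delete, costs$sub_full)
  max(0, min(1, 1 - d / (max(la, lb) * max_unit)))
}

#' Decompose an entity name into semantic units
#'
#' Greedy longest-match segmentation against the category lexicons
#' (priority: lexicon order, used only to break equal-length ties); maximal
#' stretches not covered by any lexicon term become `core_term` units. The
#' concatenation of unit texts always reproduces the name.
#'
#' @param name entity name
#' @param lexicons named list category -> character vector of unit terms
#' @return list of units, each `list(text, ucat)`
#' @export
#' @examples
#' lex <- load_unit_lexicons()
#' decompose("手部擦伤", lex)  # body_structure "手部" + core_term "擦伤"
decompose <- function(name, lexicons = load_unit_lexicons()) {
  cs <- chars(name)
  n <- length(cs)
  if (n == 0) return(list())
  maxlen <- max(c(1L, nchar(unlist(lexicons, use.names = FALSE))))
  units <- list()
  residue <- character(0)
  flush_residue <- function() {
    if (length(residue)) {
      units[[length(units) + 1L]] <<- list(
        text = paste(residue, collapse = ""), ucat = "core_term")
      residue <<- character(0)
    }
  }
  i <- 1L
  while (i <= n) {
    hit_cat <- NA_character_; hit_len <- 0L
    for (len in seq(min(maxlen, n - i + 1L), 1L)) {
      cand <- paste(cs[i:(i + len - 1L)], collapse = "")
      for (cat in names(lexicons)) {
        if (cand %in% lexicons[[cat]]) { hit_cat <- cat; hit_len <- len; break }
      }
      if (hit_len > 0L) break
    }
    if (hit_len > 0L) {
      flush_residue()
      units[[length(units) + 1L]] <- list(
        text = paste(cs[i:(i + hit_len - 1L)], collapse = ""), ucat = hit_cat)
      i <- i + hit_len
    } else {
      residue <- c(residue, cs[i])
      i <- i + 1L
    }
  }
  flush_residue()
  units
}

#' Similarity of two semantic units of the same category
#'
#' 1 for identical texts; otherwise the synonym-graph edge weight when the
#' two units are adjacent in the category subgraph; otherwise the best
#' 2-hop path product; otherwise the multilevel string similarity of the
#' two texts (so units like "arm"/"forelimb" score high via the synonym
#' graph even with disjoint surface forms).
#'
#' @param u,v units as returned by [decompose()]; categories must agree
#' @param synonyms data.frame from [load_unit_synonyms()]
#' @param maps,costs forwarded to [string_similarity()] for the fallback
#' @return similarity in `[0, 1]`
#' @export
unit_similarity <- function(u, v, synonyms = load_unit_synonyms(),
                            maps = list(), costs = cost_scheme()) {
  if (!identical(u$ucat, v$ucat))
    abort_mkg("unit categories differ", "mkg_argument_error")
  if (identical(u$text, v$text)) return(1)
  syn <- synonyms[synonyms$category == u$ucat, , drop = FALSE]
  if (nrow(syn)) {
    w_direct <- syn$weight[(syn$u == u$text & syn$v == v$text) |
                             (syn$v == u$text & syn$u == v$text)]
    if (length(w_direct)) return(max(w_direct))
    # 2-hop: best product through one intermediate unit
    nb <- function(x) {
      rbind(data.frame(other = syn$v[syn$u == x], w = syn$weight[syn$u == x]),
            data.frame(other = syn$u[syn$v == x], w = syn$weight[syn$v == x]))
    }
    nu <- nb(u$text); nv <- nb(v$text)
    common <- intersect(nu$other, nv$other)
    if (length(common)) {
      best <- max(vapply(common, function(m)
        max(nu$w[nu$other == m]) * max(nv$w[nv$other == m]), numeric(1)))
      return(best)
    }
  }
  string_similarity(u$text, v$text, maps, costs)
}

#' Linker configuration
#'
#' @param maps attribute maps used by the string level (set `list()` for a
#'   plain-edit-distance linker)
#' @param costs a [cost_scheme()]
#' @param lexicons semantic-unit lexicons (`NULL` disables unit
#'   decomposition, leaving a pure string-level linker)
#' @param synonyms unit synonym graph
#' @param w_string weight of the string-level similarity
#' @param w_unit weight of each aligned unit category (scalar, or named
#'   vector per category)
#' @param critical categories whose mismatch caps the final score
#' @param cap score ceiling applied on a critical-category mismatch
#' @param tau linking threshold: best score >= tau links, otherwise the
#'   mention is unknown
#' @param band curation band `[low, tau)` exported for human review
#' @param k number of candidates retrieved before reranking
#' @return a `linker_config` list
#' @export
linker_config <- function(maps = default_attribute_maps(),
                          costs = cost_scheme(),
                          lexicons = load_unit_lexicons(),
                          synonyms = load_unit_synonyms(),
                          w_string = 1, w_unit = 1,
                          critical = c("type_stage", "negation"),
                          cap = 0.3, tau = 0.75,
                          band = c(0.5, 0.75), k = 20L) {
  if (w_string < 0 || any(w_unit < 0) || (w_string + sum(w_unit)) <= 0)
    abort_mkg("weights must be non-negative with positive sum",
              "mkg_argument_error")
  structure(list(maps = maps, costs = costs, lexicons = lexicons,
                 synonyms = synonyms, w_string = w_string, w_unit = w_unit,
                 critical = critical, cap = cap, tau = tau, band = band,
                 k = as.integer(k)),
            class = "linker_config")
}

unit_weight <- function(config, category) {
  w <- config$w_unit
  if (!is.null(names(w)) && category %in% names(w)) return(unname(w[category]))
  if (length(w) == 1) return(unname(w[1]))
  1
}

# concatenate multiple units of one category into one comparison unit
units_by_category <- function(units) {
  cats <- vapply(units, `[[`, character(1), "ucat")
  out <- list()
  for (cat in unique(cats)) {
    texts <- vapply(units[cats == cat], `[[`, character(1), "text")
    out[[cat]] <- list(text = paste(texts, collapse = ""), ucat = cat)
  }
  out
}

#' Composite mention/candidate similarity
#'
#' Weighted combination of the string-level similarity and per-category
#' semantic-unit similarities: categories present on both sides contribute
#' their unit similarity, categories present on only one side contribute 0;
#' the result is divided by the total applicable weight. A mismatch in a
#' critical category (default: type/stage, negation) caps the final score at
#' `config$cap`, so near-identical surface forms of clinically distinct
#' entities (type 1 vs type 2 diabetes) never become linkable.
#'
#' @param mention,candidate_name strings to compare
#' @param config a [linker_config()]
#' @return list with `score` and `breakdown` (string score, per-category
#'   unit scores, cap flag)
#' @export
composite_similarity <- function(mention, candidate_name,
                                 config = linker_config()) {
  s0 <- string_similarity(mention, candidate_name, config$maps, config$costs)
  if (is.null(config$lexicons))
    return(list(score = s0, breakdown = list(string = s0, units = list(),
                                             capped = FALSE)))
  mu <- units_by_category(decompose(mention, config$lexicons))
  cu <- units_by_category(decompose(candidate_name, config$lexicons))
  cats <- union(names(mu), names(cu))
  total_w <- config$w_string
  acc <- config$w_string * s0
  unit_scores <- list()
  capped <- FALSE
  for (cat in cats) {
    w <- unit_weight(config, cat)
    sim <- if (!is.null(mu[[cat]]) && !is.null(cu[[cat]])) {
      unit_similarity(mu[[cat]], cu[[cat]], config$synonyms,
                      config$maps, config$costs)
    } else 0
    unit_scores[[cat]] <- sim
    acc <- acc + w * sim
    total_w <- total_w + w
    if (cat %in% config$critical && sim < 1) capped <- TRUE
  }
  score <- acc / total_w
  if (capped) score <- min(score, config$cap)
  list(score = score,
       breakdown = list(string = s0, units = unit_scores, capped = capped))
}

# ---- inverted-index retrieval ------------------------------------------

index_keys <- function(text, maps) {
  cs <- unique(chars(tolower(text)))
  keys <- cs
  for (m in maps) {
    vals <- m$table[cs]
    vals <- vals[!is.na(vals)]
    if (length(vals)) keys <- c(keys, paste0(m$name, ":", unique(vals)))
  }
  unique(keys)
}

#' Build an inverted index over graph entity names
#'
#' Posting lists map characters — and character attribute values such as
#' pronunciations, so homophone typos still retrieve their target — to the
#' names and synonyms that contain them.
#'
#' @param graph an `mkg` object
#' @param maps attribute maps contributing attribute-value keys
#' @return an `mkg_index` object
#' @export
build_index <- function(graph, maps = default_attribute_maps()) {
  node_ids <- character(0); names_ <- character(0)
  for (nd in graph$nodes) {
    surf <- unique(c(nd$name, nd$synonyms))
    node_ids <- c(node_ids, rep(nd$node_id, length(surf)))
    names_ <- c(names_, surf)
  }
  post <- new.env(parent = emptyenv())
  exact <- new.env(parent = emptyenv())
  keysets <- vector("list", length(names_))
  for (i in seq_along(names_)) {
    ks <- index_keys(names_[i], maps)
    keysets[[i]] <- ks
    for (k in ks) post[[k]] <- c(post[[k]], i)
    if (is.null(exact[[names_[i]]])) exact[[names_[i]]] <- node_ids[i]
  }
  structure(list(node_id = node_ids, name = names_, keysets = keysets,
                 post = post, exact = exact, maps = maps),
            class = "mkg_index")
}

#' Retrieve linking candidates for a mention
#'
#' Entries are ranked by the number of distinct index keys (characters and
#' attribute values) shared with the mention; ties break toward shorter
#' names, then lexicographically. At most `k` distinct nodes are returned.
#'
#' @param mention surface string
#' @param index an `mkg_index` from [build_index()]
#' @param k maximum number of candidate nodes (> 0)
#' @return data.frame with columns node_id, name, overlap, ranked
#' @export
retrieve_candidates <- function(mention, index, k = 20L) {
  if (k <= 0) abort_mkg("k must be positive", "mkg_argument_error")
  mkeys <- index_keys(mention, index$maps)
  entry_idx <- unique(unlist(lapply(mkeys, function(key) index$post[[key]])))
  if (length(entry_idx) == 0)
    return(data.frame(node_id = character(0), name = character(0),
                      overlap = integer(0)))
  overlap <- vapply(entry_idx, function(i)
    length(intersect(mkeys, index$keysets[[i]])), integer(1))
  nm <- index$name[entry_idx]
  ord <- order(-overlap, nchar(nm), nm, method = "radix")
  entry_idx <- entry_idx[ord]; overlap <- overlap[ord]
  seen <- character(0); keep <- logical(length(entry_idx))
  for (i in seq_along(entry_idx)) {
    nid <- index$node_id[entry_idx[i]]
    if (!nid %in% seen) { keep[i] <- TRUE; seen <- c(seen, nid) }
    if (length(seen) >= k) break
  }
  data.frame(node_id = index$node_id[entry_idx[keep]],
             name = index$name[entry_idx[keep]],
             overlap = overlap[keep], stringsAsFactors = FALSE)
}

#' Link one mention to a graph entity
#'
#' Retrieves candidates from the inverted index, reranks them (against every
#' name and synonym of each candidate node) with [composite_similarity()],
#' and links when the best score reaches the threshold `config$tau`;
#' otherwise the mention is declared unknown, to be added or corrected
#' through the curation loop.
#'
#' @param mention non-empty surface string
#' @param graph an `mkg` object
#' @param index index built from `graph` with [build_index()]
#' @param config a [linker_config()]
#' @return a `link_result`: `list(mention, decision, entity, score,
#'   breakdown, candidates)` with candidates sorted by score
#' @export
link_mention <- function(mention, graph, index, config = linker_config()) {
  if (!nzchar(mention))
    abort_mkg("empty mention", "mkg_argument_error")
  # exact name/synonym match short-circuits retrieval: composite similarity
  # of identical strings is 1, and the candidate cut must never lose it
  exact <- index$exact[[mention]]
  if (!is.null(exact))
    return(structure(list(mention = mention, decision = "linked",
                          entity = exact, score = 1,
                          breakdown = list(string = 1, units = list(),
                                           capped = FALSE),
                          candidates = data.frame(node_id = exact,
                                                  name = mention, score = 1,
                                                  stringsAsFactors = FALSE)),
                     class = "link_result"))
  cand <- retrieve_candidates(mention, index, config$k)
  if (nrow(cand) == 0)
    return(structure(list(mention = mention, decision = "unknown",
                          entity = NA_character_, score = 0,
                          breakdown = NULL,
                          candidates = data.frame(node_id = character(0),
                                                  name = character(0),
                                                  score = numeric(0))),
                     class = "link_result"))
  scores <- numeric(nrow(cand)); breakdowns <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    nd <- graph$nodes[[cand$node_id[i]]]
    best <- list(score = -1, breakdown = NULL)
    for (surf in unique(c(nd$name, nd$synonyms))) {
      cs <- composite_similarity(mention, surf, config)
      if (cs$score > best$score) best <- cs
    }
    scores[i] <- best$score; breakdowns[[i]] <- best$breakdown
  }
  ord <- order(-scores, nchar(cand$name), cand$name, method = "radix")
  cand <- cand[ord, , drop = FALSE]
  scores <- scores[ord]; breakdowns <- breakdowns[ord]
  linked <- scores[1] >= config$tau
  structure(list(
    mention = mention,
    decision = if (linked) "linked" else "unknown",
    entity = if (linked) cand$node_id[1] else NA_character_,
    score = scores[1],
    breakdown = breakdowns[[1]],
    candidates = data.frame(node_id = cand$node_id, name = cand$name,
                            score = scores, stringsAsFactors = FALSE)),
    class = "link_result")
}

#' @export
print.link_result <- function(x, ...) {
  cat(sprintf("<link: '%s' -> %s (score %.3f, %s)>\n", x$mention,
              ifelse(is.na(x$entity), "?", x$entity), x$score, x$decision))
  invisible(x)
}
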