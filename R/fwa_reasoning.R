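# Bounded path-pattern reasoning over the knowledge graph and the three
# claim-screening detectors (fraud diagnosis, excess prescription,
# irrational prescription), each emitting evidence paths as explanation.

#' Default reasoning rules for the three suspicious scenarios
#'
#' Cypher-like bounded path patterns: fraud diagnosis checks indication
#' coverage of each claimed disease by each claimed drug (with one
#' undirected disease taxonomy step and an ATC-sibling extension of the
#' drug); excess prescription flags several claimed drugs under one ATC
#' parent all indicated for one claimed disease; irrational prescription
#' flags claimed drug pairs whose ATC ancestors (up to 3 extra levels) are
#' connected by an interaction edge.
#'
#' @return named character vector of pattern strings
#' @export
default_reasoning_rules <- function() {
  c(fraud_diagnosis =
      "(Disease)-[:is_a]-(Disease)<-[:indication]-(Drug)-[:is_a*0..1]->(ATC)<-[:is_a*0..1]-(Drug)",
    excess_prescription =
      "(Drug)-[:is_a]->(ATC)<-[:is_a]-(Drug)-[:indication]->(Disease)-[:is_a]-(Disease)",
    irrational_prescription =
      "(Drug)-[:is_a]->(ATC)-[:is_a*0..3]->(ATC)<-[:is_a*0..3]-(ATC)<-[:is_a]-(Drug)")
}

#' Parse a Cypher-like path pattern
#'
#' Supports node labels `(Label)`, edge types `[:rel_type]`, direction
#' arrows (`->`, `<-`, or none for an undirected step), and bounded
#' variable-length ranges `*lo..hi`. Round-trips through
#' `format(parse_pattern(x))`.
#'
#' @param text pattern string, e.g. `"(Drug)-[:is_a]->(ATC)"`
#' @return a `path_pattern` with node labels and edge constraints
#' @export
parse_pattern <- function(text) {
  src <- text
  pos <- 1L
  fail <- function(why) abort_mkg(
    sprintf("pattern parse error at position %d ('%s'): %s",
            pos, substr(src, pos, min(nchar(src), pos + 12L)), why),
    "mkg_parse_error")
  take <- function(re) {
    m <- regexpr(re, substr(src, pos, nchar(src)), perl = TRUE)
    if (m != 1L) return(NULL)
    tok <- regmatches(substr(src, pos, nchar(src)), m)
    pos <<- pos + attr(m, "match.length")
    tok
  }
  labels <- character(0)
  edges <- list()
  node_tok <- take("^\\(([A-Za-z_][A-Za-z0-9_]*)\\)")
  if (is.null(node_tok)) fail("expected node '(Label)'")
  labels <- c(labels, sub("^\\((.*)\\)$", "\\1", node_tok))
  while (pos <= nchar(src)) {
    left <- !is.null(take("^<-"))
    if (!left && is.null(take("^-"))) fail("expected edge '-' or '<-'")
    body <- take("^\\[:([a-z_]+)(\\*([0-9]+)\\.\\.([0-9]+))?\\]")
    if (is.null(body)) fail("expected '[:rel_type]' or '[:rel_type*lo..hi]'")
    m <- regmatches(body, regexec(
      "^\\[:([a-z_]+)(\\*([0-9]+)\\.\\.([0-9]+))?\\]$", body))[[1]]
    rel <- m[2]
    lo <- if (nzchar(m[4])) as.integer(m[4]) else 1L
    hi <- if (nzchar(m[5])) as.integer(m[5]) else 1L
    if (lo > hi) fail(sprintf("hop range %d..%d has lo > hi", lo, hi))
    right <- !is.null(take("^->"))
    if (!right && is.null(take("^-"))) fail("expected '-' or '->' after edge")
    if (left && right) fail("edge cannot have arrows on both ends")
    direction <- if (left) "left" else if (right) "right" else "undirected"
    node_tok <- take("^\\(([A-Za-z_][A-Za-z0-9_]*)\\)")
    if (is.null(node_tok)) fail("expected node '(Label)' after edge")
    labels <- c(labels, sub("^\\((.*)\\)$", "\\1", node_tok))
    edges[[length(edges) + 1L]] <- list(rel_type = rel, direction = direction,
                                        lo = lo, hi = hi)
  }
  if (length(labels) < 2)
    abort_mkg("pattern must have at least two node slots", "mkg_parse_error")
  structure(list(labels = labels, edges = edges), class = "path_pattern")
}

#' @export
format.path_pattern <- function(x, ...) {
  out <- sprintf("(%s)", x$labels[1])
  for (i in seq_along(x$edges)) {
    e <- x$edges[[i]]
    star <- if (e$lo != 1L || e$hi != 1L) sprintf("*%d..%d", e$lo, e$hi) else ""
    body <- sprintf("[:%s%s]", e$rel_type, star)
    seg <- switch(e$direction,
                  right = sprintf("-%s->", body),
                  left = sprintf("<-%s-", body),
                  undirected = sprintf("-%s-", body))
    out <- paste0(out, seg, sprintf("(%s)", x$labels[i + 1L]))
  }
  out
}

#' @export
print.path_pattern <- function(x, ...) {
  cat("<path pattern> ", format(x), "\n", sep = "")
  invisible(x)
}

# enumerate walks of length lo..hi from node v along rel edges in the given
# direction; walks are simple within the segment (no repeated node), which
# guarantees termination on cyclic graphs. Returns list(nodes, erows).
segment_walks <- function(graph, v, rel, direction, lo, hi) {
  e <- graph$edges
  rel_rows <- which(e$rel_type == rel)
  out <- list()
  if (lo == 0L) out[[1L]] <- list(nodes = v, erows = integer(0))
  if (hi == 0L) return(out)
  step <- function(nodes, erows) {
    cur <- nodes[length(nodes)]
    cand <- integer(0); nxt <- character(0)
    if (direction %in% c("right", "undirected")) {
      rows <- rel_rows[e$source[rel_rows] == cur]
      cand <- c(cand, rows); nxt <- c(nxt, e$target[rows])
    }
    if (direction %in% c("left", "undirected")) {
      rows <- rel_rows[e$target[rel_rows] == cur]
      cand <- c(cand, rows); nxt <- c(nxt, e$source[rows])
    }
    for (i in seq_along(cand)) {
      w <- nxt[i]
      if (w %in% nodes) next
      nodes2 <- c(nodes, w); erows2 <- c(erows, cand[i])
      if (length(erows2) >= lo)
        out[[length(out) + 1L]] <<- list(nodes = nodes2, erows = erows2)
      if (length(erows2) < hi) step(nodes2, erows2)
    }
  }
  step(v, integer(0))
  out
}

#' Match a path pattern against the graph
#'
#' Enumerates all instantiations of the pattern, optionally anchoring
#' pattern slots to fixed nodes. Undirected steps match either direction; a
#' `*0..hi` step matched with 0 hops collapses its two node slots onto one
#' node (whose already-verified label stands in for the collapsed slot's
#' label). Variable-length segments are simple paths, so matching
#' terminates on cyclic graphs; results are deduplicated.
#'
#' @param graph an `mkg` object
#' @param pattern a `path_pattern` (or pattern string)
#' @param anchors named list/vector mapping slot numbers (as names, 1-based)
#'   to node ids, e.g. `c("1" = "D1", "5" = "G2")`
#' @return list of evidence paths: `list(slots, nodes, erows)` where `slots`
#'   are the node ids bound to the pattern's node slots, `nodes` the full
#'   node chain, and `erows` the graph edge rows traversed
#' @export
match_pattern <- function(graph, pattern, anchors = list()) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  stopifnot(inherits(pattern, "path_pattern"))
  n_slots <- length(pattern$labels)
  anchors <- unlist(anchors)
  if (length(anchors)) {
    slot_ids <- suppressWarnings(as.integer(names(anchors)))
    if (any(is.na(slot_ids)) || any(slot_ids < 1L | slot_ids > n_slots))
      abort_mkg("anchor slots must name node positions within the pattern",
                "mkg_argument_error")
    missing <- setdiff(anchors, names(graph$nodes))
    if (length(missing))
      abort_mkg(sprintf("anchor nodes not in graph: %s",
                        paste(missing, collapse = ", ")), "mkg_lookup_error")
    anchors <- stats::setNames(unname(anchors), slot_ids)
  } else {
    anchors <- character(0)
  }
  slot_ok <- function(slot, id, collapsed) {
    a <- anchors[as.character(slot)]
    if (!is.na(a) && a != id) return(FALSE)
    if (collapsed) return(TRUE)  # collapsed 0-hop slot inherits prior label
    node_category(graph, id) %in% label_categories(pattern$labels[slot])
  }
  results <- list()
  seen <- new.env(parent = emptyenv())
  emit <- function(slots, nodes, erows) {
    key <- paste(c(nodes, "|", erows), collapse = "\r")
    if (!is.null(seen[[key]])) return()
    seen[[key]] <- TRUE
    results[[length(results) + 1L]] <<- list(slots = slots, nodes = nodes,
                                             erows = erows)
  }
  recur <- function(slot, slots, nodes, erows) {
    if (slot == n_slots) { emit(slots, nodes, erows); return() }
    e <- pattern$edges[[slot]]
    v <- slots[length(slots)]
    for (w in segment_walks(graph, v, e$rel_type, e$direction, e$lo, e$hi)) {
      endpoint <- w$nodes[length(w$nodes)]
      collapsed <- length(w$erows) == 0L
      if (!slot_ok(slot + 1L, endpoint, collapsed)) next
      recur(slot + 1L, c(slots, endpoint),
            c(nodes, w$nodes[-1L]), c(erows, w$erows))
    }
  }
  start_ids <- if (!is.na(anchors["1"])) unname(anchors["1"]) else
    names(graph$nodes)
  for (v in start_ids) {
    if (!slot_ok(1L, v, collapsed = FALSE)) next
    recur(1L, v, v, integer(0))
  }
  results
}

# ---- evidence paths ------------------------------------------------------

evidence_path <- function(graph, nodes, erows) {
  list(nodes = nodes, erows = as.integer(erows),
       edges = graph$edges[erows, , drop = FALSE])
}

#' Re-validate an evidence path against a graph
#'
#' Checks that every edge of the path exists in the graph and that
#' consecutive path nodes are the endpoints (in either orientation) of the
#' corresponding edge.
#'
#' @param graph an `mkg` object
#' @param path an evidence path (`list(nodes, erows)` or with an `edges`
#'   data.frame)
#' @return TRUE/FALSE
#' @export
validate_evidence <- function(graph, path) {
  nodes <- path$nodes
  if (any(!nodes %in% names(graph$nodes))) return(FALSE)
  erows <- path$erows
  if (length(erows) != length(nodes) - 1L) return(FALSE)
  if (length(erows) == 0L) return(TRUE)
  if (any(erows < 1L | erows > nrow(graph$edges))) return(FALSE)
  for (i in seq_along(erows)) {
    s <- graph$edges$source[erows[i]]; t <- graph$edges$target[erows[i]]
    a <- nodes[i]; b <- nodes[i + 1L]
    if (!((a == s && b == t) || (a == t && b == s))) return(FALSE)
  }
  TRUE
}

fwa_finding <- function(claim_id, scenario, subtype, involved, evidence,
                        severity) {
  structure(list(claim_id = claim_id, scenario = scenario, subtype = subtype,
                 involved = involved, evidence = evidence,
                 severity = severity), class = "fwa_finding")
}

#' Detector configuration
#'
#' @param excess_threshold minimum number of same-ATC-class drugs indicated
#'   for one disease before an excess-prescription finding fires
#' @param atc_extra_hops extra `is_a` levels climbed above a drug's first
#'   ATC ancestors when checking interactions (the `*0..3` extension)
#' @param strict_literal_irrational if TRUE, a shared ATC ancestor alone
#'   flags a drug pair (the literal reading of the shipped rule); default
#'   FALSE requires an explicit interaction edge between the expanded sets
#' @param fraud_on_drugless if TRUE, diagnosis-only claims (no drugs) emit
#'   uncovered-disease findings; default FALSE (nothing to justify against)
#' @return a `detector_config` list
#' @export
detector_config <- function(excess_threshold = 2L, atc_extra_hops = 3L,
                            strict_literal_irrational = FALSE,
                            fraud_on_drugless = FALSE) {
  structure(list(excess_threshold = as.integer(excess_threshold),
                 atc_extra_hops = as.integer(atc_extra_hops),
                 strict_literal_irrational = strict_literal_irrational,
                 fraud_on_drugless = fraud_on_drugless),
            class = "detector_config")
}

# disease d plus its one-step undirected is_a disease neighbours, with the
# connecting edge rows (NA for d itself)
disease_neighbourhood <- function(graph, d) {
  out <- data.frame(node = d, erow = NA_integer_, stringsAsFactors = FALSE)
  e <- graph$edges
  rows <- which(e$rel_type == "is_a" &
                  (e$source == d | e$target == d))
  for (r in rows) {
    other <- if (e$source[r] == d) e$target[r] else e$source[r]
    if (identical(node_category(graph, other), "disease"))
      out <- rbind(out, data.frame(node = other, erow = r))
  }
  out[!duplicated(out$node), , drop = FALSE]
}

# drugs reachable from claimed drug g by the *0..1 ATC-sibling extension:
# g -is_a 0..1-> X <-is_a 0..1- g'. Returns data.frame(gprime, and the node/
# edge chain from g' to g for evidence construction).
drug_sibling_expansion <- function(graph, g) {
  e <- graph$edges
  up_rows <- which(e$rel_type == "is_a" & e$source == g)
  mids <- data.frame(mid = g, up = NA_integer_, stringsAsFactors = FALSE)
  for (r in up_rows)
    mids <- rbind(mids, data.frame(mid = e$target[r], up = r))
  out <- list()
  for (i in seq_len(nrow(mids))) {
    mid <- mids$mid[i]; up <- mids$up[i]
    down_rows <- c(NA_integer_,
                   which(e$rel_type == "is_a" & e$target == mid))
    for (r in down_rows) {
      gp <- if (is.na(r)) mid else e$source[r]
      # chain from g' toward g: nodes and edge rows, skipping collapsed hops
      nodes <- gp
      erows <- integer(0)
      if (!is.na(r)) { nodes <- c(nodes, mid); erows <- c(erows, r) }
      if (!is.na(up)) {
        if (nodes[length(nodes)] != mid) nodes <- c(nodes, mid)
        nodes <- c(nodes, g); erows <- c(erows, up)
      } else if (nodes[length(nodes)] != g) {
        # mid == g, ensure chain ends at g
        if (nodes[length(nodes)] != g) { nodes <- c(nodes, g) }
      }
      # fix chain when both hops collapsed (gp == mid == g)
      if (length(nodes) > 1 && length(erows) == 0L) nodes <- g
      out[[length(out) + 1L]] <- list(gprime = gp, nodes = nodes,
                                      erows = erows)
    }
  }
  sig <- vapply(out, function(x) paste(x$nodes, collapse = ","), character(1))
  out[!duplicated(sig)]
}

# all (disease-targeting rel) edges from g or its sibling expansion, with
# evidence chains from the claimed disease back to g
drug_disease_links <- function(graph, g, rel_type) {
  e <- graph$edges
  links <- list()
  for (exp in drug_sibling_expansion(graph, g)) {
    rows <- which(e$rel_type == rel_type & e$source == exp$gprime)
    for (r in rows)
      links[[length(links) + 1L]] <- list(
        gprime = exp$gprime, disease = e$target[r], erow = r,
        chain_nodes = exp$nodes, chain_erows = exp$erows)
  }
  links
}

# evidence path claimed-disease d -> (adjacent disease dd) -> g' -> ... -> g
coverage_evidence <- function(graph, d, adj_row, link) {
  nodes <- d; erows <- integer(0)
  if (!is.na(adj_row$erow)) {
    nodes <- c(nodes, adj_row$node); erows <- c(erows, adj_row$erow)
  }
  nodes <- c(nodes, link$chain_nodes); erows <- c(erows, link$erow,
                                                  link$chain_erows)
  evidence_path(graph, nodes, erows)
}

#' Detect fraud-diagnosis findings in a linked claim
#'
#' A claimed disease is covered by a claimed drug when the drug — or a drug
#' sharing an ATC parent within one `is_a` hop — has an indication edge to
#' the disease or to a disease one undirected taxonomy step away. Emits
#' `no_indication` per claimed drug covering none of the claimed diseases,
#' `contraindicated` per (disease, drug) pair connected by a
#' contraindication edge after the same expansions, and `uncovered_disease`
#' per claimed disease covered by no claimed drug (an absence finding, so
#' its evidence list is empty).
#'
#' @param claim a linked claim (see [normalize_claim()])
#' @param graph an `mkg` object
#' @param config a [detector_config()]
#' @return list of findings
#' @export
detect_fraud_diagnosis <- function(claim, graph, config = detector_config()) {
  D <- claim$diagnoses; G <- claim$drugs
  findings <- list()
  if (length(D) == 0) return(findings)
  if (length(G) == 0 && !config$fraud_on_drugless) return(findings)
  covered <- stats::setNames(rep(FALSE, length(D)), D)
  for (g in G) {
    ind_links <- drug_disease_links(graph, g, "indication")
    contra_links <- drug_disease_links(graph, g, "contraindication")
    g_covers <- character(0)
    g_evidence <- list()
    for (d in D) {
      adj <- disease_neighbourhood(graph, d)
      for (i in seq_len(nrow(adj))) {
        dd <- adj$node[i]
        for (lk in ind_links) {
          if (lk$disease == dd) {
            covered[d] <- TRUE
            if (!d %in% g_covers) g_covers <- c(g_covers, d)
            g_evidence[[length(g_evidence) + 1L]] <-
              coverage_evidence(graph, d, adj[i, ], lk)
          }
        }
        for (lk in contra_links) {
          if (lk$disease == dd) {
            findings[[length(findings) + 1L]] <- fwa_finding(
              claim$claim_id, "fraud_diagnosis", "contraindicated",
              involved = c(d, g),
              evidence = list(coverage_evidence(graph, d, adj[i, ], lk)),
              severity = "high")
          }
        }
      }
    }
    if (length(g_covers) == 0 && length(D) > 0 && length(G) > 0) {
      # context evidence: the drug's actual indications (what it is for)
      ctx <- list()
      for (lk in ind_links[seq_len(min(3L, length(ind_links)))])
        ctx[[length(ctx) + 1L]] <- evidence_path(
          graph, c(rev(lk$chain_nodes), lk$disease),
          c(rev(lk$chain_erows), lk$erow))
      if (length(ctx) == 0)
        ctx <- list(evidence_path(graph, g, integer(0)))
      findings[[length(findings) + 1L]] <- fwa_finding(
        claim$claim_id, "fraud_diagnosis", "no_indication",
        involved = c(g, D), evidence = ctx, severity = "high")
    }
  }
  for (d in D[!covered]) {
    if (length(G) == 0 && !config$fraud_on_drugless) next
    findings[[length(findings) + 1L]] <- fwa_finding(
      claim$claim_id, "fraud_diagnosis", "uncovered_disease",
      involved = d, evidence = list(), severity = "high")
  }
  order_findings(findings)
}

# direct indication targets of g (allowing the product -> generic hop),
# with chains for evidence
drug_own_indications <- function(graph, g) {
  e <- graph$edges
  out <- list()
  starts <- list(list(node = g, chain_nodes = g, chain_erows = integer(0)))
  up_rows <- which(e$rel_type == "is_a" & e$source == g &
                     vapply(e$target[e$rel_type == "is_a" & e$source == g],
                            function(t) node_category(graph, t) %in%
                              DRUG_CATEGORIES, logical(1)))
  for (r in up_rows)
    starts[[length(starts) + 1L]] <- list(node = e$target[r],
                                          chain_nodes = c(g, e$target[r]),
                                          chain_erows = r)
  for (st in starts) {
    rows <- which(e$rel_type == "indication" & e$source == st$node)
    for (r in rows)
      out[[length(out) + 1L]] <- list(disease = e$target[r], erow = r,
                                      chain_nodes = st$chain_nodes,
                                      chain_erows = st$chain_erows)
  }
  out
}

#' Detect excess-prescription findings
#'
#' Fires when at least `excess_threshold` claimed drugs share a direct ATC
#' parent and each is indicated (directly, or via one undirected disease
#' taxonomy step) for the same claimed disease: therapeutically duplicated
#' medication for one diagnosis.
#'
#' @inheritParams detect_fraud_diagnosis
#' @return list of findings
#' @export
detect_excess_prescription <- function(claim, graph,
                                       config = detector_config()) {
  D <- claim$diagnoses; G <- claim$drugs
  findings <- list()
  if (length(G) < config$excess_threshold || length(D) == 0)
    return(findings)
  e <- graph$edges
  # direct ATC parents per claimed drug
  parents <- lapply(G, function(g) {
    rows <- which(e$rel_type == "is_a" & e$source == g)
    rows[vapply(e$target[rows], function(t)
      identical(node_category(graph, t), "atc"), logical(1))]
  })
  names(parents) <- G
  for (d in D) {
    adj <- disease_neighbourhood(graph, d)
    atc_groups <- list()  # atc id -> list of (g, parent_erow, ind evidence)
    for (g in G) {
      inds <- drug_own_indications(graph, g)
      hit <- NULL
      for (i in seq_len(nrow(adj))) {
        for (lk in inds)
          if (lk$disease == adj$node[i]) { hit <- list(lk = lk, adj = adj[i, ]); break }
        if (!is.null(hit)) break
      }
      if (is.null(hit)) next
      for (pr in parents[[g]]) {
        a <- e$target[pr]
        atc_groups[[a]] <- c(atc_groups[[a]], list(list(
          g = g, parent_erow = pr, hit = hit)))
      }
    }
    for (a in names(atc_groups)) {
      members <- atc_groups[[a]]
      gs <- vapply(members, `[[`, character(1), "g")
      keep <- !duplicated(gs)
      members <- members[keep]; gs <- gs[keep]
      if (length(gs) < config$excess_threshold) next
      ev <- list()
      for (mb in members) {
        ev[[length(ev) + 1L]] <- evidence_path(
          graph, c(mb$g, a), mb$parent_erow)
        nodes <- c(rev(mb$hit$lk$chain_nodes), mb$hit$lk$disease)
        erows <- c(rev(mb$hit$lk$chain_erows), mb$hit$lk$erow)
        if (!is.na(mb$hit$adj$erow)) {
          nodes <- c(nodes, d); erows <- c(erows, mb$hit$adj$erow)
        }
        ev[[length(ev) + 1L]] <- evidence_path(graph, nodes, erows)
      }
      findings[[length(findings) + 1L]] <- fwa_finding(
        claim$claim_id, "excess_prescription", NA_character_,
        involved = c(d, sort(gs)), evidence = ev, severity = "info")
    }
  }
  order_findings(findings)
}

# ATC ancestry of a drug: BFS up is_a, keeping parent pointers. Returns
# data.frame(node, depth, parent, erow, atc_depth); atc nodes only.
# Drug-level hops (product -> generic) are free; once the first atc ancestor
# is reached, at most extra_hops further atc levels are climbed (the *0..3
# extension of the reasoning rule).
atc_ancestry <- function(graph, g, extra_hops = 3L) {
  e <- graph$edges
  res <- data.frame(node = g, depth = 0L, parent = NA_character_,
                    erow = NA_integer_, atc_depth = -1L,
                    stringsAsFactors = FALSE)
  frontier <- g
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      v_atc_depth <- res$atc_depth[match(v, res$node)]
      v_depth <- res$depth[match(v, res$node)]
      if (v_atc_depth >= extra_hops) next  # hop budget above first ATC spent
      rows <- which(e$rel_type == "is_a" & e$source == v)
      for (r in rows) {
        t <- e$target[r]
        if (t %in% res$node) next
        tcat <- node_category(graph, t)
        ad <- if (identical(tcat, "atc")) v_atc_depth + 1L else -1L
        res <- rbind(res, data.frame(
          node = t, depth = v_depth + 1L, parent = v, erow = r,
          atc_depth = ad, stringsAsFactors = FALSE))
        nxt <- c(nxt, t)
      }
    }
    frontier <- nxt
  }
  res[vapply(res$node, function(v)
    identical(node_category(graph, v), "atc"), logical(1)), , drop = FALSE]
}

# node chain g -> ... -> a from an ancestry table
ancestry_chain <- function(graph, g, anc, a) {
  nodes <- a; erows <- integer(0)
  cur <- a
  while (cur != g) {
    i <- which(anc$node == cur)[1]
    if (is.na(anc$parent[i])) break
    erows <- c(anc$erow[i], erows)
    cur <- anc$parent[i]
    nodes <- c(cur, nodes)
  }
  list(nodes = nodes, erows = erows)
}

#' Detect irrational-prescription findings
#'
#' Drug interactions are stored at the ATC (chemical composition) level, so
#' each claimed drug pair is expanded to its ATC ancestors (first `is_a`
#' ancestors plus up to `atc_extra_hops` further levels) and flagged when an
#' interaction edge connects the two expanded sets. Harmful interactions
#' (subtype contraindication) are high severity, promotions informational,
#' `none` never flags. Direct drug-drug interaction edges are checked too.
#'
#' @inheritParams detect_fraud_diagnosis
#' @return list of findings
#' @export
detect_irrational_prescription <- function(claim, graph,
                                           config = detector_config()) {
  G <- unique(claim$drugs)
  findings <- list()
  if (length(G) < 2) return(findings)
  e <- graph$edges
  anc <- lapply(G, function(g) atc_ancestry(graph, g, config$atc_extra_hops))
  names(anc) <- G
  pairs <- utils::combn(sort(G), 2, simplify = FALSE)
  for (p in pairs) {
    g1 <- p[1]; g2 <- p[2]
    a1 <- anc[[g1]]; a2 <- anc[[g2]]
    hits <- list()
    # direct drug-drug interaction edges
    rows <- which(e$rel_type == "interaction" &
                    ((e$source == g1 & e$target == g2) |
                       (e$source == g2 & e$target == g1)))
    for (r in rows)
      hits[[length(hits) + 1L]] <- list(
        erow = r, path = evidence_path(graph, c(g1, g2), r),
        subtype = e$subtype[r])
    # ATC-level interaction edges between the two expanded sets
    rows <- which(e$rel_type == "interaction" &
                    ((e$source %in% a1$node & e$target %in% a2$node) |
                       (e$source %in% a2$node & e$target %in% a1$node)))
    for (r in rows) {
      s <- e$source[r]; t <- e$target[r]
      if (s %in% a1$node && t %in% a2$node) { x1 <- s; x2 <- t }
      else { x1 <- t; x2 <- s }
      ch1 <- ancestry_chain(graph, g1, a1, x1)
      ch2 <- ancestry_chain(graph, g2, a2, x2)
      # ch1 runs g1 -> x1 and ch2 runs g2 -> x2; the full evidence chain is
      # g1 .. x1 -interaction- x2 .. g2
      nodes <- c(ch1$nodes, rev(ch2$nodes))
      erows <- c(ch1$erows, r, rev(ch2$erows))
      hits[[length(hits) + 1L]] <- list(
        erow = r, path = evidence_path(graph, nodes, erows),
        subtype = e$subtype[r])
    }
    if (config$strict_literal_irrational && length(hits) == 0) {
      common <- intersect(a1$node, a2$node)
      if (length(common)) {
        a <- sort(common)[1]
        ch1 <- ancestry_chain(graph, g1, a1, a)
        ch2 <- ancestry_chain(graph, g2, a2, a)
        findings[[length(findings) + 1L]] <- fwa_finding(
          claim$claim_id, "irrational_prescription", "shared_atc_ancestor",
          involved = c(g1, g2),
          evidence = list(evidence_path(graph,
                                        c(ch1$nodes, rev(ch2$nodes)[-1]),
                                        c(ch1$erows, rev(ch2$erows)))),
          severity = "info")
      }
      next
    }
    hits <- hits[vapply(hits, function(h) h$subtype != "none", logical(1))]
    if (length(hits) == 0) next
    subtypes <- vapply(hits, `[[`, character(1), "subtype")
    worst <- if ("contraindication" %in% subtypes) "contraindication"
             else "promotion"
    findings[[length(findings) + 1L]] <- fwa_finding(
      claim$claim_id, "irrational_prescription", worst,
      involved = c(g1, g2),
      evidence = lapply(hits, `[[`, "path"),
      severity = if (worst == "contraindication") "high" else "info")
  }
  order_findings(findings)
}

order_findings <- function(findings) {
  if (length(findings) <= 1) return(findings)
  key <- vapply(findings, function(f)
    paste(f$scenario, f$subtype, paste(f$involved, collapse = ",")),
    character(1))
  findings[order(key, method = "radix")]
}

#' Screen one linked claim with all three detectors
#'
#' Runs fraud-diagnosis, excess-prescription, and irrational-prescription
#' detection, in that order; output is deterministic for a given claim,
#' graph, and configuration.
#'
#' @inheritParams detect_fraud_diagnosis
#' @return list of findings (possibly empty)
#' @export
screen <- function(claim, graph, config = detector_config()) {
  c(detect_fraud_diagnosis(claim, graph, config),
    detect_excess_prescription(claim, graph, config),
    detect_irrational_prescription(claim, graph, config))
}
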