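# Shared fixtures and independent oracles used across the test files.

# small hand-built graph: two diseases (taxonomy siblings), one ATC class
# with two drugs, one off-class drug, indication/contraindication edges
tiny_graph <- function() {
  g <- kg_new()
  g <- add_node(g, concept_node("d1", "肝风病", "disease", code = "C001"))
  g <- add_node(g, concept_node("d2", "肝热病", "disease", code = "C002"))
  g <- add_node(g, concept_node("dp", "肝系统疾病", "disease", code = "P01"))
  g <- add_node(g, concept_node("a0", "药物分类根", "atc", code = "ATC"))
  g <- add_node(g, concept_node("a1", "A01类药物", "atc", code = "A01"))
  g <- add_node(g, concept_node("a2", "B01类药物", "atc", code = "B01"))
  g <- add_node(g, concept_node("g1", "氨苯平", "drug_generic"))
  g <- add_node(g, concept_node("g2", "洛伐汀", "drug_generic"))
  g <- add_node(g, concept_node("g3", "西林沙", "drug_generic"))
  g <- add_edge(g, relation_edge("d1", "dp", "is_a"))
  g <- add_edge(g, relation_edge("d2", "dp", "is_a"))
  g <- add_edge(g, relation_edge("a1", "a0", "is_a"))
  g <- add_edge(g, relation_edge("a2", "a0", "is_a"))
  g <- add_edge(g, relation_edge("g1", "a1", "is_a"))
  g <- add_edge(g, relation_edge("g2", "a1", "is_a"))
  g <- add_edge(g, relation_edge("g3", "a2", "is_a"))
  g <- add_edge(g, relation_edge("g1", "d1", "indication"))
  g <- add_edge(g, relation_edge("g2", "d1", "indication"))
  g <- add_edge(g, relation_edge("g3", "d2", "indication"))
  g <- add_edge(g, relation_edge("g3", "d1", "contraindication"))
  g
}

linked_claim_fixture <- function(claim_id, diagnoses, drugs) {
  structure(list(claim_id = claim_id, diagnoses = diagnoses, drugs = drugs,
                 examinations = character(0), unknown_terms = character(0),
                 age = 40, sex = "F"),
            class = "linked_claim")
}

# seeded random schema-valid graph for oracle-equivalence tests
random_graph <- function(seed, n_nodes = 20, p_edge = 0.15) {
  set.seed(seed)
  g <- kg_new()
  cats <- sample(c("disease", "drug_generic", "atc"), n_nodes, replace = TRUE,
                 prob = c(0.4, 0.35, 0.25))
  ids <- sprintf("n%02d", seq_len(n_nodes))
  for (i in seq_len(n_nodes))
    g <- add_node(g, concept_node(ids[i], paste0("节点", i), cats[i],
                                  code = if (cats[i] == "atc")
                                    sprintf("X%02d", i) else NA_character_))
  for (i in seq_len(n_nodes)) {
    for (j in seq_len(n_nodes)) {
      if (i == j || stats::runif(1) >= p_edge) next
      src <- ids[i]; dst <- ids[j]
      rel <- NULL
      if (cats[i] == "disease" && cats[j] == "disease") rel <- "is_a"
      if (cats[i] == "drug_generic" && cats[j] == "atc") rel <- "is_a"
      if (cats[i] == "atc" && cats[j] == "atc") rel <- "is_a"
      if (cats[i] == "drug_generic" && cats[j] == "disease")
        rel <- sample(c("indication", "contraindication"), 1)
      if (is.null(rel)) next
      edge <- if (cats[i] == "atc" && cats[j] == "atc" &&
                  stats::runif(1) < 0.3)
        relation_edge(src, dst, "interaction",
                      subtype = sample(c("promotion", "contraindication",
                                         "none"), 1))
      else relation_edge(src, dst, rel)
      g <- tryCatch(add_edge(g, edge), mkgfwa_error = function(e) g)
    }
  }
  g
}

# ---- independent oracles --------------------------------------------------

# hop-bounded reachability via igraph shortest-path distances
oracle_expand <- function(graph, start, rel_type, direction, min_hops,
                          max_hops) {
  e <- graph$edges[graph$edges$rel_type == rel_type, , drop = FALSE]
  ids <- names(graph$nodes)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = e$source, to = e$target),
    directed = TRUE, vertices = data.frame(name = ids))
  mode <- switch(direction, up = "out", down = "in", both = "all")
  d <- igraph::distances(ig, v = start, mode = mode)[1, ]
  names(d)[is.finite(d) & d >= min_hops & d <= max_hops]
}

# exhaustive memoised recursion over edit scripts (top-down, suffix-based;
# independent of the package's bottom-up DP)
oracle_distance <- function(a, b, maps = list(), costs = cost_scheme()) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  la <- length(ca); lb <- length(cb)
  sub_cost <- function(x, y) {
    if (x == y) return(0)
    best <- costs$sub_full
    for (m in maps) {
      disc <- costs$discounts[m$name]
      if (is.na(disc)) next
      vx <- m$table[x]; vy <- m$table[y]
      if (!is.na(vx) && !is.na(vy) && vx == vy) best <- min(best, disc)
    }
    best
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i > la && j > lb) 0
    else if (i > la) (lb - j + 1) * costs$insert
    else if (j > lb) (la - i + 1) * costs$delete
    else min(rec(i + 1, j) + costs$delete,
             rec(i, j + 1) + costs$insert,
             rec(i + 1, j + 1) + sub_cost(ca[i], cb[j]))
    memo[[key]] <- val
    val
  }
  rec(1, 1)
}

# random strings over a fixed fixture alphabet
rand_string <- function(alphabet, max_len = 5) {
  len <- sample(0:max_len, 1)
  if (len == 0) return("")
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# brute-force enumeration of pattern matches: plain recursive DFS over an
# adjacency list, written independently of the package matcher
oracle_match <- function(graph, pattern, anchors = list()) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  e <- graph$edges
  anchors <- unlist(anchors)
  if (is.null(anchors)) anchors <- character(0)
  labels_of <- function(lab) switch(lab,
    Drug = c("drug_generic", "drug_product"), ATC = "atc", Disease = "disease",
    Examination = "examination", Symptom = "symptom", Operation = "operation",
    lab)
  cat_of <- function(id) graph$nodes[[id]]$category
  results <- character(0)
  paths <- list()
  walk_seg <- function(v, rel, dir, lo, hi) {
    # all simple walks from v with lo..hi edges of type rel
    acc <- list()
    if (lo == 0) acc[[1]] <- list(nodes = v, erows = integer(0))
    grow <- function(nodes, erows) {
      if (length(erows) >= hi) return()
      cur <- nodes[length(nodes)]
      rows <- which(e$rel_type == rel &
                      ((dir != "left" & e$source == cur) |
                         (dir != "right" & e$target == cur)))
      for (r in rows) {
        # both orientations may apply for undirected steps
        for (w in unique(c(if (dir != "left" && e$source[r] == cur)
          e$target[r], if (dir != "right" && e$target[r] == cur)
            e$source[r]))) {
          if (w %in% nodes) next
          n2 <- c(nodes, w); e2 <- c(erows, r)
          if (length(e2) >= lo)
            acc[[length(acc) + 1]] <<- list(nodes = n2, erows = e2)
          grow(n2, e2)
        }
      }
    }
    grow(v, integer(0))
    acc
  }
  rec <- function(slot, slots, nodes, erows) {
    if (slot == length(pattern$labels)) {
      sig <- paste(c(nodes, "|", erows), collapse = "\r")
      if (!sig %in% results) {
        results <<- c(results, sig)
        paths[[length(paths) + 1]] <<- list(slots = slots, nodes = nodes,
                                            erows = erows)
      }
      return()
    }
    pe <- pattern$edges[[slot]]
    for (w in walk_seg(slots[length(slots)], pe$rel_type, pe$direction,
                       pe$lo, pe$hi)) {
      endpoint <- w$nodes[length(w$nodes)]
      a <- anchors[as.character(slot + 1)]
      if (!is.na(a) && a != endpoint) next
      if (length(w$erows) > 0 &&
          !cat_of(endpoint) %in% labels_of(pattern$labels[slot + 1])) next
      rec(slot + 1, c(slots, endpoint), c(nodes, w$nodes[-1]),
          c(erows, w$erows))
    }
  }
  starts <- if (!is.na(anchors["1"])) unname(anchors["1"]) else
    names(graph$nodes)
  for (v in starts) {
    if (!cat_of(v) %in% labels_of(pattern$labels[1])) next
    rec(1, v, v, integer(0))
  }
  paths
}

match_signatures <- function(matches) {
  sort(vapply(matches, function(m)
    paste(c(m$nodes, "|", m$erows), collapse = "\r"), character(1)))
}
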