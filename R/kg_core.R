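# Typed property-graph data model for the medical knowledge graph:
# constructors, schema validation, hop-bounded hierarchy traversal, and
# TSV persistence.

#' Create a concept node
#'
#' A node of the medical knowledge graph: a disease, drug (product, generic,
#' or ATC class), examination, symptom, or operation, with a preferred name,
#' optional terminology code (ICD-10 for diseases, ATC code for ATC classes,
#' service code for examinations), synonyms, and free-form attributes such as
#' the dosage form of a drug product.
#'
#' @param node_id unique opaque id string
#' @param name preferred term (non-empty)
#' @param category one of `disease`, `drug_generic`, `drug_product`, `atc`,
#'   `examination`, `symptom`, `operation`
#' @param code optional terminology code; required for `atc` nodes
#' @param synonyms character vector of alternative surface strings
#' @param attributes named character vector of key/value attributes
#' @return a `concept_node` list
#' @export
#' @examples
#' concept_node("D1", "糖尿病", "disease", code = "E14")
concept_node <- function(node_id, name, category, code = NA_character_,
                         synonyms = character(0), attributes = character(0)) {
  if (!is.character(node_id) || length(node_id) != 1 || !nzchar(node_id))
    abort_mkg("node_id must be a non-empty string", "mkg_schema_error")
  if (!is.character(name) || length(name) != 1 || is.na(name) || !nzchar(name))
    abort_mkg("name must be a non-empty string", "mkg_schema_error")
  if (length(category) != 1 || !category %in% NODE_CATEGORIES)
    abort_mkg(sprintf("category '%s' not in {%s}",
                      paste(category, collapse = ","),
                      paste(NODE_CATEGORIES, collapse = ", ")),
              "mkg_schema_error")
  if (category == "atc" && (is.na(code) || !nzchar(code)))
    abort_mkg("atc nodes require a non-empty code", "mkg_schema_error")
  structure(list(node_id = node_id, name = name, category = category,
                 code = as.character(code),
                 synonyms = unique(as.character(synonyms)),
                 attributes = attributes),
            class = "concept_node")
}

#' Create a relation edge
#'
#' Directed, typed edge between two nodes. `interaction` edges carry a
#' subtype (`promotion`, `contraindication`, or `none`); no other type does.
#'
#' @param source,target node ids
#' @param rel_type one of `is_a`, `indication`, `contraindication`,
#'   `interaction`, `check`, `treat`, `has_symptom`
#' @param subtype interaction subtype; required iff `rel_type = "interaction"`
#' @param provenance source document id, or `"manual"` for curated edges
#' @param confidence extraction confidence in `[0, 1]`; manually curated
#'   edges default to 1
#' @return a `relation_edge` list
#' @export
relation_edge <- function(source, target, rel_type, subtype = NA_character_,
                          provenance = "manual", confidence = 1.0) {
  if (!rel_type %in% REL_TYPES)
    abort_mkg(sprintf("rel_type '%s' not in {%s}", rel_type,
                      paste(REL_TYPES, collapse = ", ")), "mkg_schema_error")
  if (rel_type == "interaction") {
    if (is.na(subtype) || !subtype %in% INTERACTION_SUBTYPES)
      abort_mkg("interaction edges require subtype promotion|contraindication|none",
                "mkg_schema_error")
  } else if (!is.na(subtype)) {
    abort_mkg(sprintf("subtype only allowed on interaction edges (got %s on %s)",
                      subtype, rel_type), "mkg_schema_error")
  }
  if (!is.numeric(confidence) || is.na(confidence) ||
      confidence < 0 || confidence > 1)
    abort_mkg("confidence must lie in [0, 1]", "mkg_schema_error")
  structure(list(source = source, target = target, rel_type = rel_type,
                 subtype = as.character(subtype),
                 provenance = as.character(provenance),
                 confidence = as.numeric(confidence)),
            class = "relation_edge")
}

empty_edge_df <- function() {
  data.frame(source = character(0), target = character(0),
             rel_type = character(0), subtype = character(0),
             provenance = character(0), confidence = numeric(0),
             stringsAsFactors = FALSE)
}

#' Create an empty knowledge graph
#'
#' @return an object of class `mkg` holding a node map and an edge table
#' @export
kg_new <- function() {
  structure(list(nodes = list(), edges = empty_edge_df()), class = "mkg")
}

#' @export
print.mkg <- function(x, ...) {
  cats <- table(vapply(x$nodes, function(n) n$category, character(1)))
  rels <- table(x$edges$rel_type)
  cat(sprintf("<medical knowledge graph: %d nodes, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  if (length(cats)) cat("  nodes:", paste(names(cats), cats, sep = "=",
                                          collapse = " "), "\n")
  if (length(rels)) cat("  edges:", paste(names(rels), rels, sep = "=",
                                          collapse = " "), "\n")
  invisible(x)
}

node_category <- function(graph, id) {
  n <- graph$nodes[[id]]
  if (is.null(n)) NA_character_ else n$category
}

#' Add a node to a knowledge graph
#'
#' Re-adding a node with identical content is a no-op; re-using an id with
#' different content is rejected.
#'
#' @param graph an `mkg` object
#' @param node a [concept_node()]
#' @return the updated graph
#' @export
add_node <- function(graph, node) {
  stopifnot(inherits(graph, "mkg"))
  if (!inherits(node, "concept_node"))
    node <- do.call(concept_node, node)
  old <- graph$nodes[[node$node_id]]
  if (!is.null(old)) {
    if (identical(unclass(old), unclass(node))) return(graph)  # idempotent
    abort_mkg(sprintf("node id '%s' already present with different content",
                      node$node_id), "mkg_duplicate_id")
  }
  graph$nodes[[node$node_id]] <- node
  graph
}

#' Add an edge to a knowledge graph
#'
#' Both endpoints must exist and their categories must be allowed for the
#' relationship type (e.g. `indication` runs drug -> disease, `is_a` runs
#' drug_product -> drug_generic -> atc -> atc and disease -> disease).
#' Duplicate `(source, target, rel_type, subtype)` tuples are no-ops.
#'
#' @param graph an `mkg` object
#' @param edge a [relation_edge()]
#' @return the updated graph
#' @export
add_edge <- function(graph, edge) {
  stopifnot(inherits(graph, "mkg"))
  if (!inherits(edge, "relation_edge")) edge <- do.call(relation_edge, edge)
  for (endpoint in c(edge$source, edge$target))
    if (is.null(graph$nodes[[endpoint]]))
      abort_mkg(sprintf("edge endpoint '%s' not in graph", endpoint),
                "mkg_dangling_edge")
  sc <- node_category(graph, edge$source)
  tc <- node_category(graph, edge$target)
  if (!schema_allows(edge$rel_type, sc, tc))
    abort_mkg(sprintf("schema violation: %s edge %s(%s) -> %s(%s)",
                      edge$rel_type, edge$source, sc, edge$target, tc),
              "mkg_schema_error")
  e <- graph$edges
  dup <- e$source == edge$source & e$target == edge$target &
    e$rel_type == edge$rel_type &
    (is.na(e$subtype) & is.na(edge$subtype) |
       (!is.na(e$subtype) & !is.na(edge$subtype) & e$subtype == edge$subtype))
  if (any(dup)) return(graph)
  graph$edges <- rbind(e, data.frame(
    source = edge$source, target = edge$target, rel_type = edge$rel_type,
    subtype = edge$subtype, provenance = edge$provenance,
    confidence = edge$confidence, stringsAsFactors = FALSE))
  graph
}

#' Hop-bounded hierarchy traversal
#'
#' Returns all nodes whose breadth-first distance from `start` along edges of
#' `rel_type` lies in `[min_hops, max_hops]`. Direction `"up"` follows edges
#' source -> target (e.g. toward ATC ancestors along `is_a`), `"down"`
#' follows them in reverse, `"both"` ignores direction. Traversal keeps a
#' visited set, so it terminates on cyclic graphs. `min_hops = 0` includes
#' `start` itself.
#'
#' @param graph an `mkg` object
#' @param start a node id present in the graph
#' @param rel_type relationship type to follow
#' @param direction `"up"`, `"down"`, or `"both"`
#' @param min_hops,max_hops inclusive hop bounds, `0 <= min_hops <= max_hops`
#' @return character vector of node ids (a set, unordered)
#' @export
#' @examples
#' g <- kg_new()
#' g <- add_node(g, concept_node("a", "a", "atc", code = "A"))
#' g <- add_node(g, concept_node("b", "b", "atc", code = "A01"))
#' g <- add_edge(g, relation_edge("b", "a", "is_a"))
#' expand_hierarchy(g, "b", "is_a", "up", 0, 3)  # {"b", "a"}
expand_hierarchy <- function(graph, start, rel_type,
                             direction = c("up", "down", "both"),
                             min_hops = 0L, max_hops = 1L) {
  direction <- match.arg(direction)
  if (is.null(graph$nodes[[start]]))
    abort_mkg(sprintf("start node '%s' not in graph", start), "mkg_lookup_error")
  if (min_hops < 0 || max_hops < 0 || min_hops > max_hops)
    abort_mkg("require 0 <= min_hops <= max_hops", "mkg_argument_error")
  e <- graph$edges[graph$edges$rel_type == rel_type, , drop = FALSE]
  neighbours <- function(ids) {
    out <- character(0)
    if (direction %in% c("up", "both"))
      out <- c(out, e$target[e$source %in% ids])
    if (direction %in% c("down", "both"))
      out <- c(out, e$source[e$target %in% ids])
    unique(out)
  }
  visited <- stats::setNames(0L, start)
  frontier <- start
  depth <- 0L
  while (length(frontier) > 0 && depth < max_hops) {
    depth <- depth + 1L
    nxt <- setdiff(neighbours(frontier), names(visited))
    if (length(nxt)) visited[nxt] <- depth
    frontier <- nxt
  }
  names(visited)[visited >= min_hops & visited <= max_hops]
}

#' Validate a knowledge graph against the schema
#'
#' Checks every invariant: node categories and required codes, edge endpoint
#' existence, endpoint-category rules, interaction subtypes, confidence
#' bounds, and duplicate edges. `is_a` cycles produce warnings, not errors
#' (traversal is cycle-safe; real terminologies are near-acyclic).
#'
#' @param graph an `mkg` object
#' @return invisibly, a character vector of problems (empty when valid)
#' @param strict if TRUE, any problem raises an error
#' @export
validate_graph <- function(graph, strict = TRUE) {
  problems <- character(0)
  for (n in graph$nodes) {
    if (!n$category %in% NODE_CATEGORIES)
      problems <- c(problems, sprintf("node %s: bad category %s",
                                      n$node_id, n$category))
    if (n$category == "atc" && (is.na(n$code) || !nzchar(n$code)))
      problems <- c(problems, sprintf("node %s: atc node lacks code", n$node_id))
    if (!nzchar(n$name))
      problems <- c(problems, sprintf("node %s: empty name", n$node_id))
  }
  e <- graph$edges
  if (nrow(e)) {
    for (i in seq_len(nrow(e))) {
      sc <- node_category(graph, e$source[i])
      tc <- node_category(graph, e$target[i])
      if (is.na(sc) || is.na(tc)) {
        problems <- c(problems, sprintf(
          "edge row %d: dangling endpoint %s -> %s", i, e$source[i], e$target[i]))
        next
      }
      if (!schema_allows(e$rel_type[i], sc, tc))
        problems <- c(problems, sprintf(
          "edge row %d: %s not allowed %s(%s) -> %s(%s)", i,
          e$rel_type[i], e$source[i], sc, e$target[i], tc))
      if (e$rel_type[i] == "interaction" &&
          (is.na(e$subtype[i]) || !e$subtype[i] %in% INTERACTION_SUBTYPES))
        problems <- c(problems, sprintf("edge row %d: bad interaction subtype", i))
      if (e$rel_type[i] != "interaction" && !is.na(e$subtype[i]))
        problems <- c(problems, sprintf("edge row %d: subtype on %s edge",
                                        i, e$rel_type[i]))
      if (is.na(e$confidence[i]) || e$confidence[i] < 0 || e$confidence[i] > 1)
        problems <- c(problems, sprintf("edge row %d: confidence out of [0,1]", i))
    }
    key <- paste(e$source, e$target, e$rel_type, e$subtype)
    if (anyDuplicated(key))
      problems <- c(problems, sprintf("duplicate edges: %s",
                                      paste(unique(key[duplicated(key)]),
                                            collapse = "; ")))
    # warn (not fail) on is_a cycles
    isa <- e[e$rel_type == "is_a", , drop = FALSE]
    if (nrow(isa) && has_cycle(isa$source, isa$target))
      warning("is_a relation contains a cycle; traversal remains terminating")
  }
  if (strict && length(problems))
    abort_mkg(paste0("graph validation failed:\n  ",
                     paste(problems, collapse = "\n  ")), "mkg_validation_error")
  invisible(problems)
}

# simple DFS cycle check on a directed edge list
has_cycle <- function(src, dst) {
  nodes <- unique(c(src, dst))
  adj <- split(dst, factor(src, levels = nodes))
  state <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new 1 open 2 done
  visit <- function(v) {
    state[v] <<- 1L
    for (w in adj[[v]]) {
      if (state[w] == 1L) return(TRUE)
      if (state[w] == 0L && visit(w)) return(TRUE)
    }
    state[v] <<- 2L
    FALSE
  }
  for (v in nodes) if (state[v] == 0L && visit(v)) return(TRUE)
  FALSE
}

#' Save a knowledge graph to node/edge TSV tables
#'
#' `nodes.tsv` columns: node_id, name, category, code, synonyms
#' (pipe-separated), attributes (`key=value;...`). `edges.tsv` columns:
#' source, target, rel_type, subtype, provenance, confidence. UTF-8, header
#' row. `load_graph(save_graph(g))` is the identity up to row order.
#'
#' @param graph an `mkg` object
#' @param node_table,edge_table output file paths
#' @return invisibly, the graph
#' @export
save_graph <- function(graph, node_table, edge_table) {
  stopifnot(inherits(graph, "mkg"))
  nd <- data.frame(
    node_id = vapply(graph$nodes, `[[`, character(1), "node_id"),
    name = vapply(graph$nodes, `[[`, character(1), "name"),
    category = vapply(graph$nodes, `[[`, character(1), "category"),
    code = vapply(graph$nodes, function(n) ifelse(is.na(n$code), "", n$code),
                  character(1)),
    synonyms = vapply(graph$nodes, function(n)
      paste(n$synonyms, collapse = "|"), character(1)),
    attributes = vapply(graph$nodes, function(n) {
      if (length(n$attributes) == 0) return("")
      paste(names(n$attributes), n$attributes, sep = "=", collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  write_tsv_utf8(nd, node_table)
  ed <- graph$edges
  ed$subtype[is.na(ed$subtype)] <- ""
  write_tsv_utf8(ed, edge_table)
  invisible(graph)
}

#' Load a knowledge graph from node/edge TSV tables
#'
#' All schema invariants are validated on load; violations raise an error
#' listing the offending rows.
#'
#' @param node_table,edge_table paths written by [save_graph()]
#' @return an `mkg` object
#' @export
load_graph <- function(node_table, edge_table) {
  graph <- kg_new()
  if (file.exists(node_table) && file.size(node_table) > 0) {
    nd <- read_tsv_utf8(node_table)
    need <- c("node_id", "name", "category")
    if (!all(need %in% names(nd)))
      abort_mkg(sprintf("%s: missing columns %s", node_table,
                        paste(setdiff(need, names(nd)), collapse = ", ")),
                "mkg_parse_error")
    for (i in seq_len(nrow(nd))) {
      syn <- nd$synonyms[i] %||% ""
      syn <- if (is.na(syn) || !nzchar(syn)) character(0)
             else strsplit(syn, "|", fixed = TRUE)[[1]]
      att <- nd$attributes[i] %||% ""
      attributes <- character(0)
      if (!is.na(att) && nzchar(att)) {
        kv <- strsplit(strsplit(att, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
        bad <- vapply(kv, length, integer(1)) != 2
        if (any(bad))
          abort_mkg(sprintf("%s line %d: malformed attributes '%s'",
                            node_table, i + 1L, att), "mkg_parse_error")
        attributes <- stats::setNames(vapply(kv, `[`, character(1), 2),
                                      vapply(kv, `[`, character(1), 1))
      }
      code <- nd$code[i] %||% ""
      node <- tryCatch(
        concept_node(nd$node_id[i], nd$name[i], nd$category[i],
                     code = if (is.na(code) || !nzchar(code)) NA_character_
                            else code,
                     synonyms = syn, attributes = attributes),
        mkgfwa_error = function(e)
          abort_mkg(sprintf("%s line %d: %s", node_table, i + 1L,
                            conditionMessage(e)), "mkg_validation_error"))
      graph <- add_node(graph, node)
    }
  }
  if (file.exists(edge_table) && file.size(edge_table) > 0) {
    ed <- read_tsv_utf8(edge_table)
    need <- c("source", "target", "rel_type")
    if (!all(need %in% names(ed)))
      abort_mkg(sprintf("%s: missing columns %s", edge_table,
                        paste(setdiff(need, names(ed)), collapse = ", ")),
                "mkg_parse_error")
    for (i in seq_len(nrow(ed))) {
      st <- ed$subtype[i] %||% ""
      edge <- tryCatch(
        relation_edge(ed$source[i], ed$target[i], ed$rel_type[i],
                      subtype = if (is.na(st) || !nzchar(st)) NA_character_
                                else st,
                      provenance = ed$provenance[i] %||% "manual",
                      confidence = ed$confidence[i] %||% 1.0),
        mkgfwa_error = function(e)
          abort_mkg(sprintf("%s line %d: %s", edge_table, i + 1L,
                            conditionMessage(e)), "mkg_validation_error"))
      graph <- tryCatch(add_edge(graph, edge), mkgfwa_error = function(e)
        abort_mkg(sprintf("%s line %d: %s", edge_table, i + 1L,
                          conditionMessage(e)), "mkg_validation_error"))
    }
  }
  validate_graph(graph)
  graph
}

# ids of nodes with a given category
nodes_of_category <- function(graph, categories) {
  ids <- names(graph$nodes)
  ids[vapply(graph$nodes, function(n) n$category %in% categories, logical(1))]
}

# edge subset helpers (linear scans; graphs handled here are small)
edges_from <- function(graph, id, rel_type) {
  e <- graph$edges
  e[e$source == id & e$rel_type == rel_type, , drop = FALSE]
}

edges_into <- function(graph, id, rel_type) {
  e <- graph$edges
  e[e$target == id & e$rel_type == rel_type, , drop = FALSE]
}
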