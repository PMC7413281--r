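# End-to-end claim screening: JSONL claim I/O, term normalization through
# the entity linker, batch screening with per-claim findings and a batch
# summary, and the human curation loop (export low-confidence links, apply
# reviewer decisions back into the graph).

#' Read claim documents from a JSONL file
#'
#' One JSON object per line: `{"claim_id": ..., "diagnoses": [...],
#' "drugs": [...], "examinations": [...], "age": ..., "sex": ...}`.
#' Diagnoses/drugs/examinations are raw surface strings as they appear in
#' hospital systems. Invalid rows (missing claim_id, or neither diagnoses
#' nor drugs) are collected into an error report; duplicate claim ids are an
#' error.
#'
#' @param path JSONL file
#' @return list with `claims` (list of claim documents) and `errors`
#'   (data.frame line/reason)
#' @export
read_claims <- function(path) {
  if (!file.exists(path))
    abort_mkg(sprintf("cannot read claims file '%s'", path), "mkg_io_error")
  con <- file(path, encoding = "UTF-8")
  lines <- readLines(con, warn = FALSE)
  close(con)
  lines <- lines[nzchar(trimws(lines))]
  claims <- list()
  errors <- data.frame(line = integer(0), reason = character(0))
  for (i in seq_along(lines)) {
    doc <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(doc)) {
      errors <- rbind(errors, data.frame(line = i, reason = "malformed JSON"))
      next
    }
    cid <- doc$claim_id %||% NA_character_
    if (is.na(cid) || !nzchar(cid)) {
      errors <- rbind(errors, data.frame(line = i, reason = "missing claim_id"))
      next
    }
    diagnoses <- as.character(doc$diagnoses %||% character(0))
    drugs <- as.character(doc$drugs %||% character(0))
    if (length(diagnoses) == 0 && length(drugs) == 0) {
      errors <- rbind(errors, data.frame(
        line = i, reason = sprintf("claim %s has neither diagnoses nor drugs",
                                   cid)))
      next
    }
    claims[[length(claims) + 1L]] <- structure(list(
      claim_id = as.character(cid),
      diagnoses = diagnoses, drugs = drugs,
      examinations = as.character(doc$examinations %||% character(0)),
      age = if (is.null(doc$age)) NA_real_ else as.numeric(doc$age),
      sex = if (is.null(doc$sex)) NA_character_ else as.character(doc$sex)),
      class = "claim_document")
  }
  ids <- vapply(claims, `[[`, character(1), "claim_id")
  if (anyDuplicated(ids))
    abort_mkg(sprintf("duplicate claim_id: %s",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")),
              "mkg_validation_error")
  list(claims = claims, errors = errors)
}

#' Write claim documents to a JSONL file
#'
#' Inverse of [read_claims()]; `read_claims(write_claims(x))` reproduces the
#' claims.
#'
#' @param claims list of claim documents
#' @param path output file
#' @return invisibly, the path
#' @export
write_claims <- function(claims, path) {
  lines <- vapply(claims, function(cl) {
    jsonlite::toJSON(list(
      claim_id = jsonlite::unbox(cl$claim_id),
      diagnoses = cl$diagnoses, drugs = cl$drugs,
      examinations = cl$examinations,
      age = if (is.na(cl$age)) NULL else jsonlite::unbox(cl$age),
      sex = if (is.na(cl$sex)) NULL else jsonlite::unbox(cl$sex)),
      null = "null")
  }, character(1))
  con <- file(path, open = "w", encoding = "UTF-8")
  writeLines(lines, con, useBytes = TRUE)
  close(con)
  invisible(path)
}

# link one term with caching (claims batches repeat surface strings heavily)
link_cached <- function(term, graph, index, config, cache) {
  hit <- cache[[term]]
  if (!is.null(hit)) return(hit)
  res <- link_mention(term, graph, index, config)
  cache[[term]] <- res
  res
}

#' Normalize a claim's raw terms onto graph entities
#'
#' Every diagnosis/drug/examination surface string is linked through the
#' multilevel matcher; terms that fail to link are recorded in
#' `unknown_terms` (data, not errors — they feed the curation loop). A term
#' exactly equal to a node's terminology code short-circuits linking.
#'
#' @param claim a claim document from [read_claims()]
#' @param graph an `mkg` object
#' @param index index from [build_index()]; built on the fly when `NULL`
#' @param config a [linker_config()]
#' @param cache optional environment memoising term -> link result
#' @return a `linked_claim`: claim with node-id lists plus the link log
#' @export
normalize_claim <- function(claim, graph, index = NULL,
                            config = linker_config(), cache = NULL) {
  if (is.null(index)) index <- build_index(graph, config$maps)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  codes <- stats::setNames(
    names(graph$nodes),
    vapply(graph$nodes, function(n) ifelse(is.na(n$code), "", n$code),
           character(1)))
  codes <- codes[nzchar(names(codes))]
  links <- list()
  resolve <- function(terms) {
    ids <- character(0); unknown <- character(0)
    for (term in terms) {
      if (term %in% names(codes)) {
        ids <- c(ids, unname(codes[term]))
        links[[length(links) + 1L]] <<- structure(
          list(mention = term, decision = "linked",
               entity = unname(codes[term]), score = 1,
               breakdown = list(string = 1, units = list(), capped = FALSE),
               candidates = data.frame(node_id = unname(codes[term]),
                                       name = term, score = 1)),
          class = "link_result")
        next
      }
      res <- link_cached(term, graph, index, config, cache)
      links[[length(links) + 1L]] <- res
      if (res$decision == "linked") ids <- c(ids, res$entity)
      else unknown <- c(unknown, term)
    }
    list(ids = ids, unknown = unknown)
  }
  dg <- resolve(claim$diagnoses)
  dr <- resolve(claim$drugs)
  ex <- resolve(claim$examinations)
  structure(list(
    claim_id = claim$claim_id,
    diagnoses = dg$ids, drugs = dr$ids, examinations = ex$ids,
    unknown_terms = c(dg$unknown, dr$unknown, ex$unknown),
    age = claim$age, sex = claim$sex, links = links),
    class = "linked_claim")
}

#' Full screening configuration
#'
#' @param linker a [linker_config()]
#' @param detector a [detector_config()]
#' @return a `screening_config` list with a stable fingerprint
#' @export
screening_config <- function(linker = linker_config(),
                             detector = detector_config()) {
  structure(list(linker = linker, detector = detector),
            class = "screening_config")
}

#' Fingerprint of a screening configuration
#'
#' Changes iff any configuration value changes; stamped into every report to
#' guard against silent configuration drift between runs.
#'
#' @param config a [screening_config()]
#' @return 8-hex-digit string
#' @export
config_fingerprint <- function(config) {
  strip <- function(x) {
    if (inherits(x, "attribute_map")) return(list(x$name, x$table))
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  fnv1a(strip(unclass(config)))
}

#' Screen a batch of claims
#'
#' Normalizes every claim, runs the three detectors, and aggregates a batch
#' summary (finding counts per scenario, unknown-term rate). Deterministic:
#' identical inputs and configuration give byte-identical reports; claims
#' are processed independently (no cross-claim state).
#'
#' @param claims list of claim documents from [read_claims()] or
#'   [generate_claims()]
#' @param graph an `mkg` object
#' @param config a [screening_config()]
#' @return a `screening_report`: per-claim results, summary, fingerprint
#' @export
screen_batch <- function(claims, graph, config = screening_config()) {
  index <- build_index(graph, config$linker$maps)
  cache <- new.env(parent = emptyenv())
  per_claim <- vector("list", length(claims))
  n_terms <- 0L; n_unknown <- 0L
  link_log <- list()
  for (i in seq_along(claims)) {
    linked <- normalize_claim(claims[[i]], graph, index, config$linker, cache)
    findings <- screen(linked, graph, config$detector)
    n_terms <- n_terms + length(claims[[i]]$diagnoses) +
      length(claims[[i]]$drugs) + length(claims[[i]]$examinations)
    n_unknown <- n_unknown + length(linked$unknown_terms)
    link_log <- c(link_log, linked$links)
    per_claim[[i]] <- list(claim_id = linked$claim_id,
                           findings = findings,
                           unknown_terms = linked$unknown_terms)
  }
  counts <- c(fraud_diagnosis = 0L, excess_prescription = 0L,
              irrational_prescription = 0L)
  for (pc in per_claim)
    for (f in pc$findings)
      counts[f$scenario] <- counts[f$scenario] + 1L
  structure(list(
    claims = per_claim,
    summary = list(n_claims = length(claims),
                   findings_per_scenario = as.list(counts),
                   n_terms = n_terms, n_unknown = n_unknown,
                   unknown_term_rate = if (n_terms) n_unknown / n_terms else 0),
    link_log = link_log,
    config_fingerprint = config_fingerprint(config)),
    class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening report: %d claims, fingerprint %s>\n",
              x$summary$n_claims, x$config_fingerprint))
  for (sc in names(x$summary$findings_per_scenario))
    cat(sprintf("  %s: %d\n", sc, x$summary$findings_per_scenario[[sc]]))
  cat(sprintf("  unknown terms: %d/%d (%.1f%%)\n", x$summary$n_unknown,
              x$summary$n_terms, 100 * x$summary$unknown_term_rate))
  invisible(x)
}

report_to_json <- function(report) {
  s <- report$summary
  clean <- list(
    config_fingerprint = jsonlite::unbox(report$config_fingerprint),
    summary = list(
      n_claims = jsonlite::unbox(s$n_claims),
      findings_per_scenario = lapply(s$findings_per_scenario,
                                     jsonlite::unbox),
      n_terms = jsonlite::unbox(s$n_terms),
      n_unknown = jsonlite::unbox(s$n_unknown),
      unknown_term_rate = jsonlite::unbox(s$unknown_term_rate)),
    claims = lapply(report$claims, function(pc) list(
      claim_id = jsonlite::unbox(pc$claim_id),
      unknown_terms = pc$unknown_terms,
      findings = lapply(pc$findings, function(f) list(
        scenario = jsonlite::unbox(f$scenario),
        subtype = jsonlite::unbox(f$subtype),
        involved = f$involved,
        severity = jsonlite::unbox(f$severity),
        evidence = lapply(f$evidence, function(p) list(nodes = p$nodes)))))))
  jsonlite::toJSON(clean, null = "null", na = "null", pretty = TRUE)
}

#' Write a screening report as JSON
#'
#' @param report a `screening_report`
#' @param path output file
#' @return invisibly, the path
#' @export
write_report <- function(report, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  writeLines(report_to_json(report), con, useBytes = TRUE)
  close(con)
  invisible(path)
}

#' Export low-confidence links for human curation
#'
#' Collects every mention whose best score fell inside the curation band
#' `[low, tau)` — good enough to propose, not good enough to auto-link —
#' into a CSV with an empty decision column for the reviewer.
#'
#' @param link_log list of link results (e.g. `report$link_log`)
#' @param band numeric `c(low, high)`; defaults to the linker band
#' @param path optional CSV path; when `NULL` the data.frame is returned
#' @return data.frame mention / proposed / score / decision
#' @export
export_curation <- function(link_log, band = c(0.5, 0.75), path = NULL) {
  rows <- list()
  seen <- character(0)
  for (lr in link_log) {
    if (lr$mention %in% seen) next
    if (lr$score >= band[1] && lr$score < band[2]) {
      seen <- c(seen, lr$mention)
      proposed <- if (nrow(lr$candidates)) lr$candidates$node_id[1]
                  else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        mention = lr$mention, proposed = proposed, score = lr$score,
        decision = "", stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mention = character(0), proposed = character(0),
               score = numeric(0), decision = character(0))
  if (!is.null(path)) {
    con <- file(path, open = "w", encoding = "UTF-8")
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  df
}

new_entity_id <- function(graph, mention) {
  base <- sprintf("N%s", fnv1a(mention))
  id <- base; i <- 0L
  while (!is.null(graph$nodes[[id]])) { i <- i + 1L; id <- paste0(base, "_", i) }
  id
}

#' Apply reviewer curation decisions to the graph
#'
#' Decisions per mention: `accept` (add the mention as a synonym of the
#' proposed entity), `synonym_of:<node_id>`, `new_entity:<category>`, or
#' `reject` (no change). After application the graph is re-validated; a
#' subsequent [normalize_claim()] links an accepted mention with score 1.
#' This closes the self-learning loop: reviewed terms improve the next
#' round of linking.
#'
#' @param graph an `mkg` object
#' @param curation data.frame as produced by [export_curation()] with the
#'   decision column filled, or a path to such a CSV
#' @return the updated graph
#' @export
apply_curation <- function(graph, curation) {
  if (is.character(curation)) {
    con <- file(curation, encoding = "UTF-8")
    curation <- utils::read.csv(con, stringsAsFactors = FALSE)
  }
  if (anyDuplicated(curation$mention))
    abort_mkg(sprintf("conflicting decisions for mention(s): %s",
                      paste(unique(curation$mention[
                        duplicated(curation$mention)]), collapse = ", ")),
              "mkg_validation_error")
  for (i in seq_len(nrow(curation))) {
    decision <- trimws(curation$decision[i])
    mention <- curation$mention[i]
    if (decision == "" || decision == "reject") next
    if (decision == "accept") {
      target <- curation$proposed[i]
      if (is.na(target) || is.null(graph$nodes[[target]]))
        abort_mkg(sprintf("accept for '%s': proposed entity '%s' not in graph",
                          mention, target), "mkg_validation_error")
      graph$nodes[[target]]$synonyms <-
        unique(c(graph$nodes[[target]]$synonyms, mention))
    } else if (startsWith(decision, "synonym_of:")) {
      target <- sub("^synonym_of:", "", decision)
      if (is.null(graph$nodes[[target]]))
        abort_mkg(sprintf("synonym_of for '%s': node '%s' not in graph",
                          mention, target), "mkg_validation_error")
      graph$nodes[[target]]$synonyms <-
        unique(c(graph$nodes[[target]]$synonyms, mention))
    } else if (startsWith(decision, "new_entity:")) {
      category <- sub("^new_entity:", "", decision)
      graph <- add_node(graph, concept_node(
        new_entity_id(graph, mention), mention, category,
        code = if (category == "atc") mention else NA_character_))
    } else {
      abort_mkg(sprintf("unknown curation decision '%s' for '%s'",
                        decision, mention), "mkg_validation_error")
    }
  }
  validate_graph(graph)
  graph
}
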