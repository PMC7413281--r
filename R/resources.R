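# Loaders for packaged default resources: extraction pattern rules,
# dosage-form map, character attribute tables (pronunciation, radical),
# semantic-unit lexicons and the unit synonym graph.
#
# The packaged tables cover the fixture vocabulary used by the synthetic
# generators; full-coverage tables for real corpora are loaded from
# user-supplied files with the same loaders.

extdata <- function(name) {
  path <- system.file("extdata", name, package = "mkgfwa")
  if (!nzchar(path))
    abort_mkg(sprintf("packaged resource '%s' not found", name),
              "mkg_resource_error")
  path
}

#' Load property-extraction pattern rules
#'
#' Rules are regular expressions with a property category (`usage`, `dosage`,
#' `frequency`, `duration`, `population`), optional context keywords, and a
#' priority (file order). Rules with `needs_context = 1` extract raw
#' number+unit combinations and are only retained when a context keyword
#' occurs in the same clause. The packaged default file covers the standard
#' drug-label phrasings (e.g. "一次一粒", "一日3次", "18岁以下患者",
#' "静脉内注射").
#'
#' @param path TSV file with columns rule_id, category, expression,
#'   context_keywords (pipe-separated), needs_context, priority; default:
#'   the packaged rule set
#' @return data.frame of compiled-checked rules ordered by priority
#' @export
load_property_rules <- function(path = extdata("property_rules.tsv")) {
  rules <- read_tsv_utf8(path)
  need <- c("rule_id", "category", "expression", "context_keywords",
            "needs_context", "priority")
  if (!all(need %in% names(rules)))
    abort_mkg(sprintf("rule file %s lacks columns %s", path,
                      paste(setdiff(need, names(rules)), collapse = ", ")),
              "mkg_parse_error")
  if (anyDuplicated(rules$rule_id))
    abort_mkg("duplicate rule_id in rule set", "mkg_parse_error")
  for (i in seq_len(nrow(rules)))
    tryCatch(grepl(rules$expression[i], "", perl = TRUE),
             error = function(e) abort_mkg(
               sprintf("rule %s: expression does not compile: %s",
                       rules$rule_id[i], conditionMessage(e)),
               "mkg_parse_error"))
  rules[order(rules$priority), , drop = FALSE]
}

#' Load drug-drug-interaction classification rules
#'
#' Each rule is a regular expression applied to a sentence whose entity
#' mentions have been replaced by type placeholders; the first matching rule
#' (by priority) assigns the interaction category (`promotion`,
#' `contraindication`, or `none`).
#'
#' @param path TSV with columns rule_id, category, expression, priority,
#'   description; default: the packaged rule set
#' @return data.frame ordered by priority
#' @export
load_ddi_rules <- function(path = extdata("ddi_rules.tsv")) {
  rules <- read_tsv_utf8(path)
  need <- c("rule_id", "category", "expression", "priority")
  if (!all(need %in% names(rules)))
    abort_mkg("ddi rule file lacks required columns", "mkg_parse_error")
  if (anyDuplicated(rules$rule_id))
    abort_mkg("duplicate rule_id in ddi rule set", "mkg_parse_error")
  bad <- !rules$category %in% c(INTERACTION_SUBTYPES)
  if (any(bad))
    abort_mkg(sprintf("ddi rules with bad category: %s",
                      paste(rules$rule_id[bad], collapse = ", ")),
              "mkg_parse_error")
  rules[order(rules$priority), , drop = FALSE]
}

#' Load the dosage-form to usage mapping table
#'
#' Infers the administration route for drug labels that state a dosage form
#' (e.g. patch, sustained-release tablet) but no explicit usage.
#'
#' @param path TSV with columns form, usage; default: packaged table
#' @return named character vector form -> usage
#' @export
load_dosage_form_map <- function(path = extdata("dosage_form_map.tsv")) {
  df <- read_tsv_utf8(path)
  stats::setNames(df$usage, df$form)
}

#' Load a character attribute map
#'
#' An attribute map assigns each covered character an attribute value on one
#' comparison level, e.g. its pronunciation (pinyin syllable) or its radical
#' (semantic component, such as the sickness radical for disease-related
#' characters). Characters absent from the table simply have no attribute on
#' that level.
#'
#' @param path TSV with columns char, value
#' @param name level name (must match a discount name in the cost scheme)
#' @return an `attribute_map` object
#' @export
load_attribute_map <- function(path, name) {
  df <- read_tsv_utf8(path)
  attribute_map(name, stats::setNames(df$value, df$char))
}

#' Construct an attribute map from a lookup table
#'
#' @param name level name, e.g. `"pronunciation"` or `"radical"`
#' @param table named character vector, character -> attribute value
#' @return an `attribute_map` object
#' @export
attribute_map <- function(name, table) {
  stopifnot(is.character(name), length(name) == 1,
            is.character(table), !is.null(names(table)))
  structure(list(name = name, table = table), class = "attribute_map")
}

#' Packaged default attribute maps (pronunciation + radical)
#'
#' @return list of two `attribute_map` objects covering the fixture
#'   vocabulary
#' @export
default_attribute_maps <- function() {
  list(load_attribute_map(extdata("pinyin.tsv"), "pronunciation"),
       load_attribute_map(extdata("radical.tsv"), "radical"))
}

#' Load semantic-unit lexicons
#'
#' Terms grouped into unit categories (body structure, type/stage, negation,
#' degree adverb, laterality, age group, pathogen/etiology, temporal course,
#' morphology, sex); text not covered by any lexicon term forms the core
#' term during decomposition.
#'
#' @param path TSV with columns term, category; default: packaged lexicon
#' @return named list category -> character vector of terms
#' @export
load_unit_lexicons <- function(path = extdata("unit_lexicon.tsv")) {
  df <- read_tsv_utf8(path)
  split(df$term, df$category)
}

#' Load a semantic-unit synonym graph
#'
#' Per-category undirected weighted graph over unit strings; weights in
#' (0, 1] measure how exchangeable two units are (e.g. the long and short
#' surface forms of the same body structure have weight 1).
#'
#' @param path TSV with columns u, v, category, weight; default: packaged
#' @return data.frame of class `unit_synonyms`
#' @export
load_unit_synonyms <- function(path = extdata("unit_synonyms.tsv")) {
  df <- read_tsv_utf8(path)
  df$weight <- as.numeric(df$weight)
  if (any(df$weight <= 0 | df$weight > 1))
    abort_mkg("synonym weights must lie in (0, 1]", "mkg_parse_error")
  class(df) <- c("unit_synonyms", "data.frame")
  df
}

# the 11 default semantic-unit categories (core_term is the residue class)
UNIT_CATEGORIES <- c("body_structure", "laterality_position", "negation",
                     "degree_adverb", "type_stage", "pathogen_etiology",
                     "age_group", "sex", "temporal_course", "morphology",
                     "core_term")
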