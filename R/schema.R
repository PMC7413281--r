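# Closed sets and endpoint rules for the medical knowledge graph schema.
#
# Concepts: diseases (ICD-10-style hierarchy), drugs at product/generic/ATC
# level, examinations (social-insurance service codes), symptoms, operations.
# Relationships: taxonomy (is_a), drug-disease (indication, contraindication,
# treat), drug-drug (interaction, with a promotion/contraindication/none
# subtype), disease-examination (check), disease-symptom (has_symptom).

NODE_CATEGORIES <- c("disease", "drug_generic", "drug_product", "atc",
                     "examination", "symptom", "operation")

REL_TYPES <- c("is_a", "indication", "contraindication", "interaction",
               "check", "treat", "has_symptom")

INTERACTION_SUBTYPES <- c("promotion", "contraindication", "none")

DRUG_CATEGORIES <- c("drug_generic", "drug_product")

# allowed (source category, target category) pairs per relationship type
schema_rules <- function() {
  drug <- DRUG_CATEGORIES
  list(
    is_a = rbind(
      expand.grid(src = "drug_product", dst = c("drug_generic", "atc"),
                  stringsAsFactors = FALSE),
      expand.grid(src = "drug_generic", dst = "atc", stringsAsFactors = FALSE),
      data.frame(src = "atc", dst = "atc"),
      data.frame(src = "disease", dst = "disease"),
      data.frame(src = "examination", dst = "examination"),
      data.frame(src = "symptom", dst = "symptom"),
      data.frame(src = "operation", dst = "operation")
    ),
    indication = expand.grid(src = drug, dst = "disease",
                             stringsAsFactors = FALSE),
    contraindication = expand.grid(src = drug, dst = "disease",
                                   stringsAsFactors = FALSE),
    treat = expand.grid(src = drug, dst = "disease", stringsAsFactors = FALSE),
    interaction = rbind(
      data.frame(src = "atc", dst = "atc"),
      expand.grid(src = drug, dst = drug, stringsAsFactors = FALSE)
    ),
    check = data.frame(src = "disease", dst = "examination"),
    has_symptom = data.frame(src = "disease", dst = "symptom")
  )
}

# TRUE iff an edge of rel_type may run src_cat -> dst_cat
schema_allows <- function(rel_type, src_cat, dst_cat) {
  rules <- schema_rules()[[rel_type]]
  if (is.null(rules)) return(FALSE)
  any(rules$src == src_cat & rules$dst == dst_cat)
}

# pattern labels in reasoning rules -> node categories
LABEL_CATEGORIES <- list(
  Drug = DRUG_CATEGORIES,
  ATC = "atc",
  Disease = "disease",
  Examination = "examination",
  Symptom = "symptom",
  Operation = "operation"
)

label_categories <- function(label) {
  if (label %in% names(LABEL_CATEGORIES)) return(LABEL_CATEGORIES[[label]])
  if (label %in% NODE_CATEGORIES) return(label)
  abort_mkg(sprintf("unknown node label '%s'", label), "mkg_schema_error")
}
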