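# path-pattern parsing/matching and the three detectors

test_that("pattern parsing supports labels, arrows, and hop ranges, and
           round-trips", {
  for (txt in unname(default_reasoning_rules())) {
    p <- parse_pattern(txt)
    expect_identical(format(p), txt)
    expect_identical(format(parse_pattern(format(p))), txt)
  }
  fraud <- parse_pattern(default_reasoning_rules()[["fraud_diagnosis"]])
  expect_length(fraud$labels, 5L)
  ranged <- vapply(fraud$edges, function(e) e$lo == 0 && e$hi == 1,
                   logical(1))
  expect_equal(sum(ranged), 2L)
  expect_identical(fraud$edges[[1]]$direction, "undirected")
  expect_identical(fraud$edges[[2]]$direction, "left")
  p2 <- parse_pattern("(Drug)-[:is_a]->(ATC)")
  expect_length(p2$labels, 2L)
  expect_identical(p2$edges[[1]]$direction, "right")
  expect_error(parse_pattern("(Drug)-[:is_a*2..1]->(ATC)"),
               class = "mkg_parse_error")
  expect_error(parse_pattern("(Drug)-[:is_a]->"), class = "mkg_parse_error")
  expect_error(parse_pattern("(Drug)<-[:is_a]->(ATC)"),
               class = "mkg_parse_error")
  expect_error(parse_pattern("Drug-[:is_a]->(ATC)"), class = "mkg_parse_error")
})

test_that("match_pattern handles zero-hop collapse and anchored instantiation", {
  g <- tiny_graph()
  m <- match_pattern(g, "(ATC)-[:is_a*0..0]->(ATC)",
                     anchors = c("1" = "a1", "2" = "a1"))
  expect_length(m, 1L)
  expect_identical(m[[1]]$nodes, "a1")
  expect_length(m[[1]]$erows, 0L)
  # anchored fraud pattern: needs a disease one is_a step from d1 whose
  # indication reaches an ATC sibling of g1
  g2 <- add_edge(g, relation_edge("d2", "d1", "is_a"))
  g2 <- add_edge(g2, relation_edge("g2", "d2", "indication"))
  m2 <- match_pattern(
    g2, default_reasoning_rules()[["fraud_diagnosis"]],
    anchors = c("1" = "d1", "5" = "g1"))
  expect_gt(length(m2), 0L)
  expect_true(all(vapply(m2, function(p) validate_evidence(g2, p),
                         logical(1))))
  # every match binds the anchored slots
  expect_true(all(vapply(m2, function(p)
    p$slots[1] == "d1" && p$slots[5] == "g1", logical(1))))
  expect_error(match_pattern(g, "(Drug)-[:is_a]->(ATC)",
                             anchors = c("7" = "g1")),
               class = "mkg_argument_error")
  expect_error(match_pattern(g, "(Drug)-[:is_a]->(ATC)",
                             anchors = c("1" = "missing")),
               class = "mkg_lookup_error")
})

test_that("match_pattern equals brute-force DFS enumeration on random graphs", {
  rules <- default_reasoning_rules()
  for (seed in 1:20) {
    g <- random_graph(seed + 500, n_nodes = sample(10:30, 1), p_edge = 0.12)
    for (rule in rules) {
      got <- match_signatures(match_pattern(g, rule))
      want <- match_signatures(oracle_match(g, rule))
      expect_identical(got, want, label = sprintf("seed %d", seed))
    }
    # small extra patterns incl. undirected and pure-range steps
    for (rule in c("(Drug)-[:is_a]->(ATC)-[:is_a*0..2]->(ATC)",
                   "(Disease)-[:is_a]-(Disease)")) {
      expect_identical(match_signatures(match_pattern(g, rule)),
                       match_signatures(oracle_match(g, rule)))
    }
  }
})

test_that("fraud-diagnosis detection emits uncovered, contraindicated, and
           no-indication findings", {
  g <- tiny_graph()
  # claim in the style of an immunoglobulin claim: one covered disease, one
  # diagnosis no claimed drug treats
  g <- add_node(g, concept_node("d3", "目亏症", "disease", code = "C009"))
  claim <- linked_claim_fixture("c1", c("d1", "d3"), "g1")
  f <- detect_fraud_diagnosis(claim, g)
  expect_length(f, 1L)
  expect_identical(f[[1]]$subtype, "uncovered_disease")
  expect_identical(f[[1]]$involved, "d3")
  expect_length(f[[1]]$evidence, 0L)  # absence finding
  # every disease indicated by some claimed drug -> no findings
  claim2 <- linked_claim_fixture("c2", "d1", "g1")
  expect_length(detect_fraud_diagnosis(claim2, g), 0L)
  # contraindication edge g3 -x-> d1 plus coverage via g1
  claim3 <- linked_claim_fixture("c3", c("d1", "d2"), c("g1", "g3"))
  f3 <- detect_fraud_diagnosis(claim3, g)
  expect_true(any(vapply(f3, function(x)
    identical(x$subtype, "contraindicated") &&
      setequal(x$involved, c("d1", "g3")), logical(1))))
  contra <- f3[[which(vapply(f3, function(x)
    identical(x$subtype, "contraindicated"), logical(1)))[1]]]
  expect_gt(length(contra$evidence), 0L)
  expect_true(all(vapply(contra$evidence, function(p)
    validate_evidence(g, p), logical(1))))
  expect_identical(contra$severity, "high")
  # drug covering nothing -> no_indication naming the drug
  g4 <- add_node(g, concept_node("g9", "布尼多", "drug_generic"))
  claim4 <- linked_claim_fixture("c4", "d1", c("g1", "g9"))
  f4 <- detect_fraud_diagnosis(claim4, g4)
  expect_length(f4, 1L)
  expect_identical(f4[[1]]$subtype, "no_indication")
  expect_true("g9" %in% f4[[1]]$involved)
  # empty claim -> no findings
  expect_length(detect_fraud_diagnosis(
    linked_claim_fixture("c5", character(0), character(0)), g), 0L)
})

test_that("coverage extends over disease taxonomy adjacency and ATC siblings", {
  g <- tiny_graph()
  # g2 (same ATC class as g1) indicates d1; a claim of (d1, g1) must count
  # d1 as covered through the sibling, so no uncovered finding
  claim <- linked_claim_fixture("c1", "d1", "g1")
  expect_length(detect_fraud_diagnosis(claim, g), 0L)
  # one undirected is_a step: claim diagnosis dp (parent) with drug g1
  # indicated for child d1 counts as covered
  claim2 <- linked_claim_fixture("c2", "dp", "g1")
  expect_length(detect_fraud_diagnosis(claim2, g), 0L)
})

test_that("excess-prescription detection requires a shared ATC class and
           per-drug indication, with a configurable threshold", {
  g <- tiny_graph()  # g1, g2 under a1, both indicated for d1
  claim <- linked_claim_fixture("c1", "d1", c("g1", "g2"))
  f <- detect_excess_prescription(claim, g)
  expect_length(f, 1L)
  expect_true(setequal(f[[1]]$involved, c("d1", "g1", "g2")))
  expect_true(all(vapply(f[[1]]$evidence, function(p)
    validate_evidence(g, p), logical(1))))
  # drugs in different ATC classes -> no finding
  claim2 <- linked_claim_fixture("c2", c("d1", "d2"), c("g1", "g3"))
  expect_length(detect_excess_prescription(claim2, g), 0L)
  # threshold raised to 3 with only 2 duplicates -> no finding
  expect_length(detect_excess_prescription(
    claim, g, detector_config(excess_threshold = 3)), 0L)
  # the shared-class drug must itself be indicated for the disease
  g3 <- tiny_graph()
  g3$edges <- g3$edges[!(g3$edges$source == "g2" &
                           g3$edges$rel_type == "indication"), ]
  expect_length(detect_excess_prescription(claim, g3), 0L)
})

test_that("irrational-prescription detection finds ATC-level interactions
           with severity by subtype", {
  g <- tiny_graph()
  g <- add_edge(g, relation_edge("a1", "a2", "interaction",
                                 subtype = "contraindication"))
  claim <- linked_claim_fixture("c1", c("d1", "d2"), c("g1", "g3"))
  f <- detect_irrational_prescription(claim, g)
  expect_length(f, 1L)
  expect_identical(f[[1]]$severity, "high")
  expect_identical(f[[1]]$subtype, "contraindication")
  expect_true(setequal(f[[1]]$involved, c("g1", "g3")))
  expect_true(all(vapply(f[[1]]$evidence, function(p)
    validate_evidence(g, p), logical(1))))
  # promotion -> informational severity
  g2 <- tiny_graph()
  g2 <- add_edge(g2, relation_edge("a1", "a2", "interaction",
                                   subtype = "promotion"))
  f2 <- detect_irrational_prescription(claim, g2)
  expect_identical(f2[[1]]$severity, "info")
  # none-subtype edges never flag
  g3 <- tiny_graph()
  g3 <- add_edge(g3, relation_edge("a1", "a2", "interaction",
                                   subtype = "none"))
  expect_length(detect_irrational_prescription(claim, g3), 0L)
  # single-drug claim -> no findings
  expect_length(detect_irrational_prescription(
    linked_claim_fixture("c2", "d1", "g1"), g), 0L)
  # interactions climb the ATC hierarchy within the hop bound
  g4 <- tiny_graph()
  g4 <- add_node(g4, concept_node("a9", "Z类药物", "atc", code = "Z"))
  g4 <- add_edge(g4, relation_edge("a0", "a9", "is_a"))
  g4 <- add_edge(g4, relation_edge("a9", "a2", "interaction",
                                   subtype = "contraindication"))
  f4 <- detect_irrational_prescription(claim, g4)
  expect_length(f4, 1L)  # a9 is an ancestor of g1 via a1 -> a0 -> a9
  expect_length(detect_irrational_prescription(
    claim, g4, detector_config(atc_extra_hops = 0)), 0L)
})

test_that("strict-literal mode flags shared ATC ancestry without an
           interaction edge", {
  g <- tiny_graph()
  claim <- linked_claim_fixture("c1", "d1", c("g1", "g2"))  # both under a1
  expect_length(detect_irrational_prescription(claim, g), 0L)
  f <- detect_irrational_prescription(
    claim, g, detector_config(strict_literal_irrational = TRUE))
  expect_length(f, 1L)
  expect_identical(f[[1]]$subtype, "shared_atc_ancestor")
})

test_that("detectors are monotone in the evidence edges", {
  set.seed(33)
  for (seed in 1:6) {
    params <- generator_params(seed = seed, n_diseases = 20, n_drugs = 18,
                               interaction_rate = 0.15)
    g <- generate_toy_kg(params)
    e <- g$edges
    diseases <- mkgfwa:::nodes_of_category(g, "disease")
    drugs <- mkgfwa:::nodes_of_category(g, mkgfwa:::DRUG_CATEGORIES)
    claim <- linked_claim_fixture(
      "m1", sample(diseases, 2), sample(drugs, 3))
    base_fraud <- length(detect_fraud_diagnosis(claim, g))
    # adding an indication edge never increases fraud findings
    g_more <- add_edge(g, relation_edge(claim$drugs[1], claim$diagnoses[1],
                                        "indication"))
    expect_lte(length(detect_fraud_diagnosis(claim, g_more)), base_fraud)
    # removing an interaction edge never increases irrational findings
    base_irr <- length(detect_irrational_prescription(claim, g))
    inter <- which(e$rel_type == "interaction")
    if (length(inter)) {
      g_less <- g
      g_less$edges <- e[-inter[1], , drop = FALSE]
      expect_lte(length(detect_irrational_prescription(claim, g_less)),
                 base_irr)
    }
  }
})

test_that("screen concatenates the three detectors deterministically", {
  g <- tiny_graph()
  g <- add_edge(g, relation_edge("a1", "a2", "interaction",
                                 subtype = "contraindication"))
  g <- add_node(g, concept_node("d3", "目亏症", "disease"))
  # one planted event of each type in a single claim
  claim <- linked_claim_fixture("c1", c("d1", "d3"), c("g1", "g2", "g3"))
  f <- screen(claim, g)
  scen <- vapply(f, `[[`, character(1), "scenario")
  expect_true(all(c("fraud_diagnosis", "excess_prescription",
                    "irrational_prescription") %in% scen))
  ord <- as.integer(factor(scen, levels = c("fraud_diagnosis",
                                            "excess_prescription",
                                            "irrational_prescription")))
  expect_true(!is.unsorted(ord))  # stable order: fraud, excess, irrational
  expect_identical(serialize(screen(claim, g), NULL),
                   serialize(screen(claim, g), NULL))
  # clean claim -> empty
  expect_length(screen(linked_claim_fixture("c2", "d1", "g1"), g), 0L)
  # all evidence paths re-validate
  for (x in f)
    for (p in x$evidence)
      expect_true(validate_evidence(g, p))
})
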