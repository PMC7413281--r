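# dictionary tagging, B-I-O repair, property extraction and combination,
# interaction-sentence classification

lex_fixture <- c("帕金森综合症" = "Disease", "糖尿病" = "Disease",
                 "糖尿病足" = "Disease", "贾第虫病" = "Disease",
                 "氨苯平" = "Drug", "洛伐汀" = "Drug")

test_that("dictionary tagging is leftmost-longest and exact-span", {
  ts <- dictionary_tag("患者患有帕金森综合症多年", lex_fixture)
  expect_identical(ts$tags[5:10],
                   c("B-Disease", rep("I-Disease", 5)))
  expect_true(all(ts$tags[c(1:4, 11:12)] == "O"))
  # no lexicon term present -> all O
  expect_true(all(dictionary_tag("身体健康", lex_fixture)$tags == "O"))
  # overlapping terms: the longer match wins
  ts2 <- dictionary_tag("诊断为糖尿病足部溃烂", lex_fixture)
  m <- collect_mentions(ts2)
  expect_identical(m[[1]]$surface, "糖尿病足")
  # empty text
  expect_length(dictionary_tag("", lex_fixture)$tags, 0L)
})

test_that("adjust_tags repairs incomplete spans and mixed types", {
  # incomplete span: model tagged only the first half of the entity
  ts <- tag_sequence("帕金森综合症",
                     c("B-Disease", "I-Disease", "I-Disease", "O", "O", "O"))
  fixed <- adjust_tags(ts, lex_fixture)
  expect_identical(fixed$tags, c("B-Disease", rep("I-Disease", 5)))
  # mixed types resolve to the majority type
  ts2 <- tag_sequence("帕金森综合症",
                      c("B-Disease", "I-Drug", "I-Disease",
                        "I-Disease", "I-Disease", "I-Disease"))
  fixed2 <- adjust_tags(ts2, c("无关词" = "Drug"))
  expect_identical(fixed2$tags, c("B-Disease", rep("I-Disease", 5)))
  # dangling I- run (inconsistent tagging) is re-emitted as valid B-I-O
  ts3 <- tag_sequence("糖尿病人", c("I-Disease", "I-Disease", "I-Disease", "O"))
  fixed3 <- adjust_tags(ts3, lex_fixture)
  expect_identical(fixed3$tags, c("B-Disease", "I-Disease", "I-Disease", "O"))
  # already-valid correct tagging is unchanged
  ok <- dictionary_tag("患有糖尿病的病人", lex_fixture)
  expect_identical(adjust_tags(ok, lex_fixture)$tags, ok$tags)
})

random_corruption <- function(text, lexicon) {
  n <- nchar(text)
  tags <- dictionary_tag(text, lexicon)$tags
  types <- c("Disease", "Drug")
  for (k in seq_len(sample(1:4, 1))) {
    i <- sample(n, 1)
    tags[i] <- sample(c("O", paste0(sample(c("B-", "I-"), 1),
                                    sample(types, 1))), 1)
  }
  tags
}

test_that("adjust_tags always yields valid B-I-O and is idempotent on random
           corruptions", {
  set.seed(42)
  texts <- c("患者患有帕金森综合症多年", "诊断为糖尿病足部溃烂",
             "给予氨苯平与洛伐汀治疗", "复查提示贾第虫病未愈")
  for (rep in 1:200) {
    text <- sample(texts, 1)
    tags <- random_corruption(text, lex_fixture)
    out <- adjust_tags(tag_sequence(text, tags), lex_fixture)
    expect_true(mkgfwa:::is_valid_bio(out$tags))
    again <- adjust_tags(out, lex_fixture)
    expect_identical(again$tags, out$tags)
  }
})

test_that("collect_mentions extracts maximal runs with half-open spans", {
  expect_length(collect_mentions(tag_sequence("无", "O")), 0L)
  ts <- dictionary_tag("糖尿病与氨苯平", lex_fixture)
  m <- collect_mentions(ts)
  expect_length(m, 2L)
  expect_identical(m[[1]]$surface, "糖尿病")
  expect_equal(m[[1]]$start, 0L)
  expect_equal(m[[1]]$end, 3L)
  expect_identical(m[[2]]$etype, "Drug")
  expect_equal(substr("糖尿病与氨苯平", m[[2]]$start + 1, m[[2]]$end),
               m[[2]]$surface)
  expect_error(collect_mentions(tag_sequence("糖尿", c("I-Disease", "O"))),
               class = "mkg_argument_error")
})

test_that("property patterns fire with their documented categories", {
  cases <- list(
    list(text = "一次一粒", category = "dosage"),
    list(text = "10毫克/kg体重", category = "dosage"),
    list(text = "一日3次", category = "frequency"),
    list(text = "连续10天", category = "duration"),
    list(text = "18岁以下患者", category = "population"),
    list(text = "饭后口服", category = "usage"),
    list(text = "静脉内注射", category = "usage"))
  for (cs in cases) {
    hits <- recognize_properties(cs$text)
    expect_true(cs$category %in% vapply(hits, `[[`, character(1), "category"),
                label = sprintf("'%s' fires %s", cs$text, cs$category))
  }
  # normalized payloads
  h <- recognize_properties("一日3次")[[1]]
  expect_equal(h$value$low, 3)
  expect_identical(h$value$per, "day")
  h2 <- Filter(function(x) x$category == "population",
               recognize_properties("18岁以下患者"))[[1]]
  expect_equal(h2$value$low, 18)
  expect_identical(h2$value$relation, "<")
  h3 <- Filter(function(x) x$category == "dosage",
               recognize_properties("成人一次0.4-0.6克"))[[1]]
  expect_equal(h3$value$low, 0.4)
  expect_equal(h3$value$high, 0.6)
  expect_identical(h3$value$unit, "克")
})

test_that("every hit's raw substring re-matches its producing pattern", {
  rules <- load_property_rules()
  texts <- c("成人口服，一次0.4-0.6克，一日3次，连续7日。",
             "儿童一日35-50毫克/kg体重，分3次口服，连续10日。",
             "18岁以下患者禁用，一次一粒，疗程5天。")
  for (text in texts) {
    for (h in recognize_properties(text, rules)) {
      expr <- rules$expression[rules$rule_id == h$rule_id]
      expect_true(grepl(expr, h$raw, perl = TRUE))
      expect_identical(substr(text, h$start + 1, h$end), h$raw)
    }
  }
})

test_that("prohibition contexts exclude population hits from entries", {
  text <- "1岁以下儿童禁用。"
  hits <- filter_prohibited(recognize_properties(text), text)
  pops <- Filter(function(h) h$category == "population", hits)
  expect_true(all(vapply(pops, `[[`, character(1), "polarity") ==
                    "prohibited"))
  res <- combine_properties(hits)
  expect_length(res$entries, 0L)
  expect_true(all(res$discarded$reason == "prohibited_context"))
  # same text without the prohibition keyword is retained
  text2 <- "1岁以下儿童减量。"
  hits2 <- filter_prohibited(recognize_properties(text2), text2)
  expect_true(all(vapply(hits2, `[[`, character(1), "polarity") ==
                    "affirmative"))
  expect_identical(filter_prohibited(list(), text), list())
})

test_that("dosage-form mapping infers usage", {
  expect_identical(infer_usage("贴剂"), "外用")
  expect_identical(infer_usage("缓释片"), "口服")
  expect_identical(infer_usage("直肠栓剂"), "肛门用药")
  expect_identical(infer_usage("洗剂"), "外用")
  expect_identical(infer_usage("肠溶片"), "口服")
  expect_true(is.na(infer_usage("未知剂型")))
})

metronidazole_style_text <- paste0(
  "成人口服，一次0.4-0.6克，一日3次，连续7日，用于治疗肠道阿米巴病。",
  "治疗贾第虫病时，成人一次0.4克，一日3次，连续5-10日。",
  "儿童治疗阿米巴病，一日35-50毫克/kg体重，分3次口服，连续10日。",
  "治疗贾第虫病时，一日15-25毫克/kg体重，分3次服用，连续10日。")

metro_lexicon <- c("肠道阿米巴病" = "Disease", "阿米巴病" = "Disease",
                   "贾第虫病" = "Disease")

test_that("property combination yields one entry per population/indication
           context with inheritance", {
  res <- extract_medication_entries(metronidazole_style_text, metro_lexicon)
  expect_length(res$entries, 4L)
  inds <- vapply(res$entries, function(e) e$indication$term, character(1))
  expect_identical(inds, c("肠道阿米巴病", "贾第虫病", "阿米巴病", "贾第虫病"))
  pops <- vapply(res$entries, function(e) e$population$term, character(1))
  # entry 4 names no population in its sentence: inherited from entry 3
  expect_identical(pops, c("成人", "成人", "儿童", "儿童"))
  # single sentence with one full property set -> one entry
  res1 <- extract_medication_entries(
    "成人口服，一次一粒，一日3次，连续7日，用于治疗贾第虫病。", metro_lexicon)
  expect_length(res1$entries, 1L)
  # affirmative hits are conserved: assigned or logged
  n_assigned <- sum(vapply(res$entries, function(e) length(e$provenance),
                           integer(1)))
  affirmative <- sum(vapply(res$hits, function(h)
    h$polarity == "affirmative", logical(1)))
  expect_equal(n_assigned + nrow(res$discarded), affirmative)
})

test_that("a population switch blocks inheritance of frequency and duration", {
  text <- paste0("成人口服一次2片，一日3次，连续7日，用于治疗贾第虫病。",
                 "儿童一次1片。")
  res <- extract_medication_entries(text, metro_lexicon)
  expect_length(res$entries, 2L)
  e2 <- res$entries[[2]]
  expect_identical(e2$population$term, "儿童")
  expect_null(e2$frequency)   # not inherited across the population change
  expect_null(e2$duration)
  expect_false(is.null(e2$usage))  # usage still inherits
  expect_error(combine_properties(list(list(category = "dosage", raw = "x",
                                            value = list(), start = 0, end = 1,
                                            sentence = NA_integer_,
                                            polarity = "affirmative"))),
               class = "mkg_argument_error")
})

test_that("interaction sentences classify into their documented categories", {
  expect_identical(classify_relation("硝苯地平禁止与利福平合用"),
                   "contraindication")
  expect_identical(classify_relation("氯甲苯酸与青霉素有配伍禁忌"),
                   "contraindication")
  expect_identical(
    classify_relation("磺胺嘧啶片有可能干扰青霉素类药物的杀菌作用"),
    "contraindication")
  expect_identical(
    classify_relation("盐酸昂丹司琼口腔崩解片与地塞米松合用可加强止吐效果"),
    "promotion")
  expect_identical(classify_relation("维生素C可增强盐酸吗啉胍注射液的疗效"),
                   "promotion")
  expect_identical(classify_relation("扎来普隆胶囊与帕罗西丁无相互作用"),
                   "none")
  expect_identical(
    classify_relation("苯磺酸氨氯地平片不改变华法林的凝血酶原作用时间"),
    "none")
  expect_identical(classify_relation("两种药物可以一起服用"), "no_match")
})

test_that("classification masks mentions with type placeholders and rejects
           overlapping spans", {
  s <- "氨苯平禁止与洛伐汀合用"
  ts <- dictionary_tag(s, lex_fixture)
  m <- collect_mentions(ts)
  expect_length(m, 2L)
  expect_identical(classify_relation(s, m), "contraindication")
  bad <- list(list(surface = "氨苯平", start = 0L, end = 3L, etype = "Drug"),
              list(surface = "苯平禁", start = 1L, end = 4L, etype = "Drug"))
  expect_error(classify_relation(s, bad), class = "mkg_argument_error")
  expect_error(classify_relation(s, m[1]), class = "mkg_argument_error")
})
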