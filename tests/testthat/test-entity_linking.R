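# multilevel edit distance, semantic-unit decomposition, composite
# similarity, inverted-index retrieval, and mention linking

maps <- default_attribute_maps()

test_that("multilevel distance handles identity, insertions, and discounted
           homophone substitutions", {
  expect_equal(multilevel_distance("糖尿病", "糖尿病", maps), 0)
  expect_equal(multilevel_distance("", "糖尿病"), 3)
  expect_equal(multilevel_distance("糖尿病", ""), 3)
  # homophone 唐/糖 share pronunciation "tang": discounted to 0.2
  expect_equal(multilevel_distance("唐尿病", "糖尿病", maps), 0.2)
  expect_equal(multilevel_distance("唐尿病", "糖尿病"), 1)
  # radical siblings 病/症 share the sickness radical: discounted to 0.5
  expect_equal(multilevel_distance("肝风病", "肝风症", maps), 0.5)
  expect_error(cost_scheme(sub_full = 0.1,
                           discounts = c(pronunciation = 0.2)),
               class = "mkg_argument_error")
  expect_error(cost_scheme(insert = 0), class = "mkg_argument_error")
})

test_that("multilevel distance equals the exhaustive edit-script oracle", {
  alphabet <- c("糖", "唐", "尿", "病", "症", "汀")
  schemes <- list(
    cost_scheme(),
    cost_scheme(insert = 0.8, delete = 1.2, sub_full = 1.5,
                discounts = c(pronunciation = 0.3, radical = 0.9)),
    cost_scheme(insert = 2, delete = 2, sub_full = 3,
                discounts = c(pronunciation = 1, radical = 2)))
  set.seed(101)
  for (costs in schemes) {
    for (k in 1:150) {
      a <- rand_string(alphabet, 4); b <- rand_string(alphabet, 4)
      expect_equal(multilevel_distance(a, b, maps, costs),
                   oracle_distance(a, b, maps, costs),
                   label = sprintf("d('%s','%s')", a, b))
    }
  }
})

test_that("discounts never increase the distance and a single-level scheme
           satisfies the triangle inequality", {
  alphabet <- c("糖", "唐", "尿", "病", "症", "汀", "肝", "甘")
  set.seed(7)
  plain <- cost_scheme(discounts = c(pronunciation = 0.999))
  for (k in 1:300) {
    a <- rand_string(alphabet); b <- rand_string(alphabet)
    expect_lte(multilevel_distance(a, b, maps),
               multilevel_distance(a, b, list()))
  }
  # pronunciation classes are equivalence classes, so char costs are a
  # metric and the string distance inherits the triangle inequality
  pron <- maps[[1]]
  for (k in 1:100) {
    a <- rand_string(alphabet); b <- rand_string(alphabet)
    c_ <- rand_string(alphabet)
    dab <- multilevel_distance(a, b, list(pron))
    dbc <- multilevel_distance(b, c_, list(pron))
    dac <- multilevel_distance(a, c_, list(pron))
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("string similarity is normalized to [0, 1]", {
  expect_equal(string_similarity("糖尿病", "糖尿病"), 1)
  expect_equal(string_similarity("", ""), 1)
  expect_equal(string_similarity("甲乙丙", "丁戊己"), 0)
  expect_equal(string_similarity("唐尿病", "糖尿病", maps), 1 - 0.2 / 3,
               tolerance = 1e-12)
  set.seed(11)
  for (k in 1:50) {
    a <- rand_string(c("糖", "唐", "病")); b <- rand_string(c("糖", "唐", "病"))
    s <- string_similarity(a, b, maps)
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("decomposition segments names into semantic units that concatenate
           back to the name", {
  lex <- load_unit_lexicons()
  u <- decompose("手部擦伤", lex)
  expect_identical(vapply(u, `[[`, character(1), "ucat"),
                   c("body_structure", "core_term"))
  expect_identical(u[[1]]$text, "手部")
  u2 <- decompose("ii 型糖尿病", lex)
  expect_identical(u2[[1]]$ucat, "type_stage")
  expect_identical(u2[[1]]$text, "ii 型")
  expect_identical(u2[[2]]$text, "糖尿病")
  # no lexicon hits -> single core_term
  u3 <- decompose("氨苯平", lex)
  expect_length(u3, 1L)
  expect_identical(u3[[1]]$ucat, "core_term")
  expect_length(decompose("", lex), 0L)
  for (name in c("急性肝风病", "左侧手部扭伤", "无名症状", "重度腰部劳损")) {
    parts <- vapply(decompose(name, lex), `[[`, character(1), "text")
    expect_identical(paste(parts, collapse = ""), name)
  }
})

test_that("unit similarity uses the synonym graph, 2-hop products, then the
           string fallback", {
  syn <- load_unit_synonyms()
  bs <- function(x) list(text = x, ucat = "body_structure")
  expect_equal(unit_similarity(bs("手部"), bs("手部"), syn), 1)
  expect_equal(unit_similarity(bs("手臂"), bs("前肢"), syn), 0.9)
  expect_equal(unit_similarity(bs("手部"), bs("手"), syn), 1)
  # 2-hop: 1型 - i型 - "i 型"
  ts <- function(x) list(text = x, ucat = "type_stage")
  expect_equal(unit_similarity(ts("1型"), ts("i 型"), syn), 1)
  # no synonym path: falls back to string similarity
  expect_equal(unit_similarity(bs("肘部"), bs("膝部"), syn, maps),
               string_similarity("肘部", "膝部", maps))
  expect_error(unit_similarity(bs("手部"), ts("i 型"), syn),
               class = "mkg_argument_error")
})

test_that("composite similarity is symmetric, 1 on identity, and capped on
           critical-category mismatches", {
  cfg <- linker_config()
  expect_equal(composite_similarity("手部擦伤", "手部擦伤", cfg)$score, 1)
  cs <- composite_similarity("ii 型糖尿病", "i 型糖尿病", cfg)
  expect_lte(cs$score, cfg$cap)
  expect_true(cs$breakdown$capped)
  expect_gt(cs$breakdown$string, 0.8)
  # symmetric under symmetric configuration
  set.seed(3)
  names_pool <- c("手部擦伤", "手擦伤", "ii 型糖尿病", "肝风病", "急性肝风病")
  for (k in 1:10) {
    ab <- sample(names_pool, 2)
    expect_equal(composite_similarity(ab[1], ab[2], cfg)$score,
                 composite_similarity(ab[2], ab[1], cfg)$score,
                 tolerance = 1e-12)
  }
  # short/long body-structure forms stay linkable
  expect_gt(composite_similarity("手擦伤", "手部擦伤", cfg)$score, cfg$tau)
  expect_error(linker_config(w_string = 0, w_unit = 0),
               class = "mkg_argument_error")
})

test_that("inverted-index retrieval matches a brute-force scan", {
  g <- generate_toy_kg(generator_params(seed = 5, n_diseases = 60,
                                        n_drugs = 50))
  idx <- build_index(g, maps)
  all_names <- data.frame(
    node_id = rep(names(g$nodes),
                  vapply(g$nodes, function(n)
                    length(unique(c(n$name, n$synonyms))), integer(1))),
    name = unlist(lapply(g$nodes, function(n) unique(c(n$name, n$synonyms)))),
    stringsAsFactors = FALSE)
  keys_of <- function(s) {
    cs <- unique(strsplit(tolower(s), "")[[1]])
    ks <- cs
    for (m in maps) {
      v <- m$table[cs]; v <- v[!is.na(v)]
      if (length(v)) ks <- c(ks, paste0(m$name, ":", unique(v)))
    }
    unique(ks)
  }
  set.seed(8)
  mentions <- c(sample(all_names$name, 5), "唐风病", "洛伐汀", "不相干词")
  for (mention in mentions) {
    got <- retrieve_candidates(mention, idx, k = 10)
    mk <- keys_of(mention)
    ov <- vapply(all_names$name, function(nm)
      length(intersect(mk, keys_of(nm))), integer(1))
    scan <- all_names[ov > 0, , drop = FALSE]
    scan$overlap <- ov[ov > 0]
    scan <- scan[order(-scan$overlap, nchar(scan$name), scan$name,
                       method = "radix"), ]
    scan <- scan[!duplicated(scan$node_id), ][seq_len(min(10, sum(ov > 0))), ]
    expect_identical(got$node_id, scan$node_id, label = mention)
    expect_identical(got$overlap, scan$overlap)
  }
  # mention sharing nothing with any name
  expect_equal(nrow(retrieve_candidates("xyz", idx, 5)), 0L)
  expect_error(retrieve_candidates("糖", idx, 0), class = "mkg_argument_error")
})

test_that("mention linking links exact names at 1.0, resolves homophone
           typos, and declares gibberish unknown", {
  g <- tiny_graph()
  cfg <- linker_config()
  idx <- build_index(g, cfg$maps)
  lr <- link_mention("氨苯平", g, idx, cfg)
  expect_identical(lr$decision, "linked")
  expect_identical(lr$entity, "g1")
  expect_equal(lr$score, 1)
  # homophone typo of a stored disease links to it
  lr2 <- link_mention("肝风柄", g, idx, cfg)  # 柄 is a homophone of 病
  expect_identical(lr2$decision, "linked")
  expect_identical(lr2$entity, "d1")
  expect_gte(lr2$score, cfg$tau)
  lr3 <- link_mention("毫无关联词语", g, idx, cfg)
  expect_identical(lr3$decision, "unknown")
  expect_error(link_mention("", g, idx, cfg), class = "mkg_argument_error")
  # candidates are sorted by score
  expect_true(all(diff(lr2$candidates$score) <= 1e-12))
})

test_that("multilevel linking beats plain edit distance on a corrupted-name
           benchmark at the same threshold", {
  g <- generate_toy_kg(generator_params(seed = 21))
  cfg_multi <- linker_config()
  cfg_plain <- linker_config(maps = list(), lexicons = NULL)
  idx_multi <- build_index(g, cfg_multi$maps)
  idx_plain <- build_index(g, list())
  lex <- load_unit_lexicons()
  set.seed(77)
  names_all <- vapply(g$nodes, `[[`, character(1), "name")
  targets <- sample(names(names_all)[
    vapply(g$nodes, function(n) n$category == "disease", logical(1))], 120,
    replace = TRUE)
  n_multi <- 0L; n_plain <- 0L; n_tested <- 0L
  for (id in targets) {
    corrupted <- suppressWarnings(corrupt_name(
      names_all[[id]], c(homophone = 0.7, radical = 0, drop = 0.3),
      maps, lex))
    if (corrupted == names_all[[id]]) next
    n_tested <- n_tested + 1L
    if (identical(link_mention(corrupted, g, idx_multi, cfg_multi)$entity, id))
      n_multi <- n_multi + 1L
    if (identical(link_mention(corrupted, g, idx_plain, cfg_plain)$entity, id))
      n_plain <- n_plain + 1L
  }
  expect_gt(n_tested, 80)
  expect_gte(n_multi, n_plain)
  expect_gt(n_multi / n_tested, 0.9)
})
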