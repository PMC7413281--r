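# Rule-based information extraction from drug-label-like text:
# dictionary entity tagging with B-I-O repair, pattern-based property value
# recognition/combination, and pattern-based drug-drug-interaction sentence
# classification. Tokenization is per unicode character; spans are 0-based
# half-open character intervals.

ENTITY_TYPES <- c("Disease", "Drug", "Examination", "Symptom", "Operation")

#' Construct a tag sequence
#'
#' @param text a string
#' @param tags character vector of per-character labels, each `"O"` or
#'   `"B-<Type>"`/`"I-<Type>"`
#' @return a `tag_sequence` object
#' @export
tag_sequence <- function(text, tags) {
  if (length(tags) != length(chars(text)))
    abort_mkg("tags length must equal character count of text",
              "mkg_argument_error")
  structure(list(text = text, tags = as.character(tags)),
            class = "tag_sequence")
}

# lexicon: accepts named chr vector (term -> type) or data.frame(term, etype)
as_lexicon <- function(lexicon) {
  if (is.data.frame(lexicon)) {
    stopifnot(all(c("term", "etype") %in% names(lexicon)))
    lexicon <- stats::setNames(lexicon$etype, lexicon$term)
  }
  if (is.null(names(lexicon)) || any(!nzchar(names(lexicon))))
    abort_mkg("lexicon must map terms to entity types", "mkg_argument_error")
  lexicon
}

lexicon_env <- function(lexicon) {
  env <- new.env(parent = emptyenv(), size = max(29L, length(lexicon)))
  for (i in seq_along(lexicon)) assign(names(lexicon)[i], lexicon[[i]], env)
  env
}

#' Dictionary-based entity tagging
#'
#' Greedy leftmost-longest matching of lexicon terms; matched spans receive
#' `B-<Type> I-<Type>...` labels, everything else `"O"`. When two terms
#' overlap at a position the longer match wins (e.g. a term that extends
#' another, like a site-specific disease name extending the generic one).
#'
#' @param text a string
#' @param lexicon named character vector term -> entity type, or a
#'   data.frame with columns `term`, `etype`
#' @return a [tag_sequence()]
#' @export
#' @examples
#' dictionary_tag("患有糖尿病", c("糖尿病" = "Disease"))
dictionary_tag <- function(text, lexicon) {
  lexicon <- as_lexicon(lexicon)
  if (length(lexicon) == 0)
    abort_mkg("lexicon must be non-empty", "mkg_argument_error")
  cs <- chars(text)
  n <- length(cs)
  tags <- rep("O", n)
  if (n == 0) return(tag_sequence(text, tags))
  env <- lexicon_env(lexicon)
  maxlen <- max(nchar(names(lexicon)))
  i <- 1L
  while (i <= n) {
    hit_len <- 0L
    for (len in seq(min(maxlen, n - i + 1L), 1L)) {
      cand <- paste(cs[i:(i + len - 1L)], collapse = "")
      if (!is.null(env[[cand]])) { hit_len <- len; break }
    }
    if (hit_len > 0L) {
      etype <- env[[paste(cs[i:(i + hit_len - 1L)], collapse = "")]]
      tags[i] <- paste0("B-", etype)
      if (hit_len > 1L)
        tags[(i + 1L):(i + hit_len - 1L)] <- paste0("I-", etype)
      i <- i + hit_len
    } else {
      i <- i + 1L
    }
  }
  tag_sequence(text, tags)
}

tag_type <- function(tag) sub("^[BI]-", "", tag)

is_valid_bio <- function(tags) {
  prev <- "O"
  for (t in tags) {
    if (t == "O") { prev <- t; next }
    m <- regmatches(t, regexec("^([BI])-(.+)$", t))[[1]]
    if (length(m) == 0) return(FALSE)
    if (m[2] == "I") {
      if (prev == "O") return(FALSE)
      if (tag_type(prev) != m[3]) return(FALSE)
    }
    prev <- t
  }
  TRUE
}

#' Repair a (possibly invalid) model tagging against a dictionary
#'
#' Applies the three standard fixes for sequence-labeling output, in order:
#' span completion (a predicted span is grown by adjacent untagged
#' characters when the grown span is a dictionary term; the longest
#' dictionary-validated extension wins, growth capped at 10 characters and
#' never crossing another predicted span), type resolution (the dictionary
#' type overrides when the final span is in the dictionary; otherwise the
#' majority type among the model's per-character predictions is kept, ties
#' broken toward the type of the `B-` tag), and re-emission of valid B-I-O
#' labels. Output always satisfies the B-I-O invariant and the operation is
#' idempotent.
#'
#' @param ts a [tag_sequence()]; tags may violate B-I-O (e.g. dangling
#'   `I-` tags, mixed types inside one span, incomplete spans)
#' @param lexicon dictionary, as in [dictionary_tag()]
#' @param max_growth span-completion cap in characters (total both sides)
#' @return a repaired `tag_sequence`
#' @export
adjust_tags <- function(ts, lexicon, max_growth = 10L) {
  stopifnot(inherits(ts, "tag_sequence"))
  lexicon <- as_lexicon(lexicon)
  env <- lexicon_env(lexicon)
  cs <- chars(ts$text)
  n <- length(cs)
  raw <- ts$tags
  if (length(raw) != n)
    abort_mkg("tag/text length mismatch", "mkg_argument_error")
  out <- rep("O", n)
  # maximal runs of non-O tags form one predicted entity instance each; a
  # fresh B- tag inside a run starts a new instance (dangling I- tags, the
  # inconsistent-tagging mistake, attach to the running instance)
  tagged <- raw != "O"
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    if (!tagged[i]) { i <- i + 1L; next }
    s <- i
    i <- i + 1L
    while (i <= n && tagged[i] && !startsWith(raw[i], "B-")) i <- i + 1L
    starts <- c(starts, s); ends <- c(ends, i - 1L)
  }
  spans <- cbind(starts, ends)
  occupied <- tagged  # growth may only claim untagged characters
  claimed <- rep(FALSE, n)
  for (k in seq_len(nrow(spans))) {
    s <- spans[k, 1]; e <- spans[k, 2]
    # span completion: longest dictionary-validated extension within cap
    best <- c(0L, 0L)
    free_left <- 0L
    while (s - free_left - 1L >= 1L && !occupied[s - free_left - 1L] &&
           !claimed[s - free_left - 1L] && free_left < max_growth)
      free_left <- free_left + 1L
    free_right <- 0L
    while (e + free_right + 1L <= n && !occupied[e + free_right + 1L] &&
           free_right < max_growth)
      free_right <- free_right + 1L
    for (l in 0:free_left) {
      for (r in 0:min(free_right, max_growth - l)) {
        if (l + r == 0L) next
        cand <- paste(cs[(s - l):(e + r)], collapse = "")
        if (!is.null(env[[cand]]) && l + r > sum(best)) best <- c(l, r)
      }
    }
    s2 <- s - best[1]; e2 <- e + best[2]
    claimed[s2:e2] <- TRUE
    # type resolution
    span_str <- paste(cs[s2:e2], collapse = "")
    if (!is.null(env[[span_str]])) {
      etype <- env[[span_str]]
    } else {
      types <- tag_type(raw[s:e])
      counts <- table(types)
      top <- names(counts)[counts == max(counts)]
      if (length(top) == 1L) {
        etype <- top
      } else {
        b_idx <- which(startsWith(raw[s:e], "B-"))
        etype <- if (length(b_idx)) tag_type(raw[s:e][b_idx[1]])
                 else tag_type(raw[s])
        if (!etype %in% top) etype <- top[1]
      }
    }
    out[s2] <- paste0("B-", etype)
    if (e2 > s2) out[(s2 + 1L):e2] <- paste0("I-", etype)
  }
  tag_sequence(ts$text, out)
}

#' Collect entity mentions from a valid B-I-O tagging
#'
#' @param ts a [tag_sequence()] with valid B-I-O tags (repair invalid
#'   taggings with [adjust_tags()] first)
#' @return list of mentions, each `list(surface, start, end, etype)` with a
#'   0-based half-open character span, in text order
#' @export
collect_mentions <- function(ts) {
  stopifnot(inherits(ts, "tag_sequence"))
  if (!is_valid_bio(ts$tags))
    abort_mkg("tags are not valid B-I-O; run adjust_tags first",
              "mkg_argument_error")
  cs <- chars(ts$text)
  mentions <- list()
  i <- 1L
  n <- length(cs)
  while (i <= n) {
    if (startsWith(ts$tags[i], "B-")) {
      etype <- tag_type(ts$tags[i])
      j <- i
      while (j + 1L <= n && ts$tags[j + 1L] == paste0("I-", etype))
        j <- j + 1L
      mentions[[length(mentions) + 1L]] <- list(
        surface = paste(cs[i:j], collapse = ""),
        start = i - 1L, end = j, etype = etype)
      i <- j + 1L
    } else i <- i + 1L
  }
  mentions
}

# sentence segmentation (used to scope property combination)
split_sentences <- function(text) {
  cs <- chars(text)
  delim <- cs %in% c("。", "！", "？", "\n")
  starts <- integer(0); ends <- integer(0)
  s <- 1L
  for (i in seq_along(cs)) {
    if (delim[i]) {
      if (i > s) { starts <- c(starts, s); ends <- c(ends, i - 1L) }
      s <- i + 1L
    }
  }
  if (s <= length(cs)) { starts <- c(starts, s); ends <- c(ends, length(cs)) }
  data.frame(start = starts, end = ends)
}

strip_count_prefix <- function(raw) {
  sub("^(一次|一日|每次|每日|每天|疗程|连续|分)\\s*", "", raw)
}

# normalized payload for a raw pattern match
normalize_property_value <- function(category, raw) {
  core <- strip_count_prefix(raw)
  num_re <- "([0-9]+(\\.[0-9]+)?)|([一二三四五六七八九十半]+)"
  m <- gregexpr(num_re, core, perl = TRUE)[[1]]
  nums <- numeric(0)
  if (m[1] != -1) {
    toks <- regmatches(core, gregexpr(num_re, core, perl = TRUE))[[1]]
    nums <- vapply(toks, parse_cn_number, numeric(1), USE.NAMES = FALSE)
    nums <- nums[!is.na(nums)]
  }
  low <- if (length(nums)) nums[1] else NA_real_
  high <- if (length(nums) >= 2 &&
              grepl("[-~－–]", core)) nums[2] else low
  unit <- NA_character_
  unit_re <- switch(category,
    dosage = "(毫克|毫升|克|mg|ml|g)\\s*/\\s*kg|毫克|毫升|克|mg|ml|g|[片粒袋支丸]",
    frequency = "次",
    duration = "[日天]",
    population = "岁",
    NULL)
  if (!is.null(unit_re)) {
    um <- regmatches(core, regexpr(unit_re, core, perl = TRUE))
    if (length(um)) unit <- gsub("\\s", "", um)
  }
  relation <- NA_character_
  if (category == "population") {
    if (grepl("以下", raw)) relation <- "<"
    else if (grepl("以上", raw)) relation <- ">"
    else if (!is.na(low)) relation <- "="
  }
  value <- list(low = low, high = high, unit = unit, term = raw)
  if (category == "population") value$relation <- relation
  if (category == "frequency" && !is.na(low) && grepl("一日|每日|每天|一天", raw))
    value$per <- "day"
  value
}

#' Recognize property values in drug-label text
#'
#' Applies the pattern rules to the text; rules flagged `needs_context` only
#' keep a number+unit match when one of their context keywords occurs in the
#' same clause (clauses split on the Chinese comma/semicolon/full stop).
#' Overlapping matches within a category are resolved by rule priority.
#'
#' @param text label text
#' @param rules rule table from [load_property_rules()]
#' @param context_window `"clause"` (default) — keyword must share the clause
#'   with the match; or an integer character distance
#' @return list of property hits: `list(category, raw, value, start, end,
#'   sentence, polarity, rule_id)`, spans 0-based half-open, text order
#' @export
recognize_properties <- function(text, rules = load_property_rules(),
                                 context_window = "clause") {
  if (!nzchar(text)) return(list())
  clauses <- split_clauses(text)
  sentences <- split_sentences(text)
  hits <- list()
  taken <- list()  # per category: covered character positions
  for (i in seq_len(nrow(rules))) {
    cat_i <- rules$category[i]
    m <- gregexpr(rules$expression[i], text, perl = TRUE)[[1]]
    if (m[1] == -1) next
    lens <- attr(m, "match.length")
    for (j in seq_along(m)) {
      s <- m[j]; e <- m[j] + lens[j] - 1L
      cover <- taken[[cat_i]]
      if (!is.null(cover) && any(cover >= s & cover <= e)) next
      raw <- substr(text, s, e)
      if (as.integer(rules$needs_context[i]) == 1L) {
        kws <- strsplit(rules$context_keywords[i], "|", fixed = TRUE)[[1]]
        kws <- kws[nzchar(kws)]
        ok <- FALSE
        if (identical(context_window, "clause")) {
          ci <- clause_of(clauses, s)
          if (!is.na(ci)) {
            ctext <- substr(text, clauses$start[ci], clauses$end[ci])
            ok <- any(vapply(kws, grepl, logical(1), x = ctext, fixed = TRUE))
          }
        } else {
          w <- as.integer(context_window)
          ctext <- substr(text, max(1L, s - w), min(nchar(text), e + w))
          ok <- any(vapply(kws, grepl, logical(1), x = ctext, fixed = TRUE))
        }
        if (!ok) next
      }
      si <- which(sentences$start <= s & sentences$end >= s)
      hits[[length(hits) + 1L]] <- list(
        category = cat_i, raw = raw,
        value = normalize_property_value(cat_i, raw),
        start = s - 1L, end = e, sentence = if (length(si)) si[1] else NA_integer_,
        polarity = "affirmative", rule_id = rules$rule_id[i])
      taken[[cat_i]] <- c(taken[[cat_i]], s:e)
    }
  }
  if (length(hits))
    hits <- hits[order(vapply(hits, `[[`, integer(1), "start"))]
  hits
}

#' Mark property hits that fall under a prohibition context
#'
#' Drug labels state both dosing populations and prohibited populations
#' ("prohibited for children under 1 year of age"); the latter must not
#' enter dosing entries. A hit whose clause contains a prohibition keyword
#' is marked `polarity = "prohibited"`; [combine_properties()] then skips it.
#'
#' @param hits output of [recognize_properties()]
#' @param text the text the hits were extracted from
#' @param prohibition_keywords keywords marking prohibition contexts
#' @param context_window as in [recognize_properties()]
#' @return the hit list with polarity updated
#' @export
filter_prohibited <- function(hits, text,
                              prohibition_keywords = c("禁用", "禁止",
                                                       "忌用", "不得使用"),
                              context_window = "clause") {
  if (length(hits) == 0) return(hits)
  clauses <- split_clauses(text)
  for (i in seq_along(hits)) {
    s <- hits[[i]]$start + 1L
    if (identical(context_window, "clause")) {
      ci <- clause_of(clauses, s)
      ctext <- if (is.na(ci)) "" else
        substr(text, clauses$start[ci], clauses$end[ci])
    } else {
      w <- as.integer(context_window)
      ctext <- substr(text, max(1L, s - w),
                      min(nchar(text), hits[[i]]$end + w))
    }
    if (any(vapply(prohibition_keywords, grepl, logical(1), x = ctext,
                   fixed = TRUE)))
      hits[[i]]$polarity <- "prohibited"
  }
  hits
}

#' Infer usage from a dosage form
#'
#' @param dosage_form dosage form string (e.g. `"贴剂"`)
#' @param map named vector from [load_dosage_form_map()]
#' @return the mapped usage string, or `NA_character_` when unknown
#' @export
#' @examples
#' infer_usage("贴剂")   # 外用 (external)
#' infer_usage("缓释片") # 口服 (oral)
infer_usage <- function(dosage_form, map = load_dosage_form_map()) {
  if (is.na(dosage_form) || !dosage_form %in% names(map)) return(NA_character_)
  unname(map[[dosage_form]])
}

ENTRY_FIELDS <- c("usage", "dosage", "frequency", "duration",
                  "indication", "population")

#' Combine property hits into medication entries
#'
#' One entry is produced per (population, indication) context, following the
#' three combination heuristics for drug-label prose: hits within one
#' sentence combine directly; a field missing from the current context
#' inherits its value from the previous entry; and a change of population
#' starts a new entry in which indication, frequency, and duration are never
#' inherited (they change along with the population). Prohibited hits are
#' excluded; every affirmative hit is either assigned to exactly one entry
#' or logged as discarded.
#'
#' @param hits property hits carrying sentence ids (from
#'   [recognize_properties()], optionally with indication hits appended by
#'   [extract_medication_entries()])
#' @return list with `entries` (each a named list over usage/dosage/
#'   frequency/duration/indication/population plus `provenance` hit
#'   indices) and `discarded` (data.frame of hit index + reason)
#' @export
combine_properties <- function(hits) {
  if (length(hits) == 0) return(list(entries = list(), discarded = data.frame(
    hit = integer(0), reason = character(0))))
  if (any(vapply(hits, function(h) is.na(h$sentence), logical(1))))
    abort_mkg("hits must carry sentence ids", "mkg_argument_error")
  ord <- order(vapply(hits, `[[`, integer(1), "sentence"),
               vapply(hits, `[[`, integer(1), "start"))
  entries <- list()
  discarded <- data.frame(hit = integer(0), reason = character(0))
  cur <- NULL
  cur_prov <- integer(0)
  pop_changed <- FALSE
  flush <- function() {
    if (is.null(cur)) return()
    prev <- if (length(entries)) entries[[length(entries)]] else NULL
    if (!is.null(prev)) {
      inheritable <- if (pop_changed) c("usage", "dosage", "population")
                     else ENTRY_FIELDS
      for (f in inheritable)
        if (is.null(cur[[f]]) && !is.null(prev[[f]])) cur[[f]] <<- prev[[f]]
    }
    cur$provenance <- cur_prov
    entries[[length(entries) + 1L]] <<- cur
  }
  key_of <- function(h) {
    if (h$category == "population") h$value$term
    else if (h$category == "indication") h$value$term
    else NA_character_
  }
  for (idx in ord) {
    h <- hits[[idx]]
    if (identical(h$polarity, "prohibited")) {
      discarded <- rbind(discarded,
                         data.frame(hit = idx, reason = "prohibited_context"))
      next
    }
    if (!h$category %in% ENTRY_FIELDS) {
      discarded <- rbind(discarded,
                         data.frame(hit = idx, reason = "unassignable_category"))
      next
    }
    starts_new <- FALSE
    new_pop_change <- FALSE
    if (!is.null(cur)) {
      if (h$category == "population" && !is.null(cur$population) &&
          !identical(cur$population$term, key_of(h))) {
        starts_new <- TRUE; new_pop_change <- TRUE
      }
      if (h$category == "indication" && !is.null(cur$indication) &&
          !identical(cur$indication$term, key_of(h))) {
        starts_new <- TRUE
      }
    }
    if (starts_new) {
      flush()
      cur <- stats::setNames(vector("list", length(ENTRY_FIELDS)), ENTRY_FIELDS)
      cur_prov <- integer(0)
      pop_changed <- new_pop_change
    }
    if (is.null(cur))
      cur <- stats::setNames(vector("list", length(ENTRY_FIELDS)), ENTRY_FIELDS)
    if (is.null(cur[[h$category]])) {
      cur[[h$category]] <- h$value
      cur_prov <- c(cur_prov, idx)
    } else {
      discarded <- rbind(discarded,
                         data.frame(hit = idx, reason = "field_already_set"))
    }
  }
  flush()
  keep <- vapply(entries, function(e)
    any(!vapply(e[ENTRY_FIELDS], is.null, logical(1))), logical(1))
  list(entries = entries[keep], discarded = discarded)
}

#' Extract medication entries from a drug-label snippet
#'
#' End-to-end wrapper: property recognition, indication detection via
#' dictionary tagging against a disease lexicon, prohibition filtering, and
#' property combination into per-(population, indication) entries.
#'
#' @param text the usage/dosage section text of one label
#' @param disease_lexicon named vector term -> `"Disease"` used for
#'   indication detection
#' @param rules property rules, default packaged set
#' @param dosage_form optional dosage form used to backfill a missing usage
#'   via [infer_usage()]
#' @return as [combine_properties()]
#' @export
extract_medication_entries <- function(text, disease_lexicon,
                                       rules = load_property_rules(),
                                       dosage_form = NA_character_) {
  hits <- recognize_properties(text, rules)
  sentences <- split_sentences(text)
  ts <- dictionary_tag(text, disease_lexicon)
  for (m in collect_mentions(ts)) {
    s <- m$start + 1L
    si <- which(sentences$start <= s & sentences$end >= s)
    hits[[length(hits) + 1L]] <- list(
      category = "indication", raw = m$surface,
      value = list(term = m$surface), start = m$start, end = m$end,
      sentence = if (length(si)) si[1] else NA_integer_,
      polarity = "affirmative", rule_id = "indication_dictionary")
  }
  hits <- filter_prohibited(hits, text)
  res <- combine_properties(hits)
  if (!is.na(dosage_form)) {
    inferred <- infer_usage(dosage_form)
    if (!is.na(inferred))
      for (i in seq_along(res$entries))
        if (is.null(res$entries[[i]]$usage))
          res$entries[[i]]$usage <- list(term = inferred)
  }
  res$hits <- hits
  res
}

#' Classify the drug-drug interaction stated in a sentence
#'
#' The two entity mentions are replaced by type placeholders (e.g.
#' `[Drug]`), then the classification rules are applied in priority order;
#' the first matching rule assigns the category.
#'
#' @param sentence sentence text
#' @param mentions list of exactly two mentions as returned by
#'   [collect_mentions()] (0-based half-open spans within the sentence);
#'   pass `NULL` to classify the sentence as-is
#' @param rules rule table from [load_ddi_rules()]
#' @return `"promotion"`, `"contraindication"`, `"none"`, or `"no_match"`
#' @export
#' @examples
#' classify_relation("硝苯地平禁止与利福平合用")  # contraindication
classify_relation <- function(sentence, mentions = NULL,
                              rules = load_ddi_rules()) {
  masked <- sentence
  if (!is.null(mentions)) {
    if (length(mentions) != 2)
      abort_mkg("exactly two mentions required", "mkg_argument_error")
    n <- nchar(sentence)
    for (m in mentions)
      if (m$start < 0 || m$end > n || m$start >= m$end)
        abort_mkg("mention span outside sentence", "mkg_argument_error")
    a <- mentions[[1]]; b <- mentions[[2]]
    if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
    if (a$end > b$start)
      abort_mkg("mention spans overlap", "mkg_argument_error")
    masked <- paste0(
      substr(sentence, 1, a$start),
      "[", a$etype, "]",
      substr(sentence, a$end + 1, b$start),
      "[", b$etype, "]",
      substr(sentence, b$end + 1, nchar(sentence)))
  }
  for (i in seq_len(nrow(rules)))
    if (grepl(rules$expression[i], masked, perl = TRUE))
      return(rules$category[i])
  "no_match"
}
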