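# Internal helpers shared across modules.

#' Split a string into characters
#'
#' Chinese clinical text carries no whitespace token boundaries, so every
#' string-level operation in this package works per unicode character.
#' @param x a single string
#' @return character vector of single characters (length 0 for "")
#' @keywords internal
chars <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, "", fixed = FALSE)[[1]]
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

abort_mkg <- function(msg, class) {
  stop(structure(class = c(class, "mkgfwa_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Split text into clauses on the Chinese clause delimiters. Used as the
# default context window for keyword retention around pattern hits.
split_clauses <- function(text) {
  if (!nzchar(text)) return(data.frame(start = integer(0), end = integer(0)))
  cs <- chars(text)
  delim <- cs %in% c("，", "。", "；", ",", ";", "\n")
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

# clause index containing character position pos (1-based), NA if delimiter
clause_of <- function(clauses, pos) {
  hit <- which(clauses$start <= pos & clauses$end >= pos)
  if (length(hit) == 0) NA_integer_ else hit[1]
}

# 31-bit polynomial rolling hash over a serialized R object, as hex string.
# Used for config fingerprints (changes iff any config value changes).
fnv1a <- function(obj) {
  bytes <- serialize(obj, NULL, version = 2)
  # skip serialization header (R version stamps would break stability)
  bytes <- as.double(bytes[-seq_len(14)])
  h <- 5381
  p <- 2147483629  # largest prime below 2^31
  for (b in bytes) h <- (h * 33 + b + 1) %% p
  sprintf("%08x", as.integer(h))
}

# Parse a numeric that may be written with Chinese numerals (1-10, plus half).
# Returns NA when not interpretable as a simple numeral.
parse_cn_number <- function(x) {
  x <- trimws(x)
  if (grepl("^[0-9]+(\\.[0-9]+)?$", x)) return(as.numeric(x))
  digits <- c("零" = 0, "一" = 1, "二" = 2, "三" = 3,
              "四" = 4, "五" = 5, "六" = 6, "七" = 7,
              "八" = 8, "九" = 9)
  if (x == "半") return(0.5)           # half
  if (x == "十") return(10)            # ten
  cs <- chars(x)
  if (length(cs) == 1 && cs %in% names(digits)) return(unname(digits[cs]))
  if (length(cs) == 2 && cs[1] == "十" && cs[2] %in% names(digits))
    return(10 + unname(digits[cs[2]]))     # 十X
  if (length(cs) == 2 && cs[1] %in% names(digits) && cs[2] == "十")
    return(unname(digits[cs[1]]) * 10)     # X十
  if (length(cs) == 3 && cs[2] == "十" &&
      cs[1] %in% names(digits) && cs[3] %in% names(digits))
    return(unname(digits[cs[1]]) * 10 + unname(digits[cs[3]]))
  NA_real_
}

read_tsv_utf8 <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                    na.strings = NULL, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

write_tsv_utf8 <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "")
}

# run code with a temporary RNG seed, restoring caller's RNG state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
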