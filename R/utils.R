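#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.05 -> 0.1`), the convention used
#' for all displayed percentages in this package. Base R's `round()` rounds
#' half to even, which disagrees with how clinical tables are typically
#' printed.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length.
#' @examples
#' round_half_up(c(0.05, 0.15, 0.25), 1)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # tiny nudge guards against 31.95 being stored as 31.94999...
  floor(x * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# percentage on the printed scale: 0.31951 -> 32.0
as_pct <- function(p, digits = 1) round_half_up(100 * p, digits)

# semicolon-joined token fields ------------------------------------------

split_tokens <- function(x) {
  out <- stringr::str_split(dplyr::coalesce(x, ""), stringr::fixed(";"))
  lapply(out, function(tok) {
    tok <- trimws(tok)
    tok[nzchar(tok)]
  })
}

join_tokens <- function(tokens) {
  out <- purrr::map_chr(tokens, function(tok) paste(tok, collapse = ";"))
  dplyr::if_else(nzchar(out), out, NA_character_)
}

# medication tokens: "ingredient[@pct][/route]", e.g. "dextrose@50/iv"
MED_TOKEN_RE <- "^([^@/]+?)(?:@([0-9]*\\.?[0-9]+))?(?:/([a-z]+))?$"

# one long table over the whole cohort (row = record index); `ok` marks
# parseable tokens so validation can report offenders without a second pass
parse_medications_long <- function(x) {
  toks <- split_tokens(x)
  flat <- unlist(toks, use.names = FALSE)
  if (is.null(flat)) flat <- character()
  m <- stringr::str_match(stringr::str_to_lower(flat), MED_TOKEN_RE)
  tibble::tibble(
    row = rep(seq_along(toks), lengths(toks)),
    token = flat,
    ingredient = trimws(m[, 2]),
    concentration_pct = suppressWarnings(as.numeric(m[, 3])),
    route = dplyr::coalesce(m[, 4], "unknown"),
    ok = !is.na(m[, 2]) & nzchar(trimws(m[, 2]))
  )
}

compare_op <- function(comparator) {
  switch(comparator,
    "<" = `<`,
    ">" = `>`,
    abort(paste0("comparator must be '<' or '>', got '", comparator, "'"))
  )
}
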