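# Internal helpers shared across modules.

# let data.table find its API when called via :: from this namespace
.datatable.aware <- TRUE

#' Round half up
#'
#' Base R `round()` uses round-half-to-even; printed percentages in
#' concordance and resolution summaries use conventional half-up rounding
#' (e.g. 51/84 -> 60.7).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' One-decimal percentage
#'
#' @param num,den numerator and denominator counts.
#' @return `round_half_up(100 * num / den, 1)`; `NA` when `den == 0`.
#' @export
pct1 <- function(num, den) {
  ifelse(den == 0, NA_real_, round_half_up(100 * num / den, 1))
}

# last element of a character scalar
.last_char <- function(s) substr(s, nchar(s), nchar(s))

# drop first/last character
.drop_first <- function(s) substr(s, 2L, nchar(s))
.drop_last  <- function(s) substr(s, 1L, nchar(s) - 1L)

# fetch the sequence for a chromosome from a reference (named character
# vector, or a single unnamed string accepted for any chromosome)
.ref_seq <- function(reference, chrom) {
  if (is.null(names(reference))) {
    if (length(reference) != 1L)
      stop("unnamed reference must be a single sequence")
    return(reference[[1L]])
  }
  if (!chrom %in% names(reference))
    stop("reference has no sequence for chromosome '", chrom, "'")
  reference[[chrom]]
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# data.table constructor safe for a column named "key" (which the
# data.table() constructor would swallow as its key= argument)
.dtab <- function(...) {
  l <- list(...)
  n <- if (length(l)) max(lengths(l)) else 0L
  if (n > 0L) l <- lapply(l, rep_len, n)
  data.table::as.data.table(l)
}
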