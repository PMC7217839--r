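#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats median qbeta rbinom rnorm rpois runif sd
#' @importFrom utils head tail
NULL

#' Round half-up to a fixed number of decimals
#'
#' Report percentages are rounded half-away-from-zero (so 4.25 -> 4.3),
#' not to even as [base::round()] does. Applied only at report emission;
#' internal values keep full precision.
#'
#' @param x numeric vector
#' @param digits decimal places to keep
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Population (divide-by-n) standard deviation; the QC thresholds are
# calibrated against this convention, not the n-1 sample estimator.
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 1L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Chromosome sort rank
#'
#' Orders autosomes numerically, then X, Y, MT, then anything else
#' lexically. Labels are expected without a "chr" prefix.
#'
#' @param chrom character vector of chromosome labels
#' @return numeric rank usable as a sort key
#' @export
chrom_rank <- function(chrom) {
  chrom <- normalize_chrom(chrom)
  n <- suppressWarnings(as.numeric(chrom))
  special <- match(chrom, c("X", "Y", "MT", "M"))
  rank <- ifelse(!is.na(n), n,
    ifelse(!is.na(special), 22 + pmin(special, 3), 100 + xtfrm(chrom))
  )
  rank
}

#' Strip any "chr" prefix from chromosome labels
#' @param chrom character vector
#' @return labels without prefix ("chrX" -> "X", "22" -> "22")
#' @export
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom), ignore.case = TRUE)
}

# Intervals follow the caller's printed convention: start and end as
# printed, length = end - start. Internally that behaves like the
# half-open interval [start, end); IRanges is 1-based closed, so the
# equivalent IRanges runs start..(end - 1).
as_halfopen_iranges <- function(start, end) {
  stopifnot(all(end > start))
  IRanges::IRanges(start = as.integer(start), end = as.integer(end) - 1L)
}

# Ordering used for every emitted call table: chromosome (numeric then
# lexical), start, end, then type as the final tie-break.
arrange_calls <- function(calls) {
  calls[order(chrom_rank(calls$chrom), calls$start, calls$end, calls$cnv_type), , drop = FALSE]
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Derive a per-stream 32-bit seed from a master seed and a stream index.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 1e6) * 100003 + as.numeric(index) * 7 + 1) %% 2147483646L + 1L
}
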