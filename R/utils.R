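#' Round half away from zero
#'
#' Standard "commercial" rounding: 0.5 always rounds up (for positive input),
#' unlike [base::round()] which rounds half to even. Used for all printed
#' percentages and pg values so that tabulated output matches conventional
#' manual rounding.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Nucleotide scoring matrix for isoform/reference alignments.
# match/mismatch defaults follow the package-wide alignment parameters
# (match 2, mismatch -3); N scores 0 against everything.
.nuc_matrix <- function(match = 2, mismatch = -3) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m) <- match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

.is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

.is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @importFrom methods as
#' @importFrom stats dnorm kmeans lm coef rnorm rpois runif rbinom sd cor
#'   quantile setNames complete.cases
#' @importFrom utils write.table read.table head tail
NULL
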