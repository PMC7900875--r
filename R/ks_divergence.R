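#' @name ks_divergence
#' @title Nei-Gojobori Ks estimation and mixture-based divergence dating
#' @description
#' Pairwise synonymous substitution rates are estimated with the
#' Nei-Gojobori (1986) counting method: per-codon synonymous site fractions
#' from the universal genetic code, pathway-averaged synonymous and
#' nonsynonymous difference counts, and a Jukes-Cantor multiple-hit
#' correction. Peaks in the Ks distribution are located with univariate
#' Gaussian mixtures fitted by EM and selected by BIC, and converted to
#' divergence times with a synonymous clock rate.
NULL

# --- codon machinery --------------------------------------------------------

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(unname(gc), names(gc))
}

# Fraction of synonymous sites per codon: at each position, the fraction of
# the 3 possible base changes that preserve the amino acid. Changes creating
# stop codons count as nonsynonymous (denominator stays 3).
.codon_syn_sites <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc <- .codon_table()
    codons <- names(gc)
    s <- setNames(numeric(length(codons)), codons)
    for (cd in codons) {
      if (gc[[cd]] == "*") { s[cd] <- NA_real_; next }
      ch <- strsplit(cd, "")[[1]]
      frac <- 0
      for (pos in 1:3) {
        for (b in setdiff(.BASES, ch[pos])) {
          mut <- ch; mut[pos] <- b
          mutc <- paste0(mut, collapse = "")
          if (gc[[mutc]] == gc[[cd]]) frac <- frac + 1 / 3
        }
      }
      s[cd] <- frac
    }
    cache <<- s
    cache
  }
})

# All permutations of 1..n (n <= 3 here).
.perms <- function(n) {
  if (n == 1) return(list(1L))
  if (n == 2) return(list(c(1L, 2L), c(2L, 1L)))
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
}

# Pathway-averaged synonymous/nonsynonymous differences between two codons:
# every minimal mutational pathway (one ordering of the differing positions)
# carries equal weight; a step is synonymous iff it preserves the amino
# acid. Memoised on the codon pair.
.pair_cache <- new.env(hash = TRUE, parent = emptyenv())

.codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste0(c1, c2)
  hit <- .pair_cache[[key]]
  if (!is.null(hit)) return(hit)
  gc <- .codon_table()
  a1 <- strsplit(c1, "")[[1]]
  a2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(a1 != a2)
  paths <- .perms(length(diff_pos))
  sd_tot <- nd_tot <- 0
  for (ord in paths) {
    cur <- a1
    sd_p <- nd_p <- 0
    for (pos in diff_pos[ord]) {
      nxt <- cur; nxt[pos] <- a2[pos]
      if (gc[[paste0(cur, collapse = "")]] == gc[[paste0(nxt, collapse = "")]])
        sd_p <- sd_p + 1 else nd_p <- nd_p + 1
      cur <- nxt
    }
    sd_tot <- sd_tot + sd_p
    nd_tot <- nd_tot + nd_p
  }
  out <- c(sd = sd_tot / length(paths), nd = nd_tot / length(paths))
  .pair_cache[[key]] <- out
  out
}

# --- alignment --------------------------------------------------------------

#' Protein-guided codon alignment of two coding sequences
#'
#' Translates both sequences, aligns the proteins globally (BLOSUM62, gap
#' open 10 / extend 0.5), threads the codons back through the protein
#' alignment, and drops every codon column containing a gap, a stop codon
#' or an ambiguous base.
#'
#' @param cds_a,cds_b coding sequences (character), frame from position 1;
#'   trailing partial codons are trimmed with a warning.
#' @return object of class \code{codon_pair_alignment}: list with
#'   \code{codons_a}, \code{codons_b} (equal-length character vectors of
#'   retained codon columns) and \code{n_dropped}.
#' @export
pair_codon_align <- function(cds_a, cds_b) {
  trim <- function(s) {
    r <- nchar(s) %% 3
    if (r) {
      warning("trimming partial trailing codon")
      s <- substring(s, 1, nchar(s) - r)
    }
    toupper(s)
  }
  cds_a <- trim(cds_a); cds_b <- trim(cds_b)
  if (nchar(cds_a) < 3 || nchar(cds_b) < 3) .stopf("sequences must be >= 3 bp")
  split_codons <- function(s) {
    n <- nchar(s) / 3
    substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
  }
  ca <- split_codons(cds_a); cb <- split_codons(cds_b)
  gc <- .codon_table()
  aa_of <- function(cods) {
    vapply(cods, function(cd) {
      if (grepl("[^ACGT]", cd)) "X" else gc[[cd]]
    }, "")
  }
  aa_a <- aa_of(ca); aa_b <- aa_of(cb)
  # '*' is not a residue pairwiseAlignment should see; mask to X for scoring
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste0(gsub("\\*", "X", aa_a), collapse = "")),
    Biostrings::AAString(paste0(gsub("\\*", "X", aa_b), collapse = "")),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  gp <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  gs <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ia <- 0L; ib <- 0L
  keep_a <- keep_b <- character(0)
  dropped <- 0L
  for (i in seq_along(gp)) {
    if (gp[i] != "-") ia <- ia + 1L
    if (gs[i] != "-") ib <- ib + 1L
    if (gp[i] != "-" && gs[i] != "-") {
      cda <- ca[ia]; cdb <- cb[ib]
      ok <- !grepl("[^ACGT]", cda) && !grepl("[^ACGT]", cdb) &&
        gc[[cda]] != "*" && gc[[cdb]] != "*"
      if (ok) {
        keep_a <- c(keep_a, cda); keep_b <- c(keep_b, cdb)
      } else dropped <- dropped + 1L
    } else dropped <- dropped + 1L
  }
  if (!length(keep_a)) {
    warning("no aligned codons survive filtering; pair skipped")
    return(NULL)
  }
  structure(list(codons_a = keep_a, codons_b = keep_b, n_dropped = dropped),
            class = "codon_pair_alignment")
}

#' Nei-Gojobori (1986) Ks for a codon pair alignment
#'
#' @param pair a [pair_codon_align()] result (or a list with
#'   \code{codons_a}, \code{codons_b}).
#' @return object of class \code{ks_estimate}: list with \code{S} and
#'   \code{N} (synonymous and nonsynonymous sites, averaged over the two
#'   sequences), \code{Sd}, \code{Nd} (pathway-averaged differences),
#'   \code{ps}, \code{pn}, \code{ks}, \code{ka}; \code{ks} is \code{NA}
#'   (saturated) when \code{ps >= 0.75}.
#' @export
ng86_ks <- function(pair) {
  if (is.null(pair)) .stopf("empty codon pair alignment")
  ca <- pair$codons_a; cb <- pair$codons_b
  stopifnot(length(ca) == length(cb), length(ca) >= 1)
  syn <- .codon_syn_sites()
  S <- (sum(syn[ca]) + sum(syn[cb])) / 2
  N <- 3 * length(ca) - S
  d <- mapply(function(x, y) .codon_pair_diffs(x, y), ca, cb)
  Sd <- sum(d["sd", ]); Nd <- sum(d["nd", ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                 ks = jc(ps), ka = jc(pn)), class = "ks_estimate")
}

#' Ks between two coding sequences
#'
#' Convenience wrapper: [pair_codon_align()] then [ng86_ks()].
#'
#' @param cds_a,cds_b coding sequences (character).
#' @return a \code{ks_estimate}, or \code{NULL} if no codons align.
#' @export
ks_pair <- function(cds_a, cds_b) {
  pair <- pair_codon_align(cds_a, cds_b)
  if (is.null(pair)) return(NULL)
  ng86_ks(pair)
}

#' Filter a Ks sample before peak detection
#'
#' Removes undefined (saturated) values and values strictly below
#' \code{min_ks}; tiny Ks values reflect allelic/assembly redundancy and
#' produce spurious frequency peaks near zero.
#'
#' @param values numeric Ks values (NAs allowed).
#' @param min_ks exclusion threshold (default 0.001; the boundary value is
#'   kept).
#' @return filtered numeric vector.
#' @export
filter_ks <- function(values, min_ks = 0.001) {
  values[!is.na(values) & values >= min_ks]
}

# --- Gaussian mixture via EM ------------------------------------------------

.em_gmm <- function(x, k, mu0, tol = 1e-6, max_iter = 500) {
  n <- length(x)
  mu <- mu0
  sdv <- rep(sd(x), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], sdv[j]),
                   numeric(n))
    if (k == 1) dens <- matrix(dens, ncol = 1)
    rowsum_ <- rowSums(dens)
    if (any(rowsum_ <= 0) || any(!is.finite(rowsum_))) return(NULL)
    ll <- sum(log(rowsum_))
    resp <- dens / rowsum_
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sdv <- sqrt(colSums(resp * (outer(x, mu, "-")^2)) / nk)
    if (any(sdv < 1e-8)) return(NULL)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(k = k, weights = w, means = mu, sds = sdv, loglik = ll)
}

#' Fit univariate Gaussian mixtures to a Ks sample with BIC selection
#'
#' EM with \code{n_init} random restarts per component count; the model
#' minimising \code{BIC = -2 logL + (3k - 1) log(n)} is selected.
#' Degenerate runs (vanishing component standard deviation or weight) are
#' discarded and restarted; a component count whose restarts all
#' degenerate is skipped.
#'
#' @param values numeric Ks sample (>= 10 values).
#' @param k_range integer vector of component counts (default 1:5).
#' @param n_init random restarts per k (default 10).
#' @param seed integer seed for restart initialisation.
#' @param tol EM convergence tolerance on the log-likelihood.
#' @return list of class \code{mixture_fits}: per-k fits, each a
#'   \code{mixture_fit} with \code{k}, \code{weights}, \code{means},
#'   \code{sds} (sorted by mean), \code{loglik}, \code{bic},
#'   \code{selected}; attribute \code{"selected"} gives the index of the
#'   BIC-optimal fit.
#' @export
fit_mixture <- function(values, k_range = 1:5, n_init = 10, seed = 1L,
                        tol = 1e-6) {
  x <- values[is.finite(values)]
  if (length(x) < 10) .stopf("need at least 10 values to fit a mixture")
  set.seed(seed)
  n <- length(x)
  fits <- list()
  for (k in k_range) {
    best <- NULL
    for (init in seq_len(n_init)) {
      mu0 <- if (init == 1 && k > 1) {
        km <- try(kmeans(x, centers = k, nstart = 1), silent = TRUE)
        if (inherits(km, "try-error")) sample(x, k) else km$centers[, 1]
      } else sample(x, k)
      f <- .em_gmm(x, k, mu0, tol = tol)
      if (is.null(f)) next
      if (is.null(best) || f$loglik > best$loglik) best <- f
    }
    if (is.null(best)) {
      warning(sprintf("all EM restarts degenerate for k = %d; skipped", k))
      next
    }
    ord <- order(best$means)
    best$weights <- best$weights[ord]
    best$means <- best$means[ord]
    best$sds <- best$sds[ord]
    best$bic <- -2 * best$loglik + (3 * k - 1) * log(n)
    best$selected <- FALSE
    class(best) <- "mixture_fit"
    fits[[as.character(k)]] <- best
  }
  if (!length(fits)) .stopf("no mixture could be fitted")
  bics <- vapply(fits, `[[`, 0, "bic")
  sel <- which.min(bics)
  fits[[sel]]$selected <- TRUE
  attr(fits, "selected") <- unname(sel)
  class(fits) <- "mixture_fits"
  fits
}

#' BIC-selected fit from a set of mixture fits
#'
#' @param fits a \code{mixture_fits} list from [fit_mixture()].
#' @return the selected \code{mixture_fit}.
#' @export
selected_mixture <- function(fits) {
  fits[[attr(fits, "selected")]]
}

#' Mean of the dominant (highest-weight) mixture component
#'
#' @param fit a \code{mixture_fit}.
#' @return numeric mean of the highest-weight component.
#' @export
dominant_component_mean <- function(fit) {
  fit$means[which.max(fit$weights)]
}

#' Convert a Ks peak to a divergence time
#'
#' Uses a synonymous molecular clock: with the default gymnosperm rate of
#' 4.8e-9 synonymous substitutions per synonymous site per year, a Ks peak
#' of 0.04 dates to ~8.3 Ma. The default convention divides by \code{r}
#' (peak Ks interpreted as per-lineage distance); the textbook
#' two-lineage convention \code{ks / (2 r)} is available via
#' \code{convention}.
#'
#' @param ks_peak positive Ks peak location.
#' @param rate synonymous substitution rate per site per year.
#' @param convention \code{"ks-over-r"} (default) or \code{"ks-over-2r"}.
#' @return object of class \code{divergence_time}: list with
#'   \code{ks_peak}, \code{rate}, \code{convention}, \code{time_years},
#'   \code{time_ma}.
#' @export
divergence_time <- function(ks_peak, rate = 4.8e-9,
                            convention = c("ks-over-r", "ks-over-2r")) {
  convention <- match.arg(convention)
  if (ks_peak <= 0 || rate <= 0) .stopf("ks_peak and rate must be positive")
  denom <- if (convention == "ks-over-r") rate else 2 * rate
  t <- ks_peak / denom
  structure(list(ks_peak = ks_peak, rate = rate, convention = convention,
                 time_years = t, time_ma = t / 1e6),
            class = "divergence_time")
}
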