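test_that("identical sequences give zero differences and Ks = 0", {
  s <- paste(rep("ATGGCTAAA", 20), collapse = "")
  e <- ks_pair(s, s)
  expect_equal(e$Sd, 0)
  expect_equal(e$Nd, 0)
  expect_equal(e$ks, 0)
})

test_that("a single synonymous difference matches the site-counting oracle", {
  a <- paste(rep("GGT", 100), collapse = "")
  b <- paste(c(rep("GGT", 99), "GGC"), collapse = "")
  e <- ks_pair(a, b)
  # oracle: S from exhaustive per-codon enumeration, averaged over the
  # two sequences
  S_oracle <- (100 * oracle_syn_sites("GGT") +
                 99 * oracle_syn_sites("GGT") + oracle_syn_sites("GGC")) / 2
  expect_equal(e$S, S_oracle)
  expect_equal(e$Sd, 1)
  expect_equal(e$Nd, 0)
  expect_equal(e$ks, -0.75 * log(1 - (4 / 3) * (1 / S_oracle)))
})

test_that("two-hit codons average over the minimal pathways", {
  d <- oracle_pathways("TTT", "CTC")
  e <- ng86_ks(list(codons_a = "TTT", codons_b = "CTC"))
  expect_equal(e$Sd, d[["sd"]])
  expect_equal(e$Nd, d[["nd"]])
  expect_equal(d[["sd"]], 1)  # one of two steps synonymous on each path
  expect_equal(d[["nd"]], 1)
})

test_that("NG86 matches the exhaustive pathway oracle on all sense-codon pairs", {
  sense <- oracle_sense_codons()
  expect_length(sense, 61)
  for (c1 in sense) {
    for (c2 in sense) {
      e <- ng86_ks(list(codons_a = c1, codons_b = c2))
      d <- oracle_pathways(c1, c2)
      expect_equal(e$Sd, d[["sd"]], tolerance = 1e-12,
                   label = paste(c1, c2, "Sd"))
      expect_equal(e$Nd, d[["nd"]], tolerance = 1e-12,
                   label = paste(c1, c2, "Nd"))
    }
  }
})

test_that("site counts are conserved and the estimator is symmetric", {
  set.seed(5)
  sense <- oracle_sense_codons()
  for (i in 1:20) {
    n <- sample(10:60, 1)
    a <- paste(sample(sense, n, replace = TRUE), collapse = "")
    b <- paste(sample(sense, n, replace = TRUE), collapse = "")
    pab <- list(codons_a = substring(a, 3 * (1:n) - 2, 3 * (1:n)),
                codons_b = substring(b, 3 * (1:n) - 2, 3 * (1:n)))
    e1 <- ng86_ks(pab)
    e2 <- ng86_ks(list(codons_a = pab$codons_b, codons_b = pab$codons_a))
    expect_equal(e1$S + e1$N, 3 * n, tolerance = 1e-9)
    expect_equal(e1$Sd, e2$Sd)
    expect_equal(e1$ks, e2$ks)
  }
})

test_that("codon alignment drops gapped and stop columns, keeps the rest", {
  a <- "ATGGCTGCAAAAGTT"
  e <- pair_codon_align(a, a)
  expect_length(e$codons_a, 5)
  # delete one codon from b: that column is dropped, remainder aligns
  b <- "ATGGCTAAAGTT"
  e2 <- pair_codon_align(a, b)
  expect_length(e2$codons_a, 4)
  expect_identical(e2$codons_a, e2$codons_b)
  # internal stop codon columns are excluded
  e3 <- pair_codon_align("ATGTAAGTT", "ATGTAAGTT")
  expect_length(e3$codons_a, 2)
})

test_that("Ks increases with simulated divergence (rank correlation)", {
  set.seed(8)
  sense <- oracle_sense_codons()
  base <- paste(sample(sense, 200, replace = TRUE), collapse = "")
  mutate <- function(s, d) {
    ch <- strsplit(s, "")[[1]]
    idx <- which(runif(length(ch)) < d)
    for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  d_true <- runif(200, 0.01, 0.5)
  ks <- vapply(d_true, function(d) {
    e <- ks_pair(base, mutate(base, d))
    if (is.null(e) || is.na(e$ks)) NA_real_ else e$ks
  }, 0)
  keep <- !is.na(ks)
  rho <- cor(d_true[keep], ks[keep], method = "spearman")
  expect_gt(rho, 0.95)
})

test_that("ks filtering removes sub-threshold and NA values, keeps boundary", {
  expect_equal(filter_ks(c(0.0005, 0.05)), 0.05)
  expect_equal(filter_ks(c(0.001)), 0.001)
  expect_equal(filter_ks(numeric(0)), numeric(0))
  expect_equal(filter_ks(c(NA, 0.2)), 0.2)
})

test_that("single-component samples select k = 1 with the right mean", {
  x <- filter_ks(simulate_ks_sample(2000, list(c(1, 0.04, 0.01)), seed = 13))
  fits <- fit_mixture(x, seed = 13)
  sel <- selected_mixture(fits)
  expect_equal(sel$k, 1)
  expect_equal(round(sel$means, 2), 0.04)
})

test_that("two separated components are recovered within standard errors", {
  x <- simulate_ks_sample(2000, list(c(0.5, 0.04, 0.01), c(0.5, 0.30, 0.03)),
                          seed = 17)
  sel <- selected_mixture(fit_mixture(filter_ks(x), seed = 17))
  expect_equal(sel$k, 2)
  expect_lt(abs(sel$means[1] - 0.04), 3 * 0.01 / sqrt(1000))
  expect_lt(abs(sel$means[2] - 0.30), 3 * 0.03 / sqrt(1000))
  expect_equal(sum(sel$weights), 1, tolerance = 1e-9)
})

test_that("the in-package EM agrees with an independent mixture fitter", {
  suppressMessages(library(mclust))
  x <- simulate_ks_sample(1500, list(c(0.6, 0.05, 0.012), c(0.4, 0.25, 0.04)),
                          seed = 19)
  sel <- selected_mixture(fit_mixture(x, seed = 19))
  mc <- Mclust(x, G = 1:5, modelNames = "V", verbose = FALSE)
  expect_equal(sel$k, mc$G)
  expect_equal(sort(sel$means), sort(unname(mc$parameters$mean)),
               tolerance = 0.02)
})

test_that("BIC recovers the true component count in repeated simulations", {
  hits <- vapply(1:100, function(r) {
    x <- simulate_ks_sample(400, list(c(0.5, 0.04, 0.01), c(0.5, 0.30, 0.03)),
                            seed = 100 + r)
    selected_mixture(fit_mixture(x, k_range = 1:3, n_init = 4,
                                 seed = r))$k == 2
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("degenerate inputs exercise the EM error path", {
  expect_error(suppressWarnings(fit_mixture(rep(0.05, 50), seed = 1)))
  expect_error(fit_mixture(c(0.1, 0.2), seed = 1), "at least 10")
})

test_that("divergence-time arithmetic is linear and guards its domain", {
  dt <- divergence_time(0.04, 4.8e-9)
  expect_equal(dt$time_years, 0.04 / 4.8e-9)
  expect_equal(divergence_time(0.08, 4.8e-9)$time_years, 2 * dt$time_years)
  expect_equal(divergence_time(0.04, 4.8e-9, "ks-over-2r")$time_years,
               dt$time_years / 2)
  expect_error(divergence_time(0, 4.8e-9), "positive")
  expect_error(divergence_time(0.04, 0), "positive")
})
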