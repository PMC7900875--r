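make_aln <- function(eq, mi, mo, pr, re) {
  c(eq = eq, mi = mi, mo = mo, pr = pr, re = re)
}

test_that("diagnostic sites require fixed, differing, unambiguous groups", {
  aln <- make_aln("GAAC", "GAAC", "GAAC", "AAGC", "AAGC")
  sites <- find_diagnostic_sites(aln)
  # col 1: maternal A vs paternal G; col 2 identical; col 3 maternal G vs
  # paternal A; col 4 identical
  expect_equal(sites$column, c(1, 3))
  expect_equal(sites$m_allele, c("A", "G"))
  expect_equal(sites$p_allele, c("G", "A"))
  # maternal group polymorphic -> not diagnostic
  expect_equal(nrow(find_diagnostic_sites(make_aln("G", "G", "G", "A", "G"))), 0)
  # no difference -> not diagnostic
  expect_equal(nrow(find_diagnostic_sites(make_aln("A", "A", "A", "A", "A"))), 0)
  # gap or ambiguity anywhere disqualifies
  expect_equal(nrow(find_diagnostic_sites(make_aln("G", "G", "G", "A", "-"))), 0)
  expect_equal(nrow(find_diagnostic_sites(make_aln("G", "G", "G", "N", "N"))), 0)
})

test_that("a missing taxon is reported by name", {
  expect_error(find_diagnostic_sites(c(eq = "A", mi = "A", mo = "A", pr = "A")),
               "re")
})

test_that("classification agrees with exhaustive rule enumeration", {
  th <- assignment_thresholds()
  for (m in 0:12) {
    for (p in 0:12) {
      expect_identical(classify_isoform(m, p, th), oracle_classify(m, p),
                       label = sprintf("m=%d p=%d", m, p))
    }
  }
})

test_that("classification hits the documented worked examples and boundaries", {
  expect_identical(classify_isoform(10, 0), "M")
  expect_identical(classify_isoform(3, 0), "unassigned")
  expect_identical(classify_isoform(5, 5), "recombinant")
  expect_identical(classify_isoform(1, 9), "P")
  # proportions exactly 0.8 / 0.2 are recombinant (strict inequalities)
  expect_identical(classify_isoform(8, 2), "recombinant")
  expect_identical(classify_isoform(2, 8), "recombinant")
  expect_identical(classify_isoform(9, 2), "M")   # 0.818 > 0.8
  # min-site rule binds the called parent only
  expect_identical(classify_isoform(3, 20), "P")
})

test_that("isoform scoring reads the correct base at diagnostic columns", {
  cfg <- small_cfg(seed = 21)
  ogs <- simulate_progenitor_ogs(cfg)
  og <- ogs[[1]]
  sites <- find_diagnostic_sites(og$aln)
  cons <- og_consensus(og$aln)
  # the M haplotype reports the m_allele everywhere
  sc <- align_isoform_to_og(og$hap_M, cons, sites)
  expect_true(sc$matched)
  expect_identical(unname(sc$site_base), sites$m_allele)
  sc_p <- align_isoform_to_og(og$hap_P, cons, sites)
  expect_identical(unname(sc_p$site_base), sites$p_allele)
})

test_that("partial isoforms score only covered columns; short ones skip", {
  cfg <- small_cfg(seed = 22, og_length_codons = 300)
  ogs <- simulate_progenitor_ogs(cfg)
  og <- ogs[[1]]
  sites <- find_diagnostic_sites(og$aln)
  cons <- og_consensus(og$aln)
  half <- substring(og$hap_M, 1, floor(nchar(og$hap_M) / 2))
  sc <- align_isoform_to_og(half, cons, sites)
  inside <- sites$column <= nchar(half)
  expect_identical(is.na(sc$site_base), !inside)
  expect_false(align_isoform_to_og(substring(og$hap_M, 1, 200), cons,
                                   sites)$matched)
})

test_that("noiseless end-to-end phasing recovers every truth label", {
  res <- phase_sim(small_cfg(seed = 1))
  truth <- res$iso$truth
  merged <- merge(res$assignments, truth, by = "isoform_id")
  expect_true(all(merged$call == merged$subgenome))
  expect_true(all(merged$og.x == merged$og.y))
  # tabulation equals expression-profile marginals
  prof <- attr(truth, "profile")
  tab <- tabulate_homeologs(res$assignments)
  expect_equal(tab$H_MP, sum(prof$express_M & prof$express_P))
  expect_equal(tab$H_M, sum(prof$express_M & !prof$express_P))
  expect_equal(tab$H_P, sum(prof$express_P & !prof$express_M))
  expect_equal(tab$total, tab$H_MP + tab$H_M + tab$H_P)
})

test_that("phasing accuracy degrades monotonically with error rate", {
  # coupled noise: one uniform draw per base, an error occurs where the
  # draw falls below the rate, so error sets are nested across rates and
  # extra noise can only corrupt further
  cfg <- small_cfg(seed = 9, n_ogs = 15)
  ogs <- simulate_progenitor_ogs(cfg)
  iso <- simulate_polyploid_isoforms(ogs, cfg)
  set.seed(99)
  noise <- lapply(iso$isoforms, function(s) {
    n <- nchar(s)
    list(u = runif(n),
         alt = vapply(strsplit(s, "")[[1]],
                      function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                      ""))
  })
  accuracy_at <- function(rate) {
    seqs <- vapply(names(iso$isoforms), function(id) {
      ch <- strsplit(iso$isoforms[[id]], "")[[1]]
      hit <- noise[[id]]$u < rate
      ch[hit] <- noise[[id]]$alt[hit]
      paste(ch, collapse = "")
    }, "")
    asg <- phase_isoforms(seqs, ogs,
                          samples = setNames(iso$truth$sample,
                                             iso$truth$isoform_id))
    merged <- merge(asg, iso$truth, by = "isoform_id")
    mean(merged$call == merged$subgenome)
  }
  acc <- vapply(c(0, 0.005, 0.01, 0.02), accuracy_at, 0)
  expect_equal(acc[1], 1)
  expect_true(all(diff(acc) <= 1e-9))
})

test_that("every scored isoform gets exactly one call and totals add up", {
  res <- phase_sim(small_cfg(seed = 30, isoform_error_rate = 0.01,
                             recombinant_fraction = 0.1))
  calls <- res$assignments$call
  expect_true(all(calls %in% c("M", "P", "recombinant", "unassigned")))
  tab <- tabulate_homeologs(res$assignments)
  expect_equal(tab$total, tab$H_MP + tab$H_M + tab$H_P)
})

test_that("homeolog table percentages reproduce printed worked examples", {
  # percentages are count / total, rounded half-up to integer percent
  expect_equal(round_half_up(100 * 2164 / 3509), 62)
  expect_equal(round_half_up(100 * 614 / 3509), 17)
  expect_equal(round_half_up(100 * 731 / 3509), 21)
  expect_equal(round_half_up(100 * 3285 / 4389), 75)
})

test_that("pairwise correlation is 1 for identical, -1 for mirrored tables", {
  ogs <- sprintf("OG%02d", 1:20)
  a <- data.frame(sample = "A", og = ogs,
                  class = rep(c("H_M", "H_P"), 10))
  b <- a; b$sample <- "B"
  r <- pairwise_sample_correlation(rbind(a, b))
  expect_equal(r["A", "B"], 1)
  b2 <- a
  b2$sample <- "B"
  b2$class <- ifelse(a$class == "H_M", "H_P", "H_M")
  r2 <- pairwise_sample_correlation(rbind(a, b2))
  expect_equal(r2["A", "B"], -1)
})

test_that("independent random expression tables decorrelate", {
  set.seed(77)
  ogs <- sprintf("OG%04d", 1:1000)
  rnd <- function(s) data.frame(sample = s, og = ogs,
                                class = sample(c("H_MP", "H_M", "H_P"),
                                               1000, replace = TRUE))
  r <- pairwise_sample_correlation(rbind(rnd("A"), rnd("B")))
  expect_lt(abs(r["A", "B"]), 0.1)
})

test_that("zero-variance expression vectors give NA, not 0", {
  ogs <- sprintf("OG%02d", 1:5)
  a <- data.frame(sample = "A", og = ogs, class = "H_MP")
  b <- data.frame(sample = "B", og = ogs, class = "H_MP")
  r <- pairwise_sample_correlation(rbind(a, b))
  expect_true(is.na(r["A", "B"]))
})
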