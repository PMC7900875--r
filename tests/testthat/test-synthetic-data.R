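test_that("config validation rejects bad probabilities and counts", {
  expect_error(sim_config(intergroup_divergence = 1.5), "probability")
  expect_error(sim_config(n_ogs = 0), "count")
  expect_error(sim_config(og_length_codons = -3), "count")
  expect_error(sim_config(class_probs = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 7, n_ogs = 5, og_length_codons = 60)
  a <- simulate_progenitor_ogs(cfg)
  b <- simulate_progenitor_ogs(cfg)
  expect_identical(a, b)
  ia <- simulate_polyploid_isoforms(a, cfg)
  ib <- simulate_polyploid_isoforms(b, cfg)
  expect_identical(ia, ib)
  va <- simulate_allele_depth_vcf(cfg)
  vb <- simulate_allele_depth_vcf(cfg)
  expect_identical(va, vb)
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(list(ogs = a, iso = ia, vcf = va), d1)
  write_simulation(list(ogs = b, iso = ib, vcf = vb), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("orthogroup alignments are gapless, equal-length, truth retained", {
  cfg <- sim_config(seed = 3, n_ogs = 8, og_length_codons = 100)
  ogs <- simulate_progenitor_ogs(cfg)
  expect_length(ogs, 8)
  for (og in ogs) {
    expect_setequal(names(og$aln), c("eq", "mi", "mo", "pr", "re"))
    expect_true(all(nchar(og$aln) == 300))
    expect_false(any(grepl("-", og$aln)))
    expect_equal(nchar(og$hap_M), 300)
    expect_equal(nchar(og$hap_P), 300)
  }
})

test_that("zero inter-group divergence yields zero diagnostic sites", {
  cfg <- sim_config(seed = 2, n_ogs = 5, og_length_codons = 80,
                    intergroup_divergence = 0, branch_sub_prob = 0)
  ogs <- simulate_progenitor_ogs(cfg)
  for (og in ogs) {
    expect_equal(nrow(find_diagnostic_sites(og$aln)), 0)
  }
})

test_that("diagnostic-site counts follow the binomial expectation", {
  # 50 OGs x 600 sites at divergence 0.02: total fixed differences is
  # Bin(30000, 0.02); check the realised total against exact bounds
  cfg <- sim_config(seed = 1, n_ogs = 50, og_length_codons = 200,
                    intergroup_divergence = 0.02, branch_sub_prob = 0)
  ogs <- simulate_progenitor_ogs(cfg)
  counts <- vapply(ogs, function(og) nrow(find_diagnostic_sites(og$aln)), 0L)
  b <- oracle_binom_bounds(50 * 600, 0.02)
  expect_gte(sum(counts), b[["lo"]])
  expect_lte(sum(counts), b[["hi"]])
  expect_gt(mean(counts), 12 * 0.7)
  expect_lt(mean(counts), 12 * 1.3)
})

test_that("chimera counts match the configured recombinant fraction", {
  cfg <- sim_config(seed = 3, n_ogs = 120, og_length_codons = 60,
                    n_isoforms_mean = 9, recombinant_fraction = 0.05,
                    class_probs = c(both = 1, M = 0, P = 0))
  ogs <- simulate_progenitor_ogs(cfg)
  iso <- simulate_polyploid_isoforms(ogs, cfg)
  n <- nrow(iso$truth)
  n_rec <- sum(iso$truth$subgenome == "recombinant")
  # chimeras are only drawn among isoforms beyond the two guaranteed ones
  eligible <- sum(table(iso$truth$og) - 2)
  b <- oracle_binom_bounds(eligible, 0.05)
  expect_gte(n_rec, b[["lo"]])
  expect_lte(n_rec, b[["hi"]])
  expect_equal(length(iso$isoforms), n)  # one truth record per isoform
  expect_setequal(names(iso$isoforms), iso$truth$isoform_id)
})

test_that("one-sided expression profiles produce only that subgenome", {
  cfg <- sim_config(seed = 4, n_ogs = 10, og_length_codons = 60,
                    class_probs = c(both = 0, M = 1, P = 0))
  ogs <- simulate_progenitor_ogs(cfg)
  iso <- simulate_polyploid_isoforms(ogs, cfg)
  expect_true(all(iso$truth$subgenome == "M"))
})

test_that("expression profile referencing an unknown OG is rejected", {
  cfg <- sim_config(seed = 5, n_ogs = 3, og_length_codons = 60)
  ogs <- simulate_progenitor_ogs(cfg)
  cfg$expression_profile <- data.frame(og = "OG9999", sample = "S1",
                                       express_M = TRUE, express_P = TRUE,
                                       n_isoforms = 2L)
  expect_error(simulate_polyploid_isoforms(ogs, cfg), "unknown OG")
})

test_that("ks sample draws respect the mixture law and truncation", {
  x <- simulate_ks_sample(2000, list(c(1.0, 0.04, 0.01)), seed = 11)
  expect_length(x, 2000)
  expect_true(all(x > 0))
  # CLT bound: sample mean within 3 sd/sqrt(n) of 0.04
  expect_lt(abs(mean(x) - 0.04), 3 * 0.01 / sqrt(2000))
  expect_identical(simulate_ks_sample(0, list(c(1, 0.1, 0.01))), numeric(0))
  expect_error(simulate_ks_sample(10, list(c(0.5, 0.1, 0.01))), "sum to 1")
})

test_that("constructed VCF failures are removed at the stated rate", {
  cfg <- sim_config(seed = 6, n_ogs = 80, sites_per_gene_mean = 13,
                    fraction_failing_filters = 0.2,
                    autapomorphic_fraction = 0)
  v <- simulate_allele_depth_vcf(cfg)
  tf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(v$vcf, tf)
  sites <- read_vcf_sites(tf)
  passing <- filter_variants(sites)
  n_fail_truth <- sum(!is.na(v$site_truth$failing))
  expect_identical(attr(passing, "n_removed"), n_fail_truth)
  b <- oracle_binom_bounds(nrow(sites), 0.2)
  expect_gte(n_fail_truth, b[["lo"]])
  expect_lte(n_fail_truth, b[["hi"]])
})
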