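test_that("each hard filter fails and passes at its boundary", {
  th <- variant_filter_thresholds()
  cases <- list(
    list(col = "qd", fail = 1.9, pass = 2.0),
    list(col = "fs", fail = 10.1, pass = 10.0),
    list(col = "mq", fail = 39.9, pass = 40.0),
    list(col = "dp", fail = 29, pass = 30),
    list(col = "read_pos_rank_sum", fail = -8.1, pass = -8.0),
    list(col = "gq", fail = 19, pass = 20))
  for (cs in cases) {
    bad <- site_row(); bad[[cs$col]] <- cs$fail
    good <- site_row(); good[[cs$col]] <- cs$pass
    expect_equal(nrow(filter_variants(bad, th)), 0, label = cs$col)
    expect_equal(nrow(filter_variants(good, th)), 1, label = cs$col)
  }
})

test_that("missing annotations pass their criterion and are counted", {
  s <- site_row(); s$qd <- NA
  out <- filter_variants(s)
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "na_pass")[["qd"]], 1L)
})

test_that("site classification follows the parental-genotype definitions", {
  expect_equal(classify_sites(site_row(gt_poly = "0/1"))$class, "S_PM")
  expect_equal(classify_sites(site_row(gt_poly = "1/1"))$class, "S_PP")
  expect_equal(classify_sites(site_row(gt_poly = "0/0"))$class, "S_MM")
  # polyploid allele absent from both parents -> autapomorphic
  expect_equal(classify_sites(site_row(gt_poly = "0/2"))$class, "autapomorphic")
  # heterozygous or missing parent -> uninformative
  expect_true(is.na(classify_sites(site_row(gt_m = "0/1"))$class))
  expect_true(is.na(classify_sites(site_row(gt_p = "./."))$class))
  # parents identical -> uninformative
  expect_true(is.na(classify_sites(site_row(gt_p = "0/0"))$class))
})

test_that("gene classification needs four sites and obeys precedence", {
  mk <- function(n_spm, n_spp = 0, n_smm = 0) {
    rows <- c(rep("0/1", n_spm), rep("1/1", n_spp), rep("0/0", n_smm))
    d <- do.call(rbind, lapply(seq_along(rows), function(i) {
      site_row(gt_poly = rows[i], pos = i)
    }))
    classify_genes(classify_sites(d))
  }
  expect_equal(mk(3)$class, "unclassified")
  expect_equal(mk(4)$class, "G_PM")
  expect_equal(mk(0, 0, 4)$class, "G_MM")
  expect_equal(mk(5, 5)$class, "G_PM")     # precedence S_PM > S_PP
  expect_equal(mk(3, 4, 4)$class, "G_PP")  # then S_PP > S_MM
})

test_that("paternal fraction sums allele depths over S_PM sites", {
  d <- rbind(site_row(ad = "30,50", pos = 1), site_row(ad = "0,20", pos = 2),
             site_row(gt_poly = "1/1", ad = "0,99", pos = 3))
  cl <- classify_sites(d)
  expect_equal(homeolog_expression(cl), 70 / 100)
  all_m <- classify_sites(site_row(ad = "80,0"))
  expect_equal(homeolog_expression(all_m), 0)
  zero <- classify_sites(site_row(ad = "0,0"))
  expect_true(is.na(homeolog_expression(zero)))
})

test_that("dominance thresholds are strict and symmetric", {
  expect_equal(call_dominance(0.7), "P_dominant")
  expect_equal(call_dominance(0.35), "M_dominant")
  expect_equal(call_dominance(0.6), "conserved")
  expect_equal(call_dominance(0.4), "conserved")
  expect_equal(call_dominance(0.6000001), "P_dominant")
  expect_true(is.na(call_dominance(NA)))
})

test_that("noiseless synthetic VCF reproduces construction exactly", {
  cfg <- sim_config(seed = 61, n_ogs = 60, sites_per_gene_mean = 12,
                    fraction_failing_filters = 0, autapomorphic_fraction = 0)
  v <- simulate_allele_depth_vcf(cfg)
  tf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(v$vcf, tf)
  res <- snp_expression_analysis(read_vcf_sites(tf))
  truth_counts <- table(factor(v$site_truth$class,
                               levels = c("S_PM", "S_PP", "S_MM")))
  got <- res$summary$site_counts[c("S_PM", "S_PP", "S_MM")]
  expect_equal(as.integer(got), as.integer(truth_counts))
  # gene classes from truth counts under the same precedence rule
  truth_class <- with(v$gene_truth,
                      ifelse(n_spm >= 4, "G_PM",
                             ifelse(n_spp >= 4, "G_PP",
                                    ifelse(n_smm >= 4, "G_MM", "unclassified"))))
  expect_equal(res$genes$class[match(v$gene_truth$gene, res$genes$gene)],
               truth_class)
})

test_that("estimated paternal fractions track the generator's truth", {
  cfg <- sim_config(seed = 62, n_ogs = 80, depth_mean = 200,
                    fraction_failing_filters = 0, autapomorphic_fraction = 0)
  v <- simulate_allele_depth_vcf(cfg)
  tf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(v$vcf, tf)
  res <- snp_expression_analysis(read_vcf_sites(tf))
  g <- merge(res$genes[res$genes$class == "G_PM", ], v$gene_truth, by = "gene")
  expect_gt(nrow(g), 30)
  # each gene's estimate is binomial around truth; allow 5 sd of the
  # aggregated depth (~ n_spm * depth_mean draws)
  n_reads <- g$n_spm.x * cfg$depth_mean
  tol <- 5 * sqrt(g$p_fraction.y * (1 - g$p_fraction.y) / n_reads)
  expect_true(all(abs(g$p_fraction.x - g$p_fraction.y) < pmax(tol, 0.02)))
})

test_that("symmetric expression law yields balanced dominance calls", {
  cfg <- sim_config(seed = 63, n_ogs = 400, sites_per_gene_mean = 10,
                    depth_mean = 150, fraction_failing_filters = 0,
                    autapomorphic_fraction = 0)
  v <- simulate_allele_depth_vcf(cfg)
  tf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(v$vcf, tf)
  res <- snp_expression_analysis(read_vcf_sites(tf))
  dom <- res$summary$dominance_counts
  n_dom <- dom[["M_dominant"]] + dom[["P_dominant"]]
  # under the symmetric law, M-dominant ~ Bin(n_dom, 0.5)
  b <- oracle_binom_bounds(n_dom, 0.5)
  expect_gte(dom[["M_dominant"]], b[["lo"]])
  expect_lte(dom[["M_dominant"]], b[["hi"]])
})
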