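#' Infer DNA ploidy level from holoploid genome size
#'
#' Ploidy is \code{2 * round(1C / reference 1C)} where the reference is a
#' known diploid's 1C value; ratios farther than 0.25 from the nearest
#' integer multiple are rejected as ambiguous.
#'
#' @param holoploid_1c_pg measured 1C value (pg).
#' @param diploid_reference_1c_pg 1C value of the diploid calibrator (pg).
#' @return integer ploidy level (2, 4, ...).
#' @export
infer_ploidy <- function(holoploid_1c_pg, diploid_reference_1c_pg) {
  if (holoploid_1c_pg <= 0 || diploid_reference_1c_pg <= 0)
    .stopf("genome sizes must be positive")
  ratio <- holoploid_1c_pg / diploid_reference_1c_pg
  m <- round(ratio)
  if (m < 1 || abs(ratio - m) > 0.25)
    .stopf("ambiguous ploidy: 1C ratio %.3f is not near an integer multiple",
           ratio)
  as.integer(2L * m)
}

#' Monoploid (1Cx) genome size
#'
#' @param holoploid_1c_pg 1C value (pg).
#' @param ploidy even ploidy level >= 2.
#' @return 1Cx in pg, rounded half-up to 2 decimals.
#' @export
monoploid_size <- function(holoploid_1c_pg, ploidy) {
  if (ploidy < 2 || ploidy %% 2 != 0) .stopf("ploidy must be even and >= 2")
  round_half_up(holoploid_1c_pg / (ploidy / 2), 2)
}

#' Annotate a flow-cytometry table with ploidy and monoploid sizes
#'
#' @param cytometry data frame with columns \code{species},
#'   \code{holoploid_1c_pg} (and optionally \code{sd}, \code{cv_percent}).
#' @param diploid_reference_1c_pg diploid calibrator 1C value.
#' @return input with added \code{ploidy} and \code{monoploid_1cx_pg}.
#' @export
cytometry_table <- function(cytometry, diploid_reference_1c_pg) {
  cytometry$ploidy <- vapply(cytometry$holoploid_1c_pg, infer_ploidy, 0L,
                             diploid_reference_1c_pg = diploid_reference_1c_pg)
  cytometry$monoploid_1cx_pg <- mapply(monoploid_size,
                                       cytometry$holoploid_1c_pg,
                                       cytometry$ploidy)
  cytometry
}

#' Test genome-size additivity of an allotetraploid
#'
#' Flags the tetraploid as additive when its 1C value is within
#' \code{tol} (relative) of the sum of the two parental 1C values —
#' limited genome restructuring after allopolyploid formation.
#'
#' @param tetraploid_1c_pg tetraploid 1C value (pg).
#' @param maternal_1c_pg,paternal_1c_pg parental 1C values (pg).
#' @param tol relative tolerance (default 0.05).
#' @return list with \code{expected_pg}, \code{observed_pg},
#'   \code{relative_deviation}, \code{additive}.
#' @export
additivity_check <- function(tetraploid_1c_pg, maternal_1c_pg, paternal_1c_pg,
                             tol = 0.05) {
  expected <- maternal_1c_pg + paternal_1c_pg
  dev <- abs(tetraploid_1c_pg - expected) / expected
  list(expected_pg = expected, observed_pg = tetraploid_1c_pg,
       relative_deviation = dev, additive = dev <= tol)
}

#' Run the full synthetic pipeline
#'
#' Generates a synthetic dataset from \code{cfg}, then runs every analysis
#' stage in dependency order: phasing and homeolog tabulation, saturation
#' subsampling and fitting, alternative-splicing detection, Ks estimation
#' on the phased homeolog pairs with mixture dating, VCF-based SNP
#' expression, and gene-tree screening. All tables are written as TSV under
#' \code{outdir} together with a JSON run manifest (seed, parameters,
#' input checksums).
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory.
#' @param saturation_sizes subsample sizes (scaled to the synthetic pool;
#'   \code{NULL} picks 5 evenly spaced sizes up to the pool size).
#' @param ks_rate synonymous clock rate for dating.
#' @return invisibly, a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_pipeline <- function(cfg, outdir, saturation_sizes = NULL,
                         ks_rate = 4.8e-9) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ogs <- simulate_progenitor_ogs(cfg)
  iso <- simulate_polyploid_isoforms(ogs, cfg)
  vcf <- simulate_allele_depth_vcf(cfg)
  trees <- simulate_gene_trees(iso$truth, seed = cfg$seed + 3000L)
  write_simulation(list(ogs = ogs, iso = iso, vcf = vcf, trees = trees),
                   file.path(outdir, "inputs"))

  samples <- setNames(iso$truth$sample, iso$truth$isoform_id)
  assignments <- phase_isoforms(iso$isoforms, ogs, samples = samples)
  homeolog_table <- tabulate_homeologs(assignments)
  wtsv <- function(d, f) {
    write.table(d, file.path(outdir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wtsv(assignments, "assignments.tsv")
  wtsv(homeolog_table, "homeolog_table.tsv")

  pool <- assignments$isoform_id
  if (is.null(saturation_sizes)) {
    saturation_sizes <- unique(pmax(1, round(seq(0.2, 1, by = 0.2) * length(pool))))
  }
  sat_points <- subsample_counts(pool,
                                 saturation_design(sizes = saturation_sizes,
                                                   seed = cfg$seed),
                                 make_assignment_counter(assignments))
  sat_fit1 <- try(fit_loglog_quadratic(sat_points, "y1"), silent = TRUE)
  sat_fit2 <- try(fit_loglog_quadratic(sat_points, "y2"), silent = TRUE)
  wtsv(sat_points, "saturation_points.tsv")

  og_of <- setNames(assignments$og, assignments$isoform_id)
  events <- call_as_events(iso$isoforms, og_of)
  as_table <- tabulate_as(events, assignments)
  wtsv(events, "as_events.tsv")
  wtsv(as_table, "as_table.tsv")

  # Ks between the phased M and P homeologs of each H_MP orthogroup
  ks_values <- c()
  ogc <- attr(homeolog_table, "og_classes")
  hmp <- unique(ogc$og[ogc$class == "H_MP"])
  for (og in hmp) {
    a <- assignments[!is.na(assignments$og) & assignments$og == og, ]
    m_id <- a$isoform_id[a$call == "M"][1]
    p_id <- a$isoform_id[a$call == "P"][1]
    if (is.na(m_id) || is.na(p_id)) next
    est <- ks_pair(iso$isoforms[[m_id]], iso$isoforms[[p_id]])
    if (!is.null(est)) ks_values <- c(ks_values, est$ks)
  }
  ks_values <- filter_ks(ks_values)
  ks_result <- NULL
  if (length(ks_values) >= 10) {
    fits <- fit_mixture(ks_values, seed = cfg$seed)
    sel <- selected_mixture(fits)
    peak <- dominant_component_mean(sel)
    ks_result <- list(values = ks_values, fit = sel,
                      dating = divergence_time(peak, rate = ks_rate))
    wtsv(data.frame(ks = ks_values), "ks_values.tsv")
    wtsv(data.frame(component = seq_len(sel$k), weight = sel$weights,
                    mean = sel$means, sd = sel$sds), "mixture_fit.tsv")
  }

  vcf_path <- file.path(outdir, "inputs", "variants.vcf")
  snp <- snp_expression_analysis(read_vcf_sites(vcf_path))
  wtsv(snp$genes, "gene_classes.tsv")

  screened <- screen_gene_trees(trees$newick, trees$isoform_id)
  wtsv(screened, "tree_calls.tsv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("homeologr")),
    seed = cfg$seed,
    parameters = cfg[!vapply(cfg, is.data.frame, TRUE)],
    input_checksums = as.list(tools::md5sum(
      list.files(file.path(outdir, "inputs"), full.names = TRUE,
                 recursive = TRUE))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(ogs = ogs, iso = iso, assignments = assignments,
                 homeolog_table = homeolog_table, saturation = sat_points,
                 sat_fit_y1 = sat_fit1, sat_fit_y2 = sat_fit2,
                 as_events = events, as_table = as_table, ks = ks_result,
                 snp = snp, tree_calls = screened, manifest = manifest))
}
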