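#' Hard-filter thresholds for variant sites
#'
#' GATK-style removal criteria, expressed as pass conditions with boundary
#' values passing: a site passes when QD >= 2.0, FS <= 10.0, MQ >= 40.0,
#' DP >= 30, ReadPosRankSum >= -8.0 and GQ >= 20.
#'
#' @param qd_min,fs_max,mq_min,dp_min,read_pos_rank_sum_min,gq_min numeric
#'   thresholds.
#' @return object of class \code{variant_filter_thresholds}.
#' @export
variant_filter_thresholds <- function(qd_min = 2.0, fs_max = 10.0,
                                      mq_min = 40.0, dp_min = 30.0,
                                      read_pos_rank_sum_min = -8.0,
                                      gq_min = 20.0) {
  th <- list(qd_min = qd_min, fs_max = fs_max, mq_min = mq_min,
             dp_min = dp_min, read_pos_rank_sum_min = read_pos_rank_sum_min,
             gq_min = gq_min)
  if (!all(vapply(th, is.finite, TRUE))) .stopf("all thresholds must be finite")
  structure(th, class = "variant_filter_thresholds")
}

#' Read a VCF of parent and polyploid samples into a site table
#'
#' Parses a VCF v4.2 (via \pkg{vcfR}) holding two homozygous parental
#' samples and one polyploid sample, extracting genotypes, polyploid
#' allele depths and the INFO annotations used by the hard filters.
#'
#' @param path path to a plain-text VCF.
#' @param maternal,paternal,polyploid sample column names.
#' @return data frame with one row per site: \code{gene} (CHROM),
#'   \code{pos}, \code{ref}, \code{alt} (comma-joined ALT alleles),
#'   \code{qd}, \code{fs}, \code{mq}, \code{dp}, \code{read_pos_rank_sum},
#'   \code{gq}, \code{gt_m}, \code{gt_p}, \code{gt_poly}, \code{ad_poly}.
#' @export
read_vcf_sites <- function(path, maternal = "maternal", paternal = "paternal",
                           polyploid = "polyploid") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info_num <- function(field) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = field)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  gq <- suppressWarnings(apply(vcfR::extract.gt(v, element = "GQ"), 2,
                               as.numeric))
  for (s in c(maternal, paternal, polyploid)) {
    if (!s %in% colnames(gt)) .stopf("sample '%s' absent from VCF", s)
  }
  data.frame(gene = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
             alt = fix$ALT, qd = info_num("QD"), fs = info_num("FS"),
             mq = info_num("MQ"), dp = info_num("DP"),
             read_pos_rank_sum = info_num("ReadPosRankSum"),
             gq = gq[, polyploid],
             gt_m = unname(gt[, maternal]), gt_p = unname(gt[, paternal]),
             gt_poly = unname(gt[, polyploid]),
             ad_poly = unname(ad[, polyploid]), stringsAsFactors = FALSE)
}

#' Apply hard filters to a site table
#'
#' A site passes iff every annotated criterion passes; a missing
#' annotation passes that criterion (counted in the \code{"na_pass"}
#' attribute).
#'
#' @param sites site table from [read_vcf_sites()].
#' @param th a [variant_filter_thresholds()].
#' @return the passing subset, with attribute \code{"n_removed"} and
#'   \code{"na_pass"} (criterion-wise count of missing annotations).
#' @export
filter_variants <- function(sites, th = variant_filter_thresholds()) {
  crit <- list(qd = sites$qd >= th$qd_min,
               fs = sites$fs <= th$fs_max,
               mq = sites$mq >= th$mq_min,
               dp = sites$dp >= th$dp_min,
               read_pos_rank_sum = sites$read_pos_rank_sum >= th$read_pos_rank_sum_min,
               gq = sites$gq >= th$gq_min)
  na_pass <- vapply(crit, function(x) sum(is.na(x)), 0L)
  pass <- Reduce(`&`, lapply(crit, function(x) ifelse(is.na(x), TRUE, x)))
  out <- sites[pass, , drop = FALSE]
  attr(out, "n_removed") <- sum(!pass)
  attr(out, "na_pass") <- na_pass
  out
}

# genotype string -> integer allele indices, or NULL if missing
.gt_alleles <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NULL)
  a <- suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1]]))
  if (any(is.na(a))) return(NULL)
  a
}

#' Classify variant sites relative to the two parents
#'
#' At sites where both parents are homozygous for different alleles, the
#' polyploid genotype is classified as S_PM (heterozygous, carrying both
#' parental alleles), S_PP (homozygous paternal), S_MM (homozygous
#' maternal), or autapomorphic (any polyploid allele absent from both
#' parents; excluded downstream). Sites with heterozygous or missing
#' parents are uninformative.
#'
#' @param sites (filtered) site table.
#' @return input with added \code{class} column; uninformative rows carry
#'   \code{NA}.
#' @export
classify_sites <- function(sites) {
  cls <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    am <- .gt_alleles(sites$gt_m[i])
    ap <- .gt_alleles(sites$gt_p[i])
    ao <- .gt_alleles(sites$gt_poly[i])
    if (is.null(am) || is.null(ap) || is.null(ao)) next
    if (length(unique(am)) != 1 || length(unique(ap)) != 1) next
    m <- am[1]; p <- ap[1]
    if (m == p) next
    if (any(!ao %in% c(m, p))) { cls[i] <- "autapomorphic"; next }
    u <- unique(ao)
    cls[i] <- if (all(c(m, p) %in% u)) "S_PM"
      else if (all(u == p)) "S_PP"
      else "S_MM"
  }
  sites$class <- cls
  sites
}

#' Classify genes from their site-class counts
#'
#' A gene is G_PM with >= \code{min_sites} S_PM sites; otherwise G_PP with
#' >= \code{min_sites} S_PP sites; otherwise G_MM with >= \code{min_sites}
#' S_MM sites; otherwise unclassified. Precedence S_PM > S_PP > S_MM keeps
#' the classes exclusive.
#'
#' @param sites classified site table (from [classify_sites()]).
#' @param min_sites sites of the defining kind required (default 4).
#' @return data frame with one row per gene: \code{gene}, \code{n_spm},
#'   \code{n_spp}, \code{n_smm}, \code{class}.
#' @export
classify_genes <- function(sites, min_sites = 4L) {
  s <- sites[!is.na(sites$class) & sites$class != "autapomorphic", ]
  genes <- sort(unique(sites$gene))
  count <- function(g, k) sum(s$gene == g & s$class == k)
  rows <- lapply(genes, function(g) {
    n_spm <- count(g, "S_PM"); n_spp <- count(g, "S_PP"); n_smm <- count(g, "S_MM")
    cls <- if (n_spm >= min_sites) "G_PM"
      else if (n_spp >= min_sites) "G_PP"
      else if (n_smm >= min_sites) "G_MM"
      else "unclassified"
    data.frame(gene = g, n_spm = n_spm, n_spp = n_spp, n_smm = n_smm,
               class = cls, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# AD string "m,p[,other]" -> c(maternal, paternal) depths given allele
# indices; REF is index 0.
.spm_depths <- function(ad, m_idx, p_idx) {
  d <- suppressWarnings(as.integer(strsplit(ad, ",")[[1]]))
  if (any(is.na(d))) return(c(0L, 0L))
  c(d[m_idx + 1L], d[p_idx + 1L])
}

#' Paternal expression fraction of a G_PM gene
#'
#' Sums polyploid allele depths over the gene's S_PM sites:
#' \code{p_fraction} = paternal reads / (paternal + maternal reads).
#'
#' @param sites classified site table for one gene (rows with class
#'   \code{"S_PM"} are used).
#' @return numeric in \[0, 1\], or \code{NA} when total depth is zero.
#' @export
homeolog_expression <- function(sites) {
  s <- sites[!is.na(sites$class) & sites$class == "S_PM", , drop = FALSE]
  if (!nrow(s)) return(NA_real_)
  tot_m <- tot_p <- 0L
  for (i in seq_len(nrow(s))) {
    am <- .gt_alleles(s$gt_m[i])[1]
    ap <- .gt_alleles(s$gt_p[i])[1]
    d <- .spm_depths(s$ad_poly[i], am, ap)
    tot_m <- tot_m + d[1]; tot_p <- tot_p + d[2]
  }
  if (tot_m + tot_p == 0) return(NA_real_)
  tot_p / (tot_m + tot_p)
}

#' Call homeolog dominance from a paternal expression fraction
#'
#' Strictly above \code{threshold} is P-dominant, strictly below
#' \code{1 - threshold} is M-dominant, the closed central band (default
#' \[0.4, 0.6\]) is conserved.
#'
#' @param p_fraction numeric vector in \[0, 1\] (NAs preserved).
#' @param threshold dominance cutoff (default 0.6).
#' @return character vector: \code{"P_dominant"}, \code{"M_dominant"},
#'   \code{"conserved"} or \code{NA}.
#' @export
call_dominance <- function(p_fraction, threshold = 0.6) {
  ifelse(is.na(p_fraction), NA_character_,
         ifelse(p_fraction > threshold, "P_dominant",
                ifelse(p_fraction < 1 - threshold, "M_dominant", "conserved")))
}

#' Full SNP-based homeolog expression analysis of one polyploid sample
#'
#' Filters the site table, classifies sites and genes, computes the
#' paternal expression fraction of each G_PM gene and calls dominance.
#'
#' @param sites site table from [read_vcf_sites()].
#' @param th a [variant_filter_thresholds()].
#' @param min_sites gene-class threshold (default 4).
#' @param dominance_threshold dominance cutoff (default 0.6).
#' @return list with \code{sites} (classified, passing sites),
#'   \code{genes} (gene classes with \code{p_fraction} and
#'   \code{dominance}), and \code{summary} (site- and gene-class counts
#'   and shares).
#' @export
snp_expression_analysis <- function(sites, th = variant_filter_thresholds(),
                                    min_sites = 4L,
                                    dominance_threshold = 0.6) {
  passing <- filter_variants(sites, th)
  classified <- classify_sites(passing)
  genes <- classify_genes(classified, min_sites = min_sites)
  pf <- vapply(genes$gene, function(g) {
    if (genes$class[genes$gene == g] != "G_PM") return(NA_real_)
    homeolog_expression(classified[classified$gene == g, , drop = FALSE])
  }, 0)
  genes$p_fraction <- unname(pf)
  genes$dominance <- call_dominance(genes$p_fraction, dominance_threshold)
  site_counts <- table(factor(classified$class,
                              levels = c("S_PM", "S_PP", "S_MM", "autapomorphic")))
  gene_counts <- table(factor(genes$class,
                              levels = c("G_PM", "G_PP", "G_MM", "unclassified")))
  informative <- sum(site_counts[c("S_PM", "S_PP", "S_MM")])
  summary <- list(
    site_counts = site_counts,
    spm_share = if (informative > 0) site_counts[["S_PM"]] / informative else NA,
    gene_counts = gene_counts,
    dominance_counts = table(factor(genes$dominance,
                                    levels = c("M_dominant", "conserved",
                                               "P_dominant"))))
  list(sites = classified, genes = genes, summary = summary)
}
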