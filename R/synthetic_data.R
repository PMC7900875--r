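#' Configuration for the synthetic allopolyploid transcriptome generator
#'
#' Bundles every tunable of the simulation: a five-taxon progenitor panel
#' with two diverged parental groups (maternal \code{pr}, \code{re};
#' paternal \code{eq}, \code{mi}, \code{mo}), polyploid isoforms drawn from
#' the two subgenome haplotypes with sequencing error and occasional
#' chimeric (recombinant) molecules, allele-depth tables for SNP-based
#' expression analysis, and Ks draws from Gaussian mixtures.
#'
#' @param seed integer seed; the same seed yields byte-identical outputs.
#' @param n_ogs number of one-to-one orthogroups to simulate.
#' @param og_length_codons orthogroup CDS length in codons.
#' @param branch_sub_prob per-site substitution probability on each terminal
#'   branch (within-group noise), Jukes-Cantor exchanges.
#' @param intergroup_divergence expected fraction of sites carrying a fixed
#'   difference between the maternal and paternal groups.
#' @param isoform_error_rate per-base error probability injected into
#'   polyploid isoforms (base exchanges, i.i.d.).
#' @param recombinant_fraction fraction of polyploid isoforms that are
#'   single-breakpoint M/P chimeras.
#' @param n_isoforms_mean mean isoforms per expressed orthogroup and sample.
#' @param expression_profile optional data frame with columns \code{og},
#'   \code{sample}, \code{express_M}, \code{express_P}, \code{n_isoforms};
#'   when \code{NULL} one is drawn using \code{class_probs}.
#' @param class_probs length-3 probabilities that an orthogroup expresses
#'   both subgenomes, only M, or only P (in that order).
#' @param samples character vector of polyploid sample names.
#' @param depth_mean mean read depth per site for allele-depth tables.
#' @param sites_per_gene_mean mean number of parent-divergent sites per gene
#'   in the simulated VCF.
#' @param site_class_props length-3 probabilities of the S_PM / S_PP / S_MM
#'   site classes at parent-divergent sites.
#' @param p_fraction_law list describing the distribution of a gene's true
#'   paternal expression fraction: \code{conserved} weight of the central
#'   band, \code{band} its uniform support, \code{tail} the uniform support
#'   of the dominant tails (mirrored for the maternal side so the law is
#'   symmetric about 0.5).
#' @param fraction_failing_filters fraction of VCF sites constructed to fail
#'   one hard filter.
#' @param autapomorphic_fraction fraction of VCF sites where the polyploid
#'   carries an allele absent from both parents.
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_ogs = 40L,
                       og_length_codons = 200L,
                       branch_sub_prob = 0.003,
                       intergroup_divergence = 0.02,
                       isoform_error_rate = 0.002,
                       recombinant_fraction = 0.02,
                       n_isoforms_mean = 6,
                       expression_profile = NULL,
                       class_probs = c(both = 0.70, M = 0.15, P = 0.15),
                       samples = "S1",
                       depth_mean = 100,
                       sites_per_gene_mean = 12,
                       site_class_props = c(S_PM = 0.77, S_PP = 0.12, S_MM = 0.11),
                       p_fraction_law = list(conserved = 0.8,
                                             band = c(0.4, 0.6),
                                             tail = c(0.6, 0.95)),
                       fraction_failing_filters = 0,
                       autapomorphic_fraction = 0.02) {
  if (!.is_count(seed + 1)) .stopf("seed must be a single integer")
  if (!.is_count(n_ogs)) .stopf("n_ogs must be a positive count")
  if (!.is_count(og_length_codons)) .stopf("og_length_codons must be a positive count")
  for (p in c("branch_sub_prob", "intergroup_divergence", "isoform_error_rate",
              "recombinant_fraction", "fraction_failing_filters",
              "autapomorphic_fraction")) {
    if (!.is_prob(get(p))) .stopf("%s must be a probability in [0,1]", p)
  }
  if (n_isoforms_mean < 1) .stopf("n_isoforms_mean must be >= 1")
  if (abs(sum(class_probs) - 1) > 1e-9) .stopf("class_probs must sum to 1")
  if (abs(sum(site_class_props) - 1) > 1e-9) .stopf("site_class_props must sum to 1")
  if (depth_mean < 0) .stopf("depth_mean must be non-negative")
  cfg <- list(seed = as.integer(seed), n_ogs = as.integer(n_ogs),
              og_length_codons = as.integer(og_length_codons),
              branch_sub_prob = branch_sub_prob,
              intergroup_divergence = intergroup_divergence,
              isoform_error_rate = isoform_error_rate,
              recombinant_fraction = recombinant_fraction,
              n_isoforms_mean = n_isoforms_mean,
              expression_profile = expression_profile,
              class_probs = class_probs, samples = samples,
              depth_mean = depth_mean,
              sites_per_gene_mean = sites_per_gene_mean,
              site_class_props = site_class_props,
              p_fraction_law = p_fraction_law,
              fraction_failing_filters = fraction_failing_filters,
              autapomorphic_fraction = autapomorphic_fraction)
  class(cfg) <- "sim_config"
  cfg
}

.BASES <- c("A", "C", "G", "T")

# All 61 sense codons of the universal code.
.sense_codons <- function() {
  codons <- apply(expand.grid(.BASES, .BASES, .BASES, stringsAsFactors = FALSE),
                  1, paste0, collapse = "")
  codons[!codons %in% c("TAA", "TAG", "TGA")]
}

# Jukes-Cantor exchange: replace each selected position by a uniformly
# chosen different base.
.jc_mutate <- function(seq_chars, idx) {
  if (length(idx) == 0) return(seq_chars)
  cur <- seq_chars[idx]
  new <- vapply(cur, function(b) sample(setdiff(.BASES, b), 1), "")
  seq_chars[idx] <- new
  seq_chars
}

#' Simulate aligned progenitor orthogroups
#'
#' Generates \code{cfg$n_ogs} gapless equal-length CDS alignments for the
#' five diploid progenitor taxa under the fixed species topology
#' \code{((eq,(mi,mo)),(pr,re))}. Fixed inter-group differences are placed
#' on the stem separating the maternal and paternal groups (each site
#' independently with probability \code{intergroup_divergence}); each tip
#' then accumulates private Jukes-Cantor substitutions at
#' \code{branch_sub_prob} per site. The ancestral maternal (M) and paternal
#' (P) haplotypes are retained as simulation truth.
#'
#' @param cfg a [sim_config()].
#' @return an object of class \code{og_set}: a list of orthogroups, each with
#'   \code{og_id}, \code{aln} (named character vector of 5 aligned
#'   sequences), \code{hap_M}, \code{hap_P} (truth haplotypes).
#' @export
simulate_progenitor_ogs <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$og_length_codons * 3L
  sense <- .sense_codons()
  ogs <- vector("list", cfg$n_ogs)
  for (i in seq_len(cfg$n_ogs)) {
    root <- unlist(strsplit(paste0(sample(sense, cfg$og_length_codons,
                                          replace = TRUE), collapse = ""), ""))
    # fixed differences between the two parental groups live on the stem
    div_idx <- which(runif(L) < cfg$intergroup_divergence)
    hap_M <- root
    hap_P <- .jc_mutate(root, div_idx)
    tip <- function(hap) {
      .jc_mutate(hap, which(runif(L) < cfg$branch_sub_prob))
    }
    aln <- c(eq = paste0(tip(hap_P), collapse = ""),
             mi = paste0(tip(hap_P), collapse = ""),
             mo = paste0(tip(hap_P), collapse = ""),
             pr = paste0(tip(hap_M), collapse = ""),
             re = paste0(tip(hap_M), collapse = ""))
    ogs[[i]] <- list(og_id = sprintf("OG%04d", i), aln = aln,
                     hap_M = paste0(hap_M, collapse = ""),
                     hap_P = paste0(hap_P, collapse = ""))
  }
  names(ogs) <- vapply(ogs, `[[`, "", "og_id")
  class(ogs) <- "og_set"
  ogs
}

# Draw an expression profile: one row per (og, sample).
.draw_expression_profile <- function(cfg) {
  grid <- expand.grid(og = names_or_ids(cfg$n_ogs), sample = cfg$samples,
                      stringsAsFactors = FALSE)
  cls <- sample(c("both", "M", "P"), nrow(grid), replace = TRUE,
                prob = cfg$class_probs)
  data.frame(og = grid$og, sample = grid$sample,
             express_M = cls != "P", express_P = cls != "M",
             n_isoforms = 1L + rpois(nrow(grid), cfg$n_isoforms_mean - 1),
             stringsAsFactors = FALSE)
}

names_or_ids <- function(n) sprintf("OG%04d", seq_len(n))

#' Simulate polyploid full-length isoforms
#'
#' Draws isoforms for each polyploid sample from the true M and P subgenome
#' haplotypes of each expressed orthogroup, injects i.i.d. base-exchange
#' errors at \code{isoform_error_rate}, and converts a configurable fraction
#' into single-breakpoint M/P chimeras (the breakpoint uniform over internal
#' positions). When both subgenomes are expressed, at least one
#' non-recombinant isoform of each is guaranteed, so that noiseless truth
#' recovery is exact.
#'
#' @param ogs an \code{og_set} from [simulate_progenitor_ogs()].
#' @param cfg the same [sim_config()].
#' @return list with \code{isoforms} (named character vector of sequences;
#'   names are bare isoform ids) and \code{truth}, a data frame with one row
#'   per isoform: \code{isoform_id}, \code{sample}, \code{og},
#'   \code{subgenome} (\code{M}/\code{P}/\code{recombinant}),
#'   \code{breakpoint} (NA for non-chimeras), plus the expression profile as
#'   attribute \code{"profile"}. Truth is sidecar data only: analysis
#'   modules must not consume it.
#' @export
simulate_polyploid_isoforms <- function(ogs, cfg) {
  stopifnot(inherits(ogs, "og_set"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1000L)
  profile <- cfg$expression_profile
  if (is.null(profile)) profile <- .draw_expression_profile(cfg)
  bad <- setdiff(profile$og, names(ogs))
  if (length(bad)) .stopf("expression profile references unknown OG(s): %s",
                          paste(head(bad, 3), collapse = ", "))
  seqs <- character(0)
  rows <- vector("list", nrow(profile))
  counter <- 0L
  for (r in seq_len(nrow(profile))) {
    og <- ogs[[profile$og[r]]]
    em <- profile$express_M[r]; ep <- profile$express_P[r]
    if (!em && !ep) next
    n <- profile$n_isoforms[r]
    src <- if (em && ep) {
      base <- c("M", "P")
      if (n > 2) c(base, sample(c("M", "P"), n - 2, replace = TRUE)) else base[seq_len(n)]
    } else rep(if (em) "M" else "P", n)
    # chimeras only where both parental haplotypes are transcribed
    if (em && ep && n > 2) {
      extra <- seq(3, n)
      chim <- extra[runif(length(extra)) < cfg$recombinant_fraction]
      src[chim] <- "recombinant"
    }
    for (s in src) {
      counter <- counter + 1L
      id <- sprintf("iso%06d", counter)
      bp <- NA_integer_
      if (s == "recombinant") {
        L <- nchar(og$hap_M)
        bp <- sample(seq_len(L - 1L), 1)
        chars <- c(substring(og$hap_M, 1, bp), substring(og$hap_P, bp + 1, L))
        seq <- paste0(chars, collapse = "")
      } else {
        seq <- if (s == "M") og$hap_M else og$hap_P
      }
      sc <- unlist(strsplit(seq, ""))
      sc <- .jc_mutate(sc, which(runif(length(sc)) < cfg$isoform_error_rate))
      seqs[id] <- paste0(sc, collapse = "")
      rows[[counter]] <- data.frame(isoform_id = id, sample = profile$sample[r],
                                    og = og$og_id, subgenome = s,
                                    breakpoint = bp, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows[seq_len(counter)])
  attr(truth, "profile") <- profile
  list(isoforms = seqs, truth = truth)
}

# Draw a gene-level true paternal expression fraction from the configured
# law: a central conserved band plus symmetric dominant tails.
.draw_p_fraction <- function(n, law) {
  w <- law$conserved
  u <- runif(n)
  out <- numeric(n)
  central <- u < w
  out[central] <- runif(sum(central), law$band[1], law$band[2])
  k <- sum(!central)
  if (k) {
    tails <- runif(k, law$tail[1], law$tail[2])
    flip <- runif(k) < 0.5
    tails[flip] <- 1 - tails[flip]
    out[!central] <- tails
  }
  out
}

#' Simulate a VCF of parental and polyploid genotypes with allele depths
#'
#' Emulates variant calls of a tetraploid and its two diploid parents
#' against the maternal-progenitor transcript reference. Sites are
#' parent-divergent (REF = maternal allele, ALT = paternal allele) and are
#' S_PM / S_PP / S_MM in the configured proportions; allele depths at S_PM
#' sites are binomial draws around the gene's true paternal fraction. INFO
#' annotations (QD, FS, MQ, DP, ReadPosRankSum) and polyploid GQ are
#' populated, with \code{fraction_failing_filters} of sites constructed to
#' fail exactly one hard filter, and \code{autapomorphic_fraction} of sites
#' given a polyploid allele absent from both parents.
#'
#' @param cfg a [sim_config()].
#' @param n_genes number of reference genes (defaults to \code{cfg$n_ogs}).
#' @return list with \code{vcf}: character vector of VCF v4.2 lines
#'   (samples \code{maternal}, \code{paternal}, \code{polyploid});
#'   \code{site_truth}: data frame of per-site construction (gene, pos,
#'   class, failing filter if any); \code{gene_truth}: per-gene true
#'   paternal fraction and site-class counts.
#' @export
simulate_allele_depth_vcf <- function(cfg, n_genes = cfg$n_ogs) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2000L)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  p_frac <- .draw_p_fraction(n_genes, cfg$p_fraction_law)
  filters <- c("QD", "FS", "MQ", "DP", "ReadPosRankSum", "GQ")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth of coverage\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "maternal", "paternal", "polyploid", sep = "\t"))
  body <- character(0)
  site_rows <- list()
  gene_counts <- matrix(0L, n_genes, 3,
                        dimnames = list(genes, c("S_PM", "S_PP", "S_MM")))
  k <- 0L
  for (g in seq_len(n_genes)) {
    n_sites <- 1L + rpois(1, max(cfg$sites_per_gene_mean - 1, 0))
    pos <- sort(sample.int(cfg$og_length_codons * 3L, n_sites))
    cls <- sample(c("S_PM", "S_PP", "S_MM"), n_sites, replace = TRUE,
                  prob = cfg$site_class_props)
    auta <- runif(n_sites) < cfg$autapomorphic_fraction
    fail <- ifelse(runif(n_sites) < cfg$fraction_failing_filters,
                   sample(filters, n_sites, replace = TRUE), NA_character_)
    for (j in seq_len(n_sites)) {
      ref <- sample(.BASES, 1)
      alt <- sample(setdiff(.BASES, ref), 1)
      dp <- rpois(1, cfg$depth_mean)
      # AD per allele (REF=maternal, ALT=paternal)
      if (auta[j]) {
        other <- sample(setdiff(.BASES, c(ref, alt)), 1)
        alt_field <- paste(alt, other, sep = ",")
        gt <- "0/2"; ad <- c(ceiling(dp / 2), 0L, floor(dp / 2))
      } else {
        alt_field <- alt
        if (cls[j] == "S_PM") {
          p_reads <- rbinom(1, dp, p_frac[g])
          gt <- "0/1"; ad <- c(dp - p_reads, p_reads)
        } else if (cls[j] == "S_PP") {
          gt <- "1/1"; ad <- c(0L, dp)
        } else {
          gt <- "0/0"; ad <- c(dp, 0L)
        }
      }
      ann <- c(QD = round(runif(1, 5, 30), 2), FS = round(runif(1, 0, 5), 2),
               MQ = 60, DP = max(dp, 30L),
               ReadPosRankSum = round(runif(1, -2, 2), 2))
      gq <- 99L
      if (!is.na(fail[j])) {
        switch(fail[j],
               QD = { ann["QD"] <- 1.0 }, FS = { ann["FS"] <- 25.0 },
               MQ = { ann["MQ"] <- 20.0 }, DP = { ann["DP"] <- 10L },
               ReadPosRankSum = { ann["ReadPosRankSum"] <- -9.5 },
               GQ = { gq <- 5L })
      }
      info <- sprintf("QD=%s;FS=%s;MQ=%s;DP=%d;ReadPosRankSum=%s",
                      ann["QD"], ann["FS"], ann["MQ"], as.integer(ann["DP"]),
                      ann["ReadPosRankSum"])
      n_alleles <- if (auta[j]) 3L else 2L
      fmt_parent <- function(gt_p, allele_idx) {
        ad_p <- integer(n_alleles); ad_p[allele_idx + 1L] <- cfg$depth_mean
        sprintf("%s:%s:%d:99", gt_p, paste(ad_p, collapse = ","), cfg$depth_mean)
      }
      poly <- sprintf("%s:%s:%d:%d", gt, paste(ad, collapse = ","), dp, gq)
      body <- c(body, paste(genes[g], pos[j], ".", ref, alt_field, "100",
                            ".", info, "GT:AD:DP:GQ",
                            fmt_parent("0/0", 0L), fmt_parent("1/1", 1L),
                            poly, sep = "\t"))
      k <- k + 1L
      site_rows[[k]] <- data.frame(gene = genes[g], pos = pos[j],
                                   class = if (auta[j]) "autapomorphic" else cls[j],
                                   failing = fail[j], dp = dp,
                                   stringsAsFactors = FALSE)
      if (!auta[j] && is.na(fail[j])) {
        gene_counts[g, cls[j]] <- gene_counts[g, cls[j]] + 1L
      }
    }
  }
  site_truth <- do.call(rbind, site_rows)
  gene_truth <- data.frame(gene = genes, p_fraction = p_frac,
                           n_spm = gene_counts[, "S_PM"],
                           n_spp = gene_counts[, "S_PP"],
                           n_smm = gene_counts[, "S_MM"],
                           stringsAsFactors = FALSE)
  list(vcf = c(header, body), site_truth = site_truth, gene_truth = gene_truth)
}

#' Simulate synonymous-rate (Ks) values from a Gaussian mixture
#'
#' @param n number of draws.
#' @param components list of numeric triples \code{c(weight, mean, sd)};
#'   weights must sum to 1 (tolerance 1e-9), means positive.
#' @param seed integer seed.
#' @return numeric vector of length \code{n}, truncated to strictly
#'   positive values (negative draws are redrawn).
#' @export
simulate_ks_sample <- function(n, components, seed = 1L) {
  stopifnot(n >= 0)
  w <- vapply(components, `[`, 0, 1)
  mu <- vapply(components, `[`, 0, 2)
  sd_ <- vapply(components, `[`, 0, 3)
  if (abs(sum(w) - 1) > 1e-9) .stopf("mixture weights must sum to 1")
  if (any(mu <= 0)) .stopf("mixture means must be positive")
  set.seed(seed)
  if (n == 0) return(numeric(0))
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  x <- rnorm(n, mu[comp], sd_[comp])
  while (any(x <= 0)) {
    i <- which(x <= 0)
    x[i] <- rnorm(length(i), mu[comp[i]], sd_[comp[i]])
  }
  x
}

#' Simulate bootstrap-annotated gene trees consistent with isoform truth
#'
#' For each assigned isoform in a simulation truth table, emits a newick
#' gene tree that places the isoform inside its true parental clade, with a
#' bootstrap support drawn high (80-100) or, for a configurable fraction,
#' low (below 60) to exercise the screening rule.
#'
#' @param truth truth data frame from [simulate_polyploid_isoforms()]
#'   (recombinants are skipped).
#' @param low_support_fraction fraction of trees given support < 60.
#' @param seed integer seed.
#' @return data frame with \code{isoform_id}, \code{newick}, \code{support},
#'   \code{true_subgenome}.
#' @export
simulate_gene_trees <- function(truth, low_support_fraction = 0.1, seed = 1L) {
  set.seed(seed)
  t2 <- truth[truth$subgenome %in% c("M", "P"), , drop = FALSE]
  n <- nrow(t2)
  low <- runif(n) < low_support_fraction
  support <- ifelse(low, sample(20:59, n, replace = TRUE),
                    sample(80:100, n, replace = TRUE))
  newick <- ifelse(
    t2$subgenome == "M",
    sprintf("((pr,re,%s)%d,(eq,(mi,mo)100)100);", t2$isoform_id, support),
    sprintf("((pr,re)100,(eq,(mi,mo)100,%s)%d);", t2$isoform_id, support))
  data.frame(isoform_id = t2$isoform_id, newick = newick, support = support,
             true_subgenome = t2$subgenome, stringsAsFactors = FALSE)
}

#' Write simulated inputs to disk
#'
#' Writes per-OG alignment FASTAs, the isoform FASTA, the VCF, gene-tree
#' newick file and sidecar truth TSVs under \code{outdir}.
#'
#' @param sim list with components produced by the simulate_* functions
#'   (any of \code{ogs}, \code{iso}, \code{vcf}, \code{trees} may be NULL).
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  wfa <- function(seqs, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0(">", names(seqs), "\n", unlist(seqs)), con)
    path
  }
  if (!is.null(sim$ogs)) {
    ogdir <- file.path(outdir, "ogs")
    dir.create(ogdir, showWarnings = FALSE)
    for (og in sim$ogs) {
      written <- c(written, wfa(og$aln, file.path(ogdir, paste0(og$og_id, ".fasta"))))
    }
  }
  if (!is.null(sim$iso)) {
    written <- c(written, wfa(sim$iso$isoforms, file.path(outdir, "isoforms.fasta")))
    tp <- file.path(outdir, "isoform_truth.tsv")
    write.table(sim$iso$truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, tp)
  }
  if (!is.null(sim$vcf)) {
    vp <- file.path(outdir, "variants.vcf")
    writeLines(sim$vcf$vcf, vp)
    written <- c(written, vp)
  }
  if (!is.null(sim$trees)) {
    np <- file.path(outdir, "gene_trees.nwk")
    writeLines(sim$trees$newick, np)
    written <- c(written, np)
  }
  invisible(written)
}
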