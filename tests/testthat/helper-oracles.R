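# Independent oracles used across the suite. These re-derive expected
# values from first principles (exhaustive enumeration, closed forms,
# binomial bounds) without touching the package's code paths.

ORACLE_BASES <- c("A", "C", "G", "T")
ORACLE_CODE <- as.list(Biostrings::GENETIC_CODE)

oracle_sense_codons <- function() {
  all3 <- apply(expand.grid(ORACLE_BASES, ORACLE_BASES, ORACLE_BASES,
                            stringsAsFactors = FALSE), 1, paste0, collapse = "")
  all3[vapply(all3, function(cd) ORACLE_CODE[[cd]] != "*", TRUE)]
}

# Synonymous site fraction of a codon: enumerate all 9 single-base changes.
oracle_syn_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    for (b in setdiff(ORACLE_BASES, ch[pos])) {
      mut <- ch
      mut[pos] <- b
      if (ORACLE_CODE[[paste0(mut, collapse = "")]] == ORACLE_CODE[[codon]])
        syn <- syn + 1
    }
  }
  syn / 3
}

# Pathway-averaged (Sd, Nd) between two codons: recursively enumerate every
# ordering of the differing positions; each single-base step is synonymous
# iff the amino acid is unchanged.
oracle_pathways <- function(c1, c2) {
  a1 <- strsplit(c1, "")[[1]]
  a2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(a1 != a2)
  if (!length(diff_pos)) return(c(sd = 0, nd = 0))
  walk <- function(cur, remaining) {
    if (!length(remaining)) return(list(c(sd = 0, nd = 0)))
    out <- list()
    for (pos in remaining) {
      nxt <- cur
      nxt[pos] <- a2[pos]
      step_syn <- ORACLE_CODE[[paste0(cur, collapse = "")]] ==
        ORACLE_CODE[[paste0(nxt, collapse = "")]]
      rest <- walk(nxt, setdiff(remaining, pos))
      for (r in rest) {
        out[[length(out) + 1L]] <- r + c(sd = as.numeric(step_syn),
                                         nd = as.numeric(!step_syn))
      }
    }
    out
  }
  paths <- walk(a1, diff_pos)
  Reduce(`+`, paths) / length(paths)
}

# Exact two-sided binomial bound: values of X ~ Bin(n, p) outside the
# central 1 - alpha probability mass fail.
oracle_binom_bounds <- function(n, p, alpha = 0.001) {
  c(lo = qbinom(alpha / 2, n, p), hi = qbinom(1 - alpha / 2, n, p))
}

# The assignment rule restated independently as nested conditionals.
oracle_classify <- function(m, p, min_sites = 4, hi = 0.8, lo = 0.2) {
  tot <- m + p
  if (tot < min_sites) return("unassigned")
  prop <- m / tot
  if (prop > hi && m >= min_sites) return("M")
  if (prop < lo && p >= min_sites) return("P")
  "recombinant"
}

# Unrooted monophyly via an independent route: root the tree at a tip
# outside the set, then ask ape for rooted monophyly.
oracle_monophyletic <- function(tree, taxa_set) {
  if (setequal(taxa_set, tree$tip.label)) return(TRUE)
  out <- setdiff(tree$tip.label, taxa_set)[1]
  rt <- ape::root(tree, outgroup = out, resolve.root = TRUE)
  ape::is.monophyletic(rt, taxa_set)
}

# Small deterministic fixture shared by several files.
small_cfg <- function(seed = 1, n_ogs = 12L, og_length_codons = 150L,
                      branch_sub_prob = 0, isoform_error_rate = 0,
                      recombinant_fraction = 0, ...) {
  sim_config(seed = seed, n_ogs = n_ogs, og_length_codons = og_length_codons,
             branch_sub_prob = branch_sub_prob,
             isoform_error_rate = isoform_error_rate,
             recombinant_fraction = recombinant_fraction, ...)
}

phase_sim <- function(cfg) {
  ogs <- simulate_progenitor_ogs(cfg)
  iso <- simulate_polyploid_isoforms(ogs, cfg)
  asg <- phase_isoforms(iso$isoforms, ogs,
                        samples = setNames(iso$truth$sample,
                                           iso$truth$isoform_id))
  list(ogs = ogs, iso = iso, assignments = asg)
}

# One-row variant-site table with overridable fields (all filters passing
# by default), used by the SNP-expression tests.
site_row <- function(qd = 20, fs = 1, mq = 60, dp = 100, rprs = 0, gq = 99,
                     gt_m = "0/0", gt_p = "1/1", gt_poly = "0/1",
                     ad = "50,50", gene = "g1", pos = 1L) {
  data.frame(gene = gene, pos = pos, ref = "A", alt = "G", qd = qd, fs = fs,
             mq = mq, dp = dp, read_pos_rank_sum = rprs, gq = gq,
             gt_m = gt_m, gt_p = gt_p, gt_poly = gt_poly, ad_poly = ad,
             stringsAsFactors = FALSE)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(ORACLE_BASES, n, replace = TRUE), collapse = "")
}
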