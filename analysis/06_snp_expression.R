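# SNP-based homeolog expression: hard-filter the simulated VCF, classify
# sites (S_PM / S_PP / S_MM) and genes (G_PM / G_PP / G_MM), estimate each
# G_PM gene's paternal expression fraction from allele depths and call
# dominance.

source("analysis/_common.R")

vcf <- simulate_allele_depth_vcf(study_cfg)
vcf_path <- file.path(RESULTS_DIR, "simdata", "variants.vcf")
dir.create(dirname(vcf_path), recursive = TRUE, showWarnings = FALSE)
writeLines(vcf$vcf, vcf_path)

res <- snp_expression_analysis(read_vcf_sites(vcf_path))
write_result(res$genes, "gene_classes.tsv")

sc <- res$summary$site_counts
message(sprintf("sites: %d S_PM (%.1f%% of informative), %d S_PP, %d S_MM, %d autapomorphic excluded",
                sc[["S_PM"]], 100 * res$summary$spm_share, sc[["S_PP"]],
                sc[["S_MM"]], sc[["autapomorphic"]]))
gc <- res$summary$gene_counts
message(sprintf("genes: %d G_PM, %d G_PP, %d G_MM, %d unclassified",
                gc[["G_PM"]], gc[["G_PP"]], gc[["G_MM"]],
                gc[["unclassified"]]))
dom <- res$summary$dominance_counts
message(sprintf("dominance among G_PM: %d M-dominant, %d conserved, %d P-dominant",
                dom[["M_dominant"]], dom[["conserved"]], dom[["P_dominant"]]))
write_result(data.frame(class = names(dom), genes = as.integer(dom)),
             "dominance.tsv")
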