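# Phylogenetic cross-check of the SNP-based phasing: screen bootstrap-
# annotated gene trees (clades with support < 60 excluded) and compare the
# tree-based subgenome calls with the diagnostic-SNP calls.

source("analysis/_common.R")

sim <- simulated_inputs()
assignments <- phased_assignments(sim)
trees <- simulate_gene_trees(sim$iso$truth, low_support_fraction = 0.1,
                             seed = study_cfg$seed + 3000L)

screened <- screen_gene_trees(trees$newick, trees$isoform_id)
write_result(screened, "tree_calls.tsv")

snp_calls <- setNames(assignments$call, assignments$isoform_id)
usable <- screened$call %in% c("M", "P")
agree <- screened$call[usable] == snp_calls[screened$transcript[usable]]
message(sprintf("%d/%d trees pass the bootstrap screen; tree and SNP calls agree for %.1f%%",
                sum(usable), nrow(screened), 100 * mean(agree)))
print(table(tree = screened$call, snp = snp_calls[screened$transcript]))
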