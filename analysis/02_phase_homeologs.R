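# Phase polyploid isoforms into parental subgenomes by diagnostic SNPs and
# tabulate homeolog expression classes per sample, with pairwise sample
# correlations of the expression patterns.

source("analysis/_common.R")

sim <- simulated_inputs()
assignments <- phased_assignments(sim)
write_result(assignments, "assignments.tsv")

table2 <- tabulate_homeologs(assignments)
write_result(table2, "homeolog_table.tsv")
print(table2)

truth <- sim$iso$truth
merged <- merge(assignments, truth, by = "isoform_id")
message(sprintf("phasing accuracy vs simulation truth: %.1f%% of %d isoforms",
                100 * mean(merged$call == merged$subgenome), nrow(merged)))

r <- pairwise_sample_correlation(attr(table2, "og_classes"))
write_result(as.data.frame(r), "sample_correlations.tsv")
message("pairwise Pearson correlation of expression patterns:")
print(round(r, 3))
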