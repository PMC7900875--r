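# Generate the synthetic allopolyploid transcriptome used by every later
# stage and persist it for inspection: per-orthogroup progenitor
# alignments, polyploid isoforms with sidecar truth, an allele-depth VCF,
# and bootstrap-annotated gene trees.

source("analysis/_common.R")

sim <- simulated_inputs()
vcf <- simulate_allele_depth_vcf(study_cfg)
trees <- simulate_gene_trees(sim$iso$truth, seed = study_cfg$seed + 3000L)

write_simulation(list(ogs = sim$ogs, iso = sim$iso, vcf = vcf, trees = trees),
                 file.path(RESULTS_DIR, "simdata"))

truth <- sim$iso$truth
message(sprintf("simulated %d orthogroups, %d isoforms (%d M, %d P, %d chimeric), %d VCF sites",
                length(sim$ogs), nrow(truth), sum(truth$subgenome == "M"),
                sum(truth$subgenome == "P"),
                sum(truth$subgenome == "recombinant"),
                nrow(vcf$site_truth)))
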