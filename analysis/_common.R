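# Shared setup for the analysis drivers: one synthetic study configuration
# used by every stage, so the scripts can be run independently yet operate
# on the same deterministic dataset.

suppressMessages(library(homeologr))

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

# Study conditions: 60 orthogroups of 200 codons at 2% fixed inter-group
# divergence, two polyploid samples, ~6 isoforms per expressed orthogroup,
# 0.2% isoform error, 2% chimeras; allele-depth tables at depth 100 with
# the symmetric conserved/dominant expression law.
study_cfg <- sim_config(
  seed = 42L,
  n_ogs = 60L,
  og_length_codons = 200L,
  branch_sub_prob = 0.003,
  intergroup_divergence = 0.02,
  isoform_error_rate = 0.002,
  recombinant_fraction = 0.02,
  n_isoforms_mean = 6,
  samples = c("S1", "S2"),
  depth_mean = 100,
  fraction_failing_filters = 0.1,
  autapomorphic_fraction = 0.02)

simulated_inputs <- function(cfg = study_cfg) {
  ogs <- simulate_progenitor_ogs(cfg)
  iso <- simulate_polyploid_isoforms(ogs, cfg)
  list(ogs = ogs, iso = iso)
}

phased_assignments <- function(sim) {
  phase_isoforms(sim$iso$isoforms, sim$ogs,
                 samples = setNames(sim$iso$truth$sample,
                                    sim$iso$truth$isoform_id))
}

write_result <- function(d, name) {
  path <- file.path(RESULTS_DIR, name)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
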