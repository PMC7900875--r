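# Flow-cytometry arithmetic: infer ploidy from holoploid 1C values against
# the diploid calibrator (E. equisetina, 2C = 16.61 pg), derive monoploid
# 1Cx sizes, and test whether each tetraploid's genome is additive
# (1C ~ sum of its two progenitors').

source("analysis/_common.R")

cyto <- data.frame(
  species = c("E. minuta", "E. equisetina", "E. monosperma", "E. regeliana",
              "E. przewalskii", "E. sinica", "E. intermedia"),
  holoploid_1c_pg = c(8.19, 8.30, 8.54, 7.43, 7.65, 15.42, 16.06),
  sd = c(0.02, 0.01, 0.01, 0.03, 0.01, 0.03, 0.04),
  cv_percent = c(3.15, 2.63, 1.85, 2.01, 3.53, 2.46, 1.98))

out <- cytometry_table(cyto, diploid_reference_1c_pg = 16.61 / 2)
write_result(out, "cytometry.tsv")
print(out)

for (sp in c("E. sinica", "E. intermedia")) {
  ad <- additivity_check(out$holoploid_1c_pg[out$species == sp],
                         maternal_1c_pg = 7.43, paternal_1c_pg = 8.30)
  message(sprintf("%s: 1C %.2f pg vs parental sum %.2f pg (%.1f%% deviation) -> %s",
                  sp, ad$observed_pg, ad$expected_pg,
                  100 * ad$relative_deviation,
                  if (ad$additive) "additive" else "non-additive"))
}
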