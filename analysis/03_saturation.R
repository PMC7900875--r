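# Rarefaction of the isoform pool: how many orthogroups (and orthogroups
# with both homeologs, H_MP) are discovered at increasing sequencing
# depth, with a degree-2 log-log polynomial fit and its saturation value.

source("analysis/_common.R")

sim <- simulated_inputs()
assignments <- phased_assignments(sim)
pool <- assignments$isoform_id

sizes <- unique(pmax(2, round(seq(0.1, 1, by = 0.15) * length(pool))))
design <- saturation_design(sizes = sizes, replicates = 3, seed = 42)
points <- subsample_counts(pool, design, make_assignment_counter(assignments))
write_result(points, "saturation_points.tsv")

for (resp in c("y1", "y2")) {
  fit <- fit_loglog_quadratic(points, resp)
  label <- if (resp == "y1") "expressed OGs" else "H_MP OGs"
  if (!is.na(fit$saturation_value)) {
    message(sprintf(
      "%s: log(y) = %.4f (log x)^2 + %.4f log x + %.4f; saturation ~= %.0f at x ~= %.0f",
      label, fit$a, fit$b, fit$c, fit$saturation_value,
      exp(fit$vertex_log_x)))
  } else {
    message(sprintf("%s: fitted curvature non-negative (a = %.4f); no maximum in range",
                    label, fit$a))
  }
  write_result(data.frame(target = label, a = fit$a, b = fit$b, c = fit$c,
                          vertex_log_x = fit$vertex_log_x,
                          saturation_value = fit$saturation_value),
               paste0("saturation_fit_", resp, ".tsv"))
}
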