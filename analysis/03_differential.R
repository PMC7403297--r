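#!/usr/bin/env Rscript
# Differential protein analysis: per-protein linear models of normalized NPX
# on case/control status adjusted for age and race, for the three contrasts
# (comorbid PTSD-MCI, PTSD-only, MCI-only, each vs controls), with
# within-panel Benjamini-Hochberg FDR, overlap sets and cross-contrast
# coefficient correlations.

suppressPackageStartupMessages(library(npxburden))

d <- read_dataset("results/normalized")
contrasts <- default_contrasts()
diffs <- lapply(contrasts, function(ct)
  run_contrast(d$expr, d$meta, ct, alpha_p = 0.05, alpha_fdr = 0.1))

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
for (nm in names(diffs)) {
  print(diffs[[nm]])
  write.csv(diffs[[nm]]$table,
            sprintf("results/tables/diff_%s.csv", nm), row.names = FALSE)
}

ov <- overlap_sets(lapply(diffs, `[[`, "sig_p"))
cat(sprintf("Union of P<0.05 proteins across contrasts: %d\n",
            length(ov$union)))
print(ov$regions)

betas <- as.data.frame(lapply(diffs, function(x) x$table$beta))
rownames(betas) <- diffs[[1]]$table$protein
sc <- sign_consistency(betas, ov$union)
cat(sprintf("Sign-consistent across all three contrasts: %d/%d union proteins\n",
            sc$n_consistent, sc$n_total))
bc <- beta_correlation(betas)
print(bc)

jsonlite::write_json(
  list(regions = as.list(ov$regions), union = ov$union,
       n_sign_consistent = sc$n_consistent, beta_correlations = bc),
  "results/tables/overlap_summary.json", auto_unbox = TRUE, digits = NA)
cat("Differential tables and overlap summary written to results/tables\n")
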