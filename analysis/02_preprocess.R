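#!/usr/bin/env Rscript
# Per-view preprocessing: RNA counts go through the low-expression filter
# (>= 5 cpm in >= 10% of samples), TMM scale factors, log2 normalized cpm
# and the top-variance gene cap; plasma abundances go through
# probabilistic quotient normalization and a log transform.
library(momfa)

cfg <- read_config("analysis/config.yaml")
out <- "results/preprocessed"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

views <- list(
  muscle_rna = read_view("results/sim/muscle_rna.tsv", "muscle_rna", "counts"),
  blood_rna = read_view("results/sim/blood_rna.tsv", "blood_rna", "counts"),
  lipids = read_view("results/sim/lipids.tsv", "lipids", "abundance"),
  metabolites = read_view("results/sim/metabolites.tsv", "metabolites",
                          "abundance"))

proc <- preprocess_views(views, cfg)
report_rows <- list()
for (vn in names(proc$views)) {
  write_view(proc$views[[vn]], file.path(out, paste0(vn, ".tsv")))
  r <- proc$reports[[vn]]
  report_rows[[vn]] <- data.frame(view = vn, n_in = r$n_features_in,
                                  n_out = r$n_features_out,
                                  steps = paste(r$transform_log, collapse = " -> "))
  cat(sprintf("%-12s %4d -> %4d features [%s]\n", vn, r$n_features_in,
              r$n_features_out, paste(r$transform_log, collapse = ", ")))
}
write.table(do.call(rbind, report_rows), file.path(out, "report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
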