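#!/usr/bin/env Rscript
# Train the model ensemble: for each variance-pruning threshold on the
# grid, several fits from distinct random seeds; record the converged
# factor count and final ELBO of every fit.
library(momfa)

cfg <- read_config("analysis/config.yaml")
ps <- read_profile_set("results/profiles")

ens <- run_ensemble(ps, cfg, base_seed = 0, verbose = TRUE)
write.table(ens$records, "results/ensemble_records.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# persist the per-K ELBO winners for the selection step
best <- select_best_per_k(ens)
for (k in names(best))
  write_fit(best[[k]], file.path("results", "fits", paste0("K", k)))
cat(sprintf("%d fits; factor counts observed: %s\n", nrow(ens$records),
            paste(sort(unique(ens$records$k_active)), collapse = ", ")))
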