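#!/usr/bin/env Rscript
# Model selection: compare the best fit per factor count by total and
# per-view variance explained, and choose K where the overall curve
# levels off (elbow rule; override with k_override in this script to
# reproduce a visual choice).
library(momfa)

cfg <- read_config("analysis/config.yaml")
ps <- read_profile_set("results/profiles")
fit_dirs <- list.dirs("results/fits", recursive = FALSE)
best <- lapply(fit_dirs, read_fit)
names(best) <- vapply(best, function(f) as.character(f$k_active), "")
best <- best[order(as.integer(names(best)))]

curve <- selection_curve(best, ps)
write.table(curve, "results/curve.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sel <- select_model(curve, elbow_delta = cfg$elbow_delta)
cat("selected K =", sel$k, "|", sel$rationale, "\n")
write_fit(sel$fit, "results/chosen_fit")
ve <- variance_explained(sel$fit, ps)
print(ve)
tab <- data.frame(view = rownames(ve$per_factor),
                  round(100 * cbind(ve$per_factor, total = ve$per_view_total), 1))
write.table(tab, "results/variance_explained.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
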