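#!/usr/bin/env Rscript
# Match the four normalized views into multiomic profiles keyed by
# (mouse, group, week), average any duplicate samples per key, report the
# per-view missingness, and center/scale every feature for factor fitting.
library(momfa)

meta <- read_metadata("results/sim/metadata.tsv")
views <- lapply(c("muscle_rna", "blood_rna", "lipids", "metabolites"),
                function(vn) read_view(file.path("results/preprocessed",
                                                 paste0(vn, ".tsv")),
                                       vn, "normalized"))

ps <- match_profiles(views, meta)
print(ps)
print(missingness_report(ps))

ps_scaled <- scale_profile_set(ps)
write_profile_set(ps_scaled, "results/profiles")
write.table(missingness_report(ps), "results/profiles/missingness.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
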