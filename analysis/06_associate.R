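#!/usr/bin/env Rscript
# Relate the selected model's latent factors to genotype group and week:
# per-factor R2 and F tests with BH adjustment, pairwise contrasts for the
# significant factors, top loadings per view, and the muscle-vs-blood
# loading comparison for the leading factor.
library(momfa)

ps <- read_profile_set("results/profiles")
fit <- read_fit("results/chosen_fit")

assoc <- lf_anova(fit$Z, ps$profile_index)
print(assoc, digits = 3)
write.table(assoc, "results/association.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sig <- which(assoc$q_group < 0.05 | assoc$q_week < 0.05)
if (length(sig)) {
  pw <- pairwise_contrasts(fit$Z, ps$profile_index, factors = sig)
  write.table(pw, "results/pairwise.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
  cat(sprintf("pairwise contrasts for %d significant factor(s) written\n",
              length(sig)))
}

for (vn in fit$view_names)
  write.table(top_loadings(fit, vn, 1, k = 10),
              file.path("results", paste0("top_loadings_", vn, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

cmp <- cross_view_loading_comparison(fit, "muscle_rna", "blood_rna", 1)
cat(sprintf("muscle vs blood loading correlation (factor 1): %.3f; %d/%d sign-consistent\n",
            cmp$correlation, sum(cmp$table$consistent), nrow(cmp$table)))
write.table(cmp$table, "results/cross_view_muscle_blood.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
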