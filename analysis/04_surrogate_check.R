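#!/usr/bin/env Rscript
# Stage 4: IAAFT surrogate control on a few subjects -- if the entropy
# signal reflected only the (linear) power spectrum, phase-shuffled
# surrogates would show the same entropy; structured EEG-like signals
# should instead show higher surrogate entropy at fine scales.

source("analysis/00_config.R")

coh <- make_cohort()
ess <- preprocess_cohort(coh)

subset <- ess[c(1, 2, 13, 14)]  # two subjects per group
tabs <- lapply(subset, function(es)
  surrogate_entropy_test(es, mse_params(scales = c(1, 2, 5, 10, 20)),
                         n_surrogates = 19, seed = MASTER_SEED))
tab <- do.call(rbind, tabs)
write.table(tab, file.path(RESULTS_DIR, "surrogates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

agg <- aggregate(cbind(mean_diff, frac_exceed) ~ scale, tab, mean)
cat("Surrogate minus original entropy by scale (mean over channels):\n")
print(round(agg, 3))
cat("Positive differences indicate temporal structure destroyed by\n")
cat("phase shuffling; the colored-noise background is linear, so\n")
cat("differences here stay modest by construction.\n")
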