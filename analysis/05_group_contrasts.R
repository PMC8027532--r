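#!/usr/bin/env Rscript
# Stage 5: mass-univariate age-group contrasts over channel x scale
# (entropy) and channel x frequency (spectral power) grids, enhanced by
# TFCE and tested against 1000 between-subject permutations; summarised
# as per-region proportions of significant cells.

source("analysis/00_config.R")

coh <- make_cohort()
ess <- preprocess_cohort(coh)
mse_maps <- lapply(ess, subject_mse, params = MSE_PARAMS)
psd_maps <- lapply(ess, function(es)
  subject_spectra(es, WELCH$win_len, WELCH$overlap_frac, WELCH$fmin,
                  WELCH$fmax)$psd)

g <- vapply(mse_maps, function(m) m$group, character(1))
young <- g == "age9"

run_contrast <- function(maps, label, sign) {
  res <- permutation_test(maps[young], maps[!young],
                          coh$montage$adjacency,
                          E = TFCE$E, H = TFCE$H, n_perm = TFCE$n_perm,
                          alpha = TFCE$alpha, seed = MASTER_SEED)
  prop <- proportion_significant(res, TFCE$alpha, coh$montage, sign)
  prop$measure <- label
  cat(sprintf("%s contrast: %d significant cell(s) of %d\n", label,
              sum(res$p < TFCE$alpha & (if (sign == "positive")
                res$observed$t > 0 else res$observed$t < 0),
                na.rm = TRUE),
              length(res$p)))
  list(res = res, prop = prop)
}

mse_c <- run_contrast(mse_maps, "mse_increase", "positive")
psd_c <- run_contrast(psd_maps, "psd_decrease", "negative")
psd_i <- run_contrast(psd_maps, "psd_increase", "positive")

cells <- data.frame(channel = rep(rownames(mse_c$res$p),
                                  ncol(mse_c$res$p)),
                    bin = rep(colnames(mse_c$res$p),
                              each = nrow(mse_c$res$p)),
                    t = as.vector(mse_c$res$observed$t),
                    enhanced = as.vector(mse_c$res$enhanced),
                    p = as.vector(mse_c$res$p))
write.table(cells, file.path(RESULTS_DIR, "tfce_mse_cells.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(rbind(mse_c$prop, psd_c$prop, psd_i$prop),
            file.path(RESULTS_DIR, "proportions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Proportion of significant cells by region:\n")
print(rbind(mse_c$prop, psd_c$prop, psd_i$prop), row.names = FALSE)
cat("\nNote: signals are variance-normalized per channel, so the older\n")
cat("group's flatter exponent shifts power INTO the 1-30 Hz band --\n")
cat("band-limited power increases rather than decreases here. The\n")
cat("negative-sign summary is reported for use on un-normalized data.\n")
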