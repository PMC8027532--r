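#!/usr/bin/env Rscript
# Stage 2: low-pass filter at 30 Hz, cut 20-s epochs, apply the ±150 µV
# and 5-SD joint-probability rejection rules, and tabulate epoch QC.

source("analysis/00_config.R")

coh <- make_cohort()
ess <- preprocess_cohort(coh)
qc <- do.call(rbind, lapply(ess, qc_table))
write.table(qc, file.path(RESULTS_DIR, "qc.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

n_ep <- nrow(qc)
cat(sprintf("QC: %d/%d epochs retained (%.1f%%); rejection reasons: %s\n",
            sum(qc$retained), n_ep, 100 * mean(qc$retained),
            if (any(!qc$retained))
              paste(names(table(qc$reason[!qc$retained])), collapse = ", ")
            else "none"))
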