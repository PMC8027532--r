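#' Construct a recording
#'
#' One subject/condition's continuous multi-channel signal in microvolts,
#' ordered as in the montage.
#'
#' @param data numeric channel x sample matrix (µV).
#' @param fs sampling rate in Hz.
#' @param montage an `eeg_montage`; row count of `data` must match.
#' @param subject_id subject identifier.
#' @param condition `"eyes_open"` or `"eyes_closed"`.
#' @param group group (e.g. age-group) label.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, fs, montage, subject_id = "S01",
                      condition = c("eyes_closed", "eyes_open"),
                      group = NA_character_) {
  condition <- match.arg(condition)
  data <- as.matrix(data)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive sampling rate")
  if (nrow(data) != length(montage$labels))
    stop(sprintf("channel-count mismatch: data has %d rows, montage %d channels",
                 nrow(data), length(montage$labels)))
  if (!all(is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite sample at channel %s, sample %d",
                 montage$labels[bad[1]], bad[2]))
  }
  rownames(data) <- montage$labels
  structure(list(subject_id = subject_id, condition = condition,
                 group = group, fs = fs, data = data, montage = montage),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s, %s] %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$group, x$condition,
              nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Read a recording from a delimited matrix file
#'
#' The on-disk dialect is a tab-delimited UTF-8 table with one row per
#' channel: first column `label`, remaining columns the samples in µV.
#' A JSON sidecar `<path>.json` written by [write_recording()] carries
#' `fs`, `subject_id`, `condition` and `group`; absent a sidecar, `fs`
#' must be supplied.
#'
#' @param path file path.
#' @param montage an `eeg_montage`; channel count and order must match.
#' @param condition recording condition; overrides the sidecar if given.
#' @param fs sampling rate in Hz if no sidecar is present.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, montage, condition = NULL, fs = NULL) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (names(tab)[1] != "label")
    stop("recording file must have a leading 'label' column")
  if (nrow(tab) != length(montage$labels))
    stop(sprintf("channel-count mismatch: file has %d channels, montage %d",
                 nrow(tab), length(montage$labels)))
  dat <- as.matrix(tab[, -1, drop = FALSE])
  if (!all(tab$label == montage$labels)) {
    idx <- match(montage$labels, tab$label)
    if (anyNA(idx))
      stop("channel label(s) in montage not found in file: ",
           paste(montage$labels[is.na(idx)], collapse = ", "))
    dat <- dat[idx, , drop = FALSE]
  }
  meta <- list(subject_id = basename(path), condition = "eyes_closed",
               group = NA_character_)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta2 <- jsonlite::read_json(side, simplifyVector = TRUE)
    meta[names(meta2)] <- meta2
    if (is.null(fs)) fs <- meta2$fs
  }
  if (!is.null(condition)) meta$condition <- condition
  if (is.null(fs)) stop("fs not supplied and no sidecar found for ", path)
  fs <- as.numeric(fs)
  storage.mode(dat) <- "double"
  dimnames(dat) <- NULL
  if (!all(is.finite(dat))) {
    bad <- which(!is.finite(dat), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value in %s at channel %s, sample %d",
                 path, montage$labels[bad[1]], bad[2]))
  }
  recording(dat, fs, montage, subject_id = meta$subject_id,
            condition = meta$condition, group = meta$group)
}

#' Write a recording (delimited matrix + JSON sidecar)
#'
#' @param rec an `eeg_recording`.
#' @param path output path; a `<path>.json` sidecar records `fs`,
#'   `subject_id`, `condition` and `group`.
#' @param digits significant digits kept on disk (default 10).
#' @export
write_recording <- function(rec, path, digits = 10) {
  tab <- data.frame(label = rownames(rec$data),
                    signif(rec$data, digits), check.names = FALSE)
  names(tab) <- c("label", sprintf("s%d", seq_len(ncol(rec$data))))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, subject_id = rec$subject_id,
                            condition = rec$condition, group = rec$group),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Tidy long-format table from per-subject maps
#'
#' Flattens a list of `mse_map` (channel x scale) or `psd_map`
#' (channel x frequency) objects into one row per
#' subject x channel x bin cell.
#'
#' @param maps list of maps as returned by [subject_mse()] or
#'   [subject_spectra()].
#' @return A `data.frame` with columns `subject_id`, `group`, `channel`,
#'   the bin column (`scale` or `freq_hz`), and `value`.
#' @export
results_table <- function(maps) {
  stopifnot(length(maps) >= 1)
  do.call(rbind, lapply(maps, function(m) {
    v <- m$values
    bins <- if (!is.null(m$scales)) m$scales else m$freqs
    bin_name <- if (!is.null(m$scales)) "scale" else "freq_hz"
    df <- data.frame(subject_id = m$subject_id, group = m$group,
                     channel = rep(rownames(v), times = ncol(v)),
                     bin = rep(bins, each = nrow(v)),
                     value = as.vector(v))
    names(df)[4] <- bin_name
    df
  }))
}

#' Write results tables and a JSON run summary
#'
#' Writes a tidy delimited table (re-readable losslessly at the stored
#' precision) and, optionally, a JSON summary of the parameters and seeds
#' that produced it.
#'
#' @param tab a data.frame (e.g. from [results_table()]).
#' @param path output path for the tab-delimited table.
#' @param summary optional named list of parameters/seeds/versions written
#'   to `<path>.json`.
#' @export
write_results <- function(tab, path, summary = NULL) {
  num <- vapply(tab, is.numeric, logical(1))
  if (!all(vapply(tab[num], function(col) all(is.finite(col) | is.na(col)),
                  logical(1))))
    stop("results contain non-finite values")
  tab[num] <- lapply(tab[num], function(col) signif(col, 12))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary)) {
    summary$package_version <- as.character(utils::packageVersion("eegcomplexity"))
    jsonlite::write_json(summary, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
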