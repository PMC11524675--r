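## File dialects for recordings, feature tables and run configuration.
## Recordings: EDF (16-bit, written/read here) or a plain numeric
## channels x samples TSV with a channel-label sidecar. Feature tables: TSV.
## Montage and RunConfig: JSON.

.pad_field <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1, width)
  formatC(x, width = -width)  # left-justified, space padded
}

.edf_num <- function(x) as.numeric(trimws(x))

#' Write a recording to an EDF file
#'
#' Signals are scaled to 16-bit integers using integer physical limits just
#' outside the per-channel data range, so a write/read round-trip is exact to
#' within one quantization step `(physmax - physmin)/(2^16 - 1)`. The subject
#' id and group label are stored in the EDF patient and recording-id header
#' fields.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  sig <- rec$signal
  n_ch <- nrow(sig)
  n_samp <- ncol(sig)
  if (n_samp %% rec$fs == 0 && rec$fs == round(rec$fs)) {
    n_rec <- n_samp / rec$fs
    spr <- as.integer(rec$fs)
    rec_dur <- 1
  } else {
    n_rec <- 1L
    spr <- n_samp
    rec_dur <- n_samp / rec$fs
  }
  pmin <- floor(apply(sig, 1, min))
  pmax <- ceiling(apply(sig, 1, max))
  flat <- pmax <= pmin
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .pad_field("0", 8),
    .pad_field(rec$subject_id, 80),
    .pad_field(paste0("group=", rec$group), 80),
    .pad_field("01.01.00", 8),
    .pad_field("00.00.00", 8),
    .pad_field(256 * (n_ch + 1), 8),
    .pad_field("", 44),
    .pad_field(n_rec, 8),
    .pad_field(format(rec_dur, digits = 7), 8),
    .pad_field(n_ch, 4)
  )
  sig_hdr <- paste0(
    paste(.pad_field(rec$channel_labels, 16), collapse = ""),
    paste(rep(.pad_field("", 80), n_ch), collapse = ""),
    paste(rep(.pad_field("uV", 8), n_ch), collapse = ""),
    paste(.pad_field(pmin, 8), collapse = ""),
    paste(.pad_field(pmax, 8), collapse = ""),
    paste(rep(.pad_field(dmin, 8), n_ch), collapse = ""),
    paste(rep(.pad_field(dmax, 8), n_ch), collapse = ""),
    paste(rep(.pad_field("", 80), n_ch), collapse = ""),
    paste(rep(.pad_field(spr, 8), n_ch), collapse = ""),
    paste(rep(.pad_field("", 32), n_ch), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)

  scale <- (dmax - dmin) / (pmax - pmin)
  dig <- round((sig - pmin) * scale + dmin)
  dig[dig < dmin] <- dmin
  dig[dig > dmax] <- dmax
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(n_ch)) {
      writeBin(as.integer(dig[ch, idx]), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file as a recording
#'
#' Supports the plain (continuous) EDF layout written by [write_edf()] and by
#' most acquisition software: identical sampling rate across signals is
#' required.
#'
#' @param path EDF file path.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) readChar(con, w, useBytes = TRUE)
  rd(8)                                   # version
  subject_id <- trimws(rd(80))
  rec_field <- trimws(rd(80))
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(.edf_num(rd(8)))
  rec_dur <- .edf_num(rd(8))
  n_ch <- as.integer(.edf_num(rd(4)))

  labels <- trimws(vapply(seq_len(n_ch), function(i) rd(16), ""))
  for (i in seq_len(n_ch)) rd(80)         # transducer
  for (i in seq_len(n_ch)) rd(8)          # physical dimension
  pmin <- vapply(seq_len(n_ch), function(i) .edf_num(rd(8)), 0)
  pmax <- vapply(seq_len(n_ch), function(i) .edf_num(rd(8)), 0)
  dmin <- vapply(seq_len(n_ch), function(i) .edf_num(rd(8)), 0)
  dmax <- vapply(seq_len(n_ch), function(i) .edf_num(rd(8)), 0)
  for (i in seq_len(n_ch)) rd(80)         # prefiltering
  spr <- vapply(seq_len(n_ch), function(i) as.integer(.edf_num(rd(8))), 1L)
  for (i in seq_len(n_ch)) rd(32)

  if (length(unique(spr)) != 1) {
    stop("non-uniform sampling rate across EDF signals: ",
         paste(unique(spr), collapse = ", "), " samples per record")
  }
  fs <- spr[1] / rec_dur
  sig <- matrix(0, n_ch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(n_ch)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2,
                     endian = "little", signed = TRUE)
      phys <- (dig - dmin[ch]) * (pmax[ch] - pmin[ch]) / (dmax[ch] - dmin[ch]) + pmin[ch]
      sig[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- phys
    }
  }
  group <- sub("^group=", "", rec_field)
  if (!group %in% c("MDD", "HC")) group <- "unknown"
  recording(sig, fs = fs, channel_labels = labels, group = group,
            subject_id = if (nzchar(subject_id)) subject_id else "s01")
}

#' Read a recording from disk
#'
#' Dispatches on the file extension: `.edf` files are parsed as EDF; anything
#' else is read as a plain numeric channels x samples TSV matrix with a
#' required label sidecar (`labels_path`, a TSV with a `label` column and
#' optionally `fs`, `group` and `subject_id` columns on its first row).
#'
#' @param path Recording file.
#' @param labels_path Label sidecar (matrix format only).
#' @param fs Sampling rate in Hz; overrides any sidecar value (matrix format).
#' @param montage Optional `eeg_montage`; if supplied, all montage labels must
#'   be present in the file or an error lists the missing ones.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, labels_path = NULL, fs = NULL, montage = NULL) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    rec <- read_edf(path)
  } else {
    if (is.null(labels_path)) {
      stop("matrix-format recordings need a label sidecar (labels_path)")
    }
    meta <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
    if (!"label" %in% names(meta)) stop("label sidecar must have a 'label' column")
    if (anyDuplicated(meta$label)) {
      stop("duplicate channel labels in sidecar: ",
           paste(unique(meta$label[duplicated(meta$label)]), collapse = ", "))
    }
    sig <- as.matrix(utils::read.table(path, sep = "\t"))
    if (nrow(sig) != nrow(meta)) {
      stop("matrix has ", nrow(sig), " rows but sidecar lists ",
           nrow(meta), " labels")
    }
    use_fs <- fs %||% meta$fs[1]
    if (is.null(use_fs) || is.na(use_fs)) stop("sampling rate unknown: pass fs or add an fs column to the sidecar")
    grp <- if ("group" %in% names(meta)) meta$group[1] else "unknown"
    sid <- if ("subject_id" %in% names(meta)) meta$subject_id[1] else "s01"
    rec <- recording(sig, fs = use_fs, channel_labels = meta$label,
                     group = grp, subject_id = sid)
  }
  if (!is.null(montage)) {
    missing <- setdiff(montage_labels(montage), rec$channel_labels)
    if (length(missing)) {
      stop("recording is missing montage channels: ",
           paste(missing, collapse = ", "))
    }
  }
  rec
}

#' Write a recording as a matrix + label sidecar
#'
#' @param rec An `eeg_recording`.
#' @param path Matrix TSV path.
#' @param labels_path Sidecar TSV path.
#' @return `path`, invisibly.
#' @export
write_recording_matrix <- function(rec, path, labels_path) {
  utils::write.table(rec$signal, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- data.frame(label = rec$channel_labels,
                     fs = rec$fs, group = rec$group,
                     subject_id = rec$subject_id)
  utils::write.table(meta, labels_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write and read feature tables
#'
#' Tab-delimited with a header; the first three columns are always
#' `subject_id`, `window_index`, `group`, followed by one column per named
#' feature. Finite values round-trip losslessly (values are printed at full
#' double precision).
#'
#' @param tab A `feature_table` (see [feature_table()]).
#' @param path File path.
#' @return `read_feature_table()` returns a `feature_table`;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
write_feature_table <- function(tab, path) {
  stopifnot(inherits(tab, "feature_table"))
  fmat <- feature_matrix(tab)
  if (ncol(fmat) && nrow(fmat)) {
    bad <- colnames(fmat)[!apply(is.finite(fmat), 2, all)]
    if (length(bad)) {
      stop("refusing to write non-finite feature values in: ",
           paste(bad, collapse = ", "))
    }
  }
  df <- as.data.frame(tab)
  num <- vapply(df, is.numeric, TRUE) & names(df) != "window_index"
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  key <- c("subject_id", "window_index", "group")
  if (length(names(df)) < 3 || !identical(names(df)[1:3], key)) {
    stop("malformed feature table header: first columns must be ",
         paste(key, collapse = ", "))
  }
  feature_table(df)
}

.default_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(12, 30), gamma = c(30, 50))
}

#' Analysis run configuration
#'
#' Collects every tunable of the pipeline in one validated list, so a saved
#' configuration plus the input data reproduces a run exactly.
#'
#' @param band_edges Named list of `c(low, high)` Hz pairs; must be ordered,
#'   non-overlapping and jointly cover 0.5--50 Hz.
#' @param window_length Analysis window length in seconds (default 2).
#' @param coherence_threshold Binarization threshold for the network module,
#'   in (0,1) (default 0.6).
#' @param sampen_m,sampen_r Sample-entropy embedding dimension and tolerance
#'   factor (x series SD); defaults 2 and 0.2.
#' @param mse_scales Maximum coarse-graining factor for multiscale entropy
#'   (default 10).
#' @param dfa_window_lengths Increasing window lengths (samples) for DFA.
#' @param selection_alpha Significance level of the t-test route (default 0.05).
#' @param train_fraction Training fraction of the subject split (default 0.8).
#' @param svm_grid An [svm_grid()] describing the (cost, gamma) search space.
#' @param n_repeats Number of repeated train/test evaluations (default 100).
#' @param n_permutations Number of label permutations (default 100).
#' @param ica_components Number of ICA components (default 40, capped at the
#'   channel count at run time).
#' @param coherence_unit `"recording"` (default) or `"window"`: whether
#'   coherence is estimated once per cleaned recording or per 2-s window.
#' @param split_unit `"subject"` (default, leakage-free) or `"window"`.
#' @param seed Integer seed governing every stochastic step.
#' @return An object of class `run_config`.
#' @export
run_config <- function(band_edges = .default_bands(),
                       window_length = 2,
                       coherence_threshold = 0.6,
                       sampen_m = 2, sampen_r = 0.2,
                       mse_scales = 10,
                       dfa_window_lengths = c(4, 6, 9, 13, 19, 28, 42, 63, 94, 141, 211),
                       selection_alpha = 0.05,
                       train_fraction = 0.8,
                       svm_grid = NULL,
                       n_repeats = 100,
                       n_permutations = 100,
                       ica_components = 40,
                       coherence_unit = c("recording", "window"),
                       split_unit = c("subject", "window"),
                       seed = 1L) {
  if (is.null(svm_grid)) svm_grid <- resteeg::svm_grid()
  lows <- vapply(band_edges, `[`, 0, 1)
  highs <- vapply(band_edges, `[`, 0, 2)
  ord <- order(lows)
  if (any(highs <= lows)) stop("each band must have low < high")
  if (any(lows[ord][-1] < highs[ord][-length(ord)])) {
    stop("band edges overlap")
  }
  if (min(lows) > 0.5 || max(highs) < 50) {
    stop("bands must jointly cover 0.5-50 Hz")
  }
  stopifnot(train_fraction > 0, train_fraction < 1,
            coherence_threshold > 0, coherence_threshold < 1,
            sampen_m >= 1, sampen_r > 0, mse_scales >= 1,
            n_repeats >= 1, n_permutations >= 1,
            all(diff(dfa_window_lengths) > 0), min(dfa_window_lengths) >= 4)
  structure(
    list(band_edges = band_edges, window_length = window_length,
         coherence_threshold = coherence_threshold,
         sampen_m = as.integer(sampen_m), sampen_r = sampen_r,
         mse_scales = as.integer(mse_scales),
         dfa_window_lengths = as.integer(dfa_window_lengths),
         selection_alpha = selection_alpha,
         train_fraction = train_fraction, svm_grid = svm_grid,
         n_repeats = as.integer(n_repeats),
         n_permutations = as.integer(n_permutations),
         ica_components = as.integer(ica_components),
         coherence_unit = match.arg(coherence_unit),
         split_unit = match.arg(split_unit),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read or write a run configuration as JSON
#' @param path File path.
#' @param config A `run_config`.
#' @return `read_run_config()` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$band_edges <- lapply(obj$band_edges, as.numeric)
  obj$svm_grid <- do.call(svm_grid, obj$svm_grid)
  do.call(run_config, obj)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- unclass(config)
  obj$svm_grid <- unclass(obj$svm_grid)
  jsonlite::write_json(obj, path, pretty = TRUE, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
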