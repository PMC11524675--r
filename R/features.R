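## FeatureTable: the interface between extraction and learning. One row per
## sample unit (2-s window by default), keyed by subject_id / window_index /
## group, followed by named feature columns (`family:band:channel` scheme).

#' Feature table constructor
#'
#' @param df Data frame whose first columns are `subject_id`, `window_index`,
#'   `group`, followed by numeric feature columns with unique names.
#' @return An object of classes `feature_table` and `data.frame`.
#' @export
feature_table <- function(df) {
  key <- c("subject_id", "window_index", "group")
  if (!all(key %in% names(df))) {
    stop("feature table needs columns ", paste(key, collapse = ", "))
  }
  df <- df[, c(key, setdiff(names(df), key)), drop = FALSE]
  if (anyDuplicated(names(df))) {
    stop("duplicate feature names: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  }
  if (!all(df$group %in% c("MDD", "HC", "unknown"))) {
    stop("group labels must be MDD, HC or unknown")
  }
  class(df) <- c("feature_table", "data.frame")
  attr(df, "standardized") <- attr(df, "standardized") %||% FALSE
  df
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x), " rows (",
      length(unique(x$subject_id)), " subjects) x ",
      ncol(x) - 3, " features",
      if (isTRUE(attr(x, "standardized"))) " [standardized]", "\n", sep = "")
  invisible(x)
}

#' Feature columns of a table as a numeric matrix
#' @param tab A `feature_table`.
#' @return Numeric matrix (rows = sample units).
#' @export
feature_matrix <- function(tab) {
  cols <- setdiff(names(tab), c("subject_id", "window_index", "group"))
  as.matrix(as.data.frame(tab)[, cols, drop = FALSE])
}

#' Feature names of a table
#' @param tab A `feature_table`.
#' @return Character vector.
#' @export
feature_names <- function(tab) {
  setdiff(names(tab), c("subject_id", "window_index", "group"))
}

#' Combine feature blocks into one table
#'
#' Binds family blocks (each a `feature_table` on the same sample units)
#' column-wise, checking that row keys agree exactly.
#'
#' @param ... `feature_table` objects.
#' @return A single `feature_table`.
#' @export
assemble <- function(...) {
  blocks <- list(...)
  stopifnot(length(blocks) >= 1)
  key <- blocks[[1]][, c("subject_id", "window_index", "group")]
  out <- as.data.frame(blocks[[1]])
  for (b in blocks[-1]) {
    if (!identical(b[, c("subject_id", "window_index", "group")], key)) {
      stop("feature blocks were computed on mismatched sample units")
    }
    out <- cbind(out, as.data.frame(b)[, feature_names(b), drop = FALSE])
  }
  feature_table(out)
}

#' Extract all feature families from a cohort
#'
#' Runs the preprocessing chain on each recording, then computes the seven
#' feature families per 2-s window: relative band power (`relpow`), alpha
#' interhemispheric asymmetry (`asym`), the left-right coherence grid
#' (`coh`), binarized network metrics (`net`), and band-filtered sample
#' entropy, multiscale entropy and DFA (`sampen`, `mse`, `dfa`). Coherence
#' and the network indices are estimated once per cleaned recording by
#' default (config `coherence_unit`) and replicated across that subject's
#' windows.
#'
#' @param recordings List of `eeg_recording` objects with group labels.
#' @param montage An `eeg_montage`.
#' @param config A [run_config()].
#' @param families Character subset of
#'   `c("relpow", "asym", "coh", "net", "sampen", "mse", "dfa")`.
#' @param ica Run ICA cleanup (default FALSE).
#' @param use_blink_truth If TRUE and a recording carries a ground-truth
#'   `"blink_source"` attribute (synthetic data), use it as the ICA rejection
#'   template.
#' @return A `feature_table`.
#' @export
extract_features <- function(recordings, montage, config = run_config(),
                             families = c("relpow", "asym", "coh", "net",
                                          "sampen", "mse", "dfa"),
                             ica = FALSE, use_blink_truth = FALSE) {
  families <- match.arg(families, several.ok = TRUE)
  bands <- config$band_edges
  band_names <- names(bands)
  rows <- list()
  for (rec in recordings) {
    templates <- NULL
    if (ica && use_blink_truth) templates <- attr(rec, "blink_source")
    wins <- preprocess_recording(rec, config, ica = ica, templates = templates)
    clean <- attr(wins, "recording")
    if (length(wins) == 0) next

    subject_static <- numeric(0)
    if (config$coherence_unit == "recording" &&
        any(c("coh", "net") %in% families)) {
      full_coh <- coherence_bands(clean, band_edges = bands)
      subject_static <- c(
        if ("coh" %in% families) .coh_features(full_coh, montage),
        if ("net" %in% families) network_features(full_coh, config$coherence_threshold)
      )
    }

    nl_fams <- intersect(families, c("sampen", "mse", "dfa"))
    band_wins <- NULL
    if (length(nl_fams)) {
      # band-filter the cleaned recording once per band, then re-window
      band_wins <- lapply(bands, function(be) {
        bp <- bandpass_recording(clean, low = be[1], high = be[2])
        segment_recording(bp, config$window_length)
      })
    }

    for (w in wins) {
      feats <- numeric(0)
      if (any(c("relpow", "asym") %in% families)) {
        bp <- wavelet_band_decompose(w, bands)
        if ("relpow" %in% families) {
          rp <- relative_power(bp)
          v <- as.vector(rp)
          names(v) <- paste0("relpow:", rep(band_names, each = nrow(rp)), ":",
                             rep(rownames(rp), length(band_names)))
          feats <- c(feats, v)
        }
        if ("asym" %in% families) {
          feats <- c(feats, alpha_asymmetry(bp, montage))
        }
      }
      if (config$coherence_unit == "window" &&
          any(c("coh", "net") %in% families)) {
        full_coh <- coherence_bands(w, band_edges = bands,
                                    seg_sec = min(1, config$window_length / 2))
        feats <- c(feats,
                   if ("coh" %in% families) .coh_features(full_coh, montage),
                   if ("net" %in% families) network_features(full_coh, config$coherence_threshold))
      } else {
        feats <- c(feats, subject_static)
      }
      if (length(nl_fams)) {
        for (b in band_names) {
          bw <- band_wins[[b]][[w$window_index]]
          for (ch in seq_along(w$channel_labels)) {
            x <- bw$signal[ch, ]
            lab <- w$channel_labels[ch]
            if ("sampen" %in% nl_fams) {
              feats[paste0("sampen:", b, ":", lab)] <-
                suppressWarnings(sampen(x, config$sampen_m, config$sampen_r))
            }
            if ("mse" %in% nl_fams) {
              feats[paste0("mse:", b, ":", lab)] <-
                as.numeric(suppressWarnings(mse(x, config$sampen_m,
                                                config$sampen_r,
                                                config$mse_scales)))
            }
            if ("dfa" %in% nl_fams) {
              feats[paste0("dfa:", b, ":", lab)] <-
                as.numeric(dfa(x, config$dfa_window_lengths))
            }
          }
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = w$subject_id, window_index = w$window_index,
        group = w$group, t(feats), check.names = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  feature_table(do.call(rbind, rows))
}

# flatten the left x right coherence grid into named features
.coh_features <- function(full_coh, montage) {
  out <- numeric(0)
  for (b in names(full_coh)) {
    g <- full_coh[[b]][montage$left, montage$right, drop = FALSE]
    v <- as.vector(g)
    names(v) <- paste0("coh:", b, ":",
                       rep(montage$left, ncol(g)), "-",
                       rep(montage$right, each = nrow(g)))
    out <- c(out, v)
  }
  out
}
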