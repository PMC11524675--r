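#' Electrode montage
#'
#' A montage partitions the channel labels of a recording into left-hemisphere,
#' right-hemisphere and midline sets, and carries an explicit inventory of
#' left--right channel pairs used for the alpha asymmetry index. The left and
#' right sets (equal in size) define the rows and columns of the
#' interhemispheric coherence grid; the asymmetry pair list is independent of
#' that grid and is stored as data, not derived, because published pair
#' inventories need not coincide with the homologous-pair partition.
#'
#' @param left,right,midline Character vectors of channel labels. The three
#'   sets must be pairwise disjoint and `left`/`right` must have equal length.
#' @param asymmetry_pairs A two-column data frame (or matrix) with columns
#'   `left` and `right`; each row names one asymmetry pair. Every entry must
#'   belong to the corresponding hemisphere set.
#' @return An object of class `eeg_montage`: a list with elements `left`,
#'   `right`, `midline` and `asymmetry_pairs`.
#' @seealso [generate_montage()], [read_montage()]
#' @export
montage <- function(left, right, midline = character(0), asymmetry_pairs) {
  left <- as.character(left)
  right <- as.character(right)
  midline <- as.character(midline)
  all_labels <- c(left, right, midline)
  if (anyDuplicated(all_labels)) {
    stop("montage label sets must be pairwise disjoint and duplicate-free: ",
         paste(unique(all_labels[duplicated(all_labels)]), collapse = ", "))
  }
  if (length(left) != length(right)) {
    stop("left and right label sets must have equal size for the coherence grid (got ",
         length(left), " vs ", length(right), ")")
  }
  asymmetry_pairs <- as.data.frame(asymmetry_pairs, stringsAsFactors = FALSE)
  if (!all(c("left", "right") %in% names(asymmetry_pairs))) {
    names(asymmetry_pairs) <- c("left", "right")[seq_len(ncol(asymmetry_pairs))]
  }
  asymmetry_pairs$left <- as.character(asymmetry_pairs$left)
  asymmetry_pairs$right <- as.character(asymmetry_pairs$right)
  bad_l <- setdiff(asymmetry_pairs$left, left)
  bad_r <- setdiff(asymmetry_pairs$right, right)
  if (length(bad_l) || length(bad_r)) {
    stop("asymmetry pair labels outside the hemisphere sets: ",
         paste(c(bad_l, bad_r), collapse = ", "))
  }
  structure(
    list(left = left, right = right, midline = midline,
         asymmetry_pairs = asymmetry_pairs[, c("left", "right")]),
    class = "eeg_montage"
  )
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$left) + length(x$right) + length(x$midline),
      " channels: ", length(x$left), " left, ", length(x$right), " right, ",
      length(x$midline), " midline; ", nrow(x$asymmetry_pairs),
      " asymmetry pairs\n", sep = "")
  invisible(x)
}

#' All channel labels of a montage
#'
#' @param m An `eeg_montage`.
#' @return Character vector: left, right, then midline labels.
#' @export
montage_labels <- function(m) c(m$left, m$right, m$midline)

# Homologous pairs available for small symmetric test montages, in the order
# they are drawn from when a reduced channel count is requested.
.toy_pair_order <- data.frame(
  left  = c("F3", "C3", "O1", "F7", "P3", "T7", "Fp1", "FC3", "CP3", "PO3"),
  right = c("F4", "C4", "O2", "F8", "P4", "T8", "Fp2", "FC4", "CP4", "PO4"),
  stringsAsFactors = FALSE
)

#' Build a montage for a given channel count
#'
#' With `n_channels = 58` (the default) this returns the packaged 10-20/10-10
#' montage: 25 left and 25 right lateral channels, 8 midline channels, and a
#' 26-entry asymmetry pair inventory. Smaller even channel counts (up to 20)
#' return a symmetric toy montage of homologous pairs with no midline, useful
#' for fast tests; e.g. `n_channels = 6` gives F3/F4, C3/C4, O1/O2 with 3
#' asymmetry pairs and a 3x3 coherence grid.
#'
#' @param n_channels Number of channels: 58, or an even number <= 20.
#' @param path Optional path to a montage JSON file, which overrides
#'   `n_channels` entirely.
#' @return An `eeg_montage`.
#' @export
generate_montage <- function(n_channels = 58, path = NULL) {
  if (!is.null(path)) {
    return(read_montage(path))
  }
  if (identical(as.integer(n_channels), 58L)) {
    return(read_montage(system.file("extdata", "montage58.json",
                                    package = "resteeg", mustWork = TRUE)))
  }
  n_channels <- as.integer(n_channels)
  if (n_channels < 2 || n_channels %% 2 != 0 || n_channels > 2 * nrow(.toy_pair_order)) {
    stop("no built-in montage for ", n_channels,
         " channels; supply a montage JSON via `path` (built-ins: 58, or even sizes 2..",
         2 * nrow(.toy_pair_order), ")")
  }
  pairs <- .toy_pair_order[seq_len(n_channels / 2), , drop = FALSE]
  montage(left = pairs$left, right = pairs$right, midline = character(0),
          asymmetry_pairs = pairs)
}

#' Read or write a montage as JSON
#'
#' The JSON object has fields `left`, `right`, `midline` (label arrays) and
#' `asymmetry_pairs` (array of two-element [left, right] arrays).
#'
#' @param path File path.
#' @param m An `eeg_montage`.
#' @return `read_montage()` returns an `eeg_montage`; `write_montage()`
#'   returns `path` invisibly.
#' @export
read_montage <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pairs <- obj$asymmetry_pairs
  if (is.matrix(pairs)) pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  montage(left = obj$left, right = obj$right,
          midline = if (is.null(obj$midline)) character(0) else obj$midline,
          asymmetry_pairs = pairs)
}

#' @rdname read_montage
#' @export
write_montage <- function(m, path) {
  stopifnot(inherits(m, "eeg_montage"))
  obj <- list(left = m$left, right = m$right, midline = m$midline,
              asymmetry_pairs = unname(as.matrix(m$asymmetry_pairs)))
  jsonlite::write_json(obj, path, pretty = TRUE)
  invisible(path)
}
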