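#' Labeled inertial-window dataset
#'
#' The canonical container for a set of fixed-length, multi-channel sensor
#' windows is a tibble with one row per (window, channel) pair:
#' `window_id` (integer, 0-based), `label` (integer class id, 0-based),
#' `channel` (integer, 0-based), and sample columns `s0 ... s{n-1}`.
#' Sample units are g for accelerometer channels and rad/s for gyroscope
#' channels. Dataset-level metadata travels as attributes: `sample_rate`
#' (Hz), `class_names`, and `channel_names`.
#'
#' @param data tibble/data.frame with columns `window_id`, `label`,
#'   `channel` and at least two `s*` sample columns.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param class_names character vector naming the classes, one per distinct
#'   label, in label order. Defaults to `"class_0" ...`.
#' @param channel_names character vector naming the channels in channel
#'   order. Defaults to `"ch_0" ...`.
#'
#' @return A tibble of class `har_dataset`.
#' @export
#' @examples
#' ds <- generate_windows(default_synthetic_spec(2, n_per_class = 3, seed = 1))
#' n_windows(ds)
har_dataset <- function(data, sample_rate = 50,
                        class_names = NULL, channel_names = NULL) {
  data <- as_tibble(data)
  required <- c("window_id", "label", "channel")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    abort("sample_rate must be a single positive number")
  }
  sample_cols <- grep("^s[0-9]+$", names(data), value = TRUE)
  if (nrow(data) > 0 && length(sample_cols) < 2) {
    abort("dataset needs at least 2 sample columns (s0, s1, ...)")
  }
  # canonical sample-column order by index, canonical row order
  if (length(sample_cols) > 0) {
    idx <- order(as.integer(sub("^s", "", sample_cols)))
    data <- data[, c(required, sample_cols[idx],
                     setdiff(names(data), c(required, sample_cols)))]
    sample_cols <- sample_cols[idx]
  }
  data <- dplyr::arrange(data, .data$window_id, .data$channel)
  if (nrow(data) > 0) {
    vals <- as.matrix(data[, sample_cols])
    if (!all(is.finite(vals))) abort("dataset contains non-finite sample values")
    if (anyDuplicated(data[, c("window_id", "channel")]) > 0) {
      abort("duplicate (window_id, channel) pair")
    }
    per_win <- dplyr::count(data, .data$window_id)
    if (length(unique(per_win$n)) > 1) {
      abort("all windows must have the same channel count")
    }
    labs <- window_labels_raw(data)
    if (any(!is.na(labs))) {
      ulabs <- sort(unique(labs[!is.na(labs)]))
      if (any(ulabs < 0)) abort("labels must be >= 0")
      if (is.null(class_names)) class_names <- paste0("class_", ulabs)
      if (length(class_names) < length(ulabs)) {
        abort("class_names shorter than the number of distinct labels")
      }
    }
    n_channels <- per_win$n[1]
    if (is.null(channel_names)) channel_names <- paste0("ch_", seq_len(n_channels) - 1)
  }
  if (is.null(class_names)) class_names <- character(0)
  if (is.null(channel_names)) channel_names <- character(0)
  structure(data,
            sample_rate = sample_rate,
            class_names = class_names,
            channel_names = channel_names,
            class = c("har_dataset", class(data)))
}

window_labels_raw <- function(data) {
  first <- !duplicated(data$window_id)
  data$label[first]
}

#' Number of windows in a dataset
#' @param dataset a `har_dataset`.
#' @return integer count.
#' @export
n_windows <- function(dataset) {
  length(unique(dataset$window_id))
}

#' Per-window class labels
#' @param dataset a `har_dataset`.
#' @return integer vector, one 0-based label per window in window order.
#' @export
window_labels <- function(dataset) {
  data <- dplyr::arrange(as_tibble(dataset), .data$window_id, .data$channel)
  as.integer(window_labels_raw(data))
}

sample_columns <- function(dataset) {
  cols <- grep("^s[0-9]+$", names(dataset), value = TRUE)
  cols[order(as.integer(sub("^s", "", cols)))]
}

#' Extract one window as a channels-by-samples matrix
#' @param dataset a `har_dataset`.
#' @param window_id the 0-based window id.
#' @return numeric matrix, channels (rows, in channel order) by samples.
#' @export
get_window <- function(dataset, window_id) {
  rows <- dataset[dataset$window_id == window_id, , drop = FALSE]
  if (nrow(rows) == 0) abort(paste0("no window with id ", window_id))
  rows <- rows[order(rows$channel), , drop = FALSE]
  m <- as.matrix(rows[, sample_columns(dataset)])
  rownames(m) <- NULL
  m
}

#' Flatten a window's channels into one vector
#'
#' Concatenates the selected channels of a channels-by-samples window matrix
#' into a single sequence, the form consumed by the envelope spectrum stage.
#' The default order is all channels as stored (accelerometer x, y, z then
#' gyroscope x, y, z for the generators and readers in this package).
#'
#' @param window channels-by-samples numeric matrix.
#' @param channel_order integer vector of 1-based channel indices (a subset
#'   or permutation of the available rows).
#' @return numeric vector of length `length(channel_order) * ncol(window)`.
#' @export
#' @examples
#' w <- matrix(1:8, nrow = 2, byrow = TRUE)
#' flatten_window(w)          # 1 2 3 4 5 6 7 8
#' flatten_window(w, c(2, 1)) # 5 6 7 8 1 2 3 4
flatten_window <- function(window, channel_order = seq_len(nrow(window))) {
  if (!is.matrix(window)) window <- matrix(window, nrow = 1)
  if (any(channel_order < 1 | channel_order > nrow(window))) {
    abort(paste0("channel_order index out of range 1..", nrow(window)))
  }
  as.numeric(t(window[channel_order, , drop = FALSE]))
}

#' Flatten every window of a dataset into a matrix
#' @param dataset a `har_dataset`.
#' @param channel_order 1-based channel indices passed to [flatten_window()].
#' @return numeric matrix, one row per window (in window order).
#' @export
flatten_windows <- function(dataset, channel_order = NULL) {
  ids <- sort(unique(dataset$window_id))
  rows <- lapply(ids, function(i) {
    w <- get_window(dataset, i)
    ord <- channel_order %||% seq_len(nrow(w))
    flatten_window(w, ord)
  })
  do.call(rbind, rows)
}

#' Subset a dataset by window position
#' @param dataset a `har_dataset`.
#' @param which integer positions (1-based) into the ordered window list.
#' @return a `har_dataset` with re-numbered contiguous window ids.
#' @export
subset_windows <- function(dataset, which) {
  ids <- sort(unique(dataset$window_id))
  keep <- ids[which]
  out <- dataset[dataset$window_id %in% keep, , drop = FALSE]
  # renumber to contiguous 0-based ids preserving order
  map <- stats::setNames(seq_along(keep) - 1L, keep)
  out$window_id <- as.integer(map[as.character(out$window_id)])
  har_dataset(out,
              sample_rate = attr(dataset, "sample_rate"),
              class_names = attr(dataset, "class_names"),
              channel_names = attr(dataset, "channel_names"))
}

#' @export
print.har_dataset <- function(x, ...) {
  cat(sprintf("<har_dataset: %d windows x %d channels x %d samples @ %g Hz>\n",
              n_windows(x),
              if (nrow(x) > 0) sum(x$window_id == x$window_id[1]) else 0,
              length(sample_columns(x)),
              attr(x, "sample_rate")))
  NextMethod()
}
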