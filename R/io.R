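#' Read the UCI-HAR inertial-signals text layout
#'
#' Each channel file is whitespace-delimited text with one window per row
#' (the public layout uses 128 columns, one 2.56 s window at 50 Hz); the
#' label file has one integer per row. Window i gets one channel per file,
#' in the order given. Original label codes (1-based in the public data)
#' are remapped to contiguous 0-based ids preserving their sorted order;
#' the original codes are kept in `class_names`.
#'
#' @param directory directory containing the files.
#' @param channel_files character vector of channel file names, in the
#'   desired channel order (convention: accelerometer x, y, z then
#'   gyroscope x, y, z).
#' @param label_file label file name, one integer per row.
#' @param sample_rate sampling rate in Hz (default 50).
#' @return a [har_dataset()].
#' @export
read_ucihar_inertial <- function(directory, channel_files, label_file,
                                 sample_rate = 50) {
  if (length(channel_files) == 0) abort("no channel files given")
  paths <- file.path(directory, channel_files)
  missing <- channel_files[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("missing channel files in ", directory, ": ",
                 paste(missing, collapse = ", ")))
  }
  chans <- lapply(seq_along(paths), function(i) {
    read_fixed_width_numeric(paths[i], channel_files[i])
  })
  widths <- vapply(chans, ncol, integer(1))
  rows <- vapply(chans, nrow, integer(1))
  if (length(unique(rows)) > 1) {
    bad <- which(rows != rows[1])[1]
    abort(sprintf("row-count mismatch: %s has %d rows but %s has %d",
                  channel_files[1], rows[1], channel_files[bad], rows[bad]))
  }
  if (length(unique(widths)) > 1) {
    abort(paste0("channel files have differing widths: ",
                 paste(widths, collapse = ", ")))
  }
  label_path <- file.path(directory, label_file)
  if (!file.exists(label_path)) abort(paste0("missing label file: ", label_path))
  raw_labels <- scan(label_path, what = integer(), quiet = TRUE)
  if (length(raw_labels) != rows[1]) {
    abort(sprintf("row-count mismatch: channel file %s has %d rows, label file %s has %d",
                  channel_files[1], rows[1], label_file, length(raw_labels)))
  }
  codes <- sort(unique(raw_labels))
  labels <- match(raw_labels, codes) - 1L

  n_win <- rows[1]
  width <- widths[1]
  n_ch <- length(chans)
  block <- matrix(0, nrow = n_win * n_ch, ncol = width)
  for (c in seq_len(n_ch)) {
    block[seq(c, by = n_ch, length.out = n_win), ] <- chans[[c]]
  }
  colnames(block) <- paste0("s", seq_len(width) - 1)
  data <- tibble(
    window_id = rep(seq_len(n_win) - 1L, each = n_ch),
    label = rep(labels, each = n_ch),
    channel = rep(seq_len(n_ch) - 1L, times = n_win)
  )
  data <- dplyr::bind_cols(data, as_tibble(block))
  har_dataset(data, sample_rate = sample_rate,
              class_names = paste0("activity_", codes),
              channel_names = sub("\\.txt$", "", channel_files))
}

read_fixed_width_numeric <- function(path, name) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("empty file: ", name))
  rows <- lapply(seq_along(lines), function(i) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) {
      col <- which(is.na(vals))[1]
      abort(sprintf("non-numeric token '%s' in %s at row %d, column %d",
                    toks[col], name, i, col))
    }
    vals
  })
  lens <- lengths(rows)
  if (length(unique(lens)) > 1) {
    abort(sprintf("ragged rows in %s: widths %s",
                  name, paste(unique(lens), collapse = ", ")))
  }
  m <- do.call(rbind, rows)
  if (!all(is.finite(m))) abort(paste0("non-finite value in ", name))
  m
}

#' Write a dataset to the portable CSV container
#'
#' One row per (window, channel) with header
#' `window_id,label,channel,s0,...`; rows ordered by window id then channel,
#' values written at full precision so a read/write round trip is exact to
#' 1e-12 (bit-exact for finite decimals).
#'
#' @param dataset a [har_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_csv_dataset <- function(dataset, path) {
  cols <- c("window_id", "label", "channel", sample_columns(dataset))
  out <- as_tibble(dataset)[, cols, drop = FALSE]
  out <- dplyr::arrange(out, .data$window_id, .data$channel)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a dataset from the portable CSV container
#'
#' @param path CSV file written by [write_csv_dataset()] (or matching its
#'   layout: header `window_id,label,channel,s0,...`).
#' @param sample_rate sampling rate in Hz to attach (default 50).
#' @param class_names,channel_names optional metadata to attach.
#' @return a [har_dataset()].
#' @export
read_csv_dataset <- function(path, sample_rate = 50,
                             class_names = NULL, channel_names = NULL) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("window_id", "label", "channel")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("CSV is missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  har_dataset(data, sample_rate = sample_rate,
              class_names = class_names, channel_names = channel_names)
}
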