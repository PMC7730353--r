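# shared fixtures and independent oracles, all built in code

# tiny labeled dataset: n_per_class windows per class, gaussian clusters in
# the time domain so classes are trivially distinguishable
tiny_dataset <- function(n_classes = 2, n_per_class = 4, channels = 2,
                         samples = 16, seed = 42) {
  set.seed(seed)
  rows <- list()
  wi <- 0L
  for (k in seq_len(n_classes) - 1L) {
    for (w in seq_len(n_per_class)) {
      vals <- matrix(rnorm(channels * samples, mean = 2 * k), channels,
                     samples)
      colnames(vals) <- paste0("s", seq_len(samples) - 1)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(window_id = wi, label = k,
                       channel = seq_len(channels) - 1L),
        tibble::as_tibble(vals))
      wi <- wi + 1L
    }
  }
  har_dataset(dplyr::bind_rows(rows), sample_rate = 50)
}

# brute-force biased autocorrelation: O(N^2) double loop
brute_autocorrelation <- function(y, lag) {
  n <- length(y)
  lag <- abs(lag)
  if (lag >= n) return(0)
  acc <- 0
  for (k in seq_len(n - lag)) acc <- acc + y[k + lag] * y[k]
  acc / n
}

# direct total scatter about the global mean
brute_total_scatter <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  crossprod(xc)
}

# write a miniature UCI-HAR-style inertial layout into a temp dir
make_ucihar_fixture <- function(dir, n_windows = 6, width = 16,
                                n_channels = 3, labels = NULL, seed = 7) {
  set.seed(seed)
  files <- paste0("chan", seq_len(n_channels), ".txt")
  for (f in files) {
    m <- matrix(round(rnorm(n_windows * width), 6), n_windows, width)
    writeLines(apply(m, 1, paste, collapse = " "), file.path(dir, f))
  }
  if (is.null(labels)) labels <- rep_len(c(1, 2, 3), n_windows)
  writeLines(as.character(labels), file.path(dir, "y.txt"))
  list(files = files, label_file = "y.txt", labels = labels)
}

# gaussian clusters for classifier tests: centers far relative to spread
separable_clusters <- function(n_per_class = 20, centers = rbind(
  c(0, 0), c(10, 0), c(0, 10)), sd = 0.5, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
    sweep(matrix(rnorm(n_per_class * ncol(centers), sd = sd),
                 n_per_class), 2, centers[k, ], "+")
  }))
  list(x = x, labels = rep(seq_len(nrow(centers)) - 1L, each = n_per_class))
}

nearest_centroid_predict <- function(x_train, labels, x_test) {
  classes <- sort(unique(labels))
  cen <- t(vapply(classes, function(k) colMeans(x_train[labels == k, ,
                                                        drop = FALSE]),
                  numeric(ncol(x_train))))
  apply(x_test, 1, function(r) classes[which.min(rowSums(sweep(cen, 2, r)^2))])
}
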