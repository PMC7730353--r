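#' Confusion matrix
#'
#' Counts with rows = true class, columns = predicted class. Per-class
#' tallies follow the one-vs-rest convention: Tp is the diagonal entry,
#' Fp the rest of the column, Fn the rest of the row, and Tn everything
#' else, so Tp + Fp + Fn + Tn equals the total test count for every class.
#'
#' @param true_labels,predicted_labels integer vectors of equal length,
#'   values in `0 .. n_classes - 1`.
#' @param n_classes number of classes (default: inferred from the labels).
#' @param class_names optional class names for the dimnames.
#' @return a K x K integer matrix of class `har_confusion`.
#' @export
#' @examples
#' confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1))
confusion_matrix <- function(true_labels, predicted_labels,
                             n_classes = NULL, class_names = NULL) {
  if (length(true_labels) != length(predicted_labels)) {
    abort("true and predicted label vectors differ in length")
  }
  labs <- c(true_labels, predicted_labels)
  if (is.null(n_classes)) n_classes <- max(labs) + 1L
  if (length(labs) > 0 && (any(labs < 0) || any(labs >= n_classes))) {
    abort(paste0("labels must lie in 0..", n_classes - 1))
  }
  if (is.null(class_names)) class_names <- paste0("class_", 0:(n_classes - 1))
  lv <- 0:(n_classes - 1)
  m <- table(factor(true_labels, levels = lv),
             factor(predicted_labels, levels = lv))
  m <- matrix(as.integer(m), n_classes, n_classes,
              dimnames = list(true = class_names, predicted = class_names))
  structure(m, class = c("har_confusion", "matrix", "array"))
}

confusion_tallies <- function(confusion) {
  m <- unclass(confusion)
  total <- sum(m)
  tp <- unname(diag(m))
  fp <- unname(colSums(m)) - tp
  fn <- unname(rowSums(m)) - tp
  tibble(class = rownames(m) %||% paste0("class_", seq_len(nrow(m)) - 1),
         tp = tp, fp = fp, fn = fn, tn = total - tp - fp - fn)
}

#' Classification metrics from a confusion matrix
#'
#' Per-class precision `Tp/(Tp+Fp)` and recall `Tp/(Tp+Fn)` (0/0 taken as
#' 0), F1 = 2PR/(P+R) (0 when P+R = 0), and accuracy = trace/total.
#' Macro averaging takes the unweighted class mean of P and R before F1;
#' micro averaging pools Tp/Fp/Fn over classes, under which micro precision
#' = micro recall = accuracy for single-label classification. Both
#' averages are always computed; `averaging` selects which one fills the
#' headline `precision`/`recall`/`f1` fields.
#'
#' @param confusion a [confusion_matrix()].
#' @param averaging `"macro"` (default) or `"micro"`.
#' @return an object of class `har_eval`: list with `confusion`,
#'   `accuracy`, `precision`, `recall`, `f1`, `averaging`, `per_class`
#'   (tibble), `macro` and `micro` (named lists).
#' @export
eval_metrics <- function(confusion, averaging = c("macro", "micro")) {
  averaging <- match.arg(averaging)
  if (sum(confusion) == 0) abort("confusion matrix has zero total count")
  tl <- confusion_tallies(confusion)
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  per <- dplyr::mutate(tl,
    precision = safe_div(.data$tp, .data$tp + .data$fp),
    recall = safe_div(.data$tp, .data$tp + .data$fn))
  per$f1 <- ifelse(per$precision + per$recall == 0, 0,
                   2 * per$precision * per$recall /
                     (per$precision + per$recall))
  accuracy <- sum(diag(unclass(confusion))) / sum(confusion)
  macro_p <- mean(per$precision)
  macro_r <- mean(per$recall)
  macro <- list(precision = macro_p, recall = macro_r,
                f1 = if (macro_p + macro_r == 0) 0 else
                  2 * macro_p * macro_r / (macro_p + macro_r))
  micro_p <- safe_div(sum(per$tp), sum(per$tp) + sum(per$fp))
  micro_r <- safe_div(sum(per$tp), sum(per$tp) + sum(per$fn))
  micro <- list(precision = micro_p, recall = micro_r,
                f1 = if (micro_p + micro_r == 0) 0 else
                  2 * micro_p * micro_r / (micro_p + micro_r))
  pick <- if (averaging == "macro") macro else micro
  structure(
    list(confusion = confusion, accuracy = accuracy,
         precision = pick$precision, recall = pick$recall, f1 = pick$f1,
         averaging = averaging, per_class = per,
         macro = macro, micro = micro),
    class = "har_eval"
  )
}

#' @export
print.har_eval <- function(x, ...) {
  cat(sprintf("<har_eval: accuracy %.4f | %s precision %.4f recall %.4f F1 %.4f>\n",
              x$accuracy, x$averaging, x$precision, x$recall, x$f1))
  invisible(x)
}

#' @export
tidy.har_eval <- function(x, ...) x$per_class

#' @export
glance.har_eval <- function(x, ...) {
  tibble(accuracy = x$accuracy,
         precision = x$precision, recall = x$recall, f1 = x$f1,
         averaging = x$averaging,
         micro_precision = x$micro$precision,
         macro_f1 = x$macro$f1, micro_f1 = x$micro$f1,
         n = sum(x$confusion))
}

#' Write an evaluation report to JSON (and its confusion matrix to CSV)
#' @param report a [eval_metrics()] report.
#' @param json_path output JSON path.
#' @param confusion_csv optional CSV path for the confusion matrix with
#'   class-name headers.
#' @return `json_path`, invisibly.
#' @export
write_eval_report <- function(report, json_path, confusion_csv = NULL) {
  obj <- list(accuracy = report$accuracy, precision = report$precision,
              recall = report$recall, f1 = report$f1,
              averaging = report$averaging,
              macro = report$macro, micro = report$micro,
              per_class = report$per_class,
              confusion = unclass(report$confusion),
              class_names = rownames(report$confusion))
  jsonlite::write_json(obj, json_path, digits = NA, auto_unbox = TRUE)
  if (!is.null(confusion_csv)) {
    df <- as.data.frame(unclass(report$confusion))
    df <- cbind(true = rownames(df), df)
    readr::write_csv(tibble::as_tibble(df), confusion_csv, progress = FALSE)
  }
  invisible(json_path)
}

# per-class train indices for a stratified split: round(fraction * N_k)
stratified_indices <- function(labels, fraction, seed) {
  withr_seed(seed, {
    idx <- integer(0)
    for (k in sort(unique(labels))) {
      members <- which(labels == k)
      n_train <- round(fraction * length(members))
      idx <- c(idx, sort(sample(members, n_train)))
    }
    sort(idx)
  })
}

#' Stratified train/test split of a dataset
#'
#' Seeded split; with `stratified = TRUE` each class contributes
#' `round(fraction * N_k)` windows to the training set.
#'
#' @param dataset a [har_dataset()].
#' @param train_fraction fraction in (0, 1) used for training.
#' @param stratified preserve class proportions (default TRUE).
#' @param seed integer seed.
#' @return named list with `train` and `test` datasets (disjoint,
#'   exhaustive).
#' @export
split_train_test <- function(dataset, train_fraction = 0.5,
                             stratified = TRUE, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be in (0, 1)")
  }
  labels <- window_labels(dataset)
  if (stratified) {
    small <- names(which(table(labels) < 2))
    if (length(small) > 0) {
      abort(paste0("class ", small[1],
                   " has fewer than 2 windows; cannot stratify"))
    }
    idx <- stratified_indices(labels, train_fraction, seed)
  } else {
    idx <- withr_seed(seed,
      sort(sample(seq_along(labels), round(train_fraction * length(labels)))))
  }
  list(train = subset_windows(dataset, idx),
       test = subset_windows(dataset, setdiff(seq_along(labels), idx)))
}

# stratified fold ids 1..k, seeded; class sizes must be >= k. Per-class
# remainders are staggered across folds (offset by class) so overall fold
# sizes stay as equal as the stratification allows.
fold_assignment <- function(labels, k, seed) {
  folds <- integer(length(labels))
  classes <- sort(unique(labels))
  withr_seed(seed, {
    for (ci in seq_along(classes)) {
      members <- which(labels == classes[ci])
      n <- length(members)
      if (n < k) {
        abort(paste0("class ", classes[ci], " has fewer than k = ", k,
                     " windows"))
      }
      sizes <- rep(n %/% k, k)
      r <- n %% k
      if (r > 0) {
        extras <- ((ci - 1 + 0:(r - 1)) %% k) + 1
        sizes[extras] <- sizes[extras] + 1
      }
      folds[members] <- sample(rep(seq_len(k), times = sizes))
    }
  })
  folds
}

#' k-fold cross-validation of the full pipeline
#'
#' Stratified, seeded folds. In `"rotating"` mode every fold is tested once
#' and metrics are averaged across folds (standard k-fold CV). In
#' `"single-split"` mode folds 1 .. k-1 train and fold k tests, once. All
#' preprocessing — the envelope-spectrum extraction, the discriminant fit
#' and the SVM training — happens inside each training fold only.
#'
#' @param dataset a [har_dataset()].
#' @param k number of folds (>= 2).
#' @param config a [har_config()].
#' @param seed integer seed for fold assignment and training.
#' @param mode `"rotating"` (default) or `"single-split"`.
#' @return list of class `har_cv`: `mean` (tibble of averaged metrics),
#'   `folds` (list of `har_eval` reports), `models` (per-fold fitted
#'   pipelines), `fold_ids`, `mode`, `k`.
#' @export
kfold_cv <- function(dataset, k = 3, config = har_config(), seed = 1,
                     mode = c("rotating", "single-split")) {
  mode <- match.arg(mode)
  if (k < 2) abort("k must be >= 2")
  labels <- window_labels(dataset)
  folds <- fold_assignment(labels, k, seed)
  test_folds <- if (mode == "rotating") seq_len(k) else k
  fits <- lapply(test_folds, function(f) {
    train <- subset_windows(dataset, which(folds != f))
    test <- subset_windows(dataset, which(folds == f))
    model <- fit_har(train, config, seed = seed)
    list(model = model, report = evaluate_har(model, test))
  })
  reports <- lapply(fits, `[[`, "report")
  gl <- dplyr::bind_rows(lapply(reports, glance))
  mean_tbl <- tibble(accuracy = mean(gl$accuracy),
                     precision = mean(gl$precision),
                     recall = mean(gl$recall),
                     f1 = mean(gl$f1))
  structure(list(mean = mean_tbl, folds = reports,
                 models = lapply(fits, `[[`, "model"), fold_ids = folds,
                 mode = mode, k = k),
            class = "har_cv")
}

#' @export
print.har_cv <- function(x, ...) {
  cat(sprintf("<har_cv: %d-fold (%s) | mean accuracy %.4f, F1 %.4f>\n",
              x$k, x$mode, x$mean$accuracy, x$mean$f1))
  invisible(x)
}

#' Feature-count sweep experiment
#'
#' Fits the envelope-spectrum extraction and the discriminant projection
#' once on the training set, then for each feature count keeps that many
#' leading discriminant coordinates, trains a one-against-all SVM and
#' evaluates on the test set. The default counts
#' `{5, 10, 15, 20, 25, 30, 35, 40, all}` mirror the published sweep
#' layout; metrics are reported as percentages.
#'
#' @param train,test [har_dataset()]s (e.g. from [split_train_test()]).
#' @param counts integer feature counts; the string `"all"` means every
#'   available direction. Default `c(5, 10, 15, 20, 25, 30, 35, 40, "all")`.
#' @param config a [har_config()].
#' @param seed integer seed for SVM training.
#' @return a tibble of class `har_sweep`: columns `n_features` (character,
#'   `"all"` last), `accuracy`, `precision`, `recall`, `f1`, in percent.
#' @export
feature_sweep <- function(train, test,
                          counts = c(5, 10, 15, 20, 25, 30, 35, 40, "all"),
                          config = har_config(), seed = 1) {
  if (length(counts) == 0) abort("counts must be non-empty")
  feats_train <- eps_transform(train, config$channel_order,
                               config$use_envelope)
  feats_test <- eps_transform(test, config$channel_order,
                              config$use_envelope)
  lda <- fit_lda(feats_train, regularization = config$lda_regularization)
  d <- nrow(lda$projection)
  numeric_counts <- ifelse(counts == "all", d,
                           suppressWarnings(as.integer(counts)))
  if (anyNA(numeric_counts)) abort("counts must be integers or \"all\"")
  if (any(numeric_counts > d)) {
    abort(paste0("count exceeds the ", d, " available directions"))
  }
  cfg_svm <- svm_config(config$gamma_mode, gamma = config$gamma,
                        c_penalty = config$c_penalty)
  rows <- lapply(seq_along(counts), function(i) {
    nf <- numeric_counts[i]
    ztr <- lda_transform(lda, feats_train, nf)
    zte <- lda_transform(lda, feats_test, nf)
    model <- train_oaa(ztr, config = cfg_svm, seed = seed)
    pred <- predict(model, zte)
    rep <- eval_metrics(
      confusion_matrix(window_labels(test), pred,
                       n_classes = max(window_labels(train),
                                       window_labels(test)) + 1L),
      averaging = config$averaging)
    tibble(n_features = as.character(counts[i]),
           accuracy = 100 * rep$accuracy,
           precision = 100 * rep$precision,
           recall = 100 * rep$recall,
           f1 = 100 * rep$f1)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("har_sweep", class(out))
  out
}

#' Write a sweep result as a percentage CSV table
#' @param sweep a [feature_sweep()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  out <- dplyr::mutate(as_tibble(sweep),
                       dplyr::across(dplyr::where(is.numeric),
                                     ~ sprintf("%.2f", .x)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
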