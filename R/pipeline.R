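#' Pipeline configuration
#'
#' Collects every tunable of the extract-reduce-classify pipeline in one
#' validated list.
#'
#' @param channel_order 1-based channel indices fed to [flatten_window()];
#'   `NULL` means all channels in stored order (accelerometer x, y, z then
#'   gyroscope x, y, z).
#' @param use_envelope take the amplitude envelope before the periodogram
#'   (default TRUE).
#' @param lda_regularization ridge term for [fit_lda()]; `NULL` for the
#'   scaled shrinkage default `1e-2 * trace(S_w) / d`.
#' @param n_features how many leading discriminant coordinates feed the
#'   classifier (default 5, the published optimum), or `"all"`.
#' @param gamma_mode,gamma,c_penalty see [svm_config()].
#' @param train_fraction train share for [split_train_test()] (default 0.5).
#' @param k_folds folds for [kfold_cv()] (default 3).
#' @param cv_mode `"rotating"` or `"single-split"`.
#' @param averaging `"macro"` or `"micro"` headline metrics.
#' @param seed integer seed for every stochastic step.
#' @return a list of class `har_config`.
#' @export
har_config <- function(channel_order = NULL, use_envelope = TRUE,
                       lda_regularization = NULL, n_features = 5,
                       gamma_mode = "median-heuristic", gamma = NULL,
                       c_penalty = 1, train_fraction = 0.5, k_folds = 3,
                       cv_mode = "rotating", averaging = "macro", seed = 1) {
  svm_config(gamma_mode, gamma = gamma, c_penalty = c_penalty)  # validates
  if (!identical(n_features, "all") &&
      (!is.numeric(n_features) || n_features < 1)) {
    abort("n_features must be a positive integer or \"all\"")
  }
  structure(
    list(channel_order = channel_order, use_envelope = use_envelope,
         lda_regularization = lda_regularization, n_features = n_features,
         gamma_mode = gamma_mode, gamma = gamma, c_penalty = c_penalty,
         train_fraction = train_fraction, k_folds = k_folds,
         cv_mode = cv_mode, averaging = averaging, seed = seed),
    class = "har_config"
  )
}

#' Fit the full extract-reduce-classify pipeline
#'
#' Envelope-spectrum features, Fisher discriminant projection and
#' one-against-all SVM, all fitted on the given training dataset only.
#'
#' @param train a [har_dataset()] of training windows.
#' @param config a [har_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return an object of class `har_model` with elements `lda`, `svm`,
#'   `n_features`, `config`.
#' @export
fit_har <- function(train, config = har_config(), seed = config$seed) {
  feats <- eps_transform(train, config$channel_order, config$use_envelope)
  lda <- fit_lda(feats, regularization = config$lda_regularization)
  nf <- if (identical(config$n_features, "all")) nrow(lda$projection)
        else min(config$n_features, nrow(lda$projection))
  z <- lda_transform(lda, feats, nf)
  svm <- train_oaa(z, config = svm_config(config$gamma_mode,
                                          gamma = config$gamma,
                                          c_penalty = config$c_penalty),
                   seed = seed)
  structure(list(lda = lda, svm = svm, n_features = nf, config = config),
            class = "har_model")
}

#' Predict activity labels for a dataset
#' @param object a [fit_har()] model.
#' @param newdata a [har_dataset()].
#' @param ... unused.
#' @return integer vector of predicted class ids, one per window.
#' @export
predict.har_model <- function(object, newdata, ...) {
  feats <- eps_transform(newdata, object$config$channel_order,
                         object$config$use_envelope)
  z <- lda_transform(object$lda, feats, object$n_features)
  predict(object$svm, z)
}

#' Evaluate a fitted pipeline on a test dataset
#' @param model a [fit_har()] model.
#' @param test a [har_dataset()].
#' @return a `har_eval` report (see [eval_metrics()]).
#' @export
evaluate_har <- function(model, test) {
  truth <- window_labels(test)
  pred <- predict(model, test)
  n_classes <- max(length(model$svm$class_ids), max(truth) + 1L)
  cn <- attr(test, "class_names")
  if (length(cn) < n_classes) cn <- NULL
  eval_metrics(confusion_matrix(truth, pred, n_classes, cn),
               averaging = model$config$averaging)
}

#' @export
print.har_model <- function(x, ...) {
  cat(sprintf("<har_model: %d-dim spectra -> %d discriminant features -> %d-class OAA SVM>\n",
              x$lda$input_dim, x$n_features, length(x$svm$class_ids)))
  invisible(x)
}
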