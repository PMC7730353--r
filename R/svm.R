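#' Gaussian radial basis kernel
#'
#' `k(xa, xb) = exp(-||xa - xb||^2 / (2 * gamma^2))`, where `gamma` is the
#' kernel width. Values lie in (0, 1], with `k(x, x) = 1`.
#'
#' @param xa,xb numeric vectors of equal length.
#' @param gamma kernel width, > 0.
#' @return a single number in (0, 1].
#' @export
#' @examples
#' rbf_kernel(c(0, 0), c(1, 1), gamma = 1)  # exp(-1) = 0.3678794
rbf_kernel <- function(xa, xb, gamma) {
  if (length(xa) != length(xb)) abort("xa and xb must have equal length")
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
    abort("gamma must be a single positive number")
  }
  exp(-sum((xa - xb)^2) / (2 * gamma^2))
}

#' SVM configuration
#'
#' @param gamma_mode how the kernel width is chosen: `"median-heuristic"`
#'   (median pairwise Euclidean distance of a seeded subsample of at most
#'   500 standardized training rows), `"fixed"` (use `gamma` as given), or
#'   `"inverse-dim-variance"` (`gamma = sqrt(d * mean feature variance / 2)`,
#'   the 1/(d * var) inverse-width convention).
#' @param gamma kernel width for `"fixed"` mode (> 0).
#' @param c_penalty soft-margin penalty C (> 0), default 1.
#' @return a list of class `svm_config`.
#' @export
svm_config <- function(gamma_mode = c("median-heuristic", "fixed",
                                      "inverse-dim-variance"),
                       gamma = NULL, c_penalty = 1) {
  gamma_mode <- match.arg(gamma_mode)
  if (gamma_mode == "fixed") {
    if (is.null(gamma) || !is.numeric(gamma) || gamma <= 0) {
      abort("fixed gamma_mode requires gamma > 0")
    }
  }
  if (!is.numeric(c_penalty) || c_penalty <= 0) abort("c_penalty must be > 0")
  structure(list(gamma_mode = gamma_mode, gamma = gamma,
                 c_penalty = c_penalty),
            class = "svm_config")
}

resolve_gamma <- function(x_scaled, config, seed) {
  switch(config$gamma_mode,
    "fixed" = config$gamma,
    "inverse-dim-variance" = {
      v <- mean(apply(x_scaled, 2, var))
      if (v <= 0) v <- 1
      sqrt(ncol(x_scaled) * v / 2)
    },
    "median-heuristic" = {
      n <- nrow(x_scaled)
      idx <- if (n > 500) {
        withr_seed(seed, sample.int(n, 500))
      } else seq_len(n)
      d <- stats::dist(x_scaled[idx, , drop = FALSE])
      g <- median(d)
      if (!is.finite(g) || g <= 0) 1 else g
    }
  )
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Train a one-against-all multi-class SVM
#'
#' Fits a per-feature standardizer on the training data (zero-variance
#' features get unit scale), then trains one binary soft-margin SVM per
#' class (that class against the rest) with the Gaussian radial basis
#' kernel. Prediction takes the class whose binary decision value is
#' largest. The binary subproblems are solved by libsvm (via e1071); the
#' architecture, scaling, kernel width and tie-breaking live here.
#'
#' @param features numeric matrix or tibble of training rows (an optional
#'   `label` column supplies `labels`).
#' @param labels integer class labels (>= 2 classes, >= 2 rows each).
#' @param config an [svm_config()].
#' @param seed integer seed (used by the median heuristic's subsampling).
#' @return an object of class `oaa_svm`.
#' @export
train_oaa <- function(features, labels = NULL, config = svm_config(),
                      seed = 1) {
  xl <- split_features_labels(features, labels)
  x <- xl$x
  labels <- xl$labels
  class_ids <- sort(unique(labels))
  if (length(class_ids) < 2) abort("need at least 2 classes")
  small <- class_ids[table(factor(labels, levels = class_ids)) < 2]
  if (length(small) > 0) {
    abort(paste0("class ", small[1], " has fewer than 2 samples"))
  }
  center <- colMeans(x)
  scale_sd <- apply(x, 2, stats::sd)
  scale_sd[scale_sd == 0 | !is.finite(scale_sd)] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_sd, "/")
  gamma <- resolve_gamma(xs, config, seed)
  libsvm_gamma <- 1 / (2 * gamma^2)
  binary <- lapply(class_ids, function(k) {
    y <- factor(ifelse(labels == k, "target", "rest"),
                levels = c("target", "rest"))
    fit <- e1071::svm(xs, y, type = "C-classification", kernel = "radial",
                      gamma = libsvm_gamma, cost = config$c_penalty,
                      scale = FALSE)
    dv <- attr(predict(fit, xs, decision.values = TRUE), "decision.values")[, 1]
    # orient decision values so larger means "more like class k"
    flip <- if (mean(dv[labels == k]) < mean(dv[labels != k])) -1 else 1
    list(fit = fit, flip = flip)
  })
  structure(
    list(binary_models = binary, class_ids = class_ids, config = config,
         gamma = gamma, center = center, scale = scale_sd,
         input_dim = ncol(x), seed = seed),
    class = "oaa_svm"
  )
}

oaa_decision_values <- function(model, x) {
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  vapply(model$binary_models, function(b) {
    if (!is.null(b$fit)) {
      dv <- unname(attr(predict(b$fit, xs, decision.values = TRUE),
                        "decision.values")[, 1])
    } else {
      # explicit form: sum_i alpha_i k(sv_i, x) - rho
      g <- 1 / (2 * model$gamma^2)
      cross <- xs %*% t(b$sv)
      d2 <- outer(rowSums(xs^2), rowSums(b$sv^2), "+") - 2 * cross
      dv <- exp(-g * pmax(d2, 0)) %*% b$coefs - b$rho
      dv <- as.numeric(dv)
    }
    b$flip * dv
  }, numeric(nrow(x)))
}

#' Serialize a one-against-all SVM to JSON
#'
#' Writes the model in explicit support-vector form (support vectors, dual
#' coefficients, intercepts, scaler, kernel width and config, all as JSON
#' arrays), so it can be reloaded without the training backend.
#'
#' @param model an [train_oaa()] model.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_oaa_json <- function(model, path) {
  binary <- lapply(model$binary_models, function(b) {
    list(sv = unname(b$fit$SV),
         coefs = as.numeric(b$fit$coefs),
         rho = b$fit$rho,
         flip = b$flip)
  })
  obj <- list(binary_models = binary,
              class_ids = model$class_ids,
              gamma = model$gamma,
              center = unname(model$center),
              scale = unname(model$scale),
              input_dim = model$input_dim,
              config = unclass(model$config),
              seed = model$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a one-against-all SVM from JSON
#' @param path JSON path written by [write_oaa_json()].
#' @return an `oaa_svm` whose decision functions are evaluated directly
#'   from the stored support vectors.
#' @export
read_oaa_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  binary <- lapply(seq_along(obj$binary_models$rho), function(i) {
    list(fit = NULL,
         sv = matrix(as.numeric(obj$binary_models$sv[[i]]),
                     nrow = nrow(obj$binary_models$sv[[i]])),
         coefs = as.numeric(obj$binary_models$coefs[[i]]),
         rho = obj$binary_models$rho[i],
         flip = obj$binary_models$flip[i])
  })
  cfg <- svm_config(obj$config$gamma_mode,
                    gamma = obj$config$gamma,
                    c_penalty = obj$config$c_penalty)
  structure(
    list(binary_models = binary, class_ids = as.integer(obj$class_ids),
         config = cfg, gamma = obj$gamma,
         center = as.numeric(obj$center), scale = as.numeric(obj$scale),
         input_dim = obj$input_dim, seed = obj$seed),
    class = "oaa_svm"
  )
}

# argmax over per-class decision values; exact ties go to the lowest class id
oaa_argmax <- function(decisions, class_ids) {
  if (length(decisions) == 0) return(integer(0))
  decisions <- matrix(decisions, ncol = length(class_ids))
  class_ids[apply(decisions, 1, which.max)]
}

#' Predict classes with a one-against-all SVM
#'
#' Applies the stored standardizer, evaluates every per-class decision
#' function, and returns the class with the maximum value; exact ties break
#' to the lowest class id.
#'
#' @param object an [train_oaa()] model.
#' @param newdata numeric matrix or tibble of rows to classify (a `label`
#'   column, if present, is ignored).
#' @param ... unused.
#' @return integer vector of predicted class ids.
#' @export
predict.oaa_svm <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[, setdiff(colnames(newdata), "label"),
                                 drop = FALSE])
  }
  if (nrow(newdata) == 0) return(integer(0))
  if (ncol(newdata) != object$input_dim) {
    abort(sprintf("feature dimension %d does not match model input_dim %d",
                  ncol(newdata), object$input_dim))
  }
  dv <- oaa_decision_values(object, newdata)
  as.integer(oaa_argmax(dv, object$class_ids))
}

#' @export
print.oaa_svm <- function(x, ...) {
  cat(sprintf("<oaa_svm: %d classes, %d-dim input, gamma = %.4g (%s), C = %g>\n",
              length(x$class_ids), x$input_dim, x$gamma,
              x$config$gamma_mode, x$config$c_penalty))
  invisible(x)
}

#' @export
glance.oaa_svm <- function(x, ...) {
  tibble(n_classes = length(x$class_ids),
         input_dim = x$input_dim,
         gamma = x$gamma,
         gamma_mode = x$config$gamma_mode,
         c_penalty = x$config$c_penalty,
         n_support_vectors = sum(vapply(x$binary_models,
                                        function(b) b$fit$tot.nSV, numeric(1))))
}

#' Grid-search SVM hyper-parameters by stratified validation accuracy
#'
#' A convenience helper (not a published protocol): splits the training
#' data once (stratified, seeded), trains on one part and scores candidate
#' (gamma, C) pairs on the other, returning the grid sorted by accuracy.
#'
#' @param features,labels training data as in [train_oaa()].
#' @param gammas numeric vector of kernel widths to try.
#' @param costs numeric vector of penalties to try.
#' @param val_fraction fraction held out for validation.
#' @param seed integer seed.
#' @return tibble with columns `gamma`, `c_penalty`, `accuracy`, sorted
#'   descending by accuracy.
#' @export
tune_oaa <- function(features, labels = NULL, gammas, costs = 1,
                     val_fraction = 0.3, seed = 1) {
  xl <- split_features_labels(features, labels)
  idx <- stratified_indices(xl$labels, 1 - val_fraction, seed)
  grid <- expand.grid(gamma = gammas, c_penalty = costs)
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- svm_config("fixed", gamma = grid$gamma[i],
                      c_penalty = grid$c_penalty[i])
    m <- train_oaa(xl$x[idx, , drop = FALSE], xl$labels[idx], cfg, seed)
    mean(predict(m, xl$x[-idx, , drop = FALSE]) == xl$labels[-idx])
  }, numeric(1))
  out <- as_tibble(grid)
  out$accuracy <- acc
  dplyr::arrange(out, dplyr::desc(.data$accuracy))
}
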