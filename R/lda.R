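#' Within-, between- and total-scatter matrices
#'
#' For features x_n with class labels, computes the class means m_k, global
#' mean m, within-class scatter `S_w = sum_k sum_{n in k} (x_n - m_k)(x_n - m_k)'`,
#' between-class scatter `S_B = sum_k N_k (m_k - m)(m_k - m)'`, and their
#' sum, the total scatter `S_T = S_B + S_w`, which equals the scatter of all
#' samples about the global mean.
#'
#' @param features numeric matrix or data frame of feature rows (a `label`
#'   column, if present, is used as `labels` and dropped from the features).
#' @param labels integer class labels, one per row (any coding; remapped
#'   internally). Ignored when `features` carries a `label` column.
#' @return an object of class `scatter_set`: list with `class_means`
#'   (K x d matrix), `global_mean`, `within`, `between`, `total`, `counts`,
#'   `n_total`, `n_classes`, `class_ids`.
#' @export
compute_scatter <- function(features, labels = NULL) {
  xl <- split_features_labels(features, labels)
  x <- xl$x
  labels <- xl$labels
  classes <- sort(unique(labels))
  k <- length(classes)
  if (k < 2) abort("need at least 2 classes")
  d <- ncol(x)
  counts <- integer(k)
  means <- matrix(0, k, d)
  sw <- matrix(0, d, d)
  for (i in seq_len(k)) {
    xi <- x[labels == classes[i], , drop = FALSE]
    counts[i] <- nrow(xi)
    if (counts[i] == 0) abort(paste0("class ", classes[i], " is empty"))
    means[i, ] <- colMeans(xi)
    xc <- sweep(xi, 2, means[i, ])
    sw <- sw + crossprod(xc)
  }
  n <- sum(counts)
  m <- as.numeric(counts %*% means) / n
  mc <- sweep(means, 2, m)
  sb <- crossprod(mc * sqrt(counts))
  # symmetrize against roundoff
  sw <- (sw + t(sw)) / 2
  sb <- (sb + t(sb)) / 2
  structure(
    list(class_means = means, global_mean = m,
         within = sw, between = sb, total = sb + sw,
         counts = counts, n_total = n, n_classes = k, class_ids = classes),
    class = "scatter_set"
  )
}

split_features_labels <- function(features, labels) {
  if (is.data.frame(features)) {
    if ("label" %in% names(features)) {
      labels <- features$label
      features <- features[, setdiff(names(features), "label"), drop = FALSE]
    }
    features <- as.matrix(features)
  }
  if (is.null(labels)) abort("labels are required (or a 'label' column)")
  if (length(labels) != nrow(features)) {
    abort("labels length must equal the number of feature rows")
  }
  if (!all(is.finite(features))) abort("features contain non-finite values")
  list(x = features, labels = as.integer(labels))
}

#' Fit a regularized Fisher linear discriminant projection
#'
#' Solves the generalized eigenproblem for `(S_w + eps*I)^{-1} S_B` via a
#' Cholesky whitening of the regularized within-class scatter, so the raw
#' eigendirections are `(S_w + eps*I)`-orthogonal. All `input_dim`
#' directions are returned (not only K - 1), sorted by eigenvalue
#' descending; directions past K - 1 carry (near-)zero eigenvalues and act
#' as nuisance coordinates. Each direction's sign is fixed so its first
#' nonzero component is positive, and the stored projection rows are
#' unit-normalized, making the fit deterministic across linear-algebra
#' backends.
#'
#' @param features numeric feature matrix or tibble (with optional `label`
#'   column, as in [compute_scatter()]).
#' @param labels integer labels (if not carried by `features`).
#' @param regularization ridge term eps added to the diagonal of S_w.
#'   The default `NULL` uses `1e-2 * trace(S_w) / d` (one percent of the
#'   mean within-class eigenvalue). A ridge is mandatory whenever
#'   d > N - K (always true for 385-dim spectra with modest sample sizes),
#'   and in that regime a near-zero ridge lets the discriminant exploit
#'   spurious low-variance noise directions that do not generalize, so the
#'   default applies visible shrinkage. Use `0` only when S_w is
#'   nonsingular and N is large relative to d.
#' @return an object of class `fisher_lda`: list with `projection`
#'   (directions x input_dim, unit-norm rows), `raw_projection`
#'   (pre-normalization, (S_w+eps I)-orthonormal), `eigenvalues`
#'   (descending), `regularization`, `input_dim`, `n_classes`.
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, mean = 4), 20))
#' fit <- fit_lda(x, rep(0:1, each = 20))
#' fit$eigenvalues[1] / max(fit$eigenvalues[2], 1e-300)  # rank-1 between-scatter
fit_lda <- function(features, labels = NULL, regularization = NULL) {
  sc <- compute_scatter(features, labels)
  d <- ncol(sc$within)
  eps <- regularization %||% (1e-2 * sum(diag(sc$within)) / d)
  if (eps < 0) abort("regularization must be >= 0")
  sw_reg <- sc$within + diag(eps, d)
  ch <- tryCatch(chol(sw_reg), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch))^2 <= 1e-10 * max(diag(sw_reg))) {
    abort("regularized within-class scatter is singular; set regularization > 0")
  }
  # whiten: M = C^-T S_B C^-1 is symmetric PSD with the same eigenvalues
  cinv <- backsolve(ch, diag(d))
  m <- t(cinv) %*% sc$between %*% cinv
  m <- (m + t(m)) / 2
  eg <- eigen(m, symmetric = TRUE)
  w_raw <- t(cinv %*% eg$vectors)   # rows are (S_w + eps I)-orthonormal
  w_raw <- fix_direction_signs(w_raw)
  norms <- sqrt(rowSums(w_raw^2))
  norms[norms == 0] <- 1
  structure(
    list(projection = w_raw / norms,
         raw_projection = w_raw,
         eigenvalues = pmax(eg$values, 0),
         regularization = eps,
         input_dim = d,
         n_classes = sc$n_classes,
         scatter = sc),
    class = "fisher_lda"
  )
}

fix_direction_signs <- function(w, tol = 1e-12) {
  for (i in seq_len(nrow(w))) {
    nz <- which(abs(w[i, ]) > tol * max(abs(w[i, ]), tol))
    if (length(nz) > 0 && w[i, nz[1]] < 0) w[i, ] <- -w[i, ]
  }
  w
}

#' Project features onto the leading discriminant coordinates
#'
#' `y = W' x` per row, in eigenvalue order, so "top five features" means
#' the first five coordinates.
#'
#' @param model a [fit_lda()] fit.
#' @param features matrix or tibble of rows with `input_dim` columns (a
#'   `label` column is carried through unchanged).
#' @param n_features how many leading coordinates to keep
#'   (1 .. number of directions).
#' @return a tibble with columns `ld1 ... ld{n_features}` (plus `label` if
#'   present in the input).
#' @export
lda_transform <- function(model, features, n_features = model$n_classes - 1) {
  labels <- NULL
  if (is.data.frame(features)) {
    if ("label" %in% names(features)) labels <- features$label
    features <- as.matrix(features[, setdiff(colnames(features), "label"),
                                   drop = FALSE])
  }
  if (n_features < 1 || n_features > nrow(model$projection)) {
    abort(paste0("n_features must be in 1..", nrow(model$projection)))
  }
  if (ncol(features) != model$input_dim) {
    abort(sprintf("feature dimension %d does not match model input_dim %d",
                  ncol(features), model$input_dim))
  }
  y <- features %*% t(model$projection[seq_len(n_features), , drop = FALSE])
  colnames(y) <- paste0("ld", seq_len(n_features))
  out <- as_tibble(y)
  if (!is.null(labels)) out$label <- labels
  out
}

#' @export
print.fisher_lda <- function(x, ...) {
  cat(sprintf("<fisher_lda: %d-dim input, %d classes, eps = %.3g>\n",
              x$input_dim, x$n_classes, x$regularization))
  cat("leading eigenvalues:",
      paste(signif(head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.fisher_lda <- function(x, ...) {
  tibble(direction = seq_along(x$eigenvalues),
         eigenvalue = x$eigenvalues,
         proportion = if (sum(x$eigenvalues) > 0)
           x$eigenvalues / sum(x$eigenvalues) else rep(0, length(x$eigenvalues)))
}

#' @export
glance.fisher_lda <- function(x, ...) {
  tibble(input_dim = x$input_dim,
         n_classes = x$n_classes,
         regularization = x$regularization,
         rank_between = sum(x$eigenvalues > 1e-6 * max(x$eigenvalues, 1e-300)))
}

#' Serialize an LDA fit to JSON
#' @param model a [fit_lda()] fit.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_lda_json <- function(model, path) {
  obj <- list(projection = unname(model$projection),
              eigenvalues = model$eigenvalues,
              regularization = model$regularization,
              input_dim = model$input_dim,
              n_classes = model$n_classes)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an LDA fit from JSON
#' @param path JSON path written by [write_lda_json()].
#' @return a `fisher_lda` object (without the scatter component).
#' @export
read_lda_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  proj <- matrix(as.numeric(obj$projection), nrow = nrow(obj$projection))
  structure(
    list(projection = proj,
         raw_projection = proj,
         eigenvalues = as.numeric(obj$eigenvalues),
         regularization = obj$regularization,
         input_dim = obj$input_dim,
         n_classes = obj$n_classes,
         scatter = NULL),
    class = "fisher_lda"
  )
}
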