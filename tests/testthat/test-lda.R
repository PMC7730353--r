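test_that("scatter matrices match the hand-computed 1-D example", {
  x <- matrix(c(0, 0, 2, 2), ncol = 1)
  sc <- compute_scatter(x, c(0, 0, 1, 1))
  expect_equal(as.numeric(sc$class_means), c(0, 2))
  expect_equal(sc$global_mean, 1)
  expect_equal(sc$within[1, 1], 0)
  expect_equal(sc$between[1, 1], 4)
  expect_equal(sc$total[1, 1], 4)
  expect_equal(sc$counts, c(2L, 2L))
})

test_that("total scatter identity S_T = S_B + S_w holds on random data", {
  set.seed(31)
  for (i in 1:20) {
    d <- sample(2:8, 1)
    k <- sample(2:4, 1)
    n <- sample(20:60, 1)
    x <- matrix(rnorm(n * d), n, d)
    labels <- sample(0:(k - 1), n, replace = TRUE)
    while (length(unique(labels)) < k) labels <- sample(0:(k - 1), n, TRUE)
    sc <- compute_scatter(x, labels)
    # identity against the directly computed total scatter
    expect_equal(sc$total, brute_total_scatter(x), tolerance = 1e-10)
    expect_equal(sc$between + sc$within, sc$total, tolerance = 1e-10)
    # symmetry and PSD of the parts
    expect_equal(sc$within, t(sc$within), tolerance = 1e-10)
    expect_equal(sc$between, t(sc$between), tolerance = 1e-10)
    expect_gt(min(eigen(sc$within, symmetric = TRUE)$values), -1e-8)
    expect_gt(min(eigen(sc$between, symmetric = TRUE)$values), -1e-8)
    # global mean is the count-weighted class-mean average
    expect_equal(sc$global_mean,
                 as.numeric(sc$counts %*% sc$class_means) / sc$n_total,
                 tolerance = 1e-12)
  }
})

test_that("scatter is invariant to relabeling classes", {
  set.seed(8)
  x <- matrix(rnorm(60), 20, 3)
  labels <- rep(0:1, each = 10)
  a <- compute_scatter(x, labels)
  b <- compute_scatter(x, 1 - labels)   # swap the two class ids
  expect_equal(a$within, b$within)
  expect_equal(a$between, b$between)
  expect_error(compute_scatter(x, rep(0, 20)), "at least 2 classes")
})

test_that("two-class fit matches the closed-form Fisher direction", {
  set.seed(17)
  x <- rbind(matrix(rnorm(200), 50, 4),
             sweep(matrix(rnorm(200), 50, 4), 2, c(3, -1, 2, 0), "+"))
  labels <- rep(0:1, each = 50)
  eps <- 1e-6
  fit <- fit_lda(x, labels, regularization = eps)
  sc <- compute_scatter(x, labels)
  closed <- solve(sc$within + diag(eps, 4),
                  sc$class_means[1, ] - sc$class_means[2, ])
  closed <- closed / sqrt(sum(closed^2))
  lead <- fit$projection[1, ]
  angle <- acos(min(1, abs(sum(lead * closed))))
  expect_lt(angle, 1e-6)
})

test_that("1-D input gives the identity projection up to sign", {
  x <- matrix(c(rnorm(10), rnorm(10, 5)), ncol = 1)
  fit <- fit_lda(x, rep(0:1, each = 10), regularization = 1e-9)
  expect_equal(abs(fit$projection[1, 1]), 1)
})

test_that("between-class rank bounds the meaningful eigenvalues at K - 1", {
  set.seed(23)
  k <- 5; d <- 20; n_per <- 30
  means <- matrix(rnorm(k * d, sd = 6), k, d)
  x <- do.call(rbind, lapply(1:k, function(i)
    sweep(matrix(rnorm(n_per * d), n_per, d), 2, means[i, ], "+")))
  labels <- rep(0:(k - 1), each = n_per)
  sc <- compute_scatter(x, labels)
  fit <- fit_lda(x, labels,
                 regularization = 1e-6 * sum(diag(sc$within)) / d)
  expect_equal(fit$eigenvalues, sort(fit$eigenvalues, decreasing = TRUE))
  expect_true(all(fit$eigenvalues[(k + 1):d] < 1e-6 * fit$eigenvalues[1]))
  # all d directions are returned, unit-norm rows
  expect_equal(nrow(fit$projection), d)
  expect_equal(rowSums(fit$projection^2), rep(1, d), tolerance = 1e-9)
})

test_that("leading direction maximizes the Rayleigh quotient", {
  set.seed(41)
  rayleigh <- function(w, sb, sw_reg) {
    as.numeric((w %*% sb %*% w) / (w %*% sw_reg %*% w))
  }
  for (i in 1:5) {
    d <- sample(3:8, 1)
    n <- 60
    labels <- sample(0:2, n, replace = TRUE)
    while (length(unique(labels)) < 3) labels <- sample(0:2, n, TRUE)
    x <- matrix(rnorm(n * d), n, d) + outer(labels, rnorm(d))
    eps <- 1e-4
    fit <- fit_lda(x, labels, regularization = eps)
    sc <- compute_scatter(x, labels)
    sw_reg <- sc$within + diag(eps, d)
    best <- rayleigh(fit$projection[1, ], sc$between, sw_reg)
    for (j in 1:500) {
      w <- rnorm(d); w <- w / sqrt(sum(w^2))
      expect_lte(rayleigh(w, sc$between, sw_reg), best + 1e-9)
    }
  }
})

test_that("fit is invariant to a constant shift of every sample", {
  set.seed(13)
  x <- matrix(rnorm(120), 40, 3)
  labels <- rep(0:1, each = 20)
  shift <- c(100, -50, 7)
  a <- fit_lda(x, labels, regularization = 1e-6)
  b <- fit_lda(sweep(x, 2, shift, "+"), labels, regularization = 1e-6)
  expect_equal(a$projection, b$projection, tolerance = 1e-9)
  expect_equal(a$eigenvalues, b$eigenvalues, tolerance = 1e-9)
})

test_that("raw directions are (S_w + eps I)-orthogonal", {
  set.seed(19)
  x <- matrix(rnorm(200), 50, 4)
  labels <- sample(0:2, 50, replace = TRUE)
  eps <- 1e-3
  fit <- fit_lda(x, labels, regularization = eps)
  sc <- compute_scatter(x, labels)
  g <- fit$raw_projection %*% (sc$within + diag(eps, 4)) %*%
    t(fit$raw_projection)
  off <- g - diag(diag(g))
  expect_lt(max(abs(off)), 1e-8)
})

test_that("lda_transform returns leading coordinates with contract checks", {
  set.seed(29)
  clusters <- separable_clusters(n_per_class = 25,
                                 centers = rbind(c(0, 0, 0), c(8, 8, 0)),
                                 sd = 0.5)
  fit <- fit_lda(clusters$x, clusters$labels, regularization = 1e-6)
  z1 <- lda_transform(fit, clusters$x, 1)
  # midpoint threshold separates two far clusters perfectly in 1-D
  mids <- tapply(z1$ld1, clusters$labels, mean)
  thr <- mean(mids)
  pred <- as.integer(
    if (mids[1] < thr) z1$ld1 > thr else z1$ld1 < thr)
  expect_equal(pred, clusters$labels)
  # full-rank transform preserves pairwise distances of W'x
  zf <- as.matrix(lda_transform(fit, clusters$x, 3))
  direct <- clusters$x %*% t(fit$projection)
  expect_equal(as.matrix(stats::dist(zf)), as.matrix(stats::dist(direct)),
               tolerance = 1e-9)
  # linearity: zero row maps to zero
  z0 <- lda_transform(fit, matrix(0, 1, 3), 2)
  expect_equal(as.numeric(as.matrix(z0)), c(0, 0))
  expect_error(lda_transform(fit, clusters$x, 0), "n_features")
  expect_error(lda_transform(fit, clusters$x, 4), "n_features")
  expect_error(lda_transform(fit, clusters$x[, 1:2], 1), "dimension")
})

test_that("singular within-scatter without ridge raises a helpful error", {
  x <- matrix(rnorm(12), 4, 3)   # N - K = 2 < d = 3 -> singular S_w
  expect_error(fit_lda(x, c(0, 0, 1, 1), regularization = 0),
               "regularization")
})

test_that("LDA model JSON round trip preserves the projection", {
  set.seed(37)
  x <- matrix(rnorm(90), 30, 3)
  labels <- rep(0:2, each = 10)
  fit <- fit_lda(x, labels)
  path <- withr::local_tempfile(fileext = ".json")
  write_lda_json(fit, path)
  back <- read_lda_json(path)
  expect_equal(back$projection, unname(fit$projection), tolerance = 1e-12)
  expect_equal(back$eigenvalues, fit$eigenvalues, tolerance = 1e-12)
  expect_equal(back$regularization, fit$regularization)
  z1 <- lda_transform(fit, x, 2)
  z2 <- lda_transform(back, x, 2)
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("tidy and glance summarize an LDA fit", {
  set.seed(2)
  x <- matrix(rnorm(100), 25, 4)
  fit <- fit_lda(x, rep(0:4, each = 5))
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_equal(sum(td$proportion), 1, tolerance = 1e-12)
  gl <- glance(fit)
  expect_equal(gl$n_classes, 5)
  expect_lte(gl$rank_between, 4)
})
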