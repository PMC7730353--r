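test_that("confusion matrix counts and per-class tallies are consistent", {
  cm <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 2L), 2, 2,
               dimnames = list(true = c("class_0", "class_1"),
                               predicted = c("class_0", "class_1"))),
               ignore_attr = "class")
  # perfect predictions give a diagonal matrix
  perfect <- confusion_matrix(c(0, 1, 2, 2), c(0, 1, 2, 2))
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  expect_error(confusion_matrix(c(0, 1), c(0, 1, 1)), "length")
  expect_error(confusion_matrix(c(0, 3), c(0, 1), n_classes = 2), "labels")
})

test_that("per-class Tp+Fp+Fn+Tn always equals the total count", {
  set.seed(91)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    n <- sample(10:80, 1)
    cm <- confusion_matrix(sample(0:(k - 1), n, TRUE),
                           sample(0:(k - 1), n, TRUE), n_classes = k)
    tl <- epshar:::confusion_tallies(cm)
    expect_true(all(tl$tp + tl$fp + tl$fn + tl$tn == n))
    expect_equal(sum(cm), n)
  }
})

test_that("confusion is equivariant under class permutation", {
  set.seed(14)
  truth <- sample(0:2, 40, TRUE)
  pred <- sample(0:2, 40, TRUE)
  perm <- c(2L, 0L, 1L)
  a <- confusion_matrix(truth, pred, 3)
  b <- confusion_matrix(perm[truth + 1], perm[pred + 1], 3)
  reorder <- order(perm)
  expect_equal(unclass(b)[perm + 1, perm + 1], unclass(a),
               ignore_attr = "dimnames")
})

test_that("metrics match the hand-computed two-class example", {
  # class 0: Tp=8, Fp=2, Fn=1, Tn=9 -> P=0.800, R=0.8889, F1=0.8421, acc=0.85
  cm <- confusion_matrix(c(rep(0, 9), rep(1, 11)),
                         c(rep(0, 8), 1, rep(1, 9), 0, 0), 2)
  tl <- epshar:::confusion_tallies(cm)
  expect_equal(tl$tp[1], 8)
  expect_equal(tl$fp[1], 2)
  expect_equal(tl$fn[1], 1)
  expect_equal(tl$tn[1], 9)
  rep <- eval_metrics(cm)
  expect_equal(rep$per_class$precision[1], 0.8000, tolerance = 1e-4)
  expect_equal(rep$per_class$recall[1], 0.8889, tolerance = 1e-4)
  expect_equal(rep$per_class$f1[1], 0.8421, tolerance = 1e-4)
  expect_equal(rep$accuracy, 0.85, tolerance = 1e-12)
})

test_that("micro precision = micro recall = accuracy on random confusions", {
  set.seed(101)
  for (i in 1:30) {
    k <- sample(2:7, 1)
    m <- matrix(rpois(k * k, 3), k, k)
    if (sum(m) == 0) m[1, 1] <- 1
    cm <- structure(m, dimnames = list(true = paste0("c", 1:k),
                                       predicted = paste0("c", 1:k)),
                    class = c("har_confusion", "matrix", "array"))
    rep <- eval_metrics(cm, averaging = "micro")
    expect_equal(rep$micro$precision, rep$accuracy, tolerance = 1e-12)
    expect_equal(rep$micro$recall, rep$accuracy, tolerance = 1e-12)
    expect_true(all(c(rep$accuracy, rep$precision, rep$recall, rep$f1) >= 0))
    expect_true(all(c(rep$accuracy, rep$precision, rep$recall, rep$f1) <= 1))
  }
})

test_that("perfect and empty-class confusions hit the metric edge cases", {
  perfect <- confusion_matrix(c(0, 1, 2), c(0, 1, 2), 3)
  rep <- eval_metrics(perfect)
  expect_equal(c(rep$accuracy, rep$precision, rep$recall, rep$f1),
               rep(1, 4))
  # a class never predicted and never true: 0/0 conventions -> 0
  cm <- confusion_matrix(c(0, 0, 1), c(0, 0, 1), 3)
  rep <- eval_metrics(cm)
  expect_equal(rep$per_class$precision[3], 0)
  expect_equal(rep$per_class$f1[3], 0)
  expect_error(eval_metrics(confusion_matrix(integer(0), integer(0), 2)),
               "zero total")
})

test_that("macro metrics are invariant under class relabeling", {
  set.seed(22)
  truth <- sample(0:3, 60, TRUE)
  pred <- sample(0:3, 60, TRUE)
  perm <- sample(0:3)
  a <- eval_metrics(confusion_matrix(truth, pred, 4))
  b <- eval_metrics(confusion_matrix(perm[truth + 1], perm[pred + 1], 4))
  expect_equal(a$precision, b$precision, tolerance = 1e-12)
  expect_equal(a$recall, b$recall, tolerance = 1e-12)
  expect_equal(a$accuracy, b$accuracy, tolerance = 1e-12)
})

test_that("stratified split honors per-class round(fraction * N_k)", {
  ds <- tiny_dataset(n_classes = 3, n_per_class = 10, channels = 1,
                     samples = 16)
  parts <- split_train_test(ds, 0.5, TRUE, seed = 4)
  expect_equal(as.numeric(table(window_labels(parts$train))), rep(5, 3))
  expect_equal(as.numeric(table(window_labels(parts$test))), rep(5, 3))
  # disjoint and exhaustive
  expect_equal(n_windows(parts$train) + n_windows(parts$test), 30)
  parts7 <- split_train_test(ds, 0.7, TRUE, seed = 4)
  expect_equal(as.numeric(table(window_labels(parts7$train))),
               rep(round(0.7 * 10), 3))
  # determinism: same seed twice gives the identical split
  again <- split_train_test(ds, 0.5, TRUE, seed = 4)
  expect_identical(as.data.frame(parts$train), as.data.frame(again$train))
  expect_error(split_train_test(ds, 1.2), "train_fraction")
})

test_that("k-fold assigns balanced folds and rotating mode partitions", {
  ds <- tiny_dataset(n_classes = 3, n_per_class = 11, channels = 1,
                     samples = 16)
  labels <- window_labels(ds)
  folds <- epshar:::fold_assignment(labels, 3, seed = 5)
  expect_equal(length(folds), 33)
  expect_true(all(table(folds) == 11))          # 33 windows -> 11/11/11
  # every window appears in exactly one test fold
  expect_setequal(unique(folds), 1:3)
  for (cl in 0:2) {
    expect_true(all(table(folds[labels == cl]) >= 3))
  }
  expect_error(epshar:::fold_assignment(labels, 12, seed = 1), "fewer than k")
})

test_that("cross-validation fits inside folds only (no test leakage)", {
  spec <- default_synthetic_spec(3, n_per_class = 12, samples = 32, seed = 6)
  ds <- generate_windows(spec)
  cfg <- har_config(n_features = 2, seed = 6)
  cv1 <- kfold_cv(ds, 3, cfg, seed = 6, mode = "single-split")
  # corrupt the VALUES of the test-fold windows; labels (hence fold
  # assignment) are unchanged, so the trained model must be identical
  test_idx <- which(cv1$fold_ids == 3)
  ds2 <- tibble::as_tibble(ds)
  scols <- grep("^s[0-9]+$", names(ds2), value = TRUE)
  bad_rows <- ds2$window_id %in% (sort(unique(ds2$window_id))[test_idx])
  set.seed(99)
  ds2[bad_rows, scols] <- ds2[bad_rows, scols] +
    matrix(rnorm(sum(bad_rows) * length(scols)), sum(bad_rows))
  ds2 <- har_dataset(ds2, sample_rate = attr(ds, "sample_rate"))
  cv2 <- kfold_cv(ds2, 3, cfg, seed = 6, mode = "single-split")
  expect_identical(cv2$fold_ids, cv1$fold_ids)
  expect_equal(cv2$models[[1]]$lda$projection,
               cv1$models[[1]]$lda$projection, tolerance = 1e-12)
})

test_that("rotating CV averages per-fold metrics consistently", {
  spec <- default_synthetic_spec(2, n_per_class = 9, samples = 32, seed = 3)
  ds <- generate_windows(spec)
  cv <- kfold_cv(ds, 3, har_config(n_features = 1, seed = 3), seed = 3)
  expect_length(cv$folds, 3)
  accs <- vapply(cv$folds, function(r) r$accuracy, numeric(1))
  expect_equal(cv$mean$accuracy, mean(accs), tolerance = 1e-12)
  # equal fold sizes: pooled accuracy equals the fold average
  pooled <- Reduce(`+`, lapply(cv$folds, function(r) unclass(r$confusion)))
  expect_equal(sum(diag(pooled)) / sum(pooled), cv$mean$accuracy,
               tolerance = 1e-12)
})

test_that("feature sweep emits the expected row structure", {
  spec <- default_synthetic_spec(3, n_per_class = 16, samples = 32, seed = 8)
  ds <- generate_windows(spec)
  parts <- split_train_test(ds, 0.5, TRUE, seed = 8)
  cfg <- har_config(seed = 8)
  sw <- feature_sweep(parts$train, parts$test, counts = c(2, 5, "all"),
                      config = cfg, seed = 8)
  expect_equal(sw$n_features, c("2", "5", "all"))
  expect_true(all(as.matrix(sw[, -1]) >= 0 & as.matrix(sw[, -1]) <= 100))
  # single "all" row
  sw1 <- feature_sweep(parts$train, parts$test, counts = "all",
                       config = cfg, seed = 8)
  expect_equal(nrow(sw1), 1)
  expect_error(feature_sweep(parts$train, parts$test, counts = 10000,
                             config = cfg), "available directions")
  expect_error(feature_sweep(parts$train, parts$test,
                             counts = character(0)), "non-empty")
  # CSV writer formats percentages to 2 decimals
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(sw, path)
  lines <- readLines(path)
  expect_length(lines, 4)
  expect_match(lines[2], "^2,[0-9]+\\.[0-9]{2},")
})

test_that("evaluation report serializes to JSON and confusion to CSV", {
  cm <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), 2,
                         class_names = c("rest", "move"))
  rep <- eval_metrics(cm)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_eval_report(rep, jp, cp)
  obj <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(obj$accuracy, rep$accuracy)
  expect_equal(obj$class_names, c("rest", "move"))
  csv <- readr::read_csv(cp, show_col_types = FALSE)
  expect_equal(names(csv), c("true", "rest", "move"))
})
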