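# Accuracy measures, split plans, cross-validation drivers, ROC/AUC.

test_that("compute_metrics reproduces known confusion-matrix identities", {
  # perfect prediction
  r <- compute_metrics(confusion_counts(TP = 10, FP = 0, TN = 10, FN = 0))
  expect_equal(r$MCC, 1)
  expect_equal(r$AC, 100)
  expect_equal(r$SN, 100)
  expect_equal(r$SP, 100)
  # chance symmetry
  expect_equal(compute_metrics(confusion_counts(5, 5, 5, 5))$MCC, 0)
  # total inversion
  inv <- compute_metrics(confusion_counts(TP = 0, FP = 7, TN = 0, FN = 7))
  expect_equal(inv$MCC, -1)
  expect_equal(inv$AC, 0)
  # zero-denominator convention
  expect_equal(compute_metrics(confusion_counts(TP = 0, FP = 0, TN = 5, FN = 5))$MCC, 0)
  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)), "zero")
  expect_error(confusion_counts(-1, 0, 0, 0), "nonnegative")
})

test_that("MCC stays in [-1,1] and hits the endpoints only at the exact cases", {
  set.seed(11)
  for (i in 1:200) {
    cc <- confusion_counts(sample(0:20, 1), sample(0:20, 1),
                           sample(0:20, 1), sample(0:20, 1))
    if (cc$TP + cc$FP + cc$TN + cc$FN == 0) next
    m <- compute_metrics(cc)$MCC
    expect_gte(m, -1); expect_lte(m, 1)
    if (m == 1) expect_true(cc$FP == 0 && cc$FN == 0 && cc$TP > 0 && cc$TN > 0)
    if (m == -1) expect_true(cc$TP == 0 && cc$TN == 0 && cc$FP > 0 && cc$FN > 0)
    # SN + miss rate = 100
    if (cc$TP + cc$FN > 0) {
      expect_equal(compute_metrics(cc)$SN + 100 * cc$FN / (cc$TP + cc$FN), 100)
    }
  }
})

test_that("percentage_split gives floor(n*pct/100) train, is seeded, covers the set", {
  plan <- percentage_split(584, 93, seed = 42)
  expect_length(plan$train, 543L)
  expect_length(plan$test, 41L)
  expect_setequal(c(plan$train, plan$test), 1:584)
  plan2 <- percentage_split(584, 93, seed = 42)
  expect_identical(plan$train, plan2$train)
  expect_length(percentage_split(10, 50, seed = 1)$train, 5L)
  expect_error(percentage_split(10, 100, seed = 1), "between 0 and 100")
  expect_error(percentage_split(10, 0, seed = 1), "between 0 and 100")
  expect_error(percentage_split(3, 10, seed = 1), "empty")
})

test_that("k-fold folds partition the index set; k = n matches LOOCV structure", {
  bench <- make_benchmark(8, 8, seed = 6, flank = 3)
  cv <- k_fold_cv(bench$encoded, k = 4, seed = 3)
  fold <- attr(cv, "fold_assignment")
  expect_length(fold, 16L)
  expect_setequal(unique(fold), 1:4)
  # every instance tested exactly once
  expect_equal(as.vector(table(fold)), rep(4L, 4))
  # k = n: every fold is a singleton, identical structure to loocv
  kn <- k_fold_cv(bench$encoded, k = 16, seed = 3)
  expect_equal(as.vector(table(attr(kn, "fold_assignment"))), rep(1L, 16))
  lo <- loocv(bench$encoded, seed = 3)
  expect_identical(attr(lo, "fold_assignment"), attr(kn, "fold_assignment"))
  expect_equal(lo$AC, kn$AC)
  expect_identical(lo$protocol, "LOOCV")
  expect_error(k_fold_cv(bench$encoded, k = 1, seed = 1), "k must be")
  expect_error(k_fold_cv(bench$encoded, k = 17, seed = 1), "k must be")
})

test_that("stratified folds keep class counts near-equal per fold", {
  bench <- make_benchmark(20, 20, seed = 10, flank = 3)
  cv <- k_fold_cv(bench$encoded, k = 4, seed = 5, stratified = TRUE)
  fold <- attr(cv, "fold_assignment")
  pos_per_fold <- table(fold[bench$encoded$label == "positive"])
  expect_true(all(pos_per_fold == 5))
})

test_that("pooled confusion counts equal a direct recount of per-fold predictions", {
  bench <- make_benchmark(15, 15, seed = 4, flank = 3)
  cv <- k_fold_cv(bench$encoded, k = 5, seed = 9)
  folds <- attr(cv, "folds")
  tp <- sum(vapply(folds, function(f) f$counts$TP, numeric(1)))
  fp <- sum(vapply(folds, function(f) f$counts$FP, numeric(1)))
  tn <- sum(vapply(folds, function(f) f$counts$TN, numeric(1)))
  fn <- sum(vapply(folds, function(f) f$counts$FN, numeric(1)))
  expect_equal(cv$counts$TP, tp)
  expect_equal(cv$counts$FP, fp)
  expect_equal(cv$counts$TN, tn)
  expect_equal(cv$counts$FN, fn)
  expect_equal(tp + fp + tn + fn, 30)
})

test_that("self-consistency of a memorizing classifier is perfect", {
  # a 1-NN-style stub that memorizes the training set
  memorizer <- function(data, seed) {
    structure(list(x = data$x, y = data$label), class = "memorizer_stub")
  }
  assign("predict.memorizer_stub", function(object, newdata, ...) {
    x <- if (inherits(newdata, "encoded_dataset")) newdata$x else newdata
    idx <- apply(x, 1, function(v) which.min(colSums((t(object$x) - v)^2)))
    data.frame(label = object$y[idx],
               vote_fraction = as.numeric(object$y[idx] == "positive"))
  }, envir = globalenv())
  on.exit(rm("predict.memorizer_stub", envir = globalenv()))
  bench <- make_benchmark(10, 10, seed = 2, flank = 3)
  r <- self_consistency(bench$encoded, trainer = memorizer, seed = 1)
  expect_equal(r$AC, 100)
  expect_equal(r$MCC, 1)
})

test_that("a constant-positive classifier gives SN 100, SP 0 on balanced data", {
  always_pos <- function(data, seed) structure(list(), class = "constpos_stub")
  assign("predict.constpos_stub", function(object, newdata, ...) {
    n <- if (inherits(newdata, "encoded_dataset")) nrow(newdata$x) else nrow(newdata)
    data.frame(label = rep("positive", n), vote_fraction = rep(1, n))
  }, envir = globalenv())
  on.exit(rm("predict.constpos_stub", envir = globalenv()))
  bench <- make_benchmark(10, 10, seed = 2, flank = 3)
  r <- self_consistency(bench$encoded, trainer = always_pos, seed = 1)
  expect_equal(r$SN, 100)
  expect_equal(r$SP, 0)
  expect_equal(r$AC, 50)
})

test_that("AUC matches the brute-force pair statistic, including ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3),
                       c("positive", "negative", "positive", "negative"))$auc, 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c("positive", "positive", "negative", "negative"))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c("positive", "negative"), 3))$auc, 0.5)
  set.seed(31)
  for (i in 1:40) {
    n <- sample(4:15, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    truth <- sample(c("positive", "negative"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    expect_equal(roc_auc(scores, truth)$auc, oracle_auc(scores, truth))
  }
  expect_error(roc_auc(c(1, 0), c("positive", "positive")), "both classes")
})

test_that("AUC is invariant under monotone transforms and flips under inversion", {
  set.seed(13)
  scores <- runif(30)
  truth <- sample(c("positive", "negative"), 30, replace = TRUE)
  truth[1:2] <- c("positive", "negative")
  a <- roc_auc(scores, truth)$auc
  expect_equal(roc_auc(exp(3 * scores), truth)$auc, a)
  expect_equal(roc_auc(-scores, truth)$auc, 1 - a)
})

test_that("ROC points run from (0,0) to (1,1) and are monotone", {
  set.seed(17)
  roc <- roc_auc(runif(40), sample(c("positive", "negative"), 40, TRUE,
                                   prob = c(.5, .5)))$roc
  expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("AUC agrees with an independent ROC implementation on the same scores", {
  skip_if_not_installed("pROC")
  set.seed(19)
  scores <- runif(50)
  truth <- sample(c("positive", "negative"), 50, replace = TRUE)
  truth[1:2] <- c("positive", "negative")
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = truth, predictor = scores, levels = c("negative", "positive"),
    direction = "<")))
  expect_equal(roc_auc(scores, truth)$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("window_sweep reports one row per window size with class composition", {
  bench <- make_benchmark(25, 25, seed = 20, flank = 10)
  tab <- load_paper_table()
  sweep <- window_sweep(bench$windows, tab, flanks = c(3L, 5L, 10L),
                        protocol = "split", train_pct = 80, seed = 30)
  expect_equal(nrow(sweep), 3L)
  expect_identical(sweep$window, c(7L, 11L, 21L))
  expect_true(all(c("pos_train", "neg_train", "pos_test", "neg_test") %in% names(sweep)))
  expect_equal(sweep$pos_train + sweep$neg_train, rep(40L, 3))  # floor(50*0.8)
  expect_equal(sweep$pos_test + sweep$neg_test, rep(10L, 3))
  # same seed -> identical table
  sweep2 <- window_sweep(bench$windows, tab, flanks = c(3L, 5L, 10L),
                         protocol = "split", train_pct = 80, seed = 30)
  expect_identical(sweep, sweep2)
})

test_that("metrics JSON carries raw and display-rounded values", {
  r <- compute_metrics(confusion_counts(23, 1, 17, 0), protocol = "demo")
  path <- tempfile(fileext = ".json")
  write_metrics_json(r, path)
  doc <- jsonlite::read_json(path)
  expect_equal(doc$display$AC, 97.56)
  expect_equal(doc$raw$SP, 100 * 17 / 18, tolerance = 1e-12)
  expect_equal(doc$counts$TP, 23)
})
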