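# Evaluation protocols and accuracy measures.
#
# SN = TP/(TP+FN), SP = TN/(TN+FP), AC = (TP+TN)/total (all as percentages),
# MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), with MCC
# defined as 0 when the denominator vanishes.

#' Construct confusion counts
#' @param TP,FP,TN,FN nonnegative integer counts.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0)) stop("confusion counts must be nonnegative", call. = FALSE)
  structure(as.list(counts), class = "confusion_counts")
}

# Tally predicted vs true labels into confusion counts.
tally_confusion <- function(predicted, truth) {
  confusion_counts(
    TP = sum(predicted == "positive" & truth == "positive"),
    FP = sum(predicted == "positive" & truth == "negative"),
    TN = sum(predicted == "negative" & truth == "negative"),
    FN = sum(predicted == "negative" & truth == "positive")
  )
}

#' Accuracy measures from confusion counts
#'
#' @param counts a `confusion_counts` object (or list with TP/FP/TN/FN).
#' @param auc optional AUC to attach to the report.
#' @param protocol free-text tag naming the evaluation protocol.
#' @return object of class `metrics_report` with `AC`, `SN`, `SP` (percent),
#'   `MCC`, `AUC`, `counts`, `protocol`. `SN`/`SP` are `NA` when their
#'   denominator is zero.
#' @export
compute_metrics <- function(counts, auc = NA_real_, protocol = "") {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total == 0) stop("all confusion counts are zero; no metrics defined", call. = FALSE)
  sn <- if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_
  sp <- if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_
  ac <- 100 * (TP + TN) / total
  den <- sqrt((TP + FP)) * sqrt((TP + FN)) * sqrt((TN + FP)) * sqrt((TN + FN))
  mcc <- if (den == 0) 0 else (TP * TN - FP * FN) / den
  structure(
    list(AC = ac, SN = sn, SP = sp, MCC = mcc, AUC = auc,
         counts = counts, protocol = protocol),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("[%s] AC %.2f%%  SN %.2f%%  SP %.2f%%  MCC %.2f%s  (TP %d FP %d TN %d FN %d)\n",
              x$protocol, x$AC, x$SN, x$SP, x$MCC,
              if (is.na(x$AUC)) "" else sprintf("  AUC %.2f", x$AUC),
              x$counts$TP, x$counts$FP, x$counts$TN, x$counts$FN))
  invisible(x)
}

#' Percentage split of a dataset
#'
#' Seeded uniform shuffle; the first `floor(n * train_pct / 100)` shuffled
#' instances train, the remainder test.
#'
#' @param n number of instances, or an `encoded_dataset`.
#' @param train_pct training percentage in (0, 100); the resulting test set
#'   must be nonempty.
#' @param seed shuffle seed, recorded in the plan.
#' @return object of class `split_plan` with `train`, `test`, `train_pct`,
#'   `seed`.
#' @export
percentage_split <- function(n, train_pct, seed) {
  if (inherits(n, "encoded_dataset")) n <- nrow(n$x)
  if (train_pct <= 0 || train_pct >= 100) {
    stop("train_pct must be strictly between 0 and 100", call. = FALSE)
  }
  n_train <- floor(n * train_pct / 100)
  if (n_train < 1L || n_train >= n) {
    stop("split leaves an empty train or test set (n = ", n,
         ", train_pct = ", train_pct, ")", call. = FALSE)
  }
  set.seed(seed)
  perm <- sample.int(n)
  structure(
    list(train = sort(perm[seq_len(n_train)]), test = sort(perm[(n_train + 1L):n]),
         train_pct = train_pct, seed = as.integer(seed)),
    class = "split_plan"
  )
}

#' Default model builder used by the evaluation drivers
#'
#' Returns a trainer closure `(encoded_dataset, seed) -> sumo_forest` with
#' the given forest settings (10 trees by default).
#' @param n_trees,mtry,... forwarded to [train_forest()].
#' @export
default_trainer <- function(n_trees = 10L, mtry = NULL, ...) {
  function(data, seed) train_forest(data, n_trees = n_trees, mtry = mtry, seed = seed, ...)
}

#' Evaluate a train/test split
#'
#' @param data an `encoded_dataset`.
#' @param plan a `split_plan` from [percentage_split()].
#' @param trainer function `(encoded_dataset, seed) -> model` with a
#'   [predict()] method returning `label` and `vote_fraction`; defaults to a
#'   10-tree forest.
#' @param seed seed forwarded to the trainer.
#' @return a `metrics_report` (AUC from test-set vote fractions).
#' @export
evaluate_split <- function(data, plan, trainer = default_trainer(), seed = 1L) {
  model <- trainer(subset_encoded(data, plan$train), seed)
  pred <- predict(model, subset_encoded(data, plan$test))
  truth <- data$label[plan$test]
  auc <- if (length(unique(truth)) == 2L) roc_auc(pred$vote_fraction, truth)$auc else NA_real_
  compute_metrics(tally_confusion(pred$label, truth), auc = auc,
                  protocol = sprintf("split %g%%", plan$train_pct))
}

#' k-fold cross-validation
#'
#' Seeded partition into `k` near-equal folds; each fold is tested exactly
#' once against a model trained on the remaining folds, and the pooled
#' confusion counts are reported (AUC over pooled vote fractions).
#'
#' @param data an `encoded_dataset`.
#' @param k number of folds, `2 <= k <= n`.
#' @param trainer as in [evaluate_split()].
#' @param seed seed for fold assignment and per-fold trainer seeds.
#' @param stratified balance class proportions across folds (off by default).
#' @return a `metrics_report` with attribute `folds` (list of per-fold
#'   reports) and attribute `fold_assignment`.
#' @export
k_fold_cv <- function(data, k, trainer = default_trainer(), seed = 1L,
                      stratified = FALSE) {
  n <- nrow(data$x)
  if (k < 2L || k > n) stop("k must be in [2, n]; got k = ", k, ", n = ", n, call. = FALSE)
  set.seed(seed)
  if (stratified) {
    fold <- integer(n)
    for (cls in unique(data$label)) {
      i <- which(data$label == cls)
      fold[i] <- sample(rep_len(seq_len(k), length(i)))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  fold_seeds <- sample.int(.Machine$integer.max - 1L, k)
  pooled_pred <- character(n)
  pooled_vf <- numeric(n)
  fold_reports <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    model <- trainer(subset_encoded(data, which(fold != f)), fold_seeds[f])
    pred <- predict(model, subset_encoded(data, test_idx))
    pooled_pred[test_idx] <- pred$label
    pooled_vf[test_idx] <- pred$vote_fraction
    truth_f <- data$label[test_idx]
    fold_reports[[f]] <- compute_metrics(
      tally_confusion(pred$label, truth_f),
      auc = if (length(unique(truth_f)) == 2L) roc_auc(pred$vote_fraction, truth_f)$auc else NA_real_,
      protocol = sprintf("fold %d/%d", f, k)
    )
  }
  auc <- if (length(unique(data$label)) == 2L) roc_auc(pooled_vf, data$label)$auc else NA_real_
  rep <- compute_metrics(tally_confusion(pooled_pred, data$label), auc = auc,
                         protocol = sprintf("%d-fold CV", k))
  attr(rep, "folds") <- fold_reports
  attr(rep, "fold_assignment") <- fold
  rep
}

#' Leave-one-out cross-validation (jackknife)
#'
#' [k_fold_cv()] with `k = n`.
#' @inheritParams k_fold_cv
#' @export
loocv <- function(data, trainer = default_trainer(), seed = 1L) {
  rep <- k_fold_cv(data, k = nrow(data$x), trainer = trainer, seed = seed)
  rep$protocol <- "LOOCV"
  rep
}

#' Self-consistency test
#'
#' Trains on the full dataset and evaluates on the same instances: an
#' optimistic upper bound on performance.
#' @inheritParams k_fold_cv
#' @export
self_consistency <- function(data, trainer = default_trainer(), seed = 1L) {
  model <- trainer(data, seed)
  pred <- predict(model, data)
  auc <- if (length(unique(data$label)) == 2L) roc_auc(pred$vote_fraction, data$label)$auc else NA_real_
  compute_metrics(tally_confusion(pred$label, data$label), auc = auc,
                  protocol = "self-consistency")
}

#' ROC curve and AUC
#'
#' AUC by the rank statistic (Mann-Whitney with mid-ranks for ties), which
#' equals trapezoidal integration of the ROC over all score thresholds.
#'
#' @param scores numeric scores (e.g. vote fractions); larger = more positive.
#' @param truth labels `"positive"`/`"negative"`; both classes required.
#' @return list with `auc` and `roc` (data.frame of `fpr`, `tpr` points from
#'   threshold sweep, including (0,0) and (1,1)).
#' @export
roc_auc <- function(scores, truth) {
  pos <- truth == "positive"
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L) {
    stop("AUC requires both classes in the truth labels", call. = FALSE)
  }
  r <- rank(scores)                      # mid-ranks for ties
  auc <- (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  last_of_tie <- c(scores[ord][-1] != scores[ord][-length(scores)], TRUE)
  roc <- data.frame(fpr = c(0, fp[last_of_tie] / nn), tpr = c(0, tp[last_of_tie] / np))
  list(auc = auc, roc = roc)
}

#' Window-size sweep
#'
#' Evaluates the same underlying sites at several window sizes (wide windows
#' trimmed down, see [shrink_windows()]) under one protocol, producing one
#' report row per window size with train/test class composition.
#'
#' @param dataset a `window_dataset` at the widest flank.
#' @param table a `property_table`.
#' @param flanks flank sizes to compare (default 3, 5, 10).
#' @param protocol `"split"`, `"kfold"`, or `"self"`.
#' @param train_pct training percentage for `protocol = "split"`.
#' @param k folds for `protocol = "kfold"`.
#' @param trainer as in [evaluate_split()].
#' @param seed seed shared across window sizes so they see the same split.
#' @return data.frame with one row per window size: `window`, `train_pct`/`k`,
#'   `pos_train`, `neg_train`, `AC`, `SN`, `SP`, `MCC`, `AUC`, `pos_test`,
#'   `neg_test`.
#' @export
window_sweep <- function(dataset, table, flanks = c(3L, 5L, 10L),
                         protocol = c("split", "kfold", "self"),
                         train_pct = 93, k = 10L,
                         trainer = default_trainer(), seed = 1L) {
  protocol <- match.arg(protocol)
  if (any(flanks > ws_flank(dataset))) {
    stop("requested flank exceeds the dataset's flank ", ws_flank(dataset), call. = FALSE)
  }
  rows <- lapply(flanks, function(f) {
    enc <- encode_dataset(shrink_windows(dataset, f), table)
    n <- nrow(enc$x)
    if (protocol == "split") {
      plan <- percentage_split(n, train_pct, seed)
      rep <- evaluate_split(enc, plan, trainer, seed)
      tr <- plan$train; te <- plan$test
    } else if (protocol == "kfold") {
      rep <- k_fold_cv(enc, k, trainer, seed)
      tr <- seq_len(n); te <- seq_len(n)
    } else {
      rep <- self_consistency(enc, trainer, seed)
      tr <- seq_len(n); te <- seq_len(n)
    }
    data.frame(
      window = 2L * f + 1L,
      protocol = rep$protocol,
      pos_train = sum(enc$label[tr] == "positive"),
      neg_train = sum(enc$label[tr] == "negative"),
      AC = rep$AC, SN = rep$SN, SP = rep$SP, MCC = rep$MCC, AUC = rep$AUC,
      pos_test = sum(enc$label[te] == "positive"),
      neg_test = sum(enc$label[te] == "negative"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a metrics report (or sweep table) as JSON
#'
#' Raw (unrounded) values are emitted alongside display-rounded ones
#' (AC/SN/SP to 2 decimals as percent, MCC to 2 decimals).
#'
#' @param report a `metrics_report` or a [window_sweep()] data.frame.
#' @param path output file.
#' @export
write_metrics_json <- function(report, path) {
  obj <- if (inherits(report, "metrics_report")) {
    list(protocol = report$protocol,
         raw = list(AC = report$AC, SN = report$SN, SP = report$SP,
                    MCC = report$MCC, AUC = report$AUC),
         display = list(AC = round(report$AC, 2), SN = round(report$SN, 2),
                        SP = round(report$SP, 2), MCC = round(report$MCC, 2)),
         counts = unclass(report$counts))
  } else {
    report
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write ROC points as TSV for plotting
#' @param roc data.frame of `fpr`, `tpr` from [roc_auc()].
#' @param path output file.
#' @export
write_roc_tsv <- function(roc, path) {
  utils::write.table(roc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
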