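# Independent brute-force references, deliberately written with naive scalar
# loops so they share no code path with the package implementation.

# Exhaustive CART-style Gini tree: every (feature, threshold) pair is tried;
# the strictly smallest weighted impurity wins, ties to the lowest feature
# index then the lowest threshold; splits must strictly decrease impurity;
# leaf ties label negative.
oracle_tree <- function(x, y01) {
  gini <- function(p, n) {
    if (n == 0) return(0)
    1 - (p / n)^2 - ((n - p) / n)^2
  }
  grow <- function(idx) {
    np <- 0
    for (i in idx) np <- np + y01[i]
    nn <- length(idx) - np
    leaf <- list(leaf = TRUE, label = if (np > nn) "positive" else "negative")
    if (np == 0 || nn == 0) return(leaf)
    n <- length(idx)
    g0 <- gini(np, n)
    best_imp <- Inf
    best_f <- NA
    best_thr <- NA
    for (f in seq_len(ncol(x))) {
      vals <- sort(unique(x[idx, f]))
      if (length(vals) < 2) next
      for (vi in seq_len(length(vals) - 1)) {
        thr <- (vals[vi] + vals[vi + 1]) / 2
        pl <- 0; nl <- 0; pr <- 0; nr <- 0
        for (i in idx) {
          if (x[i, f] <= thr) { nl <- nl + 1; pl <- pl + y01[i] }
          else { nr <- nr + 1; pr <- pr + y01[i] }
        }
        imp <- (nl * gini(pl, nl) + nr * gini(pr, nr)) / n
        if (imp < best_imp) { best_imp <- imp; best_f <- f; best_thr <- thr }
      }
    }
    if (!is.finite(best_imp) || best_imp >= g0) return(leaf)
    L <- idx[x[idx, best_f] <= best_thr]
    R <- idx[x[idx, best_f] > best_thr]
    list(leaf = FALSE, feature = best_f, threshold = best_thr,
         left = grow(L), right = grow(R))
  }
  grow(seq_along(y01))
}

oracle_predict <- function(node, v) {
  while (!node$leaf) {
    node <- if (v[node$feature] <= node$threshold) node$left else node$right
  }
  node$label
}

# AUC by brute force over all positive-negative score pairs (ties count 1/2).
oracle_auc <- function(scores, truth) {
  ps <- scores[truth == "positive"]
  ns <- scores[truth == "negative"]
  tot <- 0
  for (a in ps) for (b in ns) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(ps) * length(ns))
}

# Wrap a matrix + labels as a minimal encoded dataset for train_forest().
as_encoded <- function(x, label) {
  colnames(x) <- sprintf("f%d", seq_len(ncol(x)))
  structure(
    list(x = x, label = label, feature_names = colnames(x),
         flank = NA_integer_,
         provenance = data.frame(accession = rep(NA_character_, nrow(x)),
                                 position = rep(NA_integer_, nrow(x)))),
    class = "encoded_dataset"
  )
}

# Exhaustive-tree forest configuration (deterministic, no bagging).
single_exhaustive_tree <- function(data) {
  train_forest(data, n_trees = 1L, mtry = ncol(data$x), seed = 1L,
               bootstrap = FALSE)
}
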