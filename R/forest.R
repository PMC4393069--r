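# Bagged ensemble of randomized Gini decision trees, majority vote.
#
# Each tree is grown on a bootstrap sample of the training instances; at each
# node a uniform random subset of `mtry` features is considered and the best
# axis-aligned split by Gini impurity decrease is taken, with thresholds at
# midpoints of adjacent distinct values. Trees grow to purity (minimum leaf
# size 1 by default). A master seed derives one independent stream per tree,
# so retraining with the same data and seed reproduces the model exactly.
#
# Deterministic tie-breaking, identical in the split search below and in any
# exact re-derivation: among candidate features the strictly smallest weighted
# impurity wins, ties going to the lowest feature index; within a feature, to
# the lowest threshold. A split must strictly decrease impurity. Leaf label is
# the majority class; an exact tie labels negative.

# Best split for one feature over instances idx. Returns c(impurity, threshold)
# or NULL when no valid split exists.
best_split_feature <- function(xcol, y01, min_leaf) {
  n <- length(xcol)
  ord <- order(xcol)
  xs <- xcol[ord]
  ys <- y01[ord]
  cp <- cumsum(ys)
  totp <- cp[n]
  cut_at <- which(xs[-n] < xs[-1])                 # split between i and i+1
  cut_at <- cut_at[cut_at >= min_leaf & (n - cut_at) >= min_leaf]
  if (length(cut_at) == 0L) return(NULL)
  nl <- cut_at
  nr <- n - nl
  pl <- cp[cut_at]
  pr <- totp - pl
  gl <- 1 - (pl / nl)^2 - ((nl - pl) / nl)^2
  gr <- 1 - (pr / nr)^2 - ((nr - pr) / nr)^2
  imp <- (nl * gl + nr * gr) / n
  best <- which.min(imp)                           # first minimum = lowest threshold
  c(imp[best], (xs[cut_at[best]] + xs[cut_at[best] + 1L]) / 2)
}

# Grow one tree; returns a data.frame of nodes (row 1 = root).
grow_tree <- function(x, y01, mtry, min_leaf) {
  p <- ncol(x)
  nodes <- vector("list", 0L)
  grow <- function(idx) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- NA  # reserve slot; always overwritten below
    np <- sum(y01[idx]); nn <- length(idx) - np
    make_leaf <- function() {
      nodes[[id]] <<- list(feature = NA_integer_, threshold = NA_real_,
                           left = NA_integer_, right = NA_integer_,
                           label = if (np > nn) "positive" else "negative",
                           n_pos = np, n_neg = nn)
      id
    }
    if (np == 0L || nn == 0L || length(idx) < 2L * min_leaf) return(make_leaf())
    ntot <- length(idx)
    g0 <- 1 - (np / ntot)^2 - (nn / ntot)^2
    feats <- if (mtry >= p) seq_len(p) else sort(sample.int(p, mtry))
    best_imp <- Inf; best_f <- NA_integer_; best_thr <- NA_real_
    for (f in feats) {
      sp <- best_split_feature(x[idx, f], y01[idx], min_leaf)
      if (!is.null(sp) && sp[1] < best_imp) {      # strict < : lowest index wins ties
        best_imp <- sp[1]; best_f <- f; best_thr <- sp[2]
      }
    }
    if (!is.finite(best_imp) || best_imp >= g0) return(make_leaf())
    go_left <- x[idx, best_f] <= best_thr
    l <- grow(idx[go_left])
    r <- grow(idx[!go_left])
    nodes[[id]] <<- list(feature = best_f, threshold = best_thr,
                         left = l, right = r, label = NA_character_,
                         n_pos = np, n_neg = nn)
    id
  }
  grow(seq_along(y01))
  data.frame(
    feature = vapply(nodes, `[[`, integer(1), "feature"),
    threshold = vapply(nodes, `[[`, numeric(1), "threshold"),
    left = vapply(nodes, `[[`, integer(1), "left"),
    right = vapply(nodes, `[[`, integer(1), "right"),
    label = vapply(nodes, `[[`, character(1), "label"),
    n_pos = vapply(nodes, `[[`, numeric(1), "n_pos"),
    n_neg = vapply(nodes, `[[`, numeric(1), "n_neg"),
    stringsAsFactors = FALSE
  )
}

#' Train a random forest of Gini decision trees
#'
#' @param data an `encoded_dataset` (both classes must be present), or a list
#'   with numeric matrix `x` and character `label`.
#' @param n_trees number of trees (default 10).
#' @param mtry features considered per node; `NULL` means
#'   `floor(log2(p)) + 1`.
#' @param seed master seed; per-tree streams are derived from it.
#' @param bootstrap grow each tree on a bootstrap sample (n draws with
#'   replacement). Disabling it (with `n_trees = 1`, `mtry = p`) reduces the
#'   forest to a single deterministic exhaustive Gini tree, which is how the
#'   split search is validated against an independent reference.
#' @param min_leaf minimum instances per leaf (default 1; trees grow to
#'   purity).
#' @return object of class `sumo_forest`.
#' @export
train_forest <- function(data, n_trees = 10L, mtry = NULL, seed = 1L,
                         bootstrap = TRUE, min_leaf = 1L) {
  x <- data$x
  y <- data$label
  if (nrow(x) < 2L) stop("need at least 2 training instances", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training data contains a single class; both classes are required",
         call. = FALSE)
  }
  p <- ncol(x)
  if (is.null(mtry)) mtry <- floor(log2(p)) + 1L
  if (mtry < 1L || mtry > p) {
    stop("mtry must be in [1, ", p, "], got ", mtry, call. = FALSE)
  }
  y01 <- as.integer(y == "positive")
  set.seed(seed)
  tree_seeds <- sample.int(.Machine$integer.max - 1L, n_trees)
  trees <- vector("list", n_trees)
  for (k in seq_len(n_trees)) {
    set.seed(tree_seeds[k])
    idx <- if (bootstrap) sample.int(nrow(x), nrow(x), replace = TRUE) else seq_len(nrow(x))
    trees[[k]] <- grow_tree(x[idx, , drop = FALSE], y01[idx], mtry, min_leaf)
  }
  structure(
    list(trees = trees, n_trees = as.integer(n_trees), mtry = as.integer(mtry),
         seed = as.integer(seed), feature_count = p,
         feature_names = colnames(x),
         training_summary = c(positive = sum(y01), negative = sum(1L - y01)),
         bootstrap = bootstrap, min_leaf = as.integer(min_leaf)),
    class = "sumo_forest"
  )
}

#' @export
print.sumo_forest <- function(x, ...) {
  cat(sprintf("sumo_forest: %d trees, mtry %d, %d features; trained on %d positive / %d negative instances (seed %d)\n",
              x$n_trees, x$mtry, x$feature_count, x$training_summary[["positive"]],
              x$training_summary[["negative"]], x$seed))
  invisible(x)
}

# Route one instance down one tree; returns 1 for a positive vote.
tree_vote <- function(tree, v) {
  id <- 1L
  repeat {
    f <- tree$feature[id]
    if (is.na(f)) return(as.integer(tree$label[id] == "positive"))
    id <- if (v[f] <= tree$threshold[id]) tree$left[id] else tree$right[id]
  }
}

#' Predict with a random forest
#'
#' Trees vote and the majority class wins: the label is positive iff the
#' fraction of positive votes exceeds 0.5; an exact tie is called negative
#' (a deliberately conservative rule for a modification-site predictor).
#'
#' @param object a `sumo_forest`.
#' @param newdata an `encoded_dataset`, numeric matrix, or a single numeric
#'   vector of length `feature_count`.
#' @param ... unused.
#' @return data.frame with columns `label` and `vote_fraction`.
#' @export
predict.sumo_forest <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "encoded_dataset")) newdata$x
       else if (is.matrix(newdata)) newdata
       else matrix(newdata, nrow = 1L)
  if (ncol(x) != object$feature_count) {
    stop("feature-length mismatch: model expects ", object$feature_count,
         ", got ", ncol(x), call. = FALSE)
  }
  votes <- matrix(0L, nrow(x), object$n_trees)
  for (k in seq_len(object$n_trees)) {
    tree <- object$trees[[k]]
    votes[, k] <- vapply(seq_len(nrow(x)), function(i) tree_vote(tree, x[i, ]), integer(1))
  }
  vf <- rowMeans(votes)
  data.frame(label = ifelse(vf > 0.5, "positive", "negative"),
             vote_fraction = vf, stringsAsFactors = FALSE)
}

#' Serialize a forest to a versioned JSON document
#'
#' Captures trees, parameters, seed and a hash of the feature names, so a
#' reloaded model is exactly the saved one.
#'
#' @param model a `sumo_forest`.
#' @param path output file.
#' @export
write_forest_json <- function(model, path) {
  doc <- list(
    format = "sumohunt-forest", version = 1L,
    n_trees = model$n_trees, mtry = model$mtry, seed = model$seed,
    feature_count = model$feature_count,
    feature_names = model$feature_names,
    feature_names_md5 = feature_names_md5(model$feature_names),
    training_summary = as.list(model$training_summary),
    bootstrap = model$bootstrap, min_leaf = model$min_leaf,
    trees = model$trees
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

feature_names_md5 <- function(fn) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(if (is.null(fn)) character(0) else fn, tmp)
  unname(tools::md5sum(tmp))
}

#' Reload a forest saved with [write_forest_json()]
#' @param path JSON model file.
#' @return a `sumo_forest`.
#' @export
read_forest_json <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "sumohunt-forest")) {
    stop("not a sumohunt forest model file: ", path, call. = FALSE)
  }
  feature_names <- unlist(doc$feature_names)
  if (!identical(feature_names_md5(feature_names), doc$feature_names_md5)) {
    stop("model file corrupt: feature-name hash mismatch", call. = FALSE)
  }
  col <- function(t, name, template) {
    vapply(t[[name]], function(x) if (is.null(x)) template[NA_integer_] else {
      storage.mode(x) <- storage.mode(template); x
    }, template)
  }
  trees <- lapply(doc$trees, function(t) {
    data.frame(
      feature = col(t, "feature", integer(1)),
      threshold = col(t, "threshold", numeric(1)),
      left = col(t, "left", integer(1)),
      right = col(t, "right", integer(1)),
      label = col(t, "label", character(1)),
      n_pos = col(t, "n_pos", numeric(1)),
      n_neg = col(t, "n_neg", numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  structure(
    list(trees = trees, n_trees = as.integer(doc$n_trees),
         mtry = as.integer(doc$mtry), seed = as.integer(doc$seed),
         feature_count = as.integer(doc$feature_count),
         feature_names = feature_names,
         training_summary = unlist(doc$training_summary),
         bootstrap = isTRUE(doc$bootstrap), min_leaf = as.integer(doc$min_leaf)),
    class = "sumo_forest"
  )
}
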