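# Compact random-forest classifier (binary, CART with Gini impurity,
# bootstrap sampling, random feature subsets at each split). Implemented
# in-package because the analysis needs only a small, well-specified subset
# of random-forest functionality: probability votes from fully grown trees
# on low-dimensional metabolite panels.

# Grow one CART tree on (x, y) with y in {0, 1}. Returns a matrix of nodes:
# columns feature (0 = leaf), threshold, left, right, prob.
grow_tree <- function(x, y, mtry, min_node = 1) {
  p <- ncol(x)
  nodes <- matrix(0, 64L, 5L)
  n_nodes <- 0L
  new_node <- function() {
    n_nodes <<- n_nodes + 1L
    if (n_nodes > nrow(nodes)) nodes <<- rbind(nodes, matrix(0, nrow(nodes), 5L))
    n_nodes
  }
  best_split <- function(idx) {
    feats <- if (mtry >= p) seq_len(p) else sample.int(p, mtry)
    n <- length(idx)
    best <- NULL
    for (f in feats) {
      v <- x[idx, f]
      ord <- order(v)
      vs <- v[ord]
      ys <- y[idx][ord]
      cuts <- which(diff(vs) > 0)
      if (length(cuts) == 0) next
      s1 <- cumsum(ys)[cuts]
      n1 <- cuts
      s_tot <- sum(ys)
      p_l <- s1 / n1
      p_r <- (s_tot - s1) / (n - n1)
      imp <- n1 * p_l * (1 - p_l) + (n - n1) * p_r * (1 - p_r)
      j <- which.min(imp)
      if (is.null(best) || imp[j] < best$imp) {
        best <- list(imp = imp[j], feature = f,
                     threshold = (vs[cuts[j]] + vs[cuts[j] + 1L]) / 2)
      }
    }
    best
  }
  build <- function(idx) {
    id <- new_node()
    yy <- y[idx]
    if (length(idx) < 2L * min_node || all(yy == yy[1])) {
      nodes[id, ] <<- c(0, 0, 0, 0, mean(yy))
      return(id)
    }
    sp <- best_split(idx)
    if (is.null(sp)) {
      nodes[id, ] <<- c(0, 0, 0, 0, mean(yy))
      return(id)
    }
    left_idx <- idx[x[idx, sp$feature] <= sp$threshold]
    right_idx <- idx[x[idx, sp$feature] > sp$threshold]
    l <- build(left_idx)
    r <- build(right_idx)
    nodes[id, ] <<- c(sp$feature, sp$threshold, l, r, mean(yy))
    id
  }
  build(seq_len(nrow(x)))
  nodes[seq_len(n_nodes), , drop = FALSE]
}

predict_tree <- function(nodes, newx) {
  n <- nrow(newx)
  out <- numeric(n)
  route <- function(id, idx) {
    f <- nodes[id, 1L]
    if (f == 0) {
      out[idx] <<- nodes[id, 5L]
      return(invisible())
    }
    go_left <- newx[idx, f] <= nodes[id, 2L]
    if (any(go_left)) route(nodes[id, 3L], idx[go_left])
    if (any(!go_left)) route(nodes[id, 4L], idx[!go_left])
  }
  route(1L, seq_len(n))
  out
}

#' Fit a random-forest classifier
#'
#' Binary random forest: `n_trees` CART trees grown to purity on bootstrap
#' resamples, each split chosen by Gini impurity over a fresh random subset
#' of at most `mtry` features. Predicted probability is the mean vote over
#' trees. Uses the current RNG state; seed externally for reproducibility.
#'
#' @param x Numeric feature matrix (samples x features).
#' @param y Binary labels: 0/1 vector, logical, or two-level factor (second
#'   level = positive).
#' @param n_trees Number of trees.
#' @param mtry Maximum features tried at each split.
#' @param min_node Minimum node size to attempt a split on.
#' @return An object of class `rf_model`.
#' @export
rf_fit <- function(x, y, n_trees = 500, mtry = min(3L, ncol(x)),
                   min_node = 1) {
  x <- as.matrix(x)
  if (is.factor(y)) {
    stopifnot(nlevels(y) == 2)
    y <- as.integer(y) - 1L
  }
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), length(y) == nrow(x), n_trees >= 1)
  if (length(unique(y)) < 2) stop("both classes must be present")
  n <- nrow(x)
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[boot])) < 2) {
      # re-draw: a single-class bootstrap gives an uninformative tree
      boot <- sample.int(n, n, replace = TRUE)
    }
    trees[[b]] <- grow_tree(x[boot, , drop = FALSE], y[boot], mtry, min_node)
  }
  structure(list(trees = trees, mtry = mtry, n_features = ncol(x),
                 feature_names = colnames(x)),
            class = "rf_model")
}

#' Predict class-1 probabilities from a random forest
#'
#' @param model An [rf_fit()] model.
#' @param newx Feature matrix with the same columns as used in fitting.
#' @return Numeric vector of probabilities (mean tree vote).
#' @export
rf_predict <- function(model, newx) {
  stopifnot(inherits(model, "rf_model"))
  newx <- as.matrix(newx)
  stopifnot(ncol(newx) == model$n_features)
  probs <- vapply(model$trees, predict_tree, numeric(nrow(newx)), newx = newx)
  if (nrow(newx) == 1L) mean(probs) else rowMeans(probs)
}
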