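# Gradient-boosted decision trees for two-class diagnosis, from scratch.
#
# Stagewise additive model on the binomial negative log-likelihood:
# F_0 = log-odds of the base rate; each stage fits a depth-limited regression
# tree (variance-reduction splits, exhaustive threshold search over the
# sorted unique values of each feature) to the negative gradient y - p, with
# leaf values set by a single Newton step sum(r)/sum(p(1-p)) and shrunk by
# the learning rate. Split ties are broken by the first feature index, then
# the smallest threshold, so fits are fully deterministic. Per-feature
# squared-error improvements are accumulated over all splits for the
# relative variable importance report.

# Find the best variance-reduction split of `r` over the rows `idx`.
# Returns NULL when no admissible split exists.
.best_split <- function(x, r, idx, min_leaf) {
  n <- length(idx)
  if (n < 2L * min_leaf) return(NULL)
  rsub <- r[idx]
  total <- sum(rsub)
  sse_parent <- sum(rsub^2) - total^2 / n
  best <- NULL
  best_gain <- 1e-12              # require strictly positive improvement
  for (j in seq_len(ncol(x))) {
    xj <- x[idx, j]
    o <- order(xj)
    xs <- xj[o]; rs <- rsub[o]
    cs <- cumsum(rs)
    k <- seq_len(n - 1L)
    valid <- xs[k] < xs[k + 1L] & k >= min_leaf & (n - k) >= min_leaf
    if (!any(valid)) next
    gain <- cs[k]^2 / k + (total - cs[k])^2 / (n - k) - total^2 / n
    gain[!valid] <- -Inf
    kbest <- which.max(gain)
    if (gain[kbest] > best_gain) {
      best_gain <- gain[kbest]
      best <- list(feature = j,
                   threshold = (xs[kbest] + xs[kbest + 1L]) / 2,
                   gain = gain[kbest],
                   left = idx[o[seq_len(kbest)]],
                   right = idx[o[(kbest + 1L):n]])
    }
  }
  best
}

# Grow one regression tree on the negative gradient. Nodes are rows of a
# list-backed table; leaf values are Newton steps clipped for stability.
.grow_tree <- function(x, r, w, max_depth, min_leaf) {
  nodes <- list()
  new_node <- function() length(nodes) + 1L
  build <- function(idx, depth) {
    id <- new_node()
    nodes[[id]] <<- list(feature = NA_integer_, threshold = NA_real_,
                         left = NA_integer_, right = NA_integer_,
                         value = NA_real_, gain = 0)
    sp <- if (depth < max_depth) .best_split(x, r, idx, min_leaf) else NULL
    if (is.null(sp)) {
      denom <- sum(w[idx])
      v <- if (denom > 1e-12) sum(r[idx]) / denom else 0
      nodes[[id]]$value <<- max(-4, min(4, v))
    } else {
      nodes[[id]]$feature <<- sp$feature
      nodes[[id]]$threshold <<- sp$threshold
      nodes[[id]]$gain <<- sp$gain
      nodes[[id]]$left <<- build(sp$left, depth + 1L)
      nodes[[id]]$right <<- build(sp$right, depth + 1L)
    }
    id
  }
  build(seq_len(nrow(x)), 0L)
  nodes
}

.predict_tree <- function(nodes, x) {
  out <- numeric(nrow(x))
  recurse <- function(id, idx) {
    nd <- nodes[[id]]
    if (is.na(nd$feature)) {
      out[idx] <<- nd$value
    } else {
      go_left <- x[idx, nd$feature] <= nd$threshold
      if (any(go_left)) recurse(nd$left, idx[go_left])
      if (any(!go_left)) recurse(nd$right, idx[!go_left])
    }
  }
  if (nrow(x) > 0) recurse(1L, seq_len(nrow(x)))
  out
}

#' Fit a gradient-boosted decision tree classifier
#'
#' @param x numeric matrix of features (samples x features, no missing
#'   values), with column names.
#' @param y class labels: a factor with two levels, or 0/1 with 1 = the
#'   positive (cancer) class.
#' @param n_trees number of boosting stages (default 200).
#' @param max_depth maximum tree depth (default 3).
#' @param learning_rate shrinkage in (0, 1] (default 0.1); 0 is accepted and
#'   yields the constant base-rate model.
#' @param min_samples_leaf minimum samples per leaf (default 5).
#' @return an object of class `gbdt` with components `trees`, `init`
#'   (base-rate log-odds), `deviance` (per-stage training deviance, non-
#'   increasing), `importance_raw`, `features`, `levels`.
#' @seealso [gbdt_importance()], [predict.gbdt()]
#' @export
gbdt <- function(x, y, n_trees = 200, max_depth = 3, learning_rate = 0.1,
                 min_samples_leaf = 5) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (anyNA(x)) stop("gbdt: x must not contain missing values (impute upstream)")
  if (n_trees < 1 || max_depth < 1) stop("gbdt: n_trees and max_depth must be >= 1")
  if (learning_rate < 0 || learning_rate > 1)
    stop("gbdt: learning_rate must be in [0, 1]")
  yl <- .binary_labels(y)
  y01 <- yl$y
  if (length(unique(y01)) < 2) stop("gbdt: both classes must be present in y")
  n <- nrow(x)
  init <- log(mean(y01) / (1 - mean(y01)))
  f <- rep(init, n)
  trees <- vector("list", n_trees)
  deviance <- numeric(n_trees)
  imp <- numeric(ncol(x))
  for (t in seq_len(n_trees)) {
    p <- stats::plogis(f)
    r <- y01 - p
    w <- pmax(p * (1 - p), 1e-12)
    tree <- .grow_tree(x, r, w, max_depth, min_samples_leaf)
    if (learning_rate > 0) {
      f <- f + learning_rate * .predict_tree(tree, x)
      for (nd in tree)
        if (!is.na(nd$feature)) imp[nd$feature] <- imp[nd$feature] + nd$gain
    }
    trees[[t]] <- tree
    p <- stats::plogis(f)
    deviance[t] <- -2 * sum(y01 * log(pmax(p, 1e-15)) +
                            (1 - y01) * log(pmax(1 - p, 1e-15)))
  }
  structure(list(trees = trees, init = init, learning_rate = learning_rate,
                 deviance = deviance, importance_raw = imp,
                 features = colnames(x), levels = yl$levels,
                 n_trees = n_trees, max_depth = max_depth,
                 min_samples_leaf = min_samples_leaf),
            class = "gbdt")
}

# Normalise y to 0/1 plus the (negative, positive) level names.
.binary_labels <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2) stop("y must have exactly two classes")
    lv <- levels(y)
    if (all(c("healthy", "cancer") %in% lv)) lv <- c("healthy", "cancer")
    list(y = as.numeric(y == lv[2]), levels = lv)
  } else if (is.character(y)) {
    .binary_labels(factor(y))
  } else {
    yv <- as.numeric(y)
    if (!all(yv %in% c(0, 1))) stop("numeric y must be 0/1")
    list(y = yv, levels = c("0", "1"))
  }
}

.align_features <- function(x, features) {
  x <- as.matrix(x)
  if (!is.null(colnames(x))) {
    missing <- setdiff(features, colnames(x))
    extra <- setdiff(colnames(x), features)
    if (length(missing) > 0)
      stop("newdata is missing feature(s): ", paste(missing, collapse = ", "),
           if (length(extra) > 0) paste0("; extra: ", paste(extra, collapse = ", ")) else "")
    x <- x[, features, drop = FALSE]
  } else if (ncol(x) != length(features)) {
    stop("newdata has ", ncol(x), " columns; model expects ", length(features))
  }
  x
}

#' Predict from a fitted GBDT model
#'
#' @param object a [gbdt()] fit.
#' @param newdata feature matrix; columns are aligned to the training
#'   features by name.
#' @param type `"prob"` for a two-column probability matrix (columns named
#'   by class, rows sum to 1), `"class"` for hard labels (ties go to the
#'   positive class), `"link"` for the additive log-odds.
#' @param ... unused.
#' @export
predict.gbdt <- function(object, newdata, type = c("prob", "class", "link"), ...) {
  type <- match.arg(type)
  x <- .align_features(newdata, object$features)
  f <- rep(object$init, nrow(x))
  if (object$learning_rate > 0)
    for (tree in object$trees)
      f <- f + object$learning_rate * .predict_tree(tree, x)
  if (type == "link") return(f)
  p1 <- stats::plogis(f)
  prob <- cbind(1 - p1, p1)
  colnames(prob) <- object$levels
  rownames(prob) <- rownames(x)
  if (type == "prob") return(prob)
  factor(object$levels[(p1 >= 0.5) + 1L], levels = object$levels)
}

#' Relative variable importance of a GBDT model
#'
#' Total squared-error improvement contributed by each feature over all
#' splits in all trees, rescaled so the most important feature scores 100.
#' Features never split on score 0.
#'
#' @param model a [gbdt()] fit.
#' @return named numeric vector in `[0, 100]`.
#' @export
gbdt_importance <- function(model) {
  stopifnot(inherits(model, "gbdt"))
  imp <- model$importance_raw
  names(imp) <- model$features
  if (max(imp) > 0) imp <- 100 * imp / max(imp)
  imp
}

#' @export
print.gbdt <- function(x, ...) {
  cat(sprintf("Gradient-boosted trees: %d stages, depth <= %d, shrinkage %.3g\n",
              x$n_trees, x$max_depth, x$learning_rate))
  cat(sprintf("Classes: %s (positive: %s); final training deviance %.3f\n",
              paste(x$levels, collapse = " / "), x$levels[2],
              x$deviance[length(x$deviance)]))
  invisible(x)
}

#' @export
summary.gbdt <- function(object, ...) {
  imp <- sort(gbdt_importance(object), decreasing = TRUE)
  cat("Relative variable importance (max = 100):\n")
  print(round(imp, 1))
  invisible(imp)
}
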