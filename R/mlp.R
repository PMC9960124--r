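# Multilayer perceptron diagnostic classifier: inputs -> one hidden layer of
# logistic units (5 by default) -> 2 softmax outputs, trained by full-batch
# minimisation of the cross-entropy with a full-memory BFGS quasi-Newton
# optimizer (the parameter vector is tiny — 77 weights for 12 inputs — so no
# limited-memory variant is needed). The line search is Armijo backtracking
# with a sufficient-decrease condition; inputs are standardized with training
# constants by default.

# pack/unpack the weight vector: W1 (d x h), b1 (h), W2 (h x 2), b2 (2)
.mlp_unpack <- function(par, d, h) {
  i <- 0L
  W1 <- matrix(par[i + seq_len(d * h)], d, h); i <- i + d * h
  b1 <- par[i + seq_len(h)]; i <- i + h
  W2 <- matrix(par[i + seq_len(h * 2L)], h, 2L); i <- i + h * 2L
  b2 <- par[i + seq_len(2L)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

.mlp_forward <- function(w, x) {
  a1 <- sweep(x %*% w$W1, 2, w$b1, "+")
  h <- stats::plogis(a1)
  a2 <- sweep(h %*% w$W2, 2, w$b2, "+")
  a2 <- a2 - apply(a2, 1, max)           # stabilised softmax
  e <- exp(a2)
  p <- e / rowSums(e)
  list(h = h, p = p)
}

# cross-entropy loss and analytic gradient; Y is an n x 2 one-hot matrix
.mlp_loss_grad <- function(par, x, Y, d, nh) {
  w <- .mlp_unpack(par, d, nh)
  fw <- .mlp_forward(w, x)
  n <- nrow(x)
  loss <- -sum(Y * log(pmax(fw$p, 1e-300))) / n
  dA2 <- (fw$p - Y) / n
  gW2 <- crossprod(fw$h, dA2)
  gb2 <- colSums(dA2)
  dH <- dA2 %*% t(w$W2)
  dA1 <- dH * fw$h * (1 - fw$h)
  gW1 <- crossprod(x, dA1)
  gb1 <- colSums(dA1)
  list(loss = loss, grad = c(gW1, gb1, gW2, gb2))
}

# Full-memory BFGS with Armijo backtracking line search.
.bfgs_minimize <- function(par, fngr, max_iter = 500, tol = 1e-6) {
  np <- length(par)
  H <- diag(np)
  fg <- fngr(par)
  f <- fg$loss; g <- fg$grad
  for (it in seq_len(max_iter)) {
    if (!is.finite(f)) return(list(par = par, value = f, converged = FALSE))
    if (max(abs(g)) < tol) break
    d <- as.vector(-H %*% g)
    slope <- sum(d * g)
    if (!is.finite(slope) || slope >= 0) {   # reset on loss of descent
      H <- diag(np); d <- -g; slope <- -sum(g * g)
    }
    step <- 1
    repeat {                                 # Armijo sufficient decrease
      cand <- par + step * d
      fg_new <- fngr(cand)
      if (is.finite(fg_new$loss) && fg_new$loss <= f + 1e-4 * step * slope) break
      step <- step / 2
      if (step < 1e-14) { fg_new <- fg; cand <- par; break }
    }
    if (identical(cand, par)) break          # line search stalled
    s <- cand - par
    yv <- fg_new$grad - g
    sy <- sum(s * yv)
    if (is.finite(sy) && sy > 1e-12) {       # curvature condition
      rho <- 1 / sy
      Hy <- H %*% yv
      H <- H - rho * (outer(s, as.vector(Hy)) + outer(as.vector(Hy), s)) +
        rho * (rho * sum(yv * Hy) + 1) * outer(s, s)
    }
    par <- cand; f <- fg_new$loss; g <- fg_new$grad
  }
  list(par = par, value = f, converged = max(abs(g)) < tol)
}

#' Fit a multilayer perceptron diagnostic classifier
#'
#' Architecture: inputs, one hidden layer of `n_hidden` logistic units
#' (5 by default, matching the small-cohort breath-diagnostic design), and a
#' 2-unit softmax output layer giving class probabilities. Training minimises
#' the full-batch cross-entropy with BFGS (Armijo backtracking line search);
#' it terminates when the gradient's max-norm falls below `tol` or after
#' `max_iter` iterations. If the loss becomes non-finite the fit restarts
#' with a smaller weight-initialisation scale (up to 3 restarts). With a
#' fixed seed the fitted weights are reproducible.
#'
#' @param x numeric feature matrix (no missing values), with column names.
#' @param y two-class labels as in [gbdt()].
#' @param n_hidden hidden units (default 5).
#' @param max_iter BFGS iteration cap (default 500).
#' @param tol gradient max-norm tolerance (default 1e-6).
#' @param init_scale standard deviation of the Gaussian weight init
#'   (default 0.5).
#' @param standardize standardize inputs with training means/sds
#'   (default TRUE).
#' @param seed integer seed for the weight initialisation.
#' @return object of class `mlp` with the weight matrices, standardization
#'   constants, training loss and convergence flag.
#' @export
mlp <- function(x, y, n_hidden = 5, max_iter = 500, tol = 1e-6,
                init_scale = 0.5, standardize = TRUE, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (anyNA(x)) stop("mlp: x must not contain missing values (impute upstream)")
  yl <- .binary_labels(y)
  if (length(unique(yl$y)) < 2) stop("mlp: both classes must be present in y")
  d <- ncol(x)
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
  } else {
    ctr <- rep(0, d); scl <- rep(1, d)
  }
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  Y <- cbind(1 - yl$y, yl$y)
  np <- d * n_hidden + n_hidden + n_hidden * 2L + 2L
  set.seed(seed)
  fit <- NULL
  scale_try <- init_scale
  for (attempt in 0:3) {
    par0 <- stats::rnorm(np, sd = scale_try)
    fit <- .bfgs_minimize(par0,
                          function(p) .mlp_loss_grad(p, xs, Y, d, n_hidden),
                          max_iter = max_iter, tol = tol)
    if (is.finite(fit$value)) break
    scale_try <- scale_try / 4
  }
  if (!is.finite(fit$value))
    stop("mlp: training diverged (non-finite loss) after 3 restarts")
  structure(list(weights = .mlp_unpack(fit$par, d, n_hidden), par = fit$par,
                 n_hidden = n_hidden, features = colnames(x),
                 center = ctr, scale = scl, levels = yl$levels,
                 loss = fit$value, converged = fit$converged, seed = seed),
            class = "mlp")
}

#' Predict from a fitted MLP
#'
#' @param object an [mlp()] fit.
#' @param newdata feature matrix; columns aligned to training features by
#'   name and standardized with the training constants.
#' @param type `"prob"` (two-column softmax matrix, rows sum to 1) or
#'   `"class"` (hard labels; a tied probability goes to the positive class).
#' @param ... unused.
#' @export
predict.mlp <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- .align_features(newdata, object$features)
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  p <- .mlp_forward(object$weights, xs)$p
  colnames(p) <- object$levels
  rownames(p) <- rownames(x)
  if (type == "prob") return(p)
  factor(object$levels[(p[, 2] >= 0.5) + 1L], levels = object$levels)
}

#' @export
print.mlp <- function(x, ...) {
  cat(sprintf("Multilayer perceptron %d-%d-2 (logistic hidden, softmax output)\n",
              length(x$features), x$n_hidden))
  cat(sprintf("BFGS training loss %.5f (%s)\n", x$loss,
              if (x$converged) "gradient converged" else "iteration cap reached"))
  invisible(x)
}
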