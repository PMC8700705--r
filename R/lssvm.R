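#' Radial basis function kernel
#'
#' `K(x, z) = exp(-||x - z||^2 / sigma2)`, the Gaussian kernel in the
#' width-parameterisation used throughout this package (sigma2 is the
#' squared kernel width, not twice it).
#'
#' @param x,z numeric vectors of equal length.
#' @param sigma2 positive kernel width parameter.
#' @return Kernel value in `(0, 1]`.
#' @export
rbf_kernel <- function(x, z, sigma2) {
  if (!is.numeric(sigma2) || sigma2 <= 0) stop("sigma2 must be positive")
  exp(-sum((x - z)^2) / sigma2)
}

# Squared Euclidean cross-distances between rows of A and rows of B.
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Fit a least-squares support vector machine classifier
#'
#' LS-SVM replaces the SVM's inequality constraints with equalities, so
#' training reduces to one linear system in the dual variables: with
#' `Omega[i, j] = y_i y_j K(x_i, x_j)` the coefficients `(b, alpha)` solve
#'
#' ```
#' [ 0   y' ] [ b     ]   [ 0 ]
#' [ y   Omega + I/gamma ] [ alpha ] = [ 1 ]
#' ```
#'
#' and the decision function is
#' `f(x) = sign(sum_i alpha_i y_i K(x, x_i) + b)`.
#'
#' @param x numeric matrix of predictors (samples x features).
#' @param y class labels, `1` / `-1`, both present.
#' @param gamma positive regularisation parameter (large = less
#'   regularised).
#' @param sigma2 positive RBF kernel width (see [rbf_kernel()]).
#' @param standardize centre and scale columns of `x` before the kernel;
#'   the stored means and scales are reapplied at prediction, never
#'   re-estimated.
#' @return An object of class `lssvm`: coefficients `alpha`, bias `b`, the
#'   hyperparameters, the (standardised) training inputs and labels, the
#'   standardisation parameters, and the solver residual
#'   `max |A [b; alpha] - [0; 1]|`.
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 4), 10))
#' fit <- lssvm(x, rep(c(1, -1), each = 10), gamma = 100, sigma2 = 1)
#' mean(predict(fit, x) == rep(c(1, -1), each = 10))
lssvm <- function(x, y, gamma = 1, sigma2 = 1, standardize = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("x and y differ in length")
  if (!all(y %in% c(1, -1))) stop("labels must be 1 or -1")
  if (!any(y == 1) || !any(y == -1)) stop("both classes must be present")
  if (gamma <= 0 || sigma2 <= 0) stop("gamma and sigma2 must be positive")
  if (standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0] <- 1
    xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  } else {
    center <- rep(0, ncol(x))
    scale <- rep(1, ncol(x))
    xs <- x
  }
  n <- nrow(xs)
  K <- exp(-cross_dist2(xs, xs) / sigma2)
  Omega <- tcrossprod(y) * K
  A <- rbind(c(0, y), cbind(y, Omega + diag(n) / gamma))
  rhs <- c(0, rep(1, n))
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    stop("LS-SVM system is singular (", conditionMessage(e),
         "); increase the ridge 1/gamma by lowering gamma")
  })
  sol <- unname(sol)
  structure(list(alpha = sol[-1], b = sol[1],
                 gamma = gamma, sigma2 = sigma2,
                 x = xs, y = y,
                 center = center, scale = scale,
                 standardize = standardize,
                 residual = max(abs(A %*% sol - rhs))),
            class = "lssvm")
}

#' Decision values and class predictions from a fitted LS-SVM
#'
#' @param object a fitted [lssvm()] model.
#' @param newdata numeric matrix with the same number of columns as the
#'   training inputs.
#' @param type `"class"` for `1`/`-1` labels, `"decision"` for the raw
#'   decision values.
#' @param ... unused.
#' @return Numeric vector of labels or decision values. An exact zero
#'   decision value maps to healthy (`1`).
#' @export
predict.lssvm <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x)) {
    stop("newdata has ", ncol(newdata), " columns; model was trained on ",
         ncol(object$x))
  }
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  K <- exp(-cross_dist2(xs, object$x) / object$sigma2)
  f <- drop(K %*% (object$alpha * object$y)) + object$b
  if (type == "decision") return(f)
  ifelse(f < 0, -1, 1)
}

#' @export
print.lssvm <- function(x, ...) {
  cat("LS-SVM classifier (RBF kernel): n = ", length(x$y), ", gamma = ",
      format(x$gamma, digits = 5), ", sigma2 = ",
      format(x$sigma2, digits = 5), "\n", sep = "")
  cat("  solver residual: ", format(x$residual, digits = 3),
      if (x$standardize) "  (standardised inputs)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
summary.lssvm <- function(object, ...) {
  print(object)
  train_acc <- mean(predict(object, sweep(sweep(object$x, 2, object$scale, "*"),
                                          2, object$center, "+")) == object$y)
  cat("  training accuracy: ", format(100 * train_acc, digits = 4), "%\n",
      sep = "")
  invisible(object)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin into folds, so every fold keeps the class proportions.
stratified_folds <- function(y, n_folds, seed) {
  folds <- integer(length(y))
  with_local_rng(seed, {
    for (lab in unique(y)) {
      idx <- which(y == lab)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

cv_accuracy <- function(x, y, gamma, sigma2, folds, standardize) {
  correct <- 0L
  for (f in sort(unique(folds))) {
    hold <- folds == f
    fit <- lssvm(x[!hold, , drop = FALSE], y[!hold], gamma, sigma2,
                 standardize = standardize)
    correct <- correct + sum(predict(fit, x[hold, , drop = FALSE]) == y[hold])
  }
  correct / length(y)
}

#' Tune LS-SVM hyperparameters by grid search with stratified k-fold CV
#'
#' Coarse-to-fine search for the regularisation parameter gamma and the RBF
#' width sigma2: every pair on the coarse log10 grids is scored by mean
#' stratified 10-fold cross-validated accuracy, then a 5 x 5 refined grid
#' (half-decade spacing) around the coarse optimum is scored with the same
#' folds. Ties go to the smaller gamma, then the smaller sigma2. Each fold
#' fit standardises on its own training portion, so no information leaks
#' from the held-out fold.
#'
#' @param x,y training data as in [lssvm()].
#' @param gamma_grid,sigma2_grid coarse candidate grids (positive).
#' @param n_folds number of CV folds (2 or more, at most `length(y)`).
#' @param standardize passed to [lssvm()].
#' @param seed integer seed for the fold shuffle.
#' @param refine logical; skip the refinement stage if `FALSE` (or if a
#'   grid has a single candidate).
#' @return List with `gamma`, `sigma2`, `cv_accuracy`, and `trace`, a data
#'   frame of every `(gamma, sigma2, cv_accuracy)` evaluated.
#' @export
tune_lssvm <- function(x, y, gamma_grid = 10^(-2:6), sigma2_grid = 10^(-2:6),
                       n_folds = 10, standardize = TRUE, seed = 1,
                       refine = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(gamma_grid) == 0 || length(sigma2_grid) == 0) {
    stop("candidate grids must be nonempty")
  }
  if (any(gamma_grid <= 0) || any(sigma2_grid <= 0)) {
    stop("gamma and sigma2 candidates must be positive")
  }
  if (n_folds < 2) stop("n_folds must be at least 2")
  if (n_folds > length(y)) stop("more folds than samples")
  folds <- stratified_folds(y, n_folds, seed)

  evaluate_grid <- function(gammas, sigma2s) {
    res <- expand.grid(gamma = sort(unique(gammas)),
                       sigma2 = sort(unique(sigma2s)),
                       KEEP.OUT.ATTRS = FALSE)
    res$cv_accuracy <- NA_real_
    for (r in seq_len(nrow(res))) {
      res$cv_accuracy[r] <- cv_accuracy(x, y, res$gamma[r], res$sigma2[r],
                                        folds, standardize)
    }
    res
  }
  pick_best <- function(res) {
    # ties -> smaller gamma, then smaller sigma2
    res <- res[order(-res$cv_accuracy, res$gamma, res$sigma2), ]
    res[1, ]
  }

  trace <- evaluate_grid(gamma_grid, sigma2_grid)
  best <- pick_best(trace)
  if (refine && (length(gamma_grid) > 1 || length(sigma2_grid) > 1)) {
    offs <- seq(-1, 1, by = 0.5)
    fine <- evaluate_grid(best$gamma * 10^offs, best$sigma2 * 10^offs)
    trace <- rbind(trace, fine)
    best <- pick_best(rbind(best, fine))
  }
  list(gamma = best$gamma, sigma2 = best$sigma2,
       cv_accuracy = best$cv_accuracy, trace = trace)
}

#' Serialize an LS-SVM model to JSON
#'
#' Stores the dual coefficients, bias, hyperparameters and standardisation
#' parameters (not the training inputs).
#'
#' @param model a fitted [lssvm()] model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lssvm_json <- function(model, path) {
  stopifnot(inherits(model, "lssvm"))
  obj <- list(alpha = model$alpha, b = model$b, gamma = model$gamma,
              sigma2 = model$sigma2, standardize = model$standardize,
              center = model$center, scale = model$scale)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
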