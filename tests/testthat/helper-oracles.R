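# Independent oracles used across the suite. These are deliberately naive
# (loops, brute force, base-R model fits) and share no code with the package
# internals they check.

# Two-group F via the pooled two-sample t statistic (base R route).
oracle_f_pooled_t2 <- function(a, b) {
  unname(stats::t.test(a, b, var.equal = TRUE)$statistic^2)
}

# Two-group F via a one-way ANOVA linear-model fit.
oracle_f_lm <- function(a, b) {
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  stats::anova(stats::lm(c(a, b) ~ g))[1, "F value"]
}

# Full ratio F matrix by a naive double loop over ordered pairs.
oracle_ratio_f_matrix <- function(set) {
  W <- ncol(set$intensities)
  Fm <- matrix(NA_real_, W, W)
  for (i in seq_len(W)) {
    for (k in seq_len(W)) {
      if (i == k) next
      Fm[i, k] <- f_oneway_two_groups(
        ratio_values(set, i, k)[set$labels == 1],
        ratio_values(set, i, k)[set$labels == -1])
    }
  }
  Fm
}

# Step-by-step greedy SPXY re-implementation (O(n^2) per step, no caching).
oracle_spxy <- function(X, y, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  dX <- as.matrix(dist(X))
  dY <- abs(outer(y, y, "-"))
  D <- (if (max(dX) > 0) dX / max(dX) else dX) +
    (if (max(dY) > 0) dY / max(dY) else dY * 0)
  sel <- integer(0)
  best <- -Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] > best) { best <- D[i, j]; sel <- c(i, j) }
  }
  while (length(sel) < k) {
    rest <- setdiff(1:n, sel)
    score <- sapply(rest, function(r) min(D[r, sel]))
    sel <- c(sel, rest[which.max(score)])   # which.max takes the first = lowest index
  }
  sel
}

# Kennard-Stone on X alone (same greedy maximin, X distances only).
oracle_kennard_stone <- function(X, k) {
  oracle_spxy(X, rep(0, nrow(as.matrix(X))), k)
}

# Exact optimum of the threshold rule: candidates at midpoints between
# consecutive sorted unique ratios plus both extremes.
oracle_threshold_best_accuracy <- function(ratios, labels) {
  u <- sort(unique(ratios))
  cand <- c(u[1], (head(u, -1) + tail(u, -1)) / 2, u[length(u)])
  acc <- sapply(cand, function(t) {
    mean(ifelse(ratios <= t, -1, 1) == labels)
  })
  max(acc)
}

# LS-SVM decision function as an explicit per-sample kernel sum.
oracle_lssvm_decision <- function(model, X) {
  X <- as.matrix(X)
  xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  sapply(seq_len(nrow(xs)), function(r) {
    sum(model$alpha * model$y *
          apply(model$x, 1, function(tr) rbf_kernel(xs[r, ], tr, model$sigma2))) +
      model$b
  })
}

# Small ready-made spectrum set for structural tests.
toy_set <- function(n_per_class = 5, W = 12, seed = 42, sep = 3) {
  set.seed(seed)
  X <- matrix(rexp(2 * n_per_class * W, rate = 0.01), 2 * n_per_class, W)
  X[(n_per_class + 1):(2 * n_per_class), 2] <-
    X[(n_per_class + 1):(2 * n_per_class), 2] + sep * 100
  spectrum_set(X, seq(680, 1000, length.out = W),
               rep(c(1, -1), each = n_per_class))
}
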