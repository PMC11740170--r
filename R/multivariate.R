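#' Rank features by one-way ANOVA and keep the best
#'
#' Computes the one-way ANOVA F statistic of every feature across the group
#' labels and retains the `top_k` best-ranked features (all of them when
#' fewer exist). Features with a degenerate F (identical group means with
#' zero within-group variance) are ranked last, with a warning.
#'
#' @param table a `feature_table`.
#' @param top_k number of features to keep (default 50).
#' @return The feature table restricted to the selected columns, ordered by
#'   decreasing F; the statistics are attached as `attr(, "F")`.
#' @export
anova_rank <- function(table, top_k = 50L) {
  g <- ft_groups(table)
  if (nlevels(g) < 2L) stopf("need at least 2 groups")
  if (any(table(g) < 2L)) stopf("every group needs at least 2 spots")
  x <- ft_matrix(table)
  f <- apply(x, 2L, function(v) anova_f(v, g))
  if (anyNA(f))
    warnf("%d feature(s) with degenerate ANOVA F (no variance); ranked last",
          sum(is.na(f)))
  o <- order(f, decreasing = TRUE, na.last = TRUE)
  keep <- o[seq_len(min(top_k, length(o)))]
  meta <- intersect(c("spot_id", "group", "replicate_group"), names(table))
  out <- cbind(as.data.frame(table)[meta],
               as.data.frame(x[, keep, drop = FALSE]))
  class(out) <- c("feature_table", "data.frame")
  attr(out, "F") <- f[keep]
  out
}

# One-way ANOVA F for one feature; NA when both between- and within-group
# mean squares vanish.
anova_f <- function(v, g) {
  n <- length(v); k <- nlevels(g)
  gm <- tapply(v, g, mean)
  gn <- tabulate(g)
  ssb <- sum(gn * (gm - mean(v))^2)
  ssw <- sum((v - gm[g])^2)
  msb <- ssb / (k - 1); msw <- ssw / (n - k)
  if (msw == 0) {
    if (msb == 0) return(NA_real_)
    return(Inf)
  }
  msb / msw
}

#' Select principal components by the cumulative-variance rule
#'
#' Components are accumulated in order of explained variance. Accumulation
#' stops as soon as the cumulative share exceeds `cum_threshold` (components
#' explaining more than 90% of the variability, by default) or as soon as the
#' next component would add no more than `min_share` percent. The two
#' conditions can conflict — the next share may drop below `min_share`
#' before the cumulative threshold is reached — in which case accumulation
#' still halts and the conflict is flagged.
#'
#' @param shares per-component explained-variance shares, in percent,
#'   non-increasing.
#' @param cum_threshold cumulative percentage to exceed (default 90).
#' @param min_share minimum percentage an additional component must add
#'   (default 0.5).
#' @return Number of retained components, with attributes `cumulative` (the
#'   cumulative share at the stop) and `conflict` (`TRUE` when the
#'   `min_share` stop fired below the cumulative threshold).
#' @examples
#' select_components(c(60, 32, 5, 2, 1))   # 2
#' select_components(c(50, 30, 10, 9, 1))  # 4
#' @export
select_components <- function(shares, cum_threshold = 90, min_share = 0.5) {
  if (!length(shares)) stopf("no components")
  keep <- 1L
  cum <- shares[1L]
  conflict <- FALSE
  while (cum <= cum_threshold && keep < length(shares)) {
    if (shares[keep + 1L] > min_share) {
      keep <- keep + 1L
      cum <- cum + shares[keep]
    } else {
      conflict <- TRUE
      break
    }
  }
  if (cum <= cum_threshold && keep == length(shares) && !conflict)
    conflict <- TRUE  # ran out of components before the threshold
  structure(keep, cumulative = cum, conflict = conflict)
}

#' PCA with the component-selection rule
#'
#' Features are standardized (centred, unit variance; constant columns are
#' dropped with a warning) before the decomposition, and the number of
#' retained components follows [select_components()].
#'
#' @param table a `feature_table`.
#' @param cum_threshold,min_share see [select_components()].
#' @return A `pca_result`: retained component count `n_components`,
#'   per-component `shares` (percent), `scores`, `loadings`, and `conflict`.
#' @export
pca_select <- function(table, cum_threshold = 90, min_share = 0.5) {
  x <- ft_matrix(table)
  if (nrow(x) < 2L) stopf("need at least 2 samples")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    warnf("%d constant feature column(s) dropped before PCA", sum(sds == 0))
    x <- x[, sds > 0, drop = FALSE]
  }
  z <- scale(x)
  p <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  shares <- 100 * p$sdev^2 / sum(p$sdev^2)
  k <- select_components(shares, cum_threshold, min_share)
  structure(list(n_components = as.integer(k), shares = shares,
                 cumulative = attr(k, "cumulative"),
                 conflict = attr(k, "conflict"),
                 scores = p$x, loadings = p$rotation,
                 groups = ft_groups(table)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d component(s) retained (%.1f%% of variance%s)\n",
              x$n_components, x$cumulative,
              if (isTRUE(x$conflict)) "; share rule halted accumulation" else ""))
  cat("  shares (%):", paste(sprintf("%.1f", utils::head(x$shares, 8)),
                             collapse = ", "), "\n")
  invisible(x)
}

# ---- classifiers ----------------------------------------------------------

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin to folds.
stratified_folds <- function(g, folds) {
  fold <- integer(length(g))
  for (lev in levels(g)) {
    idx <- sample(which(g == lev))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

fit_predict <- function(method, xtr, ytr, xte, seed) {
  switch(method,
    knn = class::knn(xtr, xte, ytr, k = 5L),
    naive_bayes = {
      fit <- e1071::naiveBayes(xtr, ytr)
      stats::predict(fit, xte)
    },
    random_forest = {
      fit <- randomForest::randomForest(xtr, ytr, ntree = 10L, nodesize = 5L)
      stats::predict(fit, xte)
    },
    neural_net = {
      fit <- mlp_fit(xtr, ytr, hidden = 200L, max_iter = 350L)
      mlp_predict(fit, xte)
    },
    stopf("unknown method '%s'", method))
}

#' Cross-validated classification of lipid fingerprints
#'
#' Stratified k-fold cross-validation (10 folds by default) of one of four
#' classifiers with fixed hyperparameters: k-nearest neighbours (k = 5,
#' Euclidean distance, uniform weights), Gaussian naive Bayes, random forest
#' (10 trees; nodes of fewer than 5 samples are not split), or a neural
#' network with one hidden layer of 200 ReLU units trained by stochastic
#' gradient descent for at most 350 iterations. The seed fixes both the fold
#' assignment and the stochastic fits.
#'
#' @param table a `feature_table`.
#' @param method one of `"knn"`, `"naive_bayes"`, `"random_forest"`,
#'   `"neural_net"`.
#' @param folds number of folds (default 10); reduced with a warning when a
#'   class has fewer samples than folds.
#' @param seed integer seed.
#' @return A `cv_report`: method, fold count, per-fold accuracies, mean
#'   accuracy, and the pooled confusion matrix.
#' @export
classify_cv <- function(table,
                        method = c("knn", "naive_bayes", "random_forest",
                                   "neural_net"),
                        folds = 10L, seed = 1L) {
  method <- match.arg(method)
  x <- ft_matrix(table)
  g <- ft_groups(table)
  if (nlevels(g) < 2L) {
    warnf("single class: accuracy is degenerate (1.0)")
    cm <- table(truth = g, predicted = g)
    return(structure(list(method = method, folds = 0L, fold_accuracy = 1,
                          mean_accuracy = 1, confusion = cm),
                     class = "cv_report"))
  }
  smallest <- min(table(g))
  if (smallest < folds) {
    warnf("smallest class has %d samples; folds reduced from %d to %d",
          smallest, folds, smallest)
    folds <- smallest
  }
  if (folds < 2L) stopf("need at least 2 samples per class for cross-validation")

  with_seed(seed, {
    fold <- stratified_folds(g, folds)
    pred <- factor(rep(NA_character_, length(g)), levels = levels(g))
    acc <- numeric(folds)
    for (f in seq_len(folds)) {
      te <- fold == f
      pred[te] <- fit_predict(method, x[!te, , drop = FALSE], g[!te],
                              x[te, , drop = FALSE], seed)
      acc[f] <- mean(pred[te] == g[te])
    }
    structure(list(method = method, folds = folds, fold_accuracy = acc,
                   mean_accuracy = mean(acc),
                   confusion = table(truth = g, predicted = pred)),
              class = "cv_report")
  })
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%s: mean %d-fold CV accuracy %.3f (folds: %s)\n",
              x$method, x$folds, x$mean_accuracy,
              paste(sprintf("%.2f", x$fold_accuracy), collapse = " ")))
  print(x$confusion)
  invisible(x)
}

# ---- single-hidden-layer ReLU network trained by SGD ----------------------
# Softmax output, cross-entropy loss, minibatch SGD with momentum. Inputs are
# z-scored inside the fit; the scaling is reapplied at prediction.

mlp_fit <- function(x, y, hidden = 200L, max_iter = 350L, lr = 0.01,
                    momentum = 0.9, batch = 16L) {
  y <- droplevels(y)
  centre <- colMeans(x)
  spread <- apply(x, 2L, stats::sd)
  spread[spread == 0] <- 1
  z <- sweep(sweep(x, 2L, centre), 2L, spread, `/`)
  n <- nrow(z); p <- ncol(z); k <- nlevels(y)
  yi <- as.integer(y)

  w1 <- matrix(stats::rnorm(p * hidden, 0, sqrt(2 / p)), p, hidden)
  b1 <- numeric(hidden)
  w2 <- matrix(stats::rnorm(hidden * k, 0, sqrt(2 / hidden)), hidden, k)
  b2 <- numeric(k)
  vw1 <- 0 * w1; vb1 <- 0 * b1; vw2 <- 0 * w2; vb2 <- 0 * b2

  for (epoch in seq_len(max_iter)) {
    ord <- sample.int(n)
    loss <- 0
    for (start in seq(1L, n, by = batch)) {
      ix <- ord[start:min(start + batch - 1L, n)]
      xb <- z[ix, , drop = FALSE]
      h <- pmax(xb %*% w1 + rep(b1, each = length(ix)), 0)  # ReLU
      s <- h %*% w2 + rep(b2, each = length(ix))
      s <- s - apply(s, 1L, max)
      es <- exp(s)
      prob <- es / rowSums(es)
      tgt <- matrix(0, length(ix), k)
      tgt[cbind(seq_along(ix), yi[ix])] <- 1
      loss <- loss - sum(log(pmax(prob[tgt == 1], 1e-12)))

      dS <- (prob - tgt) / length(ix)
      gw2 <- crossprod(h, dS); gb2 <- colSums(dS)
      dH <- dS %*% t(w2) * (h > 0)
      gw1 <- crossprod(xb, dH); gb1 <- colSums(dH)

      vw2 <- momentum * vw2 - lr * gw2; w2 <- w2 + vw2
      vb2 <- momentum * vb2 - lr * gb2; b2 <- b2 + vb2
      vw1 <- momentum * vw1 - lr * gw1; w1 <- w1 + vw1
      vb1 <- momentum * vb1 - lr * gb1; b1 <- b1 + vb1
    }
    if (loss / n < 1e-4) break
  }
  list(w1 = w1, b1 = b1, w2 = w2, b2 = b2, centre = centre, spread = spread,
       levels = levels(y))
}

mlp_predict <- function(fit, x) {
  z <- sweep(sweep(as.matrix(x), 2L, fit$centre), 2L, fit$spread, `/`)
  h <- pmax(z %*% fit$w1 + rep(fit$b1, each = nrow(z)), 0)
  s <- h %*% fit$w2 + rep(fit$b2, each = nrow(z))
  factor(fit$levels[max.col(s, ties.method = "first")], levels = fit$levels)
}

#' Per-feature univariate comparison of two groups
#'
#' For every feature, a Shapiro-Wilk normality test is reported per group and
#' a two-sided Mann-Whitney (Wilcoxon rank-sum) test compares the groups at
#' alpha = 0.05. Constant features are skipped and noted.
#'
#' @param table a `feature_table`.
#' @param group_a,group_b the two group labels to compare (>= 3 samples
#'   each).
#' @param alpha significance level (default 0.05).
#' @return A data frame with one row per feature: Shapiro-Wilk p per group,
#'   Mann-Whitney U and p, and a `significant` flag; skipped features carry
#'   `NA` and a note.
#' @export
monovariable_tests <- function(table, group_a, group_b, alpha = 0.05) {
  g <- as.character(ft_groups(table))
  ia <- g == group_a; ib <- g == group_b
  if (sum(ia) < 3L || sum(ib) < 3L)
    stopf("both groups need at least 3 samples (have %d and %d)",
          sum(ia), sum(ib))
  x <- ft_matrix(table)
  out <- lapply(colnames(x), function(f) {
    a <- x[ia, f]; b <- x[ib, f]
    if (stats::sd(c(a, b)) == 0) {
      return(data.frame(feature = f, shapiro_p_a = NA_real_,
                        shapiro_p_b = NA_real_, u = NA_real_, p = NA_real_,
                        significant = NA, note = "constant feature; skipped"))
    }
    sw <- function(v) if (stats::sd(v) == 0) NA_real_ else
      stats::shapiro.test(v)$p.value
    mw <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                              exact = FALSE))
    data.frame(feature = f, shapiro_p_a = sw(a), shapiro_p_b = sw(b),
               u = unname(mw$statistic), p = mw$p.value,
               significant = mw$p.value < alpha, note = "")
  })
  do.call(rbind, out)
}
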