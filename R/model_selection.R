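#' Cross-validation configuration
#'
#' Resampling plan for repeated stratified k-fold cross-validation. The
#' defaults follow the reference analysis protocol: 10 folds, 50 repeats,
#' folds stratified on the binary outcome, and at most
#' \code{min(n - 1, p, 10)} candidate components.
#'
#' @param k number of folds (>= 2).
#' @param repeats number of independent repetitions of the k-fold split.
#' @param strata per-sample labels used to stratify fold assignment
#'   (typically the outcome labels); \code{NULL} for unstratified folds.
#' @param seed integer master seed; each repeat derives its own sub-seed
#'   from it, so the whole resampling plan is reproducible and
#'   parallelizable.
#' @param max_components upper bound on the candidate component counts;
#'   \code{NULL} means \code{min(n - 1, p, 10)} resolved at fit time.
#' @param scale_in_fold if \code{TRUE}, predictors are rescaled to unit
#'   variance inside every training fold instead of relying on the global
#'   preprocessing scaling (leakage-averse variant; off by default for
#'   fidelity to the one-off global scaling protocol).
#' @param tss_reference \code{"global"} (default) computes the explained
#'   -variance denominator from full-data response means so percentages are
#'   comparable across repeats; \code{"train"} recomputes it per repeat from
#'   training-fold means.
#' @return An object of class \code{cv_config}.
#' @export
cv_config <- function(k = 10L, repeats = 50L, strata = NULL, seed = 1L,
                      max_components = NULL, scale_in_fold = FALSE,
                      tss_reference = c("global", "train")) {
  k <- as.integer(k); repeats <- as.integer(repeats)
  if (k < 2) stop("k must be >= 2")
  if (repeats < 1) stop("repeats must be >= 1")
  structure(list(k = k, repeats = repeats, strata = strata,
                 seed = as.integer(seed),
                 max_components = max_components,
                 scale_in_fold = isTRUE(scale_in_fold),
                 tss_reference = match.arg(tss_reference)),
            class = "cv_config")
}

# Deterministic sub-seed for repeat r of a master seed (kept < 2^31).
sub_seed <- function(seed, r) {
  as.integer((as.numeric(seed) + r * 99991) %% .Machine$integer.max)
}

#' Stratified fold assignment
#'
#' Partitions sample indices into k disjoint folds whose class composition
#' matches the overall class proportions within one sample per class:
#' within each stratum the samples are shuffled and dealt out in equal
#' shares, the remainder going to randomly chosen distinct folds. The
#' assignment is deterministic for a fixed seed.
#'
#' @param strata per-sample labels; a single level gives plain k-fold.
#' @param k number of folds; every stratum must have at least k members.
#' @param seed integer seed.
#' @return A list of k integer vectors of sample indices.
#' @export
make_stratified_folds <- function(strata, k, seed) {
  strata <- as.character(strata)
  n <- length(strata)
  if (k < 2) stop("k must be >= 2")
  folds <- vector("list", k)
  withr::with_seed(seed, {
    for (lev in sort(unique(strata))) {
      idx <- which(strata == lev)
      m <- length(idx)
      if (m < k)
        stop("stratum '", lev, "' has ", m, " members, fewer than k = ", k)
      idx <- idx[sample.int(m)]
      sizes <- rep(m %/% k, k)
      extra <- m %% k
      if (extra > 0) {
        bump <- sample.int(k, extra)
        sizes[bump] <- sizes[bump] + 1L
      }
      stops <- cumsum(sizes)
      starts <- c(1L, head(stops, -1L) + 1L)
      for (f in seq_len(k)) {
        if (sizes[f] > 0)
          folds[[f]] <- c(folds[[f]], idx[starts[f]:stops[f]])
      }
    }
  })
  lapply(folds, sort)
}

#' Cross-validated RSS and explained-variance curves
#'
#' For every repeat and every candidate component count, fits a PLS model on
#' each training fold, predicts the held-out rows, pools all out-of-fold
#' predictions of the repeat, and records the pooled residual sum of squares
#' \code{RSS_r(a)} and the explained-variance fraction
#' \code{1 - RSS_r(a)/TSS}. Pooling out-of-fold predictions before computing
#' RSS (the PRESS/Q2 convention) keeps the estimate stable for small folds.
#'
#' @param X predictor matrix or \code{\link{data_block}}.
#' @param Y response matrix, vector or \code{\link{data_block}}.
#' @param cv a \code{\link{cv_config}}.
#' @return An object of class \code{cv_curve}: matrices \code{rss} and
#'   \code{evar} (repeats x max_components) plus the resolved
#'   \code{max_components}.
#' @export
cv_curve <- function(X, Y, cv) {
  stopifnot(inherits(cv, "cv_config"))
  X <- as_block_matrix(X)
  Y <- as_block_matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y row counts differ")
  strata <- if (is.null(cv$strata)) rep("all", n) else as.character(cv$strata)
  if (length(strata) != n) stop("strata length does not match sample count")
  n_train_min <- n - ceiling(n / cv$k)
  a_max <- min(n_train_min - 1L, ncol(X),
               if (is.null(cv$max_components)) 10L else cv$max_components)
  if (a_max < 1) stop("no admissible component count for this fold size")
  y_bar <- colMeans(Y)
  tss_global <- sum(sweep(Y, 2, y_bar)^2)
  if (tss_global < 1e-300) stop("response has zero total variance")

  rss <- matrix(NA_real_, cv$repeats, a_max)
  evar <- matrix(NA_real_, cv$repeats, a_max)
  for (r in seq_len(cv$repeats)) {
    folds <- make_stratified_folds(strata, cv$k, sub_seed(cv$seed, r))
    oof <- array(0, dim = c(n, ncol(Y), a_max))
    tss_r <- tss_global
    if (cv$tss_reference == "train") tss_r <- 0
    for (f in seq_len(cv$k)) {
      test <- folds[[f]]
      train <- setdiff(seq_len(n), test)
      Xtr <- X[train, , drop = FALSE]
      Xte <- X[test, , drop = FALSE]
      if (cv$scale_in_fold) {
        sds <- apply(Xtr, 2, stats::sd)
        sds[sds == 0] <- 1
        Xtr <- sweep(Xtr, 2, sds, "/")
        Xte <- sweep(Xte, 2, sds, "/")
      }
      if (all(apply(Xtr, 2, stats::sd) == 0))
        stop("training fold has only constant predictors")
      fit <- fit_pls(Xtr, Y[train, , drop = FALSE],
                     min(a_max, length(train) - 1L, ncol(X)))
      for (a in seq_len(a_max))
        oof[test, , a] <- predict(fit, Xte, ncomp = a)
      if (cv$tss_reference == "train")
        tss_r <- tss_r +
          sum(sweep(Y[test, , drop = FALSE], 2,
                    colMeans(Y[train, , drop = FALSE]))^2)
    }
    for (a in seq_len(a_max)) {
      rss[r, a] <- sum((Y - oof[, , a])^2)
      evar[r, a] <- 1 - rss[r, a] / tss_r
    }
  }
  structure(list(rss = rss, evar = evar, max_components = a_max,
                 k = cv$k, repeats = cv$repeats, seed = cv$seed),
            class = "cv_curve")
}

#' One-standard-error component selection
#'
#' Selects the most parsimonious component count whose mean cross-validated
#' residual sum of squares is no greater than the smallest mean RSS plus one
#' standard deviation, where the standard deviation is taken across the CV
#' repetitions at the minimizing component count. Ties in the minimum go to
#' the smaller count.
#'
#' @param curve a \code{\link{cv_curve}}, or any object with an \code{rss}
#'   matrix of per-repeat RSS values (repeats x components).
#' @return The selected component count (integer >= 1).
#' @export
one_se_select <- function(curve) {
  rss <- curve$rss
  if (is.null(rss) || length(rss) == 0) stop("empty CV curve")
  rss <- as.matrix(rss)
  m <- colMeans(rss)
  a_star <- which.min(m)
  s <- if (nrow(rss) > 1) stats::sd(rss[, a_star]) else 0
  as.integer(which(m <= m[a_star] + s)[1])
}

#' Cross-validated explained variance at a fixed component count
#'
#' Mean and standard deviation, across the CV repetitions, of the
#' out-of-fold explained-variance fraction at the given component count,
#' expressed in percent. This is the quantity reported as a global or
#' partial effect.
#'
#' @param X,Y predictors and response (matrices or data blocks).
#' @param n_components fixed component count (>= 1).
#' @param cv a \code{\link{cv_config}}.
#' @param curve optionally, a precomputed \code{\link{cv_curve}} for the same
#'   data and configuration, reused instead of recomputing.
#' @return A list with \code{mean_percent} and \code{sd_percent}.
#' @export
cv_explained_variance <- function(X, Y, n_components, cv, curve = NULL) {
  if (n_components < 1) stop("n_components must be >= 1")
  if (is.null(curve)) curve <- cv_curve(X, Y, cv)
  if (n_components > curve$max_components)
    stop("n_components exceeds the curve's component range")
  vals <- curve$evar[, n_components]
  list(mean_percent = 100 * mean(vals),
       sd_percent = 100 * stats::sd(vals))
}
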