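#' Bootstrap VIP summary for a fitted model size
#'
#' Draws \code{n_boot} bootstrap resamples of the rows (with replacement,
#' stratified on the outcome so that class counts are preserved — important
#' with only ~100 samples), refits the PLS model on each resample at the
#' component count already selected on the full data (early stopping
#' allowed on rank-deficient resamples), and summarizes each variable's VIP
#' by its bootstrap mean and standard deviation next to the observed
#' full-data VIP. A resample with a constant response is redrawn (bounded
#' retries).
#'
#' @param X predictors (block or matrix); @param Y response.
#' @param n_components fixed component count from the full-data selection.
#' @param n_boot number of bootstrap repetitions (default 500).
#' @param strata per-sample labels preserved by the resampling; \code{NULL}
#'   for plain (unstratified) bootstrap.
#' @param seed integer seed; results are deterministic given it.
#' @param threshold mean-bootstrap-VIP importance cutoff (default 1).
#' @param variable_ids optional variable names (defaults to X's column
#'   names).
#' @param max_retries redraw budget for degenerate resamples.
#' @return An object of class \code{vip_result}: \code{observed_vip},
#'   \code{boot_mean}, \code{boot_sd}, \code{n_boot}, \code{threshold} and
#'   the logical \code{important} flags (\code{boot_mean > threshold}).
#' @export
bootstrap_vip <- function(X, Y, n_components, n_boot = 500L, strata = NULL,
                          seed = 1L, threshold = 1, variable_ids = NULL,
                          max_retries = 25L) {
  Xm <- as_block_matrix(X)
  Ym <- as_block_matrix(Y)
  n <- nrow(Xm); p <- ncol(Xm)
  if (is.null(variable_ids))
    variable_ids <- if (!is.null(colnames(Xm))) colnames(Xm)
                    else paste0("V", seq_len(p))
  if (n_boot < 2) stop("n_boot must be >= 2")
  obs <- vip(fit_pls(Xm, Ym, n_components))
  strata <- if (is.null(strata)) rep("all", n) else as.character(strata)
  by_level <- split(seq_len(n), strata)

  vips <- matrix(NA_real_, n_boot, p)
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      for (retry in seq_len(max_retries)) {
        idx <- unlist(lapply(by_level, function(ii)
          ii[sample.int(length(ii), length(ii), replace = TRUE)]),
          use.names = FALSE)
        Yb <- Ym[idx, , drop = FALSE]
        if (sum(sweep(Yb, 2, colMeans(Yb))^2) > 1e-12) break
        if (retry == max_retries)
          stop("could not draw a resample with non-constant response")
      }
      a_b <- min(n_components, length(idx) - 1L, p)
      fit <- fit_pls(Xm[idx, , drop = FALSE], Yb, a_b)
      if (fit$n_components >= 1) vips[b, ] <- vip(fit)
    }
  })
  ok <- stats::complete.cases(vips)
  vips <- vips[ok, , drop = FALSE]
  bm <- colMeans(vips)
  bs <- apply(vips, 2, stats::sd)
  structure(list(variable_ids = variable_ids,
                 observed_vip = unname(obs),
                 boot_mean = bm, boot_sd = bs,
                 n_boot = as.integer(nrow(vips)),
                 threshold = threshold,
                 important = bm > threshold),
            class = "vip_result")
}

#' @export
print.vip_result <- function(x, ...) {
  cat(sprintf("<vip_result> %d variables, %d bootstrap repetitions, threshold %.2f\n",
              length(x$variable_ids), x$n_boot, x$threshold))
  cat("  important:", paste(x$variable_ids[x$important], collapse = ", "), "\n")
  invisible(x)
}

#' Variables whose mean bootstrap VIP exceeds a threshold
#'
#' @param vip_res a \code{\link{bootstrap_vip}} result.
#' @param threshold importance cutoff (> 0); defaults to the one recorded in
#'   \code{vip_res}.
#' @return Character vector of variable ids with mean bootstrap VIP strictly
#'   above the threshold, ordered by decreasing mean bootstrap VIP.
#' @export
select_important <- function(vip_res, threshold = vip_res$threshold) {
  stopifnot(inherits(vip_res, "vip_result"))
  if (threshold < 0) stop("threshold must be positive")
  sel <- which(vip_res$boot_mean > threshold)
  sel <- sel[order(vip_res$boot_mean[sel], decreasing = TRUE)]
  vip_res$variable_ids[sel]
}

#' Log2 fold-change of each variable between outcome classes
#'
#' Per variable, \code{log2(mean over cases / mean over controls)},
#' computed on data that are neither mean-centered nor scaled to unit
#' variance — i.e. the transformed-but-unscaled block (post zero-replacement
#' and log transform for intensity data, raw for clinical variables). A
#' non-positive group mean yields \code{NA} for that variable rather than an
#' error. No fold-change is defined for residual blocks.
#'
#' @param block_unscaled a \code{\link{data_block}} before unit-variance
#'   scaling.
#' @param outcome an \code{\link{encode_outcome}} result aligned with it.
#' @return Named numeric vector (NA where a group mean is not positive).
#' @export
log2_fold_change <- function(block_unscaled, outcome) {
  stopifnot(inherits(block_unscaled, "data_block"),
            inherits(outcome, "outcome"))
  x <- block_unscaled$values
  if (nrow(x) != length(outcome$coded))
    stop("block and outcome sample counts differ")
  cases <- outcome$coded == 1
  if (!any(cases) || all(cases)) stop("both outcome classes must be non-empty")
  m1 <- colMeans(x[cases, , drop = FALSE])
  m0 <- colMeans(x[!cases, , drop = FALSE])
  fc <- rep(NA_real_, ncol(x))
  ok <- m1 > 0 & m0 > 0
  fc[ok] <- log2(m1[ok] / m0[ok])
  names(fc) <- block_unscaled$variable_ids
  fc
}
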