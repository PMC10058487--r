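#' Declare a three-vertex path diagram
#'
#' Assigns named blocks to the three roles of the path: A (input block whose
#' effect is quantified), B (mediating block), and C (output, usually the
#' binary outcome).
#'
#' @param input name of the input block (role A).
#' @param mediator name of the mediating block (role B).
#' @param output name of the output (role C); default \code{"y"}, the
#'   outcome.
#' @return An object of class \code{path_diagram}.
#' @export
path_diagram <- function(input, mediator, output = "y") {
  roles <- c(input = input, mediator = mediator, output = output)
  if (anyDuplicated(roles)) stop("the three path roles must be distinct")
  structure(as.list(roles), class = "path_diagram")
}

effect_estimate <- function(kind, mean_percent, sd_percent, n_components_main,
                            n_components_CB = NULL, n_components_AB = NULL,
                            degenerate = FALSE) {
  structure(list(kind = kind, mean_percent = mean_percent,
                 sd_percent = sd_percent,
                 n_components_main = n_components_main,
                 n_components_CB = n_components_CB,
                 n_components_AB = n_components_AB,
                 degenerate = degenerate),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<%s effect> %.2f %% (SD %.2f), %d component(s)",
              x$kind, x$mean_percent, x$sd_percent, x$n_components_main))
  if (!is.null(x$n_components_CB))
    cat(sprintf(" [C~B: %d, A~B: %d]", x$n_components_CB, x$n_components_AB))
  cat("\n")
  invisible(x)
}

# Training (resubstitution) explained-variance fraction of Y ~ X at ncomp.
training_explained_variance <- function(X, Y, n_components) {
  fit <- fit_pls(X, Y, n_components)
  if (fit$n_components == 0L) return(0)
  explained_variance_fraction(as_block_matrix(Y), predict(fit, X))
}

#' Global effect of an input block on an output
#'
#' The global effect of A on C is the share of C's variance explained when C
#' is regressed on A by PLS: the component count is chosen by repeated
#' stratified k-fold cross-validation with the one-standard-error rule, and
#' the reported percentage is the mean (with SD) over the CV repetitions of
#' the out-of-fold explained variance at that count. With
#' \code{estimation = "training"} the resubstitution explained variance is
#' returned instead (useful for closed-form checks: for single standardized
#' variables it equals the squared correlation).
#'
#' @param A input block (\code{\link{data_block}} or matrix), scaled
#'   upstream.
#' @param C output: the coded outcome vector, a matrix, or a block; centered
#'   internally by the model, never scaled.
#' @param cv a \code{\link{cv_config}}.
#' @param n_components optional fixed component count, bypassing selection.
#' @param estimation \code{"cv"} (default) or \code{"training"}.
#' @return An \code{effect_estimate} of kind \code{"global"}.
#' @export
global_effect <- function(A, C, cv, n_components = NULL,
                          estimation = c("cv", "training")) {
  estimation <- match.arg(estimation)
  X <- as_block_matrix(A)
  Y <- as_block_matrix(C)
  if (estimation == "training") {
    if (is.null(n_components))
      stop("training estimation requires a fixed n_components")
    ev <- training_explained_variance(X, Y, n_components)
    return(effect_estimate("global", 100 * ev, 0, as.integer(n_components)))
  }
  curve <- cv_curve(X, Y, cv)
  a <- if (is.null(n_components)) one_se_select(curve)
       else as.integer(n_components)
  est <- cv_explained_variance(X, Y, a, cv, curve = curve)
  effect_estimate("global", est$mean_percent, est$sd_percent, a)
}

#' Remove the part of a target explained by a mediating block
#'
#' Fits a PLS regression of the target on the mediator B, the component
#' count chosen by cross-validation with the one-SE rule, and returns the
#' training residuals (centered target minus centered fitted values). These
#' residual blocks are the inputs of the partial-effect regression; their
#' column means are zero by construction.
#'
#' @param target matrix, vector or \code{\link{data_block}} to residualize.
#' @param B the mediating block.
#' @param cv a \code{\link{cv_config}} used to select the component count.
#' @param n_components optional fixed component count, bypassing selection.
#' @return An object of class \code{pls_residuals}: the residual
#'   \code{values} matrix, the fitted \code{model}, and \code{n_components}.
#' @export
residualize <- function(target, B, cv, n_components = NULL) {
  Y <- as_block_matrix(target)
  X <- as_block_matrix(B)
  if (is.null(n_components)) {
    curve <- cv_curve(X, Y, cv)
    n_components <- one_se_select(curve)
  }
  fit <- fit_pls(X, Y, n_components)
  res <- Y - predict(fit, X)
  structure(list(values = res, model = fit,
                 n_components = fit$n_components),
            class = "pls_residuals")
}

#' Partial effect of an input block on an output, given a mediator
#'
#' The partial effect of A on C given B first removes the linear dependence
#' of both C and A on B (two PLS residualizations fitted on the full data,
#' each with its own CV-selected component count) and then measures, by the
#' same cross-validated procedure as the global effect, the share of the C
#' residuals' variance explained by the A residuals. Percentages are of the
#' residual variance, not of the original variance of C, generalizing the
#' squared partial correlation. Residual blocks are deliberately not
#' rescaled: the effect is a ratio of raw residual norms.
#'
#' If B reproduces A exactly the A residuals vanish and the partial effect
#' is returned as 0 with a degeneracy warning, the correct limiting value.
#'
#' @param A input block; @param C output; @param B mediating block.
#' @param cv a \code{\link{cv_config}}.
#' @param n_components optional fixed component count for the final
#'   residual-on-residual regression.
#' @param n_components_CB,n_components_AB optional fixed counts for the two
#'   residualizations.
#' @param estimation \code{"cv"} (default) or \code{"training"}
#'   (resubstitution; equals the squared partial correlation for single
#'   standardized variables).
#' @return An \code{effect_estimate} of kind \code{"partial"} carrying all
#'   three component counts.
#' @export
partial_effect <- function(A, C, B, cv, n_components = NULL,
                           n_components_CB = NULL, n_components_AB = NULL,
                           estimation = c("cv", "training")) {
  estimation <- match.arg(estimation)
  EBC <- residualize(C, B, cv, n_components = n_components_CB)
  EBA <- residualize(A, B, cv, n_components = n_components_AB)
  if (sum(EBA$values^2) < 1e-20 * max(1, sum(as_block_matrix(A)^2))) {
    warning("mediator reproduces the input block exactly; partial effect is 0")
    return(effect_estimate("partial", 0, 0, 1L,
                           EBC$n_components, EBA$n_components,
                           degenerate = TRUE))
  }
  if (estimation == "training") {
    if (is.null(n_components))
      stop("training estimation requires a fixed n_components")
    ev <- training_explained_variance(EBA$values, EBC$values, n_components)
    return(effect_estimate("partial", 100 * ev, 0,
                           as.integer(n_components),
                           EBC$n_components, EBA$n_components))
  }
  curve <- cv_curve(EBA$values, EBC$values, cv)
  a <- if (is.null(n_components)) one_se_select(curve)
       else as.integer(n_components)
  est <- cv_explained_variance(EBA$values, EBC$values, a, cv, curve = curve)
  effect_estimate("partial", est$mean_percent, est$sd_percent, a,
                  EBC$n_components, EBA$n_components)
}

#' Run a full path analysis
#'
#' Executes the whole pipeline for one path diagram: the global effect of
#' the input block on the output, the partial effect given the mediator,
#' bootstrap VIP analyses of both final models (global model on the input
#' block; partial model on the residual blocks), and log2 fold-changes of
#' the input block's variables computed on unscaled data when available
#' (fold-changes are not meaningful on residuals, so none are reported for
#' the partial model).
#'
#' @param diagram a \code{\link{path_diagram}} whose names resolve into
#'   \code{blocks} (role C may name the outcome).
#' @param blocks named list of preprocessed (scaled) \code{data_block}s.
#' @param outcome an \code{\link{encode_outcome}} result; used as C when the
#'   diagram's output role is not a block, and as the stratification and
#'   bootstrap grouping variable throughout.
#' @param cv a \code{\link{cv_config}}; if its \code{strata} is \code{NULL}
#'   the outcome labels are used.
#' @param n_boot bootstrap repetitions for the VIP summaries (default 500).
#' @param vip_threshold_global,vip_threshold_partial mean-bootstrap-VIP
#'   importance thresholds for the two models (analyst-chosen; default 1).
#' @param unscaled_blocks optional named list of transformed-but-unscaled
#'   blocks (post zero-replacement and log transform) used for log2
#'   fold-changes; fold-changes are omitted when the input block is absent.
#' @return An object of class \code{path_report}.
#' @export
run_path <- function(diagram, blocks, outcome, cv,
                     n_boot = 500L, vip_threshold_global = 1,
                     vip_threshold_partial = 1, unscaled_blocks = NULL) {
  stopifnot(inherits(diagram, "path_diagram"), inherits(outcome, "outcome"))
  get_block <- function(role) {
    nm <- diagram[[role]]
    if (!nm %in% names(blocks))
      stop("diagram role '", role, "' names unknown block '", nm, "'")
    blocks[[nm]]
  }
  A <- get_block("input")
  B <- get_block("mediator")
  C <- if (diagram$output %in% names(blocks)) blocks[[diagram$output]]$values
       else matrix(outcome$coded, ncol = 1, dimnames = list(NULL, diagram$output))
  if (is.null(cv$strata)) cv$strata <- outcome$labels

  glob <- global_effect(A, C, cv)
  part <- partial_effect(A, C, B, cv)

  vip_global <- bootstrap_vip(A, C, n_components = glob$n_components_main,
                              n_boot = n_boot, strata = outcome$labels,
                              seed = sub_seed(cv$seed, 7717L),
                              threshold = vip_threshold_global)
  EBC <- residualize(C, B, cv, n_components = part$n_components_CB)
  EBA <- residualize(A, B, cv, n_components = part$n_components_AB)
  vip_partial <- if (!isTRUE(part$degenerate)) {
    bootstrap_vip(EBA$values, EBC$values,
                  n_components = part$n_components_main,
                  n_boot = n_boot, strata = outcome$labels,
                  seed = sub_seed(cv$seed, 7919L),
                  threshold = vip_threshold_partial,
                  variable_ids = A$variable_ids)
  } else NULL

  log2_fc <- NULL
  if (!is.null(unscaled_blocks) && diagram$input %in% names(unscaled_blocks))
    log2_fc <- log2_fold_change(unscaled_blocks[[diagram$input]], outcome)

  structure(list(diagram = diagram,
                 global = glob, partial = part,
                 vip_global = vip_global, vip_partial = vip_partial,
                 log2_fc = log2_fc,
                 n_samples = nrow(A$values),
                 class_counts = as.list(table(outcome$labels)),
                 cv = list(k = cv$k, repeats = cv$repeats, seed = cv$seed),
                 n_boot = as.integer(n_boot)),
            class = "path_report")
}

#' @export
print.path_report <- function(x, ...) {
  cat(sprintf("<path_report> %s => %s | %s  (n = %d)\n",
              x$diagram$input, x$diagram$output, x$diagram$mediator,
              x$n_samples))
  print(x$global); print(x$partial)
  invisible(x)
}
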