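#' Specification of a synthetic multiblock dataset
#'
#' Describes a latent-factor generative model emulating the structure of a
#' clinical + metabolomics case-control study: a low-dimensional
#' clinical-like block A, a high-dimensional collinear metabolomics-like
#' block B, and a binary outcome driven by the shared latent factors. The
#' defaults mirror the case-study dimensions (99 samples, 6 clinical
#' variables, 102 metabolomic variables).
#'
#' Three mediation scenarios with known qualitative truth are built in:
#' \describe{
#'   \item{\code{shared_plus_unique}}{one latent factor loads on both
#'     blocks, one only on A, one only on B; the outcome depends on all
#'     three, so the partial effect of A given B is strictly below its
#'     global effect.}
#'   \item{\code{full_mediation}}{every latent loading on A also loads on
#'     B and the outcome depends only on those latents, so the population
#'     partial effect of A given B is zero.}
#'   \item{\code{independent_inputs}}{A and B load on disjoint latent sets
#'     and the outcome depends only on A's latents, so conditioning on B
#'     changes nothing: partial equals global.}
#' }
#'
#' @param n_samples,p_A,p_B dimensions (defaults 99, 6, 102).
#' @param mediation_scenario one of \code{"shared_plus_unique"},
#'   \code{"full_mediation"}, \code{"independent_inputs"}.
#' @param n_latents number of latent factors; default depends on scenario
#'   (3, 3 and 4 respectively).
#' @param loadings_A,loadings_B optional explicit loading matrices
#'   (p x n_latents); by default drawn from the scenario's sparsity pattern.
#' @param latent_to_outcome weight vector mapping latents to the continuous
#'   outcome score; scenario default.
#' @param noise_sd_A,noise_sd_B independent Gaussian noise SDs (default 0.5,
#'   a moderate noise level for unit-variance latent signal).
#' @param outcome_model \code{"threshold"} (default; median split, which
#'   guarantees near-balanced classes as in a matched case-control design)
#'   or \code{"logistic"} (Bernoulli draw on the logistic-transformed
#'   score).
#' @param seed integer seed; the dataset is a deterministic function of the
#'   spec.
#' @return An object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_samples = 99L, p_A = 6L, p_B = 102L,
                           mediation_scenario = c("shared_plus_unique",
                                                  "full_mediation",
                                                  "independent_inputs"),
                           n_latents = NULL,
                           loadings_A = NULL, loadings_B = NULL,
                           latent_to_outcome = NULL,
                           noise_sd_A = 0.5, noise_sd_B = 0.5,
                           outcome_model = c("threshold", "logistic"),
                           seed = 1L) {
  mediation_scenario <- match.arg(mediation_scenario)
  outcome_model <- match.arg(outcome_model)
  if (is.null(n_latents))
    n_latents <- switch(mediation_scenario,
                        shared_plus_unique = 3L,
                        full_mediation = 3L,
                        independent_inputs = 4L)
  if (noise_sd_A < 0 || noise_sd_B < 0) stop("noise SDs must be >= 0")
  structure(list(n_samples = as.integer(n_samples),
                 p_A = as.integer(p_A), p_B = as.integer(p_B),
                 n_latents = as.integer(n_latents),
                 mediation_scenario = mediation_scenario,
                 loadings_A = loadings_A, loadings_B = loadings_B,
                 latent_to_outcome = latent_to_outcome,
                 noise_sd_A = noise_sd_A, noise_sd_B = noise_sd_B,
                 outcome_model = outcome_model,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Which latents load on A / on B, and the outcome weights, per scenario.
scenario_pattern <- function(spec) {
  L <- spec$n_latents
  switch(spec$mediation_scenario,
    shared_plus_unique = {
      shared <- seq_len(max(1L, L - 2L))
      a_only <- if (L >= 2) max(1L, L - 2L) + 1L else integer(0)
      b_only <- if (L >= 3) L else integer(0)
      w <- numeric(L); w[shared] <- 1; w[a_only] <- 0.8; w[b_only] <- 0.8
      list(on_A = c(shared, a_only), on_B = c(shared, b_only), w = w)
    },
    full_mediation = {
      list(on_A = seq_len(L), on_B = seq_len(L), w = rep(1, L))
    },
    independent_inputs = {
      half <- max(1L, L %/% 2L)
      on_A <- seq_len(half); on_B <- seq.int(half + 1L, L)
      w <- numeric(L); w[on_A] <- 1
      list(on_A = on_A, on_B = on_B, w = w)
    })
}

#' Generate a synthetic multiblock dataset with known latent structure
#'
#' Draws latent factors F (independent standard normal), builds
#' \code{A = F L_A' + noise} and \code{B = F L_B' + noise}, computes the
#' continuous score \code{s = F w}, and dichotomizes it into a binary
#' outcome (median threshold by default). Everything — loadings included —
#' is a deterministic function of the spec's seed.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return A list with data blocks \code{A} and \code{B}, the
#'   \code{outcome}, and a \code{truth} record (latent factors, score,
#'   loadings, outcome weights, scenario).
#' @export
generate_multiblock <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pat <- scenario_pattern(spec)
  n <- spec$n_samples; L <- spec$n_latents
  withr::with_seed(spec$seed, {
    LA <- spec$loadings_A
    if (is.null(LA)) {
      LA <- matrix(0, spec$p_A, L)
      LA[, pat$on_A] <- matrix(stats::runif(spec$p_A * length(pat$on_A),
                                            0.5, 1.2) *
                                 sample(c(-1, 1), spec$p_A * length(pat$on_A),
                                        replace = TRUE),
                               spec$p_A)
    }
    LB <- spec$loadings_B
    if (is.null(LB)) {
      LB <- matrix(0, spec$p_B, L)
      LB[, pat$on_B] <- matrix(stats::runif(spec$p_B * length(pat$on_B),
                                            0.5, 1.2) *
                                 sample(c(-1, 1), spec$p_B * length(pat$on_B),
                                        replace = TRUE),
                               spec$p_B)
    }
    w <- if (is.null(spec$latent_to_outcome)) pat$w else spec$latent_to_outcome
    if (length(w) != L) stop("latent_to_outcome must have n_latents entries")
    FF <- matrix(stats::rnorm(n * L), n, L)
    A <- FF %*% t(LA) +
      matrix(stats::rnorm(n * spec$p_A, sd = spec$noise_sd_A), n)
    B <- FF %*% t(LB) +
      matrix(stats::rnorm(n * spec$p_B, sd = spec$noise_sd_B), n)
    s <- drop(FF %*% w)
    labels <- if (spec$outcome_model == "threshold") {
      ifelse(s > stats::median(s), "case", "control")
    } else {
      ifelse(stats::runif(n) < stats::plogis(s), "case", "control")
    }
  })
  ids <- sprintf("S%03d", seq_len(n))
  list(A = data_block(A, ids, sprintf("A%02d", seq_len(spec$p_A))),
       B = data_block(B, ids, sprintf("B%03d", seq_len(spec$p_B))),
       outcome = encode_outcome(labels, case = "case", sample_ids = ids),
       truth = list(latents = FF, score = s, loadings_A = LA, loadings_B = LB,
                    outcome_weights = w,
                    scenario = spec$mediation_scenario))
}

#' Draw a trivariate Gaussian test system
#'
#' Generates n samples of three single-variable blocks (A, B, C) from a
#' standard trivariate normal with the given correlations — the
#' unidimensional setting in which the global effect reduces to the squared
#' correlation and the partial effect to the squared partial correlation.
#'
#' @param correlations numeric vector \code{c(r_AB, r_AC, r_BC)} (named
#'   entries \code{r_AB}, \code{r_AC}, \code{r_BC} also accepted).
#' @param n number of samples.
#' @param seed integer seed.
#' @return A list of three single-column \code{data_block}s \code{A},
#'   \code{B}, \code{C}.
#' @export
generate_trivariate <- function(correlations, n, seed = 1L) {
  S <- trivariate_sigma(correlations)
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < -1e-10)
    stop("correlation matrix is not positive semi-definite")
  R <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  X <- withr::with_seed(seed, matrix(stats::rnorm(n * 3), n, 3) %*% R)
  ids <- sprintf("S%04d", seq_len(n))
  list(A = data_block(X[, 1, drop = FALSE], ids, "xA"),
       B = data_block(X[, 2, drop = FALSE], ids, "xB"),
       C = data_block(X[, 3, drop = FALSE], ids, "xC"))
}

trivariate_sigma <- function(correlations) {
  r <- as.numeric(correlations)
  if (length(r) != 3) stop("correlations must be c(r_AB, r_AC, r_BC)")
  if (!is.null(names(correlations)) &&
      all(c("r_AB", "r_AC", "r_BC") %in% names(correlations)))
    r <- as.numeric(correlations[c("r_AB", "r_AC", "r_BC")])
  matrix(c(1, r[1], r[2],
           r[1], 1, r[3],
           r[2], r[3], 1), 3, 3)
}

#' Population global and partial effects in the unidimensional case
#'
#' For single standardized variables with correlations
#' \code{(r_AB, r_AC, r_BC)}, the global effect of A on C is the squared
#' correlation \code{r_AC^2} and the partial effect given B is the squared
#' partial correlation
#' \code{((r_AC - r_AB r_BC) / sqrt((1 - r_AB^2)(1 - r_BC^2)))^2}. These
#' closed forms are the oracles against which the PLS pipeline is checked.
#'
#' @param correlations as in \code{\link{generate_trivariate}}.
#' @return A list with \code{global} and \code{partial} (fractions, not
#'   percent).
#' @export
population_effects_unidimensional <- function(correlations) {
  S <- trivariate_sigma(correlations)
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("correlation matrix is not positive semi-definite")
  r_ab <- S[1, 2]; r_ac <- S[1, 3]; r_bc <- S[2, 3]
  if (abs(r_ab) >= 1 || abs(r_bc) >= 1)
    stop("conditioning on B is degenerate when |r_AB| or |r_BC| equals 1")
  partial <- ((r_ac - r_ab * r_bc) / sqrt((1 - r_ab^2) * (1 - r_bc^2)))^2
  list(global = r_ac^2, partial = partial)
}
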