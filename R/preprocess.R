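#' Replace zero intensities by a fraction of the per-variable minimum
#'
#' Every zero entry of a variable is replaced by \code{fraction} times the
#' smallest strictly positive value observed for that variable, the usual
#' minimum-based imputation applied to untargeted metabolomics intensity
#' tables before log transformation. Non-zero entries are untouched.
#'
#' @param block a \code{\link{data_block}} with non-negative entries.
#' @param fraction replacement fraction in (0, 1]; default 0.8.
#' @return The block with zeros replaced and \code{"zeros_replaced"} appended
#'   to its provenance.
#' @export
replace_zeros <- function(block, fraction = 0.8) {
  stopifnot(inherits(block, "data_block"))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be a single number in (0, 1]")
  x <- block$values
  if (any(x < 0, na.rm = TRUE))
    stop("replace_zeros requires non-negative entries")
  has_zero <- apply(x == 0, 2, any)
  has_zero[is.na(has_zero)] <- FALSE
  for (j in which(has_zero)) {
    pos <- x[, j][x[, j] > 0 & !is.na(x[, j])]
    if (length(pos) == 0)
      stop("all-zero variable: '", block$variable_ids[j],
           "' has no positive minimum")
    x[, j][x[, j] == 0 & !is.na(x[, j])] <- fraction * min(pos)
  }
  block_with(block, x, "zeros_replaced")
}

#' Elementwise logarithm of a block
#'
#' @param block a \code{\link{data_block}} with strictly positive entries
#'   (apply \code{\link{replace_zeros}} first).
#' @param base logarithm base (> 1); default natural log.
#' @return The log-transformed block, \code{"log"} appended to provenance.
#' @export
log_transform <- function(block, base = exp(1)) {
  stopifnot(inherits(block, "data_block"))
  if (!is.numeric(base) || length(base) != 1 || base <= 1)
    stop("base must be a single number > 1")
  x <- block$values
  bad <- which(x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-positive entry at sample '%s', variable '%s'",
                 block$sample_ids[bad[1, 1]], block$variable_ids[bad[1, 2]]))
  block_with(block, log(x, base = base), "log")
}

#' Scale every variable to unit variance
#'
#' Divides each column by its sample standard deviation (denominator n - 1).
#' Columns are deliberately not mean-centered here: centering is done per
#' training set inside model fitting, so that cross-validation remains honest,
#' while scaling is a one-off global preprocessing step.
#'
#' @param block a \code{\link{data_block}} with at least 2 samples.
#' @return The scaled block, \code{"uv_scaled"} appended to provenance.
#' @export
scale_unit_variance <- function(block) {
  stopifnot(inherits(block, "data_block"))
  x <- block$values
  if (nrow(x) < 2) stop("scaling requires at least 2 samples")
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  zero <- which(!is.finite(sds) | sds == 0)
  if (length(zero))
    stop("zero-variance variable: '", block$variable_ids[zero[1]], "'")
  block_with(block, sweep(x, 2, sds, "/"), "uv_scaled")
}

#' Encode a two-class outcome as 0/1
#'
#' Deterministically codes a binary status vector, mapping the case label to 1
#' and the other label to 0. All explained-variance results downstream are
#' invariant to swapping which label is called the case (the centered coded
#' vector merely flips sign).
#'
#' @param labels per-sample class labels (exactly two distinct values).
#' @param case the label to map to 1; defaults to the last label in sort
#'   order so that \code{c("case", "control")} maps "control" to 0.
#' @param sample_ids optional sample identifiers aligned with \code{labels}.
#' @return An object of class \code{outcome} with fields \code{labels},
#'   \code{coded}, \code{case_label} and \code{sample_ids}.
#' @export
encode_outcome <- function(labels, case = NULL, sample_ids = NULL) {
  labels <- as.character(labels)
  lv <- sort(unique(labels[!is.na(labels)]))
  if (length(lv) != 2)
    stop("outcome must have exactly two distinct labels, got: ",
         paste(lv, collapse = ", "))
  if (is.null(case)) case <- if ("case" %in% lv) "case" else lv[1]
  if (!case %in% lv) stop("case label '", case, "' not present")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_along(labels))
  structure(list(labels = labels,
                 coded = as.numeric(labels == case),
                 case_label = case,
                 sample_ids = as.character(sample_ids)),
            class = "outcome")
}

#' Keep only samples complete across all blocks and the outcome
#'
#' Removes, consistently from every block and the outcome, each sample with a
#' missing value anywhere, so that all returned objects share identical
#' sample ids in identical order.
#'
#' @param blocks a named list of \code{\link{data_block}}s sharing sample ids.
#' @param outcome an \code{\link{encode_outcome}} result aligned with them.
#' @param min_class_size smallest admissible class size after filtering
#'   (cross-validation needs at least k members per class); default 2.
#' @return A list with the filtered \code{blocks}, \code{outcome}, and the
#'   per-class sample \code{counts}.
#' @export
complete_cases <- function(blocks, outcome, min_class_size = 2L) {
  stopifnot(is.list(blocks), length(blocks) >= 1, inherits(outcome, "outcome"))
  ids <- blocks[[1]]$sample_ids
  for (b in blocks) {
    if (!identical(b$sample_ids, ids))
      stop("blocks do not share identical sample ids")
  }
  if (!identical(outcome$sample_ids, ids))
    stop("outcome sample ids do not match the blocks")
  keep <- !is.na(outcome$labels)
  for (b in blocks) keep <- keep & stats::complete.cases(b$values)
  if (!any(keep)) stop("no complete samples remain")
  counts <- table(outcome$labels[keep])
  if (length(counts) < 2 || any(counts < min_class_size))
    stop("a class has fewer than ", min_class_size,
         " complete samples; cross-validation impossible")
  blocks <- lapply(blocks, function(b)
    data_block(b$values[keep, , drop = FALSE], b$sample_ids[keep],
               b$variable_ids, b$provenance))
  outcome <- structure(list(labels = outcome$labels[keep],
                            coded = outcome$coded[keep],
                            case_label = outcome$case_label,
                            sample_ids = outcome$sample_ids[keep]),
                       class = "outcome")
  list(blocks = blocks, outcome = outcome, counts = counts)
}
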