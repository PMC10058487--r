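#' Construct a data block
#'
#' A data block is a samples x variables numeric matrix together with sample
#' and variable identifiers and a provenance record listing, in order, the
#' preprocessing steps already applied (e.g. \code{"zeros_replaced"},
#' \code{"log"}, \code{"uv_scaled"}).
#'
#' @param values numeric matrix, samples in rows, variables in columns.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to the row names of \code{values}.
#' @param variable_ids character vector of unique variable identifiers;
#'   defaults to the column names of \code{values}.
#' @param provenance character vector of transformation tags already applied.
#' @return An object of class \code{data_block}.
#' @export
data_block <- function(values, sample_ids = rownames(values),
                       variable_ids = colnames(values),
                       provenance = character()) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("data_block values must be numeric")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(variable_ids)) variable_ids <- paste0("V", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  variable_ids <- as.character(variable_ids)
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length does not match number of rows")
  if (length(variable_ids) != ncol(values))
    stop("variable_ids length does not match number of columns")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(variable_ids))
    stop("duplicate variable ids: ",
         paste(unique(variable_ids[duplicated(variable_ids)]), collapse = ", "))
  dimnames(values) <- list(sample_ids, variable_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 variable_ids = variable_ids,
                 provenance = as.character(provenance)),
            class = "data_block")
}

#' @export
as.matrix.data_block <- function(x, ...) x$values

#' @export
dim.data_block <- function(x) dim(x$values)

#' @export
print.data_block <- function(x, ...) {
  cat(sprintf("<data_block> %d samples x %d variables\n",
              nrow(x$values), ncol(x$values)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

# Coerce a block, matrix or vector to a plain numeric matrix.
as_block_matrix <- function(x) {
  if (inherits(x, "data_block")) return(x$values)
  if (is.null(dim(x))) return(matrix(as.numeric(x), ncol = 1))
  as.matrix(x)
}

# Tag a new provenance step on a block, replacing its values.
block_with <- function(block, values, tag) {
  data_block(values, block$sample_ids, block$variable_ids,
             c(block$provenance, tag))
}

#' @export
print.outcome <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<outcome> %d samples (%s); case label: '%s' -> 1\n",
              length(x$coded),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              x$case_label))
  invisible(x)
}
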