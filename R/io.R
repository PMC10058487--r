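#' Read a data block from a delimited text table
#'
#' First column: sample ids; header row: variable ids. Separator inferred
#' from the extension (".tsv"/".txt" tab, otherwise comma) unless given.
#' Missing values may be encoded as empty cells or \code{NA}; any other
#' non-numeric cell is an error that names its location.
#'
#' @param path file path.
#' @param sep field separator; \code{NULL} to infer from the extension.
#' @return A \code{\link{data_block}} with ids in file order.
#' @export
read_block <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("block file needs an id column and >= 1 variable")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate sample id: '", ids[duplicated(ids)][1], "'")
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2, as.numeric))
  num <- matrix(num, nrow = nrow(vals), dimnames = dimnames(vals))
  bad <- which(is.na(num) & !(is.na(vals) | trimws(vals) %in% c("", "NA")),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell '%s' at sample '%s', variable '%s'",
                 vals[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]))
  data_block(num, sample_ids = ids, variable_ids = colnames(vals))
}

#' Read an outcome file (two columns: sample id, label)
#'
#' @param path file path; @param sep as in \code{\link{read_block}}.
#' @param case label coded as 1 (see \code{\link{encode_outcome}}).
#' @return An \code{outcome} object.
#' @export
read_outcome <- function(path, sep = NULL, case = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) != 2) stop("outcome file must have exactly two columns")
  encode_outcome(df[[2]], case = case, sample_ids = df[[1]])
}

#' Serialize a path report to JSON
#'
#' The report round-trips losslessly through
#' \code{write_path_report}/\code{read_path_report} (numbers at full
#' precision).
#'
#' @param report a \code{\link{run_path}} result.
#' @param path output file.
#' @export
write_path_report <- function(report, path) {
  stopifnot(inherits(report, "path_report"))
  out <- report
  out$global <- unclass(out$global)
  out$partial <- unclass(out$partial)
  out$diagram <- unclass(out$diagram)
  if (!is.null(out$vip_global)) out$vip_global <- unclass(out$vip_global)
  if (!is.null(out$vip_partial)) out$vip_partial <- unclass(out$vip_partial)
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_path_report
#' @export
read_path_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$diagram <- structure(as.list(raw$diagram), class = "path_diagram")
  raw$global <- structure(raw$global, class = "effect_estimate")
  raw$partial <- structure(raw$partial, class = "effect_estimate")
  if (!is.null(raw$vip_global))
    raw$vip_global <- structure(raw$vip_global, class = "vip_result")
  if (!is.null(raw$vip_partial))
    raw$vip_partial <- structure(raw$vip_partial, class = "vip_result")
  structure(raw, class = "path_report")
}

#' Tabular effect summary across path reports
#'
#' One row per effect (global and partial per path), mirroring the usual
#' effects-table layout: explained variance with its SD and the component
#' counts.
#'
#' @param reports a list of \code{path_report}s (or a single one).
#' @return A data.frame.
#' @export
effects_table <- function(reports) {
  if (inherits(reports, "path_report")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    lab <- sprintf("%s => %s", r$diagram$input, r$diagram$output)
    data.frame(
      effect = c(sprintf("%s (global)", lab),
                 sprintf("%s | %s (partial)", lab, r$diagram$mediator)),
      explained_variance_pct = c(r$global$mean_percent, r$partial$mean_percent),
      sd_pct = c(r$global$sd_percent, r$partial$sd_percent),
      n_components = c(r$global$n_components_main, r$partial$n_components_main),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' VIP table for one model of a path report
#'
#' Columns mirror the usual importance-table layout: variable id, observed
#' VIP, mean bootstrap VIP, its SD, log2 fold-change (empty, not zero, for
#' partial-effect models, where fold-changes on residuals are not
#' meaningful) and the importance flag. Rows are sorted by decreasing mean
#' bootstrap VIP.
#'
#' @param report a \code{path_report}.
#' @param model \code{"global"} or \code{"partial"}.
#' @return A data.frame.
#' @export
vip_table <- function(report, model = c("global", "partial")) {
  model <- match.arg(model)
  v <- if (model == "global") report$vip_global else report$vip_partial
  if (is.null(v)) stop("no VIP result for the ", model, " model")
  fc <- rep(NA_real_, length(v$variable_ids))
  if (model == "global" && !is.null(report$log2_fc))
    fc <- unname(report$log2_fc[v$variable_ids])
  df <- data.frame(variable_id = v$variable_ids,
                   observed_vip = v$observed_vip,
                   boot_mean_vip = v$boot_mean,
                   boot_sd_vip = v$boot_sd,
                   log2_fc = fc,
                   important = v$important,
                   stringsAsFactors = FALSE)
  df[order(df$boot_mean_vip, decreasing = TRUE), , drop = FALSE]
}

#' Read a run configuration (YAML or JSON)
#'
#' Schema: block paths with roles, outcome path, per-block preprocessing
#' options (\code{zero_fraction}, \code{apply_log}, \code{log_base},
#' \code{scale}), CV options (\code{k}, \code{repeats}, \code{seed},
#' \code{max_components}, \code{scale_in_fold}), \code{n_boot}, VIP
#' thresholds, and the output directory. Validated before any computation.
#'
#' @param path YAML (.yaml/.yml) or JSON file.
#' @return A validated named list of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a named list with the same schema (for programmatic use).
#' @export
validate_run_config <- function(cfg) {
  req <- c("blocks", "outcome", "output_dir", "seed")
  miss <- setdiff(req, names(cfg))
  if (length(miss)) stop("config is missing: ", paste(miss, collapse = ", "))
  roles <- vapply(cfg$blocks, function(b) b$role %||% "", "")
  for (role in c("A", "B"))
    if (sum(roles == role) != 1)
      stop("config must assign role ", role, " to exactly one block")
  defaults <- list(k = 10L, repeats = 50L, max_components = 10L,
                   n_boot = 500L, vip_threshold_global = 1,
                   vip_threshold_partial = 1, scale_in_fold = FALSE,
                   both_paths = TRUE)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

preprocess_block <- function(block, opts) {
  opts <- opts %||% list()
  unscaled <- block
  if (isTRUE(opts$apply_log)) {
    unscaled <- replace_zeros(unscaled, opts$zero_fraction %||% 0.8)
    unscaled <- log_transform(unscaled, opts$log_base %||% exp(1))
  }
  scaled <- if (isTRUE(opts$scale %||% TRUE)) scale_unit_variance(unscaled)
            else unscaled
  list(scaled = scaled, unscaled = unscaled)
}

#' Run the full effects pipeline from a configuration
#'
#' Reads the blocks and outcome, applies the configured preprocessing
#' (zero replacement and log transform where requested, then unit-variance
#' scaling), keeps complete cases, runs the path analysis for the declared
#' A/B roles (and, by default, also the swapped path), and writes the
#' effects table, the VIP tables, the JSON path reports and a plain-text
#' log into the output directory.
#'
#' @param cfg a \code{\link{read_run_config}} result or an equivalent list.
#' @return Invisibly, the list of \code{path_report}s.
#' @export
run_effects <- function(cfg) {
  cfg <- validate_run_config(cfg)
  blocks_raw <- list(); unscaled <- list(); scaled <- list()
  for (b in cfg$blocks) {
    blk <- read_block(b$path)
    pp <- preprocess_block(blk, b)
    nm <- b$name %||% b$role
    scaled[[nm]] <- pp$scaled
    unscaled[[nm]] <- pp$unscaled
    if (b$role == "A") a_name <- nm
    if (b$role == "B") b_name <- nm
  }
  outc <- read_outcome(cfg$outcome, case = cfg$case_label %||% NULL)
  cc <- complete_cases(scaled, outc, min_class_size = cfg$k)
  keep_ids <- cc$outcome$sample_ids
  unscaled <- lapply(unscaled, function(bl)
    data_block(bl$values[match(keep_ids, bl$sample_ids), , drop = FALSE],
               keep_ids, bl$variable_ids, bl$provenance))
  cv <- cv_config(k = cfg$k, repeats = cfg$repeats,
                  strata = cc$outcome$labels, seed = cfg$seed,
                  max_components = cfg$max_components,
                  scale_in_fold = cfg$scale_in_fold)
  diagrams <- list(path_diagram(a_name, b_name))
  if (isTRUE(cfg$both_paths))
    diagrams <- c(diagrams, list(path_diagram(b_name, a_name)))
  reports <- lapply(diagrams, function(d)
    run_path(d, cc$blocks, cc$outcome, cv, n_boot = cfg$n_boot,
             vip_threshold_global = cfg$vip_threshold_global,
             vip_threshold_partial = cfg$vip_threshold_partial,
             unscaled_blocks = unscaled))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) utils::write.table(
    df, file.path(cfg$output_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE, na = "")
  tsv(effects_table(reports), "effects.tsv")
  log_lines <- c(sprintf("seed: %d", cfg$seed),
                 sprintf("k: %d  repeats: %d  n_boot: %d",
                         cfg$k, cfg$repeats, cfg$n_boot),
                 sprintf("samples kept: %d (%s)", length(keep_ids),
                         paste(sprintf("%s: %d", names(cc$counts), cc$counts),
                               collapse = ", ")))
  for (i in seq_along(reports)) {
    r <- reports[[i]]
    tag <- sprintf("path%d", i)
    write_path_report(r, file.path(cfg$output_dir, paste0(tag, "_report.json")))
    tsv(vip_table(r, "global"), paste0(tag, "_vip_global.tsv"))
    if (!is.null(r$vip_partial))
      tsv(vip_table(r, "partial"), paste0(tag, "_vip_partial.tsv"))
    log_lines <- c(log_lines, sprintf(
      "%s (%s => %s | %s): global %d comp, partial %d comp (C~B %d, A~B %d)",
      tag, r$diagram$input, r$diagram$output, r$diagram$mediator,
      r$global$n_components_main, r$partial$n_components_main,
      r$partial$n_components_CB, r$partial$n_components_AB))
  }
  writeLines(log_lines, file.path(cfg$output_dir, "run.log"))
  invisible(reports)
}

#' Write a synthetic dataset to disk
#'
#' Writes A.csv, B.csv, outcome.csv and truth.json for a
#' \code{\link{synthetic_spec}} — the file layout consumed by
#' \code{\link{run_effects}}.
#'
#' @param spec a \code{synthetic_spec}; @param dir output directory.
#' @return Invisibly, the generated dataset.
#' @export
write_synthetic <- function(spec, dir) {
  dat <- generate_multiblock(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wb <- function(block, name) {
    df <- data.frame(sample_id = block$sample_ids,
                     block$values, check.names = FALSE)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  }
  wb(dat$A, "A.csv")
  wb(dat$B, "B.csv")
  utils::write.csv(data.frame(sample_id = dat$outcome$sample_ids,
                              status = dat$outcome$labels),
                   file.path(dir, "outcome.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(scenario = dat$truth$scenario,
                            outcome_weights = dat$truth$outcome_weights,
                            score = dat$truth$score),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dat)
}
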