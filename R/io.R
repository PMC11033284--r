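#' Write a residue table as delimited text
#'
#' Comma-separated, UTF-8, '.' decimal, with the documented header
#' `pesticide,temperature_C,rh_pct,day,conc_mgkg` (plus `arm` when the
#' table distinguishes the two one-factor arms of the study design).
#'
#' @param df Long residue data frame (see [generate_study_dataset()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_residue_table <- function(df, path) {
  req <- c("pesticide", "temperature_C", "rh_pct", "day", "conc_mgkg")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cols <- c("pesticide", if ("arm" %in% names(df)) "arm",
            "temperature_C", "rh_pct", "day", "conc_mgkg")
  utils::write.csv(df[, cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a residue table
#'
#' Validates the schema (required columns, numeric cells, non-negative
#' concentrations, no duplicated day within a series) and groups the rows
#' into residue series by pesticide, storage condition and (when present)
#' design arm.
#'
#' @param path Path to a delimited residue table written by
#'   [write_residue_table()].
#' @return Named list of `residue_series`; the raw table is attached as
#'   attribute `"table"`.
#' @export
read_residue_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  req <- c("pesticide", "temperature_C", "rh_pct", "day", "conc_mgkg")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("temperature_C", "rh_pct", "day", "conc_mgkg")) {
    v <- df[[col]]
    if (is.character(v)) df[[col]] <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(df[[col]]))
    if (length(bad))
      stop("missing or non-numeric value in column ", col, " at row ", bad[1])
  }
  neg <- which(df$conc_mgkg < 0)
  if (length(neg))
    stop("negative concentration at row ", neg[1])
  series <- split_series(df)
  attr(series, "table") <- df
  series
}

#' Default pipeline configuration
#'
#' @param seed Root seed; all stage sub-seeds derive from it.
#' @param data Optional path to an existing residue table; `NULL` simulates
#'   the study design instead.
#' @param design List overriding [study_design()] arguments: `days`,
#'   `noise_sd`, and optionally `profiles`, a named list whose entries give
#'   [pesticide_profile()] arguments (the entry name is used when `name` is
#'   omitted).
#' @param quatformer List overriding [quatformer_control()] arguments.
#' @param grading List with `k_range` (length-2 min/max) and `restarts`.
#' @param stats List with `alpha` for the multiple range test.
#' @return A nested configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, data = NULL, design = list(),
                            quatformer = list(), grading = list(),
                            stats = list()) {
  if (!is.null(design$profiles)) {
    design$profiles <- lapply(names(design$profiles), function(nm) {
      args <- design$profiles[[nm]]
      if (is.null(args$name)) args$name <- nm
      do.call(pesticide_profile, args)
    })
    names(design$profiles) <- vapply(design$profiles, function(p) p$name,
                                     character(1))
  }
  cfg <- list(
    seed = as.integer(seed), data = data,
    design = utils::modifyList(list(days = 30, noise_sd = NULL), design,
                               keep.null = TRUE),
    quatformer = quatformer,
    grading = utils::modifyList(list(k_range = c(3, 7), restarts = 10),
                                grading),
    stats = utils::modifyList(list(alpha = 0.05), stats))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read a pipeline configuration file
#'
#' @param path Path to a YAML configuration mirroring [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[intersect(names(raw), names(formals(pipeline_config)))])
}
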