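# Tab-separated interchange readers with strict schema validation: required
# columns must be present and no unknown column is tolerated, so a typo or a
# unit mix-up (times are serialized as t_min for tracks and t_s for
# photokinetics, with the unit in the column name) fails loudly before any
# computation.

validate_schema <- function(df, required, optional = character(), what) {
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    abort(paste0(what, " is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  extra <- setdiff(names(df), c(required, optional))
  if (length(extra) > 0)
    abort(paste0(what, " has unknown column(s): ", paste(extra, collapse = ", ")))
  invisible(df)
}

read_checked <- function(path, required, optional, what) {
  if (!file.exists(path)) abort(paste0("input file does not exist: ", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_schema(df, required, optional, what)
  as_tibble(df)
}

#' Read a centroid-track table
#'
#' Expected TSV schema: `cell_id`, `t_min`, `x_nm`, optionally `y_nm`.
#' @param path TSV path.
#' @return A tibble.
#' @export
read_tracks <- function(path) {
  read_checked(path, c("cell_id", "t_min", "x_nm"), "y_nm", "tracks table")
}

#' Read a partition-event table
#'
#' Expected TSV schema: `event_id`, `measure_kind`, `daughter_a`,
#' `daughter_b`.
#' @param path TSV path.
#' @return A tibble.
#' @export
read_partition_events <- function(path) {
  read_checked(path, c("event_id", "measure_kind", "daughter_a", "daughter_b"),
               character(), "partition-event table")
}

#' Read an intensity-trace table
#'
#' Expected TSV schema: `cell_id`, `zone`, `t_s`, `roi`, `cell`, `bg`,
#' `event_frame`.
#' @param path TSV path.
#' @return A tibble.
#' @export
read_intensity_traces <- function(path) {
  read_checked(path, c("cell_id", "zone", "t_s", "roi", "cell", "bg", "event_frame"),
               character(), "intensity-trace table")
}

#' Read a kymograph front-line table
#'
#' Expected TSV schema: `filament_id`, `t_s`, `front_nm`.
#' @param path TSV path.
#' @return A tibble.
#' @export
read_fronts <- function(path) {
  read_checked(path, c("filament_id", "t_s", "front_nm"), character(),
               "fronts table")
}

#' Write an analysis report as JSON
#'
#' Serializes a [partition_report()] (or any list of scalars/vectors) to
#' JSON atomically (temp file + rename), with scalars unboxed.
#'
#' @param x a `partition_report` or plain list.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  if (inherits(x, "partition_report")) {
    x <- list(
      n = x$fit$n,
      lambda = x$fit$lambda,
      lambda_se = x$fit$lambda_se,
      lambda_mle = x$fit$lambda_mle,
      median = x$fit$median,
      fit_R = x$fit$fit_R,
      r_squared = x$fit$r_squared,
      ks_D = x$ks$D,
      ks_p = x$ks$p_value,
      bucket_counts = as.list(setNames(as.integer(x$bucket_counts),
                                       names(x$bucket_counts)))
    )
  }
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}
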