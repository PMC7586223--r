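#' Read and write the pipeline's CSV table formats
#'
#' The pipeline exchanges three plain CSV dialects with fixed headers:
#' fibril fields (`fibril_id,length_um,n_bundles,x1,y1,x2,y2`), event tables
#' (`fibril_id,molecule_id,t_bind,t_end,end_cause,mode`) and trajectory
#' tables (`track_id,frame,t,x,y,truth_state`).  Readers validate the header
#' and basic invariants; events read without a `mode` column get
#' `mode = "unknown"`.
#'
#' @param x table to write (a data.frame of the matching shape).
#' @param path file path.
#' @return readers return the classed data.frame; writers return `path`
#'   invisibly.
#' @name table_io
NULL

write_table_checked <- function(x, path, cols) {
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols))
    abort_invalid(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  utils::write.csv(x[, cols, drop = FALSE], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_table_checked <- function(path, cols, optional = character()) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- setdiff(cols, optional)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    abort_parse(sprintf("%s: missing columns %s", path,
                        paste(missing_cols, collapse = ", ")))
  x
}

#' @rdname table_io
#' @export
write_fibril_field <- function(x, path) {
  write_table_checked(x, path,
                      c("fibril_id", "length_um", "n_bundles", "x1", "y1", "x2", "y2"))
}

#' @rdname table_io
#' @export
read_fibril_field <- function(path) {
  x <- read_table_checked(path,
                          c("fibril_id", "length_um", "n_bundles", "x1", "y1", "x2", "y2"))
  class(x) <- c("fibril_field", "data.frame")
  as_fibril_field(x)
}

#' @rdname table_io
#' @export
write_event_table <- function(x, path) {
  write_table_checked(x, path,
                      c("fibril_id", "molecule_id", "t_bind", "t_end", "end_cause", "mode"))
}

#' @rdname table_io
#' @export
read_event_table <- function(path) {
  x <- read_table_checked(path,
                          c("fibril_id", "molecule_id", "t_bind", "t_end", "end_cause", "mode"),
                          optional = "mode")
  if (is.null(x$mode)) x$mode <- "unknown"
  if (any(x$t_end < x$t_bind))
    abort_parse(sprintf("%s: t_end earlier than t_bind", path))
  class(x) <- c("event_table", "data.frame")
  x
}

#' @rdname table_io
#' @export
write_trajectory_table <- function(x, path) {
  write_table_checked(x, path,
                      c("track_id", "frame", "t", "x", "y", "truth_state"))
}

#' @rdname table_io
#' @export
read_trajectory_table <- function(path) {
  x <- read_table_checked(path,
                          c("track_id", "frame", "t", "x", "y", "truth_state"),
                          optional = "truth_state")
  if (is.null(x$truth_state)) x$truth_state <- "unknown"
  class(x) <- c("trajectory_table", "data.frame")
  x
}
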