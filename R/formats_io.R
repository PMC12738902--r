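#' Read DarkLabel-style annotation CSV
#'
#' Ground-truth trajectories are exchanged in the headerless CSV grammar of
#' the DarkLabel video annotation tool: one record per line,
#' `frame,cname,id,x1,y1,x2,y2`, where `frame` is the 0-based frame index,
#' `cname` a transplanting state label, `id` the object identity and the
#' remaining four fields the top-left and bottom-right box corners in
#' pixels. Class names are canonicalized on read (case-insensitive); any
#' row that does not have exactly seven fields, or whose numeric fields do
#' not parse, raises an error naming the offending line.
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `frame` (integer), `cname`
#'   (canonical state label), `id` (integer), `x1`, `y1`, `x2`, `y2`
#'   (numeric), in file order. An empty file yields a zero-row frame.
#' @seealso [write_darklabel_csv()]
#' @export
read_darklabel_csv <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_annotations())
  parts <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 7L)) {
    stop("malformed annotation row at line ", which(nf != 7L)[1L],
         ": expected 7 comma-separated fields, got ", nf[nf != 7L][1L],
         call. = FALSE)
  }
  m <- matrix(trimws(unlist(parts)), ncol = 7L, byrow = TRUE)
  num <- suppressWarnings(apply(m[, c(1L, 3L:7L), drop = FALSE], 2L, as.numeric))
  num <- matrix(num, ncol = 6L)
  if (anyNA(num)) {
    bad <- which(apply(num, 1L, anyNA))[1L]
    stop("malformed annotation row at line ", bad,
         ": non-numeric frame/id/coordinate field", call. = FALSE)
  }
  out <- data.frame(
    frame = as.integer(num[, 1L]),
    cname = canonical_state(m[, 2L]),
    id    = as.integer(num[, 2L]),
    x1 = num[, 3L], y1 = num[, 4L], x2 = num[, 5L], y2 = num[, 6L],
    stringsAsFactors = FALSE
  )
  bad_box <- out$x1 >= out$x2 | out$y1 >= out$y2
  if (any(bad_box)) {
    stop("degenerate bounding box at line ", which(bad_box)[1L],
         ": need x1 < x2 and y1 < y2", call. = FALSE)
  }
  out
}

empty_annotations <- function() {
  data.frame(frame = integer(), cname = character(), id = integer(),
             x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric(),
             stringsAsFactors = FALSE)
}

#' Write DarkLabel-style annotation CSV
#'
#' Inverse of [read_darklabel_csv()]: writes headerless
#' `frame,cname,id,x1,y1,x2,y2` rows. Coordinates are written with enough
#' decimal digits (up to 15 significant) that a write/read round trip
#' reproduces the records exactly, sub-pixel coordinates included.
#'
#' @param records Data frame with columns `frame`, `cname`, `id`, `x1`,
#'   `y1`, `x2`, `y2`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_darklabel_csv <- function(records, path) {
  required <- c("frame", "cname", "id", "x1", "y1", "x2", "y2")
  if (!all(required %in% names(records)))
    stop("records must have columns ", paste(required, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  cname <- canonical_state(records$cname)
  fmt <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)
  lines <- paste(as.integer(records$frame), cname, as.integer(records$id),
                 fmt(records$x1), fmt(records$y1), fmt(records$x2), fmt(records$y2),
                 sep = ",")
  writeLines(lines, path)
  invisible(path)
}

#' Read and write detection streams
#'
#' Detections are the tracker's input unit: one classified, scored bounding
#' box per row. The on-disk form is a CSV with header
#' `frame,cname,conf,x1,y1,x2,y2`. On read, rows are grouped by ascending
#' frame index (stable within a frame) so that out-of-order files present
#' the tracker with a monotone stream; confidences must lie in \[0, 1\].
#'
#' @param path CSV path.
#' @return Data frame with columns `frame` (integer), `cname` (canonical
#'   label), `conf` (numeric), `x1`, `y1`, `x2`, `y2`.
#' @seealso [write_detections()]
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("detection file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("frame", "cname", "conf", "x1", "y1", "x2", "y2")
  if (!all(required %in% names(df)))
    stop("detection CSV must have header ", paste(required, collapse = ","), call. = FALSE)
  if (nrow(df) == 0L) return(empty_detections())
  df <- df[required]
  df$frame <- as.integer(df$frame)
  df$cname <- canonical_state(df$cname)
  if (any(df$conf < 0 | df$conf > 1))
    stop("detection confidence outside [0, 1]", call. = FALSE)
  if (any(df$x1 >= df$x2 | df$y1 >= df$y2))
    stop("degenerate detection bounding box", call. = FALSE)
  df <- df[order(df$frame), , drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_detections <- function() {
  data.frame(frame = integer(), cname = character(), conf = numeric(),
             x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric(),
             stringsAsFactors = FALSE)
}

#' @rdname read_detections
#' @param detections Data frame with the columns above.
#' @export
write_detections <- function(detections, path) {
  required <- c("frame", "cname", "conf", "x1", "y1", "x2", "y2")
  if (!all(required %in% names(detections)))
    stop("detections must have columns ", paste(required, collapse = ", "), call. = FALSE)
  df <- detections[required]
  if (nrow(df) > 0L) df$cname <- canonical_state(df$cname)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a count report to JSON
#'
#' A count report carries the cumulative per-state tallies produced by the
#' virtual-line counter, their total, and the per-state rates (fractions of
#' the total; absent while the total is zero). The JSON schema is
#' `{"counts": {state: int}, "total": int, "rates": {state: real}}`.
#'
#' @param report A count report, as returned by [count_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_count_report()]
#' @export
write_count_report <- function(report, path) {
  stopifnot(is.list(report), !is.null(report$counts), !is.null(report$total))
  obj <- list(
    counts = as.list(as.integer(report$counts)),
    total = as.integer(report$total),
    rates = if (is.null(report$rates)) structure(list(), names = character()) else as.list(report$rates)
  )
  names(obj$counts) <- names(report$counts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_count_report
#' @export
read_count_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  counts <- unlist(obj$counts)
  counts <- stats::setNames(as.integer(counts), names(counts))
  rates <- if (length(obj$rates) == 0L) NULL else unlist(obj$rates)
  list(counts = counts, total = as.integer(obj$total), rates = rates)
}
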