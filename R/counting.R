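#' Virtual counting line
#'
#' A horizontal segment from `(x0, y0)` to `(x1, y0)` acting as a tally
#' gate: a tracked identity is counted exactly once, in its current
#' transplanting state, when its box center moves from above the line
#' (`y < y0`) to below it (`y > y0`) while its x coordinate lies within
#' the segment. Counting on the crossing event — rather than on track
#' creation — is what makes the tally robust to identity churn at the
#' image border.
#'
#' @param x0,x1 Horizontal endpoints, `x0 < x1`.
#' @param y0 Vertical coordinate of the line.
#' @return A `counting_line` list.
#' @export
counting_line <- function(x0, x1, y0) {
  if (!(x0 < x1)) stop("counting line needs x0 < x1", call. = FALSE)
  structure(list(x0 = as.numeric(x0), x1 = as.numeric(x1),
                 y0 = as.numeric(y0)),
            class = "counting_line")
}

#' Default counting-line placement for a frame
#'
#' Full-width line at 60% of the frame height — far enough down that
#' tracks are confirmed before they reach it, with room below to observe
#' the crossing.
#'
#' @param frame_size `c(width, height)` in pixels.
#' @return A [counting_line()].
#' @export
default_counting_line <- function(frame_size) {
  counting_line(0, frame_size[[1]], 0.6 * frame_size[[2]])
}

#' Create an empty crossing ledger
#'
#' The ledger remembers, per track id, which side of the counting line
#' the id was last seen on and whether it has already been counted; a
#' counted id never increments the tally again.
#'
#' @return A `crossing_ledger` list.
#' @export
new_crossing_ledger <- function() {
  structure(list(side = stats::setNames(character(), character()),
                 counted = stats::setNames(logical(), character()),
                 counts = stats::setNames(rep(0L, 3L), transplant_states())),
            class = "crossing_ledger")
}

#' Update the crossing counter with one frame of tracks
#'
#' For every confirmed track at this frame the ledger records the current
#' side of the line (`above` if center `y < y0`, else `below`). An id
#' whose previous side was `above`, whose current center lies below the
#' line with x within the segment, and which has not been counted yet,
#' increments the tally of its current state label and is marked counted.
#' An id first seen already below the line is never counted (it entered
#' the scene past the gate). The cumulative report is monotone
#' non-decreasing over frames.
#'
#' @param ledger A [new_crossing_ledger()] (or the result of a previous
#'   update).
#' @param line A [counting_line()].
#' @param tracks Data frame of tracks at one frame with columns `id`,
#'   `cname`, `x1`, `y1`, `x2`, `y2` (as produced by [tracker_step()]).
#' @return List with the updated `ledger` and the cumulative `report`
#'   (see [count_report()]).
#' @export
update_counter <- function(ledger, line, tracks) {
  if (nrow(tracks) > 0L) {
    for (k in seq_len(nrow(tracks))) {
      id <- as.character(tracks$id[[k]])
      ctr <- box_center(c(tracks$x1[[k]], tracks$y1[[k]],
                          tracks$x2[[k]], tracks$y2[[k]]))
      side <- if (ctr[["y"]] < line$y0) "above" else "below"
      prev <- if (id %in% names(ledger$side)) ledger$side[[id]] else "unseen"
      if (prev == "above" && side == "below" &&
          ctr[["x"]] >= line$x0 && ctr[["x"]] <= line$x1 &&
          !isTRUE(ledger$counted[[id]])) {
        st <- tracks$cname[[k]]
        ledger$counts[[st]] <- ledger$counts[[st]] + 1L
        ledger$counted[[id]] <- TRUE
      }
      if (!(id %in% names(ledger$counted))) ledger$counted[[id]] <- FALSE
      ledger$side[[id]] <- side
    }
  }
  list(ledger = ledger, report = count_report(ledger))
}

#' Cumulative count report
#'
#' @param ledger A crossing ledger.
#' @return List with `counts` (named integer vector over the three
#'   states), `total`, and `rates` (per-state fraction of the total;
#'   `NULL` while the total is zero).
#' @export
count_report <- function(ledger) {
  counts <- ledger$counts
  list(counts = counts, total = sum(counts), rates = compute_rates(counts))
}

#' Per-state transplanting rates
#'
#' Rates are the per-state fractions of the total tally — e.g. the
#' buried-seedling rate and bare-root rate reported alongside the counts
#' as the operation-quality summary. Undefined (returned as `NULL`) when
#' nothing has been counted yet.
#'
#' @param counts Named non-negative integer vector over the states.
#' @return Named numeric vector summing to 1, or `NULL` if
#'   `sum(counts) == 0`.
#' @export
#' @examples
#' compute_rates(c(normal = 119, buried_seedling = 16, bare_root = 9))
compute_rates <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total == 0) return(NULL)
  counts / total
}

#' Count line crossings over a full track dump
#'
#' Convenience driver: replays a multi-frame track table through
#' [update_counter()] in frame order and returns the final report.
#'
#' @param tracks Data frame with columns `frame`, `id`, `cname`, `x1`,
#'   `y1`, `x2`, `y2`.
#' @param line A [counting_line()].
#' @return Final count report.
#' @export
count_crossings <- function(tracks, line) {
  ledger <- new_crossing_ledger()
  for (f in sort(unique(tracks$frame))) {
    upd <- update_counter(ledger, line, tracks[tracks$frame == f, , drop = FALSE])
    ledger <- upd$ledger
  }
  count_report(ledger)
}
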