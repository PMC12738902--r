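#' Minimum-cost linear assignment (Hungarian algorithm)
#'
#' Solves the rectangular linear sum assignment problem by shortest
#' augmenting paths (Jonker-Volgenant), the algorithm behind the
#' Hungarian matching step of tracking-by-detection: the returned
#' one-to-one matching minimizes total cost over all assignments of rows
#' to columns. Pairs whose cost exceeds `max_cost` are struck from the
#' matching afterwards, so an over-threshold row/column pair comes back
#' unmatched rather than forced together. Ties are resolved
#' deterministically (lowest row index first).
#'
#' @param cost Numeric matrix of finite costs (rows x columns); may be
#'   rectangular or empty.
#' @param max_cost Matches with cost strictly greater than this are
#'   discarded (default `Inf`, keep all).
#' @return List with `matches` (integer matrix, columns `row` and `col`,
#'   zero rows when nothing matches), `unmatched_rows` and
#'   `unmatched_cols` (integer vectors of indices).
#' @export
#' @examples
#' linear_assignment(matrix(c(0, 1, 1, 0), 2, 2))
linear_assignment <- function(cost, max_cost = Inf) {
  if (is.null(cost) || length(cost) == 0L) {
    nr <- if (is.matrix(cost)) nrow(cost) else 0L
    nc <- if (is.matrix(cost)) ncol(cost) else 0L
    return(list(matches = cbind(row = integer(), col = integer()),
                unmatched_rows = seq_len(nr), unmatched_cols = seq_len(nc)))
  }
  if (!is.matrix(cost)) cost <- as.matrix(cost)
  if (!all(is.finite(cost))) stop("assignment costs must be finite", call. = FALSE)
  nr <- nrow(cost); nc <- ncol(cost)
  transposed <- nr > nc
  C <- if (transposed) t(cost) else cost
  sol <- lsap_solve(C)
  # sol$col4row[i] = column assigned to row i of C (every row assigned
  # since nrow(C) <= ncol(C))
  if (transposed) {
    pairs <- cbind(row = sol$col4row, col = seq_len(nrow(C)))
  } else {
    pairs <- cbind(row = seq_len(nrow(C)), col = sol$col4row)
  }
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  keep <- cost[pairs] <= max_cost
  matches <- pairs[keep, , drop = FALSE]
  list(
    matches = matches,
    unmatched_rows = setdiff(seq_len(nr), matches[, 1L]),
    unmatched_cols = setdiff(seq_len(nc), matches[, 2L])
  )
}

# Shortest augmenting path solver for nr <= nc cost matrices.
# Returns col4row: the column assigned to each row.
lsap_solve <- function(C) {
  nr <- nrow(C); nc <- ncol(C)
  u <- numeric(nr); v <- numeric(nc)
  col4row <- integer(nr)          # 0 = unassigned
  row4col <- integer(nc)
  for (cur_row in seq_len(nr)) {
    # Dijkstra over columns for the cheapest augmenting path from cur_row
    min_val <- 0
    i <- cur_row
    sink <- 0L
    shortest <- rep(Inf, nc)
    path <- integer(nc)
    SR <- logical(nr); SC <- logical(nc)
    remaining <- seq_len(nc)
    while (sink == 0L) {
      SR[i] <- TRUE
      r <- min_val + C[i, remaining] - u[i] - v[remaining]
      upd <- r < shortest[remaining]
      if (any(upd)) {
        js <- remaining[upd]
        shortest[js] <- r[upd]
        path[js] <- i
      }
      lowest <- min(shortest[remaining])
      if (!is.finite(lowest)) stop("infeasible assignment", call. = FALSE)
      # prefer an unassigned column among the minima (termination rule)
      cand <- remaining[shortest[remaining] == lowest]
      free <- cand[row4col[cand] == 0L]
      j <- if (length(free) > 0L) free[[1L]] else cand[[1L]]
      min_val <- lowest
      SC[j] <- TRUE
      remaining <- remaining[remaining != j]
      if (row4col[j] == 0L) sink <- j else i <- row4col[j]
    }
    # dual updates
    u[cur_row] <- u[cur_row] + min_val
    others <- which(SR); others <- others[others != cur_row]
    if (length(others) > 0L)
      u[others] <- u[others] + min_val - shortest[col4row[others]]
    js <- which(SC)
    v[js] <- v[js] - (min_val - shortest[js])
    # augment along the alternating path back to cur_row
    j <- sink
    repeat {
      i <- path[j]
      row4col[j] <- i
      tmp <- col4row[i]
      col4row[i] <- j
      if (i == cur_row) break
      j <- tmp
    }
  }
  list(col4row = col4row, row4col = row4col, u = u, v = v)
}
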