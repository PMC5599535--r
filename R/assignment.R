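# Minimum-cost linear assignment via shortest augmenting paths
# (Jonker-Volgenant style Hungarian algorithm, O(n^3)). Costs must be
# finite; the public wrapper maps gated-out pairs to a large sentinel and
# strips them from the result.

.lsap_square <- function(C) {
  n <- nrow(C)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j+1]: row currently assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0L
      cur <- C[i0, ] - u[i0 + 1] - v[2:(n + 1)]
      upd <- !used[2:(n + 1)] & cur < minv[2:(n + 1)]
      minv[2:(n + 1)][upd] <- cur[upd]
      way[2:(n + 1)][upd] <- j0
      free_j <- which(!used[2:(n + 1)])
      jb <- free_j[which.min(minv[free_j + 1])]
      delta <- minv[jb + 1]; j1 <- jb
      iu <- which(used)
      u[p[iu] + 1] <- u[p[iu] + 1] + delta
      v[iu] <- v[iu] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) assign[p[j + 1]] <- j
  assign  # assign[i] = column matched to row i
}

#' Solve the track-to-detection assignment problem
#'
#' Finds the minimum-total-cost one-to-one matching between rows (tracks)
#' and columns (detections) of a cost matrix. Entries of `Inf` (or `NA`)
#' mark forbidden pairs, which are never matched; rows or columns whose
#' admissible pairs are exhausted come back unmatched. The matching is
#' maximum-cardinality over admissible pairs, with ties resolved by total
#' cost.
#'
#' @param cost numeric matrix, tracks in rows, detections in columns.
#' @return a list with `matches` (two-column matrix of row index, column
#'   index), `unmatched_tracks`, `unmatched_detections` (integer vectors),
#'   and `total_cost`.
#' @export
solve_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  empty <- list(matches = matrix(integer(), 0, 2,
                                 dimnames = list(NULL, c("track", "detection"))),
                unmatched_tracks = seq_len(nr %||% 0),
                unmatched_detections = seq_len(nc %||% 0),
                total_cost = 0)
  if (is.null(nr) || nr == 0 || nc == 0) return(empty)
  forb <- !is.finite(cost)
  fin <- cost[!forb]
  big <- if (length(fin)) (max(abs(fin)) + 1) * (max(nr, nc) + 1) + 1e6 else 1e6
  n <- max(nr, nc)
  C <- matrix(0, n, n)
  C[seq_len(nr), seq_len(nc)] <- ifelse(forb, big, cost)
  a <- .lsap_square(C)
  m <- cbind(track = seq_len(nr), detection = a[seq_len(nr)])
  ok <- m[, 2] <= nc
  ok[ok] <- !forb[m[ok, , drop = FALSE]]
  matches <- m[ok, , drop = FALSE]
  list(matches = matches,
       unmatched_tracks = setdiff(seq_len(nr), matches[, 1]),
       unmatched_detections = setdiff(seq_len(nc), matches[, 2]),
       total_cost = if (nrow(matches)) sum(cost[matches]) else 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
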