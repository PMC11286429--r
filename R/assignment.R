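#' Linear sum assignment
#'
#' Shortest-augmenting-path implementation of the Hungarian method (the
#' Jonker-Volgenant formulation with dual potentials), used to find the
#' minimum-total-cost one-to-one matching between tracks and detections.
#'
#' @name assignment
NULL

# Sentinel cost marking an entry that must never be matched. Kept as a large
# finite value so the solver needs no special infinity handling; any pair at or
# above it is demoted to unmatched afterwards.
INFEASIBLE_COST <- 1e5

# Solve the square/rectangular assignment problem for a finite cost matrix
# with nrow(cost) <= ncol(cost). Returns, for each row, the 1-based column it
# is assigned to. O(n^2 m).
lsap_solve <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  stopifnot(n <= m, all(is.finite(cost)))
  if (n == 0L) {
    return(integer(0))
  }
  # index offset of 1: position j+1 holds column j, position 1 a virtual
  # column 0 used as the augmenting-path root
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L) # p[j+1]: row assigned to column j (0 = free)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_j <- which(!used[-1L])
      cur <- cost[i0, free_j] - u[i0 + 1L] - v[free_j + 1L]
      upd <- cur < minv[free_j]
      if (any(upd)) {
        minv[free_j[upd]] <- cur[upd]
        way[free_j[upd] + 1L] <- j0
      }
      j1 <- free_j[which.min(minv[free_j])]
      delta <- minv[j1]
      used_j <- which(used) - 1L
      rows <- p[used_j + 1L]
      u[rows + 1L] <- u[rows + 1L] + delta
      v[used_j + 1L] <- v[used_j + 1L] - delta
      minv[free_j] <- minv[free_j] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) {
    if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  }
  assignment
}

#' Match result container
#'
#' @param matches 2-column integer matrix of (track index, detection index)
#'   pairs.
#' @param unmatched_tracks,unmatched_detections integer vectors.
#' @return an object of class `match_result`. Every input index appears exactly
#'   once across the matches and the unmatched lists.
#' @keywords internal
match_result <- function(matches, unmatched_tracks, unmatched_detections) {
  if (is.null(matches) || length(matches) == 0L) {
    matches <- matrix(integer(0), ncol = 2L)
  }
  colnames(matches) <- c("track", "detection")
  structure(
    list(
      matches = matches,
      unmatched_tracks = as.integer(sort(unmatched_tracks)),
      unmatched_detections = as.integer(sort(unmatched_detections))
    ),
    class = "match_result"
  )
}

#' Minimum-cost assignment with a cost cap
#'
#' Solves the assignment problem over the feasible entries of `cost` and then
#' demotes any assigned pair whose cost exceeds `max_cost` to unmatched.
#' Entries at or above the infeasible sentinel (`1e5`) are never matched.
#' Among equally cheap optima, ties are broken toward the lowest
#' (track index, detection index) pair through an infinitesimal deterministic
#' perturbation.
#'
#' @param cost T x D numeric matrix of nonnegative costs.
#' @param max_cost pairs with cost above this value stay unmatched.
#' @return a `match_result`.
#' @export
solve_assignment <- function(cost, max_cost) {
  cost <- as.matrix(cost)
  n_t <- nrow(cost)
  n_d <- ncol(cost)
  if (n_t == 0L || n_d == 0L) {
    return(match_result(NULL, seq_len(n_t), seq_len(n_d)))
  }
  work <- pmin(cost, INFEASIBLE_COST)
  # deterministic lexicographic tie-break, far below meaningful cost gaps
  eps <- 1e-9 / (n_t * n_d)
  pert <- outer(seq_len(n_t) - 1L, seq_len(n_d), function(i, j) i * n_d + j)
  work <- work + eps * pert
  transposed <- n_t > n_d
  if (transposed) work <- t(work)
  assignment <- lsap_solve(work)
  if (transposed) {
    pairs <- cbind(assignment, seq_len(n_d))
  } else {
    pairs <- cbind(seq_len(n_t), assignment)
  }
  ok <- cost[pairs] <= max_cost & cost[pairs] < INFEASIBLE_COST
  pairs <- pairs[ok, , drop = FALSE]
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  match_result(
    pairs,
    setdiff(seq_len(n_t), pairs[, 1L]),
    setdiff(seq_len(n_d), pairs[, 2L])
  )
}
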