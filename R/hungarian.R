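#' @title One-to-one point matching
#' @description
#' Cost construction and exact minimum-cost one-to-one assignment between N
#' ground-truth particle centres and M >= N predicted points. The cost of a
#' pair combines spatial distance and prediction confidence,
#' `D[i, j] = gamma * ||p_i - phat_j|| - chat_j`, so the matcher prefers
#' predictions that are both close and confident. The solver is a
#' shortest-augmenting-path (Jonker-Volgenant style) implementation for
#' rectangular problems; tests verify exact agreement with exhaustive
#' enumeration.
#' @name matching
NULL

#' Matching cost matrix
#'
#' `D[i, j] = gamma * Euclidean(p_i, phat_j) - chat_j`.
#'
#' @param gt N x 2 matrix of ground-truth (x, y)
#' @param pred M x 2 matrix of predicted (x, y)
#' @param conf length-M confidences aligned with `pred`
#' @param gamma equilibrium parameter balancing distance against confidence
#' @return N x M cost matrix
#' @export
costMatrix <- function(gt, pred, conf, gamma) {
  gt <- as.matrix(gt); pred <- as.matrix(pred)
  N <- nrow(gt); M <- nrow(pred)
  if (N > M) stop("matching infeasible: more ground-truth points (", N,
                  ") than predictions (", M, ")")
  stopifnot(length(conf) == M)
  dx <- outer(gt[, 1L], pred[, 1L], `-`)
  dy <- outer(gt[, 2L], pred[, 2L], `-`)
  gamma * sqrt(dx * dx + dy * dy) - matrix(conf, N, M, byrow = TRUE)
}

# Successive-shortest-path assignment with potentials for an N x M matrix,
# N <= M; returns integer vector a with a[i] = assigned column of row i.
# Column index 1 in the internal arrays is a virtual start column.
lapSolve <- function(D) {
  N <- nrow(D); M <- ncol(D)
  u <- numeric(N)
  v <- numeric(M + 1L)          # v[1] is the virtual column
  p <- integer(M + 1L)          # p[j+1] = row assigned to column j (0 free)
  way <- integer(M + 1L)
  cols <- seq_len(M)
  for (i in seq_len(N)) {
    p[1L] <- i
    j0 <- 0L                    # current column (0 = virtual)
    minv <- rep(Inf, M)
    used <- logical(M + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_j <- which(!used[-1L])
      cur <- D[i0, free_j] - u[i0] - v[free_j + 1L]
      upd <- cur < minv[free_j]
      if (any(upd)) {
        minv[free_j[upd]] <- cur[upd]
        way[free_j[upd] + 1L] <- j0
      }
      j1 <- free_j[which.min(minv[free_j])]
      delta <- minv[j1]
      usedc <- which(used)
      if (length(usedc)) {
        rowsu <- p[usedc]
        u[rowsu[rowsu > 0L]] <- u[rowsu[rowsu > 0L]] + delta
        v[usedc] <- v[usedc] - delta
      }
      minv[!used[-1L]] <- minv[!used[-1L]] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    # augment: walk predecessor columns back to the virtual start
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  rowsol <- integer(N)
  for (j in cols) if (p[j + 1L] > 0L) rowsol[p[j + 1L]] <- j
  rowsol
}

#' Exact minimum-cost one-to-one matching (Hungarian)
#'
#' Finds the injective assignment of the N rows of `D` into its M >= N
#' columns minimizing the total cost. With `canonical = TRUE` the result is
#' additionally refined to the lexicographically smallest assignment vector
#' among all optima (row 1's column minimized first, then row 2's, ...),
#' giving a fully deterministic tie-break; this refinement re-solves reduced
#' problems and is intended for small/analysis use — the training loop calls
#' the plain solver, which is already deterministic.
#'
#' @param D N x M finite cost matrix, N <= M
#' @param canonical enforce the lexicographic tie-break (default TRUE)
#' @return list with `assignment` (length-N integer vector of column
#'   indices), `totalCost`, and `costMatrix`
#' @export
hungarianMatch <- function(D, canonical = TRUE) {
  D <- as.matrix(D)
  if (!all(is.finite(D))) stop("cost matrix must be finite")
  N <- nrow(D); M <- ncol(D)
  if (N > M) stop("matching infeasible: N > M")
  if (N == 0L) {
    return(list(assignment = integer(0), totalCost = 0, costMatrix = D))
  }
  a <- lapSolve(D)
  best <- sum(D[cbind(seq_len(N), a)])
  if (canonical && N >= 1L) {
    tol <- 1e-9 * max(1, abs(best))
    fixed <- integer(0)
    used <- logical(M)
    acc <- 0
    for (i in seq_len(N)) {
      rest_rows <- if (i < N) (i + 1L):N else integer(0)
      for (j in order(seq_len(M))) {
        if (used[j]) next
        cost_ij <- acc + D[i, j]
        rem <- if (length(rest_rows)) {
          sub <- D[rest_rows, !used & seq_len(M) != j, drop = FALSE]
          if (ncol(sub) < length(rest_rows)) next
          aa <- lapSolve(sub)
          sum(sub[cbind(seq_along(rest_rows), aa)])
        } else 0
        if (cost_ij + rem <= best + tol) {
          fixed <- c(fixed, j)
          used[j] <- TRUE
          acc <- cost_ij
          break
        }
      }
    }
    a <- fixed
  }
  list(assignment = as.integer(a),
       totalCost = sum(D[cbind(seq_len(N), a)]),
       costMatrix = D)
}

#' Match ground truth to predictions by cost
#'
#' Convenience wrapper: builds the cost matrix and solves the assignment.
#'
#' @inheritParams costMatrix
#' @param canonical see [hungarianMatch()]
#' @return as [hungarianMatch()]
#' @export
matchPoints <- function(gt, pred, conf, gamma, canonical = FALSE) {
  hungarianMatch(costMatrix(gt, pred, conf, gamma), canonical = canonical)
}
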