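#' Discretized belief simplex
#'
#' Enumerates the uniform composition lattice on the probability simplex:
#' all vectors `(q_1/n, ..., q_k/n)` with non-negative integers `q_i` summing
#' to `n`. This is the grid on which the exact solvers run; the default
#' resolution `n = 200` gives 201 points per edge.
#'
#' @param k Number of locations (>= 2).
#' @param n Grid resolution (>= 1); the lattice has `choose(n+k-1, k-1)`
#'   points.
#' @param max_points Overflow guard: error if the lattice would exceed this
#'   many points.
#' @return An object of class `belief_grid`: list with `k`, `n`,
#'   `points` (npoints x k matrix of beliefs), `q` (integer compositions),
#'   `npoints`, and an internal index map.
#' @examples
#' g <- belief_grid(k = 3, n = 200)
#' g$npoints  # choose(202, 2) = 20301
#' @export
belief_grid <- function(k, n, max_points = 5e6) {
  if (k < 2 || k != round(k)) stop("`k` must be an integer >= 2")
  if (n < 1 || n != round(n)) stop("`n` must be an integer >= 1")
  npoints <- choose(n + k - 1, k - 1)
  if (npoints > max_points)
    stop(sprintf("belief grid would have %.0f points (> max_points = %.0f)",
                 npoints, max_points))
  q <- compositions_of(as.integer(n), as.integer(k))
  key <- as.vector(q[, seq_len(k - 1), drop = FALSE] %*%
                     (n + 1)^(0:(k - 2)))
  lut <- NULL
  if ((n + 1)^(k - 1) <= 2^26) {
    lut <- integer((n + 1)^(k - 1))
    lut[key + 1L] <- seq_len(nrow(q))
  }
  structure(
    list(k = as.integer(k), n = as.integer(n), npoints = nrow(q),
         points = q / n, q = q, key = key, lut = lut),
    class = "belief_grid")
}

#' @export
print.belief_grid <- function(x, ...) {
  cat(sprintf("Belief grid: k = %d, resolution n = %d (%d points, %d per edge)\n",
              x$k, x$n, x$npoints, x$n + 1L))
  invisible(x)
}

# All compositions of n into k non-negative parts, lexicographic in the first
# k-1 coordinates.
compositions_of <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  parts <- lapply(0:n, function(a) {
    sub <- compositions_of(n - a, k - 1L)
    cbind(a, sub, deparse.level = 0)
  })
  do.call(rbind, parts)
}

# Flat index of integer compositions (rows of Q summing to grid$n).
# Rows that are not valid lattice points yield NA.
grid_index <- function(grid, Q) {
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1L)
  valid <- rowSums(Q < 0L | Q > grid$n) == 0L & rowSums(Q) == grid$n
  Qc <- pmin(pmax(Q, 0L), grid$n)
  key <- as.vector(Qc[, seq_len(grid$k - 1), drop = FALSE] %*%
                     (grid$n + 1)^(0:(grid$k - 2)))
  idx <- if (!is.null(grid$lut)) grid$lut[key + 1L] else match(key, grid$key)
  idx[!valid | idx == 0L] <- NA_integer_
  idx
}

#' Nearest grid point to a belief state
#'
#' Rounds a belief to the nearest lattice point (used for categorical policy
#' lookups during simulation; value interpolation uses [interpolate()]
#' instead).
#'
#' @param grid A [belief_grid()].
#' @param p Belief state of length `grid$k`.
#' @return Flat grid index.
#' @export
nearest_grid_point <- function(grid, p) {
  qf <- p * grid$n
  q <- round(qf)
  d <- grid$n - sum(q)
  while (d != 0L) {        # repair rounding so the composition sums to n
    r <- qf - q
    if (d > 0) {
      i <- which.max(r); q[i] <- q[i] + 1L; d <- d - 1L
    } else {
      ok <- q > 0L
      i <- which(ok)[which.min(r[ok])]; q[i] <- q[i] - 1L; d <- d + 1L
    }
  }
  grid_index(grid, q)
}

# Barycentric interpolation weights on the composition lattice.
#
# Uses the Freudenthal (Kuhn) triangulation in cumulative coordinates
# v_j = sum_{i >= j} q_i (j = 2..k), whose cells respect the simplex: every
# vertex maps back to a valid composition. Exact for affine functions.
# P: m x k matrix of beliefs. Returns list(idx = m x k vertex indices,
# w = m x k non-negative weights, rows summing to 1).
bary_weights <- function(grid, P) {
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  k <- grid$k; n <- grid$n; m <- nrow(P); d <- k - 1L
  P <- pmax(P, 0); P <- P / rowSums(P)
  # cumulative coords v_j for j = 2..k (columns 1..d), non-increasing in j
  V <- matrix(0, m, d)
  acc <- P[, k]
  V[, d] <- acc
  if (d >= 2L) for (j in (d - 1L):1L) {
    acc <- acc + P[, j + 1L]
    V[, j] <- acc
  }
  V <- pmin(pmax(V * n, 0), n)
  B <- floor(V)
  f <- V - B
  hit <- B == n        # v exactly at the top: fold into the cell below
  B[hit] <- n - 1
  f[hit] <- 1
  # per-row permutation sorting f descending, ties by column index ascending
  ord <- sort_desc_idx(f)
  # weights
  W <- matrix(0, m, k)
  fs <- matrix(f[cbind(rep(seq_len(m), d), as.vector(ord))], m, d)
  W[, 1L] <- 1 - fs[, 1L]
  if (d >= 2L) for (t in seq_len(d - 1L)) W[, t + 1L] <- fs[, t] - fs[, t + 1L]
  W[, k] <- fs[, d]
  # vertices: v-space points B + cumulative indicators of ord columns
  idx <- matrix(0L, m, k)
  Vt <- B
  idx[, 1L] <- grid_index(grid, v_to_q(Vt, n, k))
  for (t in seq_len(d)) {
    Vt[cbind(seq_len(m), ord[, t])] <- Vt[cbind(seq_len(m), ord[, t])] + 1
    idx[, t + 1L] <- grid_index(grid, v_to_q(Vt, n, k))
  }
  bad <- is.na(idx)
  if (any(bad)) {           # only zero-weight vertices may fall off-lattice
    if (any(W[bad] > 1e-9)) stop("internal error: off-lattice interpolation vertex")
    idx[bad] <- 1L
    W[bad] <- 0
  }
  W <- pmax(W, 0)
  W <- W / rowSums(W)
  list(idx = idx, w = W)
}

# Map cumulative-coordinate integer points back to compositions.
v_to_q <- function(V, n, k) {
  d <- k - 1L
  Q <- matrix(0L, nrow(V), k)
  Q[, 1L] <- as.integer(round(n - V[, 1L]))
  if (d >= 2L) for (j in seq_len(d - 1L))
    Q[, j + 1L] <- as.integer(round(V[, j] - V[, j + 1L]))
  Q[, k] <- as.integer(round(V[, d]))
  Q
}

# Per-row descending order of the columns of f (ties: lower column first).
sort_desc_idx <- function(f) {
  m <- nrow(f); d <- ncol(f)
  if (d == 1L) return(matrix(1L, m, 1L))
  if (d == 2L) {
    first <- ifelse(f[, 1L] >= f[, 2L], 1L, 2L)
    return(cbind(first, 3L - first, deparse.level = 0))
  }
  t(apply(f, 1L, function(r) order(-r, seq_len(d))))
}

#' Barycentric interpolation of a value field on the belief grid
#'
#' Interpolates grid-point values at an arbitrary belief using the simplex
#' triangulation of the lattice. Exact at grid points and for affine
#' functions of the belief; the result always lies within the range of the
#' containing cell's vertex values.
#'
#' @param values Numeric vector of length `grid$npoints` (one value per grid
#'   point), or a matrix of beliefs in rows is not accepted here -- see
#'   Details.
#' @param p A belief state, or a matrix of belief states in rows.
#' @param grid A [belief_grid()].
#' @return Interpolated value(s).
#' @export
interpolate <- function(values, p, grid) {
  if (length(values) != grid$npoints)
    stop("`values` must have one entry per grid point")
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  if (ncol(p) != grid$k) stop("belief dimension does not match grid")
  if (any(p < -1e-9) || any(abs(rowSums(p) - 1) > 1e-9))
    stop("`p` must lie on the probability simplex")
  bw <- bary_weights(grid, p)
  out <- rowSums(matrix(values[bw$idx], nrow(bw$idx)) * bw$w)
  if (nrow(p) == 1L) out[[1L]] else out
}
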