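# Precomputed Bellman backup operator on the belief grid.
#
# For every fixation j and observation outcome o the posterior of each grid
# point is a fixed off-grid belief, so its barycentric interpolation weights
# can be assembled once into a sparse matrix W[[j]][[o]] (npoints x npoints).
# A backup of a value column V_j then costs one sparse mat-vec per outcome:
#   EV_j = sum_o pred[[j]][, o] * (W[[j]][[o]] %*% V_j).
# Also caches the exact entropy of every posterior (used by Infomax).
build_backup <- function(model, grid) {
  L <- likelihood_tables(model)
  npts <- grid$npoints
  P <- grid$points
  pred <- vector("list", model$n_fix)
  W <- vector("list", model$n_fix)
  Hpost <- vector("list", model$n_fix)
  for (j in seq_len(model$n_fix)) {
    pred[[j]] <- matrix(0, npts, model$n_out)
    Hpost[[j]] <- matrix(0, npts, model$n_out)
    W[[j]] <- vector("list", model$n_out)
    for (o in seq_len(model$n_out)) {
      lv <- L[[j]][, o]
      U <- P %*% diag(lv, nrow = model$k)
      m <- rowSums(U)
      pred[[j]][, o] <- m
      post <- U / ifelse(m > 0, m, 1)
      post[m <= 0, ] <- P[m <= 0, , drop = FALSE]  # unreachable: weight 0
      Hpost[[j]][, o] <- row_entropy(post)
      bw <- bary_weights(grid, post)
      W[[j]][[o]] <- Matrix::sparseMatrix(
        i = rep(seq_len(npts), grid$k), j = as.vector(bw$idx),
        x = as.vector(bw$w), dims = c(npts, npts))
    }
  }
  list(model = model, grid = grid, L = L, pred = pred, W = W, Hpost = Hpost)
}

# Expected interpolated next-step value for fixating j, given value column v
# on the grid (length npoints). Returns a vector over grid points.
backup_ev <- function(bk, j, v) {
  ev <- numeric(bk$grid$npoints)
  for (o in seq_len(bk$model$n_out)) {
    m <- bk$pred[[j]][, o]
    ev <- ev + m * as.vector(bk$W[[j]][[o]] %*% v)
  }
  ev
}
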