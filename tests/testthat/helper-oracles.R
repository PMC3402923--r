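# Independent oracles used by the tests. These deliberately avoid the
# package's SVD route.

euler_rotation <- function(a, b, g) {
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                             0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                             -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
  Rz(a) %*% Ry(b) %*% Rz(g)
}

# Brute-force minimum RMSD over proper rotations: for any fixed rotation
# the optimal translation matches centroids, so search Euler angles only —
# a coarse grid followed by Nelder-Mead polish from the best grid point.
grid_kabsch_rmsd <- function(mobile, target, n_grid = 14) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(target, 2, colMeans(target))
  obj <- function(ang) {
    R <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((P %*% R - Q)^2)))
  }
  alphas <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  betas <- seq(0, pi, length.out = n_grid)
  best <- c(0, 0, 0); best_v <- obj(best)
  for (a in alphas) for (b in betas) for (g in alphas) {
    v <- obj(c(a, b, g))
    if (v < best_v) { best_v <- v; best <- c(a, b, g) }
  }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_move <- function(xyz, R = random_rotation(),
                       t = stats::rnorm(3, sd = 5)) {
  sweep(xyz %*% R, 2, t, `+`)
}
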