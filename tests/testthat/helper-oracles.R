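# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: distances are accumulated componentwise, line/segment
# distances come from dense 1-D minimization, and the rigid fit is checked
# against a general-purpose 6-parameter numeric optimizer.

# componentwise sum-of-squares distance
oracle_distance <- function(a, b) {
  acc <- 0
  for (i in 1:3) acc <- acc + (a[i] - b[i])^2
  sqrt(acc)
}

# min over t of |p - (lp + t*d)| on a dense grid, with two refinement passes
oracle_point_line <- function(p, lp, d, span = 500) {
  f <- function(t) {
    q <- lp + t * d
    oracle_distance(p, q)
  }
  lo <- -span; hi <- span
  for (pass in 1:3) {
    ts <- seq(lo, hi, length.out = 2001)
    vals <- vapply(ts, f, numeric(1))
    i <- which.min(vals)
    step <- ts[2] - ts[1]
    lo <- ts[i] - step; hi <- ts[i] + step
  }
  stats::optimize(f, c(lo, hi), tol = 1e-12)$objective
}

# min over t in [0, 1] of |p - (a + t*(b-a))| by dense sampling + refinement
oracle_point_segment <- function(p, a, b) {
  f <- function(t) oracle_distance(p, a + t * (b - a))
  ts <- seq(0, 1, length.out = 4001)
  vals <- vapply(ts, f, numeric(1))
  i <- which.min(vals)
  lo <- max(0, ts[i] - 1e-3); hi <- min(1, ts[i] + 1e-3)
  stats::optimize(f, c(lo, hi), tol = 1e-12)$objective
}

# Euler-angle rotation built independently of the package internals
oracle_rotation <- function(ang) {
  cz <- cos(ang[1]); sz <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cx <- cos(ang[3]); sx <- sin(ang[3])
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Rz %*% Ry %*% Rx
}

# best achievable RMS residual for a rigid fit, by multi-start numeric
# optimization over 3 Euler angles + 3 translations
oracle_rigid_rms <- function(S, D, n_starts = 5) {
  obj <- function(par) {
    R <- oracle_rotation(par[1:3])
    res <- S %*% t(R) + matrix(par[4:6], nrow(S), 3, byrow = TRUE) - D
    sum(res^2)
  }
  starts <- rbind(rep(0, 6),
                  matrix(stats::runif(6 * (n_starts - 1), -pi / 2, pi / 2),
                         ncol = 6))
  starts[, 4:6] <- matrix(rep(colMeans(D) - colMeans(S), each = nrow(starts)),
                          ncol = 3) + starts[, 4:6]
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    o1 <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
    o2 <- stats::optim(o1$par, obj, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o1$value, o2$value)
  }
  sqrt(best / nrow(S))
}

# random helpers for property tests (frames fixed by the caller)
rand_pt <- function(frame = "LOWFIELD", scale = 100) {
  pt3(stats::runif(3, -scale, scale), frame = frame)
}

rand_rigid <- function(from = "TEMPLATE", to = "LOWFIELD", max_deg = 180) {
  rigid_transform(oracle_rotation(stats::runif(3, -1, 1) * max_deg * pi / 180),
                  stats::runif(3, -50, 50), from, to)
}
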