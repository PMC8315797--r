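# Low-level numerical primitives shared by the body-geometry and landscape
# modules: rotation matrices, deterministic low-discrepancy sequences, the
# constrained support-function solver for ellipsoid surface regions, and
# bilinear interpolation on regular grids.

DEG <- pi / 180

rot_x <- function(deg) {
  r <- deg * DEG
  matrix(c(1, 0, 0, 0, cos(r), sin(r), 0, -sin(r), cos(r)), 3, 3)
}

rot_y <- function(deg) {
  r <- deg * DEG
  matrix(c(cos(r), 0, -sin(r), 0, 1, 0, sin(r), 0, cos(r)), 3, 3)
}

rot_z <- function(deg) {
  r <- deg * DEG
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
}

#' Body rotation matrix from yaw, pitch and roll
#'
#' Intrinsic Z-Y'-X' (Tait-Bryan) convention: yaw about the world Z axis,
#' then pitch about the rotated Y axis, then roll about the twice-rotated X
#' axis. A body-frame point `p` maps to the world frame as `R %*% p`.
#'
#' @param yaw,pitch,roll Angles in degrees.
#' @return A 3x3 rotation matrix.
#' @export
euler_rotation <- function(yaw = 0, pitch = 0, roll = 0) {
  rot_z(yaw) %*% rot_y(pitch) %*% rot_x(roll)
}

# Third row of euler_rotation(0, pitch, roll), vectorised over nodes.
# Row i is the world-up direction expressed in the body frame for node i;
# world z of a body point p is drop(w %*% p).
up_rows <- function(pitch, roll) {
  b <- pitch * DEG
  g <- roll * DEG
  cbind(-sin(b), cos(b) * sin(g), cos(b) * cos(g))
}

# Radical-inverse Halton sequence, deterministic (skips the origin).
halton_seq <- function(n, dim = 2) {
  primes <- c(2, 3, 5, 7, 11, 13)
  out <- matrix(0, n, dim)
  for (d in seq_len(dim)) {
    b <- primes[d]
    i <- seq_len(n)
    h <- numeric(n)
    f <- 1 / b
    while (any(i > 0)) {
      h <- h + f * (i %% b)
      i <- i %/% b
      f <- f / b
    }
    out[, d] <- h
  }
  out
}

# --- constrained support minimisation on the unit sphere -------------------
#
# Minimise e . q over the unit sphere subject to axis-aligned halfspace
# constraints dir_k * q[axis_k] >= bound_k (at most one constraint per axis).
# Used to find the lowest point of an ellipsoid surface region: for an
# ellipsoid x = diag(a,b,c) q with |q| = 1, the world height of a surface
# point in up-direction w is (diag(a,b,c) w) . q, so the support (lowest)
# height is the constrained minimum of a linear functional on the sphere.
#
# E is an n x 3 matrix (one functional per row); constraints is a data frame
# with columns axis, dir, bound (possibly zero rows). Returns the n-vector of
# minima. The active-set enumeration is closed-form for every subset.
sphere_linear_min <- function(E, constraints = NULL, tol = 1e-9) {
  n <- nrow(E)
  if (is.null(constraints) || nrow(constraints) == 0L) {
    return(-sqrt(rowSums(E^2)))
  }
  m <- nrow(constraints)
  ax <- constraints$axis
  dir <- constraints$dir
  bnd <- constraints$bound

  feasible <- function(Q) {
    ok <- rep(TRUE, nrow(Q))
    for (k in seq_len(m)) ok <- ok & (dir[k] * Q[, ax[k]] >= bnd[k] - 1e-7)
    ok
  }

  best <- rep(Inf, n)
  for (mask in 0:(2^m - 1)) {
    act <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    fixed_ax <- ax[act]
    fixed_v <- dir[act] * bnd[act]          # q[axis] on the boundary
    r2 <- 1 - sum(fixed_v^2)
    if (r2 < -tol) next
    r <- sqrt(max(r2, 0))
    free_ax <- setdiff(1:3, fixed_ax)
    Q <- matrix(0, n, 3)
    if (length(fixed_ax)) Q[, fixed_ax] <- rep(fixed_v, each = n)
    if (length(free_ax)) {
      Ef <- E[, free_ax, drop = FALSE]
      nf <- sqrt(rowSums(Ef^2))
      deg <- nf < 1e-12
      Qf <- -r * Ef / pmax(nf, 1e-300)
      if (any(deg)) {
        # objective is flat over the free circle: pick a feasible direction,
        # biased toward the slack side of the inactive constraints
        d <- numeric(length(free_ax))
        for (k in setdiff(seq_len(m), act)) {
          j <- match(ax[k], free_ax)
          if (!is.na(j)) d[j] <- dir[k]
        }
        if (all(d == 0)) d[1] <- 1
        d <- d / sqrt(sum(d^2))
        Qf[deg, ] <- matrix(rep(r * d, each = sum(deg)), ncol = length(free_ax))
      }
      Q[, free_ax] <- Qf
    }
    ok <- feasible(Q)
    if (any(ok)) {
      val <- rowSums(E * Q)
      upd <- ok & (val < best)
      best[upd] <- val[upd]
    }
  }
  if (any(!is.finite(best))) {
    rlang::abort("empty ellipsoid surface region: constraints admit no point",
                 class = "selfright_invalid_geometry")
  }
  best
}

# Bilinear interpolation on a regular grid. x, y are strictly increasing
# axis vectors; Z is length(x) x length(y). Query points outside the axes
# are an error (callers clamp/wrap as appropriate).
bilinear <- function(x, y, Z, xq, yq) {
  nx <- length(x); ny <- length(y)
  eps <- 1e-9
  if (any(xq < x[1] - eps | xq > x[nx] + eps) ||
      any(yq < y[1] - eps | yq > y[ny] + eps)) {
    rlang::abort("interpolation query outside grid", class = "selfright_domain_error")
  }
  xq <- pmin(pmax(xq, x[1]), x[nx])
  yq <- pmin(pmax(yq, y[1]), y[ny])
  i <- findInterval(xq, x, rightmost.closed = TRUE)
  j <- findInterval(yq, y, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nx - 1L)
  j <- pmin(pmax(j, 1L), ny - 1L)
  tx <- (xq - x[i]) / (x[i + 1L] - x[i])
  ty <- (yq - y[j]) / (y[j + 1L] - y[j])
  z00 <- Z[cbind(i, j)]
  z10 <- Z[cbind(i + 1L, j)]
  z01 <- Z[cbind(i, j + 1L)]
  z11 <- Z[cbind(i + 1L, j + 1L)]
  (1 - tx) * (1 - ty) * z00 + tx * (1 - ty) * z10 +
    (1 - tx) * ty * z01 + tx * ty * z11
}

# wrap angle(s) to [-180, 180]
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y
}

# wrapped angular difference
ang_diff <- function(a, b) wrap180(a - b)
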