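# Cubic regression spline bases parameterised by function values at knots,
# with the implied integrated-squared-second-derivative penalty. Two
# variants: cyclic (value, first- and second-derivative continuity at the
# period wrap; k-1 free columns) for hour-of-day and day-of-year, and
# natural (zero second derivative at the end knots; k columns) for
# aperiodic covariates such as lunar fraction and chlorophyll-a.
#
# Construction: on knots x_1 < ... < x_n a cubic interpolating spline is
# determined by its values y and second derivatives m, linked by a banded
# system B m = D y (first-derivative continuity); the curvature penalty is
# \int f''^2 = m' B m = y' D' B^{-1} D y, and evaluation rows combine the
# piecewise-cubic interpolation weights in y and m.

#' Cyclic cubic regression spline basis
#'
#' Equally spaced knots on [0, period]; the wrap point identifies knot k
#' with knot 1, giving k-1 free coefficients with value/1st/2nd-derivative
#' continuity across the wrap. Returns the evaluation matrix and the
#' curvature penalty.
#'
#' @param x covariate values; mapped into [0, period) modulo the period.
#' @param period cycle length (24 for hour, 365 for day of year).
#' @param k basis dimension as conventionally quoted (number of knots
#'   including the wrap duplicate); must be >= 4.
#' @return list: `X` (length(x) x (k-1)), `S` ((k-1) x (k-1) penalty),
#'   `knots`, `period`, `type = "cyclic"`.
#' @export
cyclic_cubic_basis <- function(x, period, k = 7) {
  if (k < 4) stop("k must be >= 4", call. = FALSE)
  n <- k - 1L
  knots <- seq(0, period, length.out = k)[seq_len(n)]
  h <- rep(period / n, n)                       # equal spacing, cyclic
  ip <- function(j) ifelse(j == n, 1L, j + 1L)  # cyclic successor
  im <- function(j) ifelse(j == 1L, n, j - 1L)
  B <- matrix(0, n, n); D <- matrix(0, n, n)
  for (j in seq_len(n)) {
    B[j, j] <- (h[im(j)] + h[j]) / 3
    B[j, im(j)] <- B[j, im(j)] + h[im(j)] / 6
    B[j, ip(j)] <- B[j, ip(j)] + h[j] / 6
    D[j, im(j)] <- D[j, im(j)] + 1 / h[im(j)]
    D[j, j] <- D[j, j] - 1 / h[im(j)] - 1 / h[j]
    D[j, ip(j)] <- D[j, ip(j)] + 1 / h[j]
  }
  BiD <- solve(B, D)
  xm <- x %% period
  seg <- pmin(floor(xm / h[1]) + 1L, n)         # segment index
  x0 <- knots[seg]
  hj <- h[seg]
  t1 <- (x0 + hj - xm)                          # distance to right knot
  t0 <- (xm - x0)
  Ay <- matrix(0, length(x), n)
  Am <- matrix(0, length(x), n)
  rows <- seq_along(x)
  right <- ip(seg)
  Ay[cbind(rows, seg)] <- t1 / hj
  Ay[cbind(rows, right)] <- Ay[cbind(rows, right)] + t0 / hj
  Am[cbind(rows, seg)] <- t1^3 / (6 * hj) - hj * t1 / 6
  Am[cbind(rows, right)] <- Am[cbind(rows, right)] + t0^3 / (6 * hj) - hj * t0 / 6
  X <- Ay + Am %*% BiD
  S <- t(D) %*% BiD
  S <- (S + t(S)) / 2
  list(X = X, S = S, knots = knots, period = period, k = k, type = "cyclic")
}

#' Natural cubic regression spline basis
#'
#' Knots equally spaced over `range` (default the data range); natural
#' boundary conditions (zero second derivative at the end knots); k free
#' coefficients. Evaluation outside the knot range extrapolates linearly.
#'
#' @param x covariate values.
#' @param k number of knots (basis dimension); must be >= 4.
#' @param range knot range, default `range(x)`.
#' @return list: `X`, `S`, `knots`, `type = "natural"`.
#' @export
natural_cubic_basis <- function(x, k = 7, range = NULL) {
  if (k < 4) stop("k must be >= 4", call. = FALSE)
  if (is.null(range)) range <- base::range(x)
  if (diff(range) <= 0) stop("degenerate covariate range", call. = FALSE)
  knots <- seq(range[1], range[2], length.out = k)
  h <- diff(knots)
  ni <- k - 2L
  B <- matrix(0, ni, ni); D <- matrix(0, ni, k)
  for (j in seq_len(ni)) {
    jj <- j + 1L   # knot index 2..k-1
    B[j, j] <- (h[jj - 1] + h[jj]) / 3
    if (j > 1L) B[j, j - 1L] <- h[jj - 1] / 6
    if (j < ni) B[j, j + 1L] <- h[jj] / 6
    D[j, jj - 1L] <- 1 / h[jj - 1]
    D[j, jj] <- -1 / h[jj - 1] - 1 / h[jj]
    D[j, jj + 1L] <- 1 / h[jj]
  }
  BiD <- solve(B, D)
  xc <- pmin(pmax(x, knots[1]), knots[k])
  seg <- pmin(findInterval(xc, knots), k - 1L)
  x0 <- knots[seg]; hj <- h[seg]
  t1 <- (knots[seg + 1L] - xc); t0 <- (xc - x0)
  rows <- seq_along(x)
  Ay <- matrix(0, length(x), k)
  Amf <- matrix(0, length(x), k)   # full m weights; m_1 = m_k = 0
  Ay[cbind(rows, seg)] <- t1 / hj
  Ay[cbind(rows, seg + 1L)] <- Ay[cbind(rows, seg + 1L)] + t0 / hj
  Amf[cbind(rows, seg)] <- t1^3 / (6 * hj) - hj * t1 / 6
  Amf[cbind(rows, seg + 1L)] <- Amf[cbind(rows, seg + 1L)] +
    t0^3 / (6 * hj) - hj * t0 / 6
  Am <- Amf[, 2:(k - 1L), drop = FALSE]
  X <- Ay + Am %*% BiD
  # linear extrapolation beyond the knot range using end-segment slopes
  out_lo <- which(x < knots[1]); out_hi <- which(x > knots[k])
  if (length(out_lo) || length(out_hi)) {
    eps <- diff(range) * 1e-6
    slope_rows <- function(x0v) {
      b1 <- natural_cubic_basis(c(x0v, x0v + eps), k = k, range = range)
      (b1$X[2, ] - b1$X[1, ]) / eps
    }
    if (length(out_lo)) {
      g <- slope_rows(knots[1])
      base_row <- X[out_lo[1], ] * 0
      b0 <- natural_cubic_basis(knots[1], k = k, range = range)$X[1, ]
      for (i in out_lo) X[i, ] <- b0 + g * (x[i] - knots[1])
    }
    if (length(out_hi)) {
      g <- slope_rows(knots[k] - eps)
      bk <- natural_cubic_basis(knots[k], k = k, range = range)$X[1, ]
      for (i in out_hi) X[i, ] <- bk + g * (x[i] - knots[k])
    }
  }
  S <- t(D) %*% BiD
  S <- (S + t(S)) / 2
  list(X = X, S = S, knots = knots, k = k, type = "natural", range = range)
}

# Absorb the sum-to-zero constraint 1'X beta = 0 into the basis: X -> X Z,
# S -> Z' S Z with Z an orthonormal basis of the constraint null space.
# Keeps smooths identifiable next to the intercept.
absorb_constraint <- function(basis) {
  C <- matrix(colSums(basis$X), nrow = 1)
  qr_ <- qr(t(C))
  Z <- qr.Q(qr_, complete = TRUE)[, -1, drop = FALSE]
  basis$Z <- Z
  basis$X_raw <- basis$X
  basis$S_raw <- basis$S
  basis$X <- basis$X %*% Z
  basis$S <- t(Z) %*% basis$S %*% Z
  basis
}

# Evaluate a (constrained) basis at new covariate values.
eval_basis <- function(basis, x) {
  raw <- if (basis$type == "cyclic") {
    cyclic_cubic_basis(x, basis$period, basis$k)$X
  } else {
    natural_cubic_basis(x, basis$k, basis$range)$X
  }
  if (!is.null(basis$Z)) raw %*% basis$Z else raw
}
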