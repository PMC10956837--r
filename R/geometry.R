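# Hyperbolic primitives: Lorentz (hyperboloid), Poincare-ball and Klein
# models, and the operators the model and the disk visualization rely on.
# Points are plain numeric vectors; internal matrix (row-wise) versions used
# by the training loop live at the bottom of the file.

.EPS_DEN <- 1e-15 # floor for 1 - ||p||^2 denominators
.EPS_ACOSH <- 1e-15 # arccosh arguments are clamped to >= 1 + .EPS_ACOSH

#' Lorentzian inner product
#'
#' `<x, y>_L = -x0*y0 + sum_{i>=1} xi*yi` on the ambient space `R^{d+1}`.
#' The hyperboloid of curvature `-1/beta` is the set `<x, x>_L = -beta`,
#' `x0 > 0`.
#'
#' @param x,y numeric vectors of equal length `d + 1 >= 2`.
#' @return a single number.
#' @examples
#' lorentzInner(c(1, 0, 0), c(1, 0, 0)) # -1: the hyperboloid origin
#' @export
lorentzInner <- function(x, y) {
  if (length(x) != length(y)) stop("dimension mismatch between x and y")
  if (length(x) < 2L) stop("ambient dimension must be at least 2")
  -x[1L] * y[1L] + sum(x[-1L] * y[-1L])
}

.checkOnManifold <- function(x, beta = 1, tol = 1e-6, what = "point") {
  ip <- lorentzInner(x, x)
  if (abs(ip + beta) > tol || x[1L] <= 0) {
    stop(sprintf(
      "%s is off the hyperboloid: <x,x>_L = %.3g (expected %.3g)", what, ip, -beta
    ))
  }
  invisible(TRUE)
}

#' Squared Lorentzian distance
#'
#' `d_L^2(x, y) = <x - y, x - y>_L = -2*beta - 2*<x, y>_L` for points on the
#' hyperboloid of curvature `-1/beta`. Satisfies all metric axioms except
#' the triangle inequality.
#'
#' @param x,y on-manifold points (ambient numeric vectors).
#' @param beta positive curvature parameter; default 1.
#' @param tol manifold-membership tolerance.
#' @return a nonnegative number.
#' @export
squaredLorentzDistance <- function(x, y, beta = 1, tol = 1e-6) {
  stopifnot(beta > 0)
  .checkOnManifold(x, beta, tol, "x")
  .checkOnManifold(y, beta, tol, "y")
  max(0, -2 * beta - 2 * lorentzInner(x, y))
}

#' Poincare distance in the open unit ball
#'
#' `d_P(p, q) = arccosh(1 + 2*||p - q||^2 / ((1 - ||p||^2) (1 - ||q||^2)))`.
#'
#' @param p,q numeric vectors with Euclidean norm < 1.
#' @return a nonnegative number.
#' @examples
#' poincareDistance(c(0, 0), c(0.5, 0)) # log(3)
#' @export
poincareDistance <- function(p, q) {
  .checkInBall(p)
  .checkInBall(q)
  a <- max(1 - sum(p^2), .EPS_DEN)
  b <- max(1 - sum(q^2), .EPS_DEN)
  arg <- 1 + 2 * sum((p - q)^2) / (a * b)
  acosh(max(arg, 1)) # arg can dip below 1 only by rounding; p == q gives 0
}

.checkInBall <- function(p, what = "point") {
  if (sum(p^2) >= 1) stop(sprintf("%s lies outside the open unit ball", what))
  invisible(TRUE)
}

#' Map a hyperboloid point to the Poincare ball
#'
#' The diffeomorphism `h(x) = (x1, ..., xd) / (x0 + 1)`.
#'
#' @param x an on-manifold ambient vector (beta = 1).
#' @return a numeric vector of length `d` with norm < 1.
#' @export
lorentzToPoincare <- function(x) {
  if (x[1L] <= -1) stop("x0 must exceed -1")
  x[-1L] / (x[1L] + 1)
}

#' Lift a Poincare-ball point onto the hyperboloid
#'
#' Inverse of [lorentzToPoincare()] for `beta = 1`:
#' `x0 = (1 + ||p||^2) / (1 - ||p||^2)`, `xi = 2 pi / (1 - ||p||^2)`; for
#' general `beta` the result is scaled by `sqrt(beta)` so that
#' `<x, x>_L = -beta`.
#'
#' @param p numeric vector with norm < 1.
#' @param beta positive curvature parameter.
#' @return an ambient vector of length `d + 1` on the hyperboloid.
#' @export
poincareToLorentz <- function(p, beta = 1) {
  stopifnot(beta > 0)
  .checkInBall(p)
  den <- max(1 - sum(p^2), .EPS_DEN)
  sqrt(beta) * c((1 + sum(p^2)) / den, 2 * p / den)
}

#' Exponential map at the hyperboloid origin
#'
#' Lifts an encoder output `v` in `R^d` to the canonical tangent vector
#' `(0, v)` at the origin `(sqrt(beta), 0, ..., 0)` and maps it onto the
#' manifold along the geodesic:
#' `exp_0(v) = cosh(r / sqrt(beta)) x0 + sqrt(beta) sinh(r / sqrt(beta)) v / r`
#' where the geodesic radius is the tangent norm
#' `||v||_L = sqrt(<(0,v), (0,v)>_L) = ||v||`. `v = 0` returns the origin.
#'
#' @param v numeric vector of length `d` (tangent coordinates).
#' @param beta positive curvature parameter.
#' @return an on-manifold ambient vector of length `d + 1`.
#' @export
expMapOrigin <- function(v, beta = 1) {
  stopifnot(beta > 0)
  if (any(!is.finite(v))) stop("non-finite tangent vector")
  r <- sqrt(sum(v^2))
  sb <- sqrt(beta)
  if (r < 1e-12) {
    return(c(sb, rep(0, length(v))))
  }
  c(sb * cosh(r / sb), sb * sinh(r / sb) * v / r)
}

#' Clip a vector to a maximum Euclidean norm
#'
#' The clip regularization applied to latent embeddings before the
#' exponential map: vectors with norm above `alpha` are rescaled onto the
#' `alpha`-sphere, shorter vectors pass unchanged.
#'
#' @param v numeric vector.
#' @param alpha positive threshold.
#' @export
clipNorm <- function(v, alpha = 1) {
  stopifnot(alpha > 0)
  nv <- sqrt(sum(v^2))
  if (nv <= alpha) v else v * (alpha / nv)
}

#' Convert between the Poincare and Klein ball models
#'
#' `poincareToKlein(p) = 2 p / (1 + ||p||^2)`;
#' `kleinToPoincare(k) = k / (1 + sqrt(1 - ||k||^2))`. The two maps are
#' mutually inverse on the open unit ball.
#'
#' @param p,k numeric vectors with norm < 1.
#' @name kleinConvert
#' @export
poincareToKlein <- function(p) {
  .checkInBall(p)
  2 * p / (1 + sum(p^2))
}

#' @rdname kleinConvert
#' @export
kleinToPoincare <- function(k) {
  .checkInBall(k)
  k / (1 + sqrt(max(1 - sum(k^2), 0)))
}

#' Einstein midpoint of Poincare-ball points
#'
#' The hyperbolic average: points are converted to Klein coordinates, the
#' Lorentz-factor-weighted mean `sum_i gamma_i k_i / sum_i gamma_i` with
#' `gamma_i = 1 / sqrt(1 - ||k_i||^2)` is taken, and the result is converted
#' back to the Poincare ball.
#'
#' @param points a list of numeric vectors, or a numeric matrix with one
#'   point per row; all norms < 1.
#' @return a numeric vector (a Poincare-ball point).
#' @export
einsteinMidpoint <- function(points) {
  if (is.list(points)) points <- do.call(rbind, points)
  if (!is.matrix(points)) points <- matrix(points, nrow = 1L)
  if (nrow(points) == 0L) stop("empty point set")
  if (any(rowSums(points^2) >= 1)) stop("all points must lie inside the unit ball")
  K <- t(apply(points, 1L, poincareToKlein))
  if (ncol(points) == 1L) K <- t(K)
  gamma <- 1 / sqrt(pmax(1 - rowSums(K^2), .EPS_DEN))
  kleinToPoincare(colSums(K * gamma) / sum(gamma))
}

#' Mobius addition in the Poincare ball
#'
#' `a (+) x = ((1 + 2<a,x> + ||x||^2) a + (1 - ||a||^2) x) /
#'  (1 + 2<a,x> + ||a||^2 ||x||^2)`.
#'
#' @param a,x numeric vectors with norm < 1.
#' @export
mobiusAdd <- function(a, x) {
  .checkInBall(a)
  .checkInBall(x)
  ax <- sum(a * x)
  na2 <- sum(a^2)
  nx2 <- sum(x^2)
  ((1 + 2 * ax + nx2) * a + (1 - na2) * x) / (1 + 2 * ax + na2 * nx2)
}

#' Translate the Poincare disk so a chosen point becomes the origin
#'
#' Applies the gyro-translation `x -> (-a) (+) x` with `a = newOrigin` to
#' every point. All pairwise Poincare distances are preserved; the chosen
#' point maps to the disk center, which acts as a "zoom-in" on its
#' neighborhood since spatial resolution is amplified near the origin.
#'
#' @param points a numeric matrix (one point per row) or list of vectors.
#' @param newOrigin the point to move to the center.
#' @return a matrix of translated points (same shape and row names).
#' @export
mobiusTranslate <- function(points, newOrigin) {
  lst <- is.list(points)
  if (lst) points <- do.call(rbind, points)
  if (!is.matrix(points)) points <- matrix(points, nrow = 1L)
  .checkInBall(newOrigin, "newOrigin")
  out <- t(apply(points, 1L, function(x) mobiusAdd(-newOrigin, x)))
  if (ncol(points) == 1L) out <- t(out)
  dimnames(out) <- dimnames(points)
  out
}

# ---- vectorized internals (rows = points) ----------------------------------

# exp map at the origin applied row-wise; U is n x d, returns n x (d+1)
rowsExpMapOrigin <- function(U, beta = 1) {
  r <- sqrt(rowSums(U^2))
  sb <- sqrt(beta)
  s <- ifelse(r < 1e-12, 1 / sb, sinh(r / sb) / r) # sqrt(beta)*sinh(r/sb)/r
  cbind(sb * cosh(r / sb), sb * s * U, deparse.level = 0)
}

# Lorentzian Gram matrix between row sets X (n x (d+1)) and Y (m x (d+1))
lorentzGram <- function(X, Y) {
  X[, -1L, drop = FALSE] %*% t(Y[, -1L, drop = FALSE]) -
    outer(X[, 1L], Y[, 1L])
}

# squared Lorentzian distances between all rows of X and Y
rowsSquaredLorentz <- function(X, Y, beta = 1) {
  pmax(-2 * beta - 2 * lorentzGram(X, Y), 0)
}

# row-wise clip to norm <= alpha
rowsClipNorm <- function(U, alpha) {
  n <- sqrt(rowSums(U^2))
  f <- ifelse(n > alpha, alpha / n, 1)
  U * f
}

# row-wise hyperboloid -> Poincare ball (beta = 1 convention)
rowsLorentzToPoincare <- function(X) {
  X[, -1L, drop = FALSE] / (X[, 1L] + 1)
}

# full Poincare distance matrix for rows of P (n x d, norms < 1)
poincareDistanceMatrix <- function(P) {
  n2 <- rowSums(P^2)
  if (any(n2 >= 1)) stop("all points must lie inside the open unit ball")
  sq <- outer(n2, n2, "+") - 2 * (P %*% t(P)) # ||p_i - p_j||^2
  sq <- pmax(sq, 0)
  den <- outer(pmax(1 - n2, .EPS_DEN), pmax(1 - n2, .EPS_DEN))
  arg <- pmax(1 + 2 * sq / den, 1)
  D <- acosh(arg)
  diag(D) <- 0
  D
}
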