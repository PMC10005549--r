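# Free-space dyadic Green's tensor and dipole-dipole coupling matrices.
#
# Internal scalar kernels, with x = k0 * r:
#   G(r) = (k0 / 4 pi) * [ A(x) I + B(x) rhat %o% rhat ],
#   A(x) = e^{ix} (x^2 + i x - 1) / x^3,
#   B(x) = -e^{ix} (x^2 + 3 i x - 3) / x^3.
# Projections onto real unit dipoles give
#   Omega_ij = -(3/4) Gamma0 [ ReA (pi.pj) + ReB (pi.rhat)(pj.rhat) ],
#   Gamma_ij =  (3/2) Gamma0 [ ImA (pi.pj) + ImB (pi.rhat)(pj.rhat) ].
# Im A = f1(x), Im B = -f2(x) are O(1) differences of O(1/x^3) terms and are
# evaluated by a truncated Taylor series below x_switch to avoid catastrophic
# cancellation (LH2-scale separations sit at k0 r ~ 1e-2).

# f1 = ((x^2-1) sin x + x cos x) / x^3  -> 2/3 as x -> 0
# f2 = ((x^2-3) sin x + 3 x cos x) / x^3 -> 0
# Series coefficients: f1 = sum_j (-1)^j x^(2j) [1/(2j+1)! - (2j+2)/(2j+3)!]
#                      f2 = sum_j (-1)^j x^(2j) [1/(2j+1)! - 3(2j+2)/(2j+3)!]
.f_series_coef <- local({
  j <- 0:11
  list(c1 = (-1)^j * (1 / factorial(2 * j + 1) -
                        (2 * j + 2) / factorial(2 * j + 3)),
       c2 = (-1)^j * (1 / factorial(2 * j + 1) -
                        3 * (2 * j + 2) / factorial(2 * j + 3)),
       pow = 2 * j)
})

.im_kernels <- function(x, x_switch = 1e-2) {
  f1 <- ((x^2 - 1) * sin(x) + x * cos(x)) / x^3
  f2 <- ((x^2 - 3) * sin(x) + 3 * x * cos(x)) / x^3
  small <- x < x_switch
  if (any(small)) {
    xs <- x[small]
    xp <- outer(xs, .f_series_coef$pow, `^`)
    f1[small] <- drop(xp %*% .f_series_coef$c1)
    f2[small] <- drop(xp %*% .f_series_coef$c2)
  }
  list(f1 = f1, f2 = f2)
}

.re_kernels <- function(x) {
  # no cancellation: the 1/x^3 term dominates at small x
  g1 <- ((x^2 - 1) * cos(x) - x * sin(x)) / x^3
  g2 <- ((x^2 - 3) * cos(x) - 3 * x * sin(x)) / x^3
  list(g1 = g1, g2 = g2)
}

#' Free-space dyadic Green's tensor at the transition frequency
#'
#' Evaluates the classical electromagnetic Green's tensor
#' \eqn{G(r, \omega_0)} for a point dipole in vacuum, in wavelength units
#' (\code{k0 = 2*pi} by default). The tensor is symmetric (\eqn{G = G^T})
#' and even in \code{r}; it diverges at \code{r = 0}, where emitter
#' self-terms are instead fixed by the Gamma0 normalization.
#'
#' @param r separation 3-vector, in lambda.
#' @param k0 wavenumber (defaults to \code{2*pi}).
#' @param x_switch below this value of \code{k0*|r|} the imaginary parts of
#'   the scalar kernels are evaluated by a Taylor series.
#' @return 3x3 complex matrix.
#' @export
green_tensor <- function(r, k0 = 2 * pi, x_switch = 1e-2) {
  r <- as.numeric(r)
  stopifnot(length(r) == 3, all(is.finite(r)))
  rn <- sqrt(sum(r^2))
  if (rn == 0) stop("Green's tensor is singular at r = 0")
  x <- k0 * rn
  re <- .re_kernels(x)
  im <- .im_kernels(x, x_switch)
  A <- complex(real = re$g1, imaginary = im$f1)
  B <- -complex(real = re$g2, imaginary = im$f2)
  rhat <- r / rn
  (k0 / (4 * pi)) * (A * diag(3) + B * (rhat %o% rhat))
}

#' Coherent and dissipative coupling of one emitter pair
#'
#' Projects the Green's tensor between two real unit dipoles to obtain the
#' coherent (\code{omega}) and dissipative (\code{gamma}) dipole-dipole
#' coupling rates, in units of Gamma0:
#' \deqn{\Omega_{ij} = -\frac{3\pi\Gamma_0}{k_0}
#'   \mathrm{Re}[\hat p_i \cdot G(r_i - r_j) \cdot \hat p_j], \quad
#'   \Gamma_{ij} = \frac{6\pi\Gamma_0}{k_0}
#'   \mathrm{Im}[\hat p_i \cdot G(r_i - r_j) \cdot \hat p_j].}
#'
#' @param ri,rj emitter positions (3-vectors, lambda).
#' @param pi_,pj_ real unit dipole orientation vectors.
#' @param k0 wavenumber.
#' @param x_switch series-switch threshold, see \code{\link{green_tensor}}.
#' @return list with numeric scalars \code{omega} and \code{gamma} [Gamma0].
#' @export
coupling_pair <- function(ri, pi_, rj, pj_, k0 = 2 * pi, x_switch = 1e-2) {
  if (is.complex(pi_) || is.complex(pj_))
    stop("complex dipole polarization vectors are not supported")
  r <- as.numeric(ri) - as.numeric(rj)
  rn <- sqrt(sum(r^2))
  if (rn == 0) stop("coincident emitter positions")
  x <- k0 * rn
  rhat <- r / rn
  pp <- sum(pi_ * pj_)
  prr <- sum(pi_ * rhat) * sum(pj_ * rhat)
  re <- .re_kernels(x)
  im <- .im_kernels(x, x_switch)
  list(omega = -0.75 * (re$g1 * pp - re$g2 * prr),
       gamma = 1.5 * (im$f1 * pp - im$f2 * prr))
}

#' Assemble the coupling matrices of an emitter array
#'
#' Builds the real symmetric coherent (\code{omega}) and dissipative
#' (\code{gamma}) coupling matrices over all emitters, in units of Gamma0,
#' with the diagonal convention \code{omega[i,i] = 0},
#' \code{gamma[i,i] = Gamma0 = 1}. \code{gamma} is positive semidefinite up
#' to numerical tolerance for any geometry.
#'
#' @param array an \code{emitter_array}.
#' @param k0 wavenumber.
#' @param x_switch series-switch threshold.
#' @return list of class \code{coupling_matrices} with fields \code{omega}
#'   and \code{gamma}.
#' @export
coupling_matrices <- function(array, k0 = 2 * pi, x_switch = 1e-2) {
  P <- array$positions
  D <- array$dipoles
  n <- nrow(P)
  dnorm2 <- rowSums(D^2)
  if (any(abs(dnorm2 - 1) > 1e-12))
    stop("dipole vectors must have unit norm")
  dx <- outer(P[, 1], P[, 1], `-`)
  dy <- outer(P[, 2], P[, 2], `-`)
  dz <- outer(P[, 3], P[, 3], `-`)
  rr <- sqrt(dx^2 + dy^2 + dz^2)
  off <- upper.tri(rr) | lower.tri(rr)
  if (any(rr[off] == 0)) {
    bad <- which(rr == 0 & off, arr.ind = TRUE)[1, ]
    stop(sprintf("emitters %d and %d have coincident positions",
                 bad[1], bad[2]))
  }
  diag(rr) <- 1  # dummy; diagonals are overwritten below
  # pi . rhat with row index i, pj . rhat with column index j
  pi_r <- (dx * D[, 1] + dy * D[, 2] + dz * D[, 3]) / rr
  pj_r <- (t(t(dx) * D[, 1]) + t(t(dy) * D[, 2]) + t(t(dz) * D[, 3])) / rr
  pp <- D %*% t(D)
  x <- k0 * rr
  re <- .re_kernels(x)
  im <- .im_kernels(x, x_switch)
  omega <- -0.75 * (re$g1 * pp - re$g2 * pi_r * pj_r)
  gamma <- 1.5 * (im$f1 * pp - im$f2 * pi_r * pj_r)
  diag(omega) <- 0
  diag(gamma) <- 1
  # enforce exact symmetry against rounding asymmetries in the outer products
  omega <- (omega + t(omega)) / 2
  gamma <- (gamma + t(gamma)) / 2
  structure(list(omega = omega, gamma = gamma), class = "coupling_matrices")
}
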