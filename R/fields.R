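# Scattered-field reconstruction of collective modes via the input-output
# relation: E+(r) is the superposition of the Green's-tensor response of
# every emitter weighted by its coherence amplitude. The overall field
# prefactor is set to 1 (intensities in arbitrary units).

# Vectorized Green's-tensor application: rows of Rm are separations r - r_i,
# p is the (real) source dipole; returns n x 3 complex field contributions.
.green_apply <- function(Rm, p, k0 = 2 * pi, x_switch = 1e-2) {
  rn <- sqrt(rowSums(Rm^2))
  x <- k0 * rn
  re <- .re_kernels(x)
  im <- .im_kernels(x, x_switch)
  A <- complex(real = re$g1, imaginary = im$f1)
  B <- -complex(real = re$g2, imaginary = im$f2)
  rhat <- Rm / rn
  rp <- drop(rhat %*% p)
  (k0 / (4 * pi)) * (A * matrix(p, nrow(Rm), 3, byrow = TRUE) +
                       (B * rp) * rhat)
}

#' Scattered field of a set of emitter coherences
#'
#' Evaluates \eqn{E^+(r) = \sum_i G(r - r_i, \omega_0)\,\hat p_i\,c_i} on a
#' grid of observation points; grid points closer than \code{r_excl} to any
#' emitter are masked (the Green's tensor diverges there).
#'
#' @param array an \code{emitter_array}.
#' @param amplitudes complex coherence amplitudes, one per emitter.
#' @param grid numeric matrix (n x 3) of observation points [lambda].
#' @param k0 wavenumber.
#' @param r_excl exclusion radius around emitters [lambda].
#' @return A \code{field_grid}: list with \code{points}, complex
#'   \code{values} (n x 3), \code{intensity} (|E|^2 summed over components,
#'   NA on masked points) and logical \code{mask}.
#' @export
scattered_field <- function(array, amplitudes, grid, k0 = 2 * pi,
                            r_excl = 0.02) {
  grid <- as.matrix(grid)
  if (nrow(grid) == 0) stop("empty observation grid")
  if (ncol(grid) != 3) stop("grid must have 3 columns")
  n_em <- n_emitters(array)
  if (length(amplitudes) != n_em)
    stop("need one amplitude per emitter")
  E <- matrix(0i, nrow(grid), 3)
  mask <- rep(FALSE, nrow(grid))
  for (i in seq_len(n_em)) {
    Rm <- sweep(grid, 2, array$positions[i, ])
    mask <- mask | sqrt(rowSums(Rm^2)) < r_excl
    if (amplitudes[i] != 0)
      E <- E + amplitudes[i] * .green_apply(Rm, array$dipoles[i, ], k0)
  }
  E[mask, ] <- NA_complex_
  intensity <- rowSums(Mod(E)^2)
  structure(list(points = grid, values = E, intensity = intensity,
                 mask = mask),
            class = "field_grid")
}

#' Per-emitter amplitudes of a Bloch mode
#'
#' Maps a Bloch mode (angular momentum m, unit-cell eigenvector v) to
#' per-emitter coherences \eqn{c_{\ell\alpha} = e^{i 2\pi m \ell/N}
#' v_\alpha/\sqrt N}, a unit-norm vector for unit-norm v.
#'
#' @param array an \code{emitter_array}.
#' @param m angular momentum.
#' @param eigvec complex unit-cell eigenvector (length \code{n_cell});
#'   defaults to 1 for a single-component array.
#' @export
bloch_mode_amplitudes <- function(array, m, eigvec = NULL) {
  if (is.null(eigvec)) {
    if (array$n_cell != 1L)
      stop("eigvec required for multi-component arrays")
    eigvec <- 1 + 0i
  }
  if (length(eigvec) != array$n_cell)
    stop("eigvec length must equal n_cell")
  exp(2i * pi * m * array$cell / array$N) * eigvec[array$component] /
    sqrt(array$N)
}

#' Planar intensity cut through a mode's scattered field
#'
#' Samples the scattered-field intensity of a collective mode on a square
#' grid in a plane of constant z or constant y.
#'
#' @param array an \code{emitter_array}.
#' @param amplitudes per-emitter coherences (e.g. from
#'   \code{\link{bloch_mode_amplitudes}}).
#' @param plane \code{"z"} or \code{"y"}: the held-constant coordinate.
#' @param at value of the held coordinate [lambda].
#' @param extent half-width of the square cut [lambda].
#' @param res grid points per axis.
#' @param ... passed to \code{\link{scattered_field}}.
#' @return A \code{field_grid} with an additional \code{shape} attribute
#'   (res x res) and axis vectors \code{u}, \code{v}.
#' @export
intensity_cut <- function(array, amplitudes, plane = c("z", "y"), at = 0,
                          extent = 3, res = 101, ...) {
  plane <- match.arg(plane)
  u <- seq(-extent, extent, length.out = res)
  gg <- expand.grid(u = u, v = u)
  grid <- switch(plane,
                 z = cbind(gg$u, gg$v, at),
                 y = cbind(gg$u, at, gg$v))
  fg <- scattered_field(array, amplitudes, grid, ...)
  fg$u <- u
  fg$v <- u
  fg$shape <- c(res, res)
  fg$plane <- plane
  fg$at <- at
  fg
}

#' Export a field grid as a data frame
#'
#' @param x a \code{field_grid}.
#' @return data.frame with point coordinates, real/imaginary field
#'   components and intensity; masked points carry NA.
#' @export
as.data.frame.field_grid <- function(x, ...) {
  data.frame(x = x$points[, 1], y = x$points[, 2], z = x$points[, 3],
             Ex_re = Re(x$values[, 1]), Ex_im = Im(x$values[, 1]),
             Ey_re = Re(x$values[, 2]), Ey_im = Im(x$values[, 2]),
             Ez_re = Re(x$values[, 3]), Ez_im = Im(x$values[, 3]),
             intensity = x$intensity, masked = x$mask)
}
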