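#' Ring specification
#'
#' Describes one N-fold symmetric ring of two-level emitters. All lengths are
#' in units of the transition wavelength lambda (so the wavenumber is
#' \code{k0 = 2*pi}); detunings and rates are in units of the single-emitter
#' decay rate Gamma0.
#'
#' The emitter dipole orientation is parameterized in the local ring frame as
#' \deqn{\hat p_i = \sin\theta\cos\phi\,\hat e_{\phi,i}
#'   + \sin\theta\sin\phi\,\hat e_{r,i} + \cos\theta\,\hat e_z,}
#' where \eqn{\hat e_{r,i}} and \eqn{\hat e_{\phi,i}} are the radial and
#' tangential unit vectors at emitter i. Hence \code{theta = 0} gives
#' transverse (out-of-plane) polarization, \code{theta = pi/2, phi = 0}
#' tangential and \code{theta = pi/2, phi = pi/2} radial polarization.
#'
#' @param N integer number of emitters (>= 2).
#' @param R ring radius in lambda. Exactly one of \code{R}, \code{d} must be
#'   given; the lattice constant is \code{d = 2 R sin(pi/N)}.
#' @param d nearest-neighbour (chord) distance in lambda.
#' @param z vertical offset of the ring plane in lambda.
#' @param delta rigid rotation of the ring about the z axis, in radians.
#' @param theta,phi polar and azimuthal dipole angles, radians.
#' @param detuning on-site transition-frequency offset in Gamma0.
#' @param label optional character label for the ring.
#' @return An object of class \code{ring_spec}.
#' @export
ring_spec <- function(N, R = NULL, d = NULL, z = 0, delta = 0,
                      theta = 0, phi = 0, detuning = 0, label = NULL) {
  N <- as.integer(N)
  if (is.na(N) || N < 2L) stop("N must be an integer >= 2")
  if (is.null(R) == is.null(d))
    stop("exactly one of 'R' or 'd' must be supplied")
  if (is.null(R)) {
    d <- as.numeric(d)
    if (!is.finite(d) || d <= 0) stop("d must be finite and > 0")
    R <- d / (2 * sin(pi / N))
  }
  R <- as.numeric(R); z <- as.numeric(z); delta <- as.numeric(delta)
  theta <- as.numeric(theta); phi <- as.numeric(phi)
  detuning <- as.numeric(detuning)
  vals <- c(R = R, z = z, delta = delta, theta = theta, phi = phi,
            detuning = detuning)
  if (!all(is.finite(vals)))
    stop("non-finite ring parameter(s): ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  if (R <= 0) stop("R must be > 0")
  structure(
    list(N = N, R = R, z = z, delta = delta %% (2 * pi), theta = theta,
         phi = phi, detuning = detuning,
         label = if (is.null(label)) NA_character_ else as.character(label)),
    class = "ring_spec")
}

#' Lattice constant of a ring
#'
#' @param spec a \code{ring_spec}.
#' @return \code{2 R sin(pi/N)}, the chord between neighbouring emitters.
#' @export
lattice_constant <- function(spec) 2 * spec$R * sin(pi / spec$N)

new_emitter_array <- function(positions, dipoles, detunings, cell, component,
                              N, n_cell, labels = NULL) {
  structure(
    list(positions = positions, dipoles = dipoles, detunings = detunings,
         cell = cell, component = component, N = N, n_cell = n_cell,
         labels = labels),
    class = "emitter_array")
}

#' Number of emitters in an array
#' @param array an \code{emitter_array}.
#' @export
n_emitters <- function(array) nrow(array$positions)

#' @export
print.emitter_array <- function(x, ...) {
  cat(sprintf("<emitter_array> %d emitters, %d-fold symmetry, %d component(s) per cell\n",
              n_emitters(x), x$N, x$n_cell))
  invisible(x)
}

#' Build a single ring of emitters
#'
#' Places N emitters at angles \code{2*pi*i/N + delta}, i = 0..N-1, radius R,
#' height z, with dipoles oriented per the \code{ring_spec} angle convention.
#'
#' @param spec a \code{ring_spec}.
#' @return An \code{emitter_array} with one component per unit cell.
#' @export
build_ring <- function(spec) {
  stopifnot(inherits(spec, "ring_spec"))
  i <- seq_len(spec$N) - 1L
  gam <- 2 * pi * i / spec$N + spec$delta
  pos <- cbind(spec$R * cos(gam), spec$R * sin(gam), rep(spec$z, spec$N))
  er <- cbind(cos(gam), sin(gam), 0)
  eph <- cbind(-sin(gam), cos(gam), 0)
  dip <- sin(spec$theta) * cos(spec$phi) * eph +
    sin(spec$theta) * sin(spec$phi) * er
  dip[, 3] <- dip[, 3] + cos(spec$theta)
  new_emitter_array(pos, dip, rep(spec$detuning, spec$N),
                    cell = i, component = rep(1L, spec$N),
                    N = spec$N, n_cell = 1L,
                    labels = rep(spec$label, spec$N))
}

#' Stack several rings sharing one N-fold symmetry
#'
#' Concatenates rings into a multi-component array: the unit cell contains one
#' site of each ring (component alpha enumerates rings), and cell index ell is
#' shared. All rings must have the same N, otherwise the common rotational
#' symmetry (and the Bloch reduction built on it) would be lost.
#'
#' @param specs list of \code{ring_spec}s with identical \code{N}.
#' @return An \code{emitter_array} with \code{n_cell = length(specs)}.
#' @export
build_stack <- function(specs) {
  if (inherits(specs, "ring_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1, all(vapply(specs, inherits, TRUE, "ring_spec")))
  Ns <- vapply(specs, function(s) s$N, 1L)
  if (length(unique(Ns)) != 1L)
    stop("all rings in a stack must share the same N (got ",
         paste(Ns, collapse = ", "), ")")
  N <- Ns[1]
  parts <- lapply(specs, build_ring)
  arr <- new_emitter_array(
    positions = do.call(rbind, lapply(parts, `[[`, "positions")),
    dipoles = do.call(rbind, lapply(parts, `[[`, "dipoles")),
    detunings = unlist(lapply(parts, `[[`, "detunings")),
    cell = unlist(lapply(parts, `[[`, "cell")),
    component = rep(seq_along(parts), each = N),
    N = N, n_cell = length(parts),
    labels = unlist(lapply(parts, `[[`, "labels")))
  dmin <- min_pair_distance(arr)
  if (dmin <= 0)
    stop("stack contains coincident emitter positions")
  arr
}

min_pair_distance <- function(array) {
  D <- as.matrix(stats::dist(array$positions))
  diag(D) <- Inf
  min(D)
}

#' Verify the N-fold rotational symmetry of an array
#'
#' Rotates all positions and dipoles by 2*pi/N about the z axis and checks
#' that the array maps onto itself with cell index ell -> ell + 1 (mod N),
#' component fixed.
#'
#' @param array an \code{emitter_array}.
#' @param tol maximum allowed coordinate deviation.
#' @return Invisibly, the maximum deviation. Errors if it exceeds \code{tol}.
#' @export
check_nfold_symmetry <- function(array, tol = 1e-10) {
  a <- 2 * pi / array$N
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  rot_pos <- array$positions %*% t(Rz)
  rot_dip <- array$dipoles %*% t(Rz)
  # index of the image emitter (same component, next cell)
  key <- function(cell, comp) paste(cell, comp)
  idx <- match(key((array$cell + 1L) %% array$N, array$component),
               key(array$cell, array$component))
  dev <- max(abs(rot_pos - array$positions[idx, , drop = FALSE]),
             abs(rot_dip - array$dipoles[idx, , drop = FALSE]),
             abs(array$detunings - array$detunings[idx]))
  if (dev > tol)
    stop(sprintf("array violates %d-fold symmetry (max deviation %.3g > %.3g)",
                 array$N, dev, tol))
  invisible(dev)
}

#' Rescale an emitter array about the symmetry axis
#'
#' Multiplies all positions (in-plane radii and vertical offsets) by a common
#' factor \code{alpha}, leaving dipole orientations and detunings untouched.
#' Used for size sweeps of the LH2 motif.
#'
#' @param array an \code{emitter_array}.
#' @param alpha positive scale factor.
#' @export
scale_geometry <- function(array, alpha) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be finite and > 0")
  array$positions <- array$positions * alpha
  array
}

#' Default (synthetic) LH2 structural parameter set
#'
#' An approximate, clearly synthetic stand-in for the LH2 antenna geometry of
#' purple bacteria: a 9-fold symmetric motif of three rings, two closely
#' spaced B850 components (18 emitters total) plus one vertically offset B800
#' ring (9 emitters). Lengths are entered in nanometres and converted to
#' units of the B850 transition wavelength (850 nm); the B800 detuning is
#' positive (B800 absorbs at shorter wavelength) and of order 1e7 Gamma0.
#'
#' These values are plausible for the real complex at the level of ring radii,
#' inter-ring offsets and mostly-in-plane alternating dipoles, but they are
#' NOT fitted to crystallographic coordinates; all analyses built on them are
#' qualitative/structural.
#'
#' @param lambda_nm reference transition wavelength in nanometres.
#' @return A list with fields \code{N}, \code{lambda_nm} and one sub-list per
#'   component (\code{b850a}, \code{b850b}, \code{b800}) holding
#'   \code{R_nm}, \code{z_nm}, \code{offset_rad}, \code{theta_rad},
#'   \code{phi_rad}, \code{detuning_Gamma0}.
#' @export
lh2_params <- function(lambda_nm = 850) {
  list(
    N = 9L,
    lambda_nm = lambda_nm,
    # Two strongly coupled B850 components: radius ~2.6-2.7 nm, dipoles
    # nearly tangential with a small vertical tilt, roughly antiparallel
    # between the two components (alternating around the ring).
    b850a = list(R_nm = 2.59, z_nm = 0.0, offset_rad = -0.1786,
                 theta_rad = 1.74, phi_rad = 0.20, detuning_Gamma0 = 0),
    b850b = list(R_nm = 2.70, z_nm = 0.3, offset_rad = 0.1786,
                 theta_rad = 1.40, phi_rad = pi - 0.20,
                 detuning_Gamma0 = 0),
    # B800 ring: larger radius, vertically offset, nearly in-plane dipoles.
    # The transition-frequency offset (order 1e7 Gamma0) is set so that at
    # the nominal size the upper B850-derived band sits just below the B800
    # band: the motif is slightly above its critical size, as in the real
    # complex.
    b800 = list(R_nm = 3.10, z_nm = 1.66, offset_rad = 2 * pi / 18,
                theta_rad = 1.75, phi_rad = 0.0,
                detuning_Gamma0 = 6.0e6)
  )
}

#' Build the three-ring LH2 emitter array
#'
#' Constructs the 27-emitter, 9-fold symmetric LH2 motif (two B850
#' components + one B800 ring) from a structural parameter set in the format
#' of \code{\link{lh2_params}}.
#'
#' @param params parameter set; defaults to the synthetic fixture.
#' @return An \code{emitter_array} with \code{n_cell = 3}; components are
#'   ordered (b850a, b850b, b800).
#' @export
lh2_geometry <- function(params = lh2_params()) {
  comp_names <- c("b850a", "b850b", "b800")
  if (!all(comp_names %in% names(params)))
    stop("params must contain components ", paste(comp_names, collapse = ", "))
  N <- as.integer(params$N)
  if (N != 9L) stop("the LH2 motif has 9-fold symmetry; got N = ", N)
  lam <- params$lambda_nm
  specs <- lapply(comp_names, function(nm) {
    p <- params[[nm]]
    ring_spec(N = N, R = p$R_nm / lam, z = p$z_nm / lam,
              delta = p$offset_rad, theta = p$theta_rad, phi = p$phi_rad,
              detuning = p$detuning_Gamma0, label = nm)
  })
  arr <- build_stack(specs)
  check_nfold_symmetry(arr)
  arr
}

#' Export an emitter array as a data frame
#'
#' @param array an \code{emitter_array}.
#' @return data.frame with columns x, y, z, px, py, pz, detuning, cell,
#'   component (lengths in lambda, detuning in Gamma0).
#' @export
as.data.frame.emitter_array <- function(x, ...) {
  data.frame(x = x$positions[, 1], y = x$positions[, 2], z = x$positions[, 3],
             px = x$dipoles[, 1], py = x$dipoles[, 2], pz = x$dipoles[, 3],
             detuning = x$detunings, cell = x$cell, component = x$component)
}
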