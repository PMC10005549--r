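# Effective non-Hermitian Hamiltonian of the single-excitation manifold and
# its diagonalization, dense and via the Bloch (angular momentum) reduction.

#' Effective non-Hermitian Hamiltonian
#'
#' Assembles \code{H = diag(detunings) + Omega - i Gamma / 2} over all
#' emitters [Gamma0]. Each eigenvalue of H is \code{Omega_m - i Gamma_m / 2}:
#' its real part is the collective frequency shift, minus twice its imaginary
#' part the collective decay rate. For real dipole orientations H is complex
#' symmetric.
#'
#' @param array an \code{emitter_array}.
#' @param k0 wavenumber.
#' @return complex matrix of class \code{effective_hamiltonian} with the
#'   source array attached as attribute \code{"array"}.
#' @export
effective_hamiltonian <- function(array, k0 = 2 * pi) {
  cm <- coupling_matrices(array, k0 = k0)
  H <- cm$omega - 1i * cm$gamma / 2
  diag(H) <- diag(H) + array$detunings
  structure(H, class = c("effective_hamiltonian", "matrix"),
            array = array, gamma = cm$gamma)
}

new_mode_spectrum <- function(modes, vectors, populations = NULL) {
  structure(list(modes = modes, vectors = vectors, populations = populations),
            class = "mode_spectrum")
}

#' @export
print.mode_spectrum <- function(x, ...) {
  cat(sprintf("<mode_spectrum> %d collective modes\n", nrow(x$modes)))
  print(utils::head(x$modes, 10))
  if (nrow(x$modes) > 10) cat("...\n")
  invisible(x)
}

#' Dense diagonalization of the effective Hamiltonian
#'
#' Right-eigendecomposition of H; the reference path against which the
#' symmetry-reduced (Bloch) spectrum is checked. Modes are sorted by decay
#' rate (ascending), then by frequency shift.
#'
#' @param H an \code{effective_hamiltonian} (or any complex square matrix).
#' @param ref_detuning reference transition frequency subtracted from the
#'   reported shifts [Gamma0].
#' @return A \code{mode_spectrum}: \code{$modes} is a data.frame with columns
#'   \code{m} (NA for the dense path), \code{branch}, \code{omega} (shift),
#'   \code{gamma} (decay rate); \code{$vectors} holds unit-norm right
#'   eigenvectors in matching column order.
#' @export
full_eigenmodes <- function(H, ref_detuning = 0) {
  if (!all(is.finite(Re(H)) & is.finite(Im(H)))) stop("H must be finite")
  gam <- attr(H, "gamma")
  e <- eigen(unclass(H), symmetric = FALSE)
  vec <- sweep(e$vectors, 2, sqrt(colSums(Mod(e$vectors)^2)), `/`)
  shift <- Re(e$values) - ref_detuning
  # rate via the PSD quadratic form when the dissipative matrix is known
  # (numerically robust for ultra-subradiant modes), else -2 Im(lambda)
  rate <- if (is.null(gam)) -2 * Im(e$values) else
    Re(diag(Conj(t(vec)) %*% gam %*% vec))
  ord <- order(rate, shift)
  vec <- vec[, ord, drop = FALSE]
  new_mode_spectrum(
    data.frame(m = NA_integer_, branch = seq_along(ord),
               omega = shift[ord], gamma = rate[ord]),
    vec)
}

#' Canonical angular-momentum set
#'
#' Integers in \code{(-N/2, N/2]}; for odd N this is
#' \code{0, +/-1, ..., +/-(N-1)/2}.
#'
#' @param N fold of the rotational symmetry.
#' @export
canonical_m <- function(N) seq.int(-floor((N - 1) / 2), floor(N / 2))

#' Bloch blocks of an N-fold symmetric array
#'
#' Uses the N-fold rotational symmetry to block-diagonalize H: couplings
#' depend only on the cell separation \code{ell = j - i (mod N)}, so for each
#' angular momentum m the dynamics reduce to the \code{n_cell x n_cell}
#' matrix
#' \deqn{\tilde G_m^{\alpha\beta} = \sum_{\ell=0}^{N-1}
#'   e^{i 2\pi m \ell / N} G_\ell^{\alpha\beta},}
#' where \eqn{G_\ell^{\alpha\beta}} couples component alpha of cell 0 to
#' component beta of cell ell (self term \code{detuning - i/2} on
#' \code{ell = 0, alpha = beta}). The union of the block eigenvalues over the
#' canonical m-set equals the dense spectrum of H.
#'
#' @param array an \code{emitter_array} passing
#'   \code{\link{check_nfold_symmetry}}.
#' @param k0 wavenumber.
#' @param tol maximum allowed deviation of H from circulant-block structure.
#' @return list of \code{bloch_block}s, one per canonical m, each with
#'   fields \code{m} and \code{gtilde}.
#' @export
bloch_blocks <- function(array, k0 = 2 * pi, tol = 1e-9) {
  check_nfold_symmetry(array)
  cm <- coupling_matrices(array, k0 = k0)
  H <- cm$omega - 1i * cm$gamma / 2
  diag(H) <- diag(H) + array$detunings
  N <- array$N
  nc <- array$n_cell
  idx <- matrix(NA_integer_, N, nc)  # idx[ell+1, alpha]
  for (k in seq_len(nrow(array$positions)))
    idx[array$cell[k] + 1L, array$component[k]] <- k
  # G_ell[alpha, beta, ell+1] from cell 0; verify independence of base cell
  G_ell <- array(NA_complex_, c(nc, nc, N))
  Gam_ell <- array(NA_real_, c(nc, nc, N))
  for (l in 0:(N - 1)) {
    G_ell[, , l + 1] <- H[idx[1, ], idx[(l %% N) + 1, ], drop = FALSE]
    Gam_ell[, , l + 1] <- cm$gamma[idx[1, ], idx[(l %% N) + 1, ],
                                   drop = FALSE]
  }
  worst <- 0
  worst_pair <- c(NA, NA)
  for (i in 1:(N - 1)) {
    for (l in 0:(N - 1)) {
      block <- H[idx[i + 1, ], idx[((i + l) %% N) + 1, ], drop = FALSE]
      dev <- max(Mod(block - G_ell[, , l + 1]))
      if (dev > worst) {
        worst <- dev
        worst_pair <- c(i, (i + l) %% N)
      }
    }
  }
  # tolerance is relative to the coupling scale: detunings/couplings of
  # order 1e6-1e7 Gamma0 (LH2) carry rounding of that order times eps
  scale <- max(1, max(Mod(G_ell)))
  if (worst > tol * scale)
    stop(sprintf(paste0("H is not circulant in the cell index (max deviation",
                        " %.3g between cells %d and %d); the array breaks ",
                        "the N-fold symmetry"),
                 worst, worst_pair[1], worst_pair[2]))
  lapply(canonical_m(N), function(m) {
    ph <- exp(2i * pi * m * (0:(N - 1)) / N)
    gt <- matrix(0i, nc, nc)
    gam <- matrix(0i, nc, nc)
    for (l in 0:(N - 1)) {
      gt <- gt + ph[l + 1] * G_ell[, , l + 1]
      gam <- gam + ph[l + 1] * Gam_ell[, , l + 1]
    }
    gam <- (gam + Conj(t(gam))) / 2  # Hermitian PSD compression of Gamma
    structure(list(m = m, gtilde = gt, gamma_tilde = gam, N = N),
              class = "bloch_block")
  })
}

# Eigen-decomposition of one Bloch block. Decay rates are evaluated as the
# quadratic form v' gamma_tilde v of the dissipative block with the computed
# right eigenvector: algebraically equal to -2 Im(lambda) (the coherent part
# of the block has a real expectation value), but numerically far more
# accurate for ultra-subradiant modes when the coherent couplings are many
# orders of magnitude larger than the rates (backward error of a general
# eigensolver scales with ||G||).
block_eigen <- function(block) {
  nc <- nrow(block$gtilde)
  if (nc == 1L) {
    val <- block$gtilde[1, 1]
    v <- matrix(1 + 0i, 1, 1)
    rate <- Re(block$gamma_tilde[1, 1])
    return(list(omega = Re(val), gamma = rate, vectors = v))
  }
  e <- eigen(block$gtilde, symmetric = FALSE)
  v <- sweep(e$vectors, 2, sqrt(colSums(Mod(e$vectors)^2)), `/`)
  rate <- Re(diag(Conj(t(v)) %*% block$gamma_tilde %*% v))
  list(omega = Re(e$values), gamma = rate, vectors = v)
}

#' Eigenmodes from Bloch blocks
#'
#' Diagonalizes each angular-momentum block; within each m, branches are
#' labeled 1..n_cell by increasing frequency shift (band index).
#' Per-component populations are the squared magnitudes of the unit-norm
#' right eigenvector and sum to 1.
#'
#' @param blocks list from \code{\link{bloch_blocks}}.
#' @param ref_detuning reference transition frequency [Gamma0].
#' @return A \code{mode_spectrum}; \code{$modes} has one row per (m, branch),
#'   \code{$populations} the per-component populations.
#' @export
bloch_eigenmodes <- function(blocks, ref_detuning = 0) {
  rows <- list()
  vecs <- list()
  for (b in blocks) {
    e <- block_eigen(b)
    ord <- order(e$omega)
    for (k in seq_along(ord)) {
      rows[[length(rows) + 1]] <-
        data.frame(m = b$m, branch = k,
                   omega = e$omega[ord[k]] - ref_detuning,
                   gamma = e$gamma[ord[k]])
      vecs[[length(vecs) + 1]] <- e$vectors[, ord[k]]
    }
  }
  modes <- do.call(rbind, rows)
  V <- do.call(cbind, vecs)
  pops <- t(Mod(V)^2)
  colnames(pops) <- paste0("pop_component_", seq_len(nrow(V)))
  new_mode_spectrum(modes, V, pops)
}

#' Symmetric / antisymmetric band splitting of two identical rings
#'
#' For two identical non-rotated rings the 2x2 Bloch block is complex
#' symmetric with equal diagonals, so its eigenvectors are the symmetric and
#' antisymmetric superpositions \eqn{(|m,1\rangle \pm |m,2\rangle)/\sqrt2}
#' with eigenvalues \eqn{\tilde G_m^{11} \pm \tilde G_m^{12}}. Writing
#' \code{Omega_inter = Re(g12)}, \code{Gamma_inter = -2 Im(g12)}, the two
#' branches are
#' \code{Omega(+/-) = Omega_m +/- Omega_inter},
#' \code{Gamma(+/-) = Gamma_m +/- Gamma_inter}.
#'
#' @param gm scalar single-ring block value \eqn{\tilde G_m^{11}}.
#' @param g12 scalar inter-ring block value \eqn{\tilde G_m^{12}}.
#' @param check_tol used when full 2x2 blocks are supplied instead of
#'   scalars, to verify equal diagonals / symmetric off-diagonals.
#' @return list with \code{omega_plus/minus}, \code{gamma_plus/minus},
#'   \code{omega_inter}, \code{gamma_inter}, and the two superposition
#'   states.
#' @export
symmetric_split <- function(gm, g12, check_tol = 1e-10) {
  if (is.matrix(gm)) {
    B <- gm
    if (max(Mod(B[1, 1] - B[2, 2]), Mod(B[1, 2] - B[2, 1])) > check_tol)
      stop("block is not that of two identical non-rotated rings")
    g12 <- B[1, 2]
    gm <- B[1, 1]
  }
  om <- Re(gm); gam <- -2 * Im(gm)
  oi <- Re(g12); gi <- -2 * Im(g12)
  list(omega_plus = om + oi, omega_minus = om - oi,
       gamma_plus = gam + gi, gamma_minus = gam - gi,
       omega_inter = oi, gamma_inter = gi,
       state_plus = c(1, 1) / sqrt(2), state_minus = c(1, -1) / sqrt(2))
}

#' Relative inter-ring phase of a rotated double-ring mode
#'
#' For equal-radius rings in the small-ring regime the off-diagonal Bloch
#' couplings satisfy \eqn{\tilde G_m^{21} = (\tilde G_m^{12})^*} and the
#' eigenmodes take the form \eqn{(|m,1\rangle \pm e^{i\eta}|m,2\rangle)/
#' \sqrt 2} with
#' \eqn{\eta = \mathrm{atan2}(\mathrm{Im}\,\tilde G_m^{12},
#' \mathrm{Re}\,\tilde G_m^{12})}.
#'
#' @param g12 complex scalar \eqn{\tilde G_m^{12}}.
#' @return eta in (-pi, pi].
#' @export
relative_phase_eta <- function(g12) {
  if (Mod(g12) == 0) stop("inter-ring coupling vanishes; phase undefined")
  atan2(Im(g12), Re(g12))
}

#' Small-ring (Dicke limit) effective dipole and bright-mode rate
#'
#' When all inter-emitter separations are far below the wavelength, Bloch
#' mode m of a single ring radiates as one effective dipole
#' \deqn{p_{m,\mathrm{eff}} = N^{-1/2} \sum_\ell e^{i 2\pi m \ell/N}
#'   \hat p_\ell, \qquad \Gamma_m = |p_{m,\mathrm{eff}}|^2 \Gamma_0.}
#' For transverse polarization only m = 0 is bright
#' (\eqn{\Gamma_0^{coll} = N \cos^2\theta\,\Gamma_0}); for tangential or
#' radial polarization only m = +/-1 (\eqn{N \sin^2\theta\,\Gamma_0/2}).
#'
#' @param ring a single-component \code{emitter_array} (or a
#'   \code{ring_spec}).
#' @param m angular momentum.
#' @return list with complex 3-vector \code{p_eff} and rate \code{gamma}
#'   [Gamma0].
#' @export
effective_dipole_dicke <- function(ring, m) {
  if (inherits(ring, "ring_spec")) ring <- build_ring(ring)
  if (ring$n_cell != 1L) stop("expected a single-ring array")
  N <- ring$N
  ph <- exp(2i * pi * m * (0:(N - 1)) / N)
  ord <- order(ring$cell)
  p_eff <- drop(ph %*% ring$dipoles[ord, , drop = FALSE]) / sqrt(N)
  list(p_eff = p_eff, gamma = sum(Mod(p_eff)^2))
}

#' Nearest-neighbour cosine approximation to the single-ring band
#'
#' In the small-ring regime the coherent shifts are dominated by
#' nearest-neighbour couplings, giving
#' \eqn{\Omega_m \approx 2 \Omega_d \cos(2\pi m/N)} with \eqn{\Omega_d} the
#' first-neighbour coherent coupling (computed numerically from the Green's
#' tensor).
#'
#' @param ring a single-component \code{emitter_array} or \code{ring_spec}.
#' @param m angular momentum (vectorized).
#' @return approximate shift(s) [Gamma0].
#' @export
cosine_band <- function(ring, m) {
  if (inherits(ring, "ring_spec")) ring <- build_ring(ring)
  if (ring$n_cell != 1L) stop("expected a single-ring array")
  ord <- order(ring$cell)
  cp <- coupling_pair(ring$positions[ord[1], ], ring$dipoles[ord[1], ],
                      ring$positions[ord[2], ], ring$dipoles[ord[2], ])
  2 * cp$omega * cos(2 * pi * m / ring$N)
}

#' Light-line angular momentum of a ring
#'
#' On a large dense ring, modes with \code{|m|} above \code{m0 = N d /
#' lambda} have quasi-momentum beyond the light line and are guided
#' (evanescent, subradiant); below it they radiate. Guided modes require
#' \code{d < lambda/2}.
#'
#' @param ring a \code{ring_spec} or single-ring \code{emitter_array}.
#' @return real-valued m0.
#' @export
light_line_m <- function(ring) {
  if (inherits(ring, "emitter_array")) {
    if (ring$n_cell != 1L) stop("expected a single ring")
    d <- min_pair_distance(ring)
    return(ring$N * d)
  }
  ring$N * lattice_constant(ring)
}

#' Bloch-wave decomposition of a dense eigenmode (double ring)
#'
#' Projects a full-array eigenvector of a two-component (double-ring) array
#' onto the orthonormal basis of symmetric/antisymmetric Bloch waves
#' \eqn{(|m,1\rangle \pm |m,2\rangle)/\sqrt2}; overlaps of m and -m are
#' combined under |m|.
#'
#' @param eigvec complex amplitude vector over all 2N emitters (ordered as
#'   the array).
#' @param array the two-component \code{emitter_array}.
#' @return data.frame with columns \code{abs_m}, \code{parity}
#'   ("sym"/"antisym"), \code{overlap}; overlaps sum to 1 for a unit-norm
#'   input.
#' @export
mode_overlap <- function(eigvec, array) {
  if (array$n_cell != 2L) stop("mode_overlap expects a two-component array")
  n <- n_emitters(array)
  if (length(eigvec) != n) stop("eigenvector length does not match array")
  N <- array$N
  res <- list()
  for (m in canonical_m(N)) {
    b <- complex(length.out = n)
    ph <- exp(2i * pi * m * array$cell / N) / sqrt(N)
    b1 <- ifelse(array$component == 1L, ph, 0)
    b2 <- ifelse(array$component == 2L, ph, 0)
    for (parity in c(1, -1)) {
      bv <- (b1 + parity * b2) / sqrt(2)
      ov <- Mod(sum(Conj(bv) * eigvec))^2
      res[[length(res) + 1]] <- data.frame(
        abs_m = abs(m), parity = if (parity > 0) "sym" else "antisym",
        overlap = ov)
    }
  }
  agg <- do.call(rbind, res)
  stats::aggregate(overlap ~ abs_m + parity, data = agg, FUN = sum)
}

#' Single-excitation amplitude propagation
#'
#' Evolves the single-excitation amplitudes under \code{dc/dt = -i H c}
#' via the eigendecomposition of H, and reports the survival probability
#' \code{||c(t)||^2} (non-increasing whenever the dissipative matrix is
#' positive semidefinite).
#'
#' @param H effective Hamiltonian (complex matrix).
#' @param c0 initial amplitude vector (normalized).
#' @param times numeric vector of times [1/Gamma0].
#' @return list with \code{times}, complex matrix \code{amplitudes}
#'   (length(times) x n) and numeric \code{survival}.
#' @export
propagate_amplitudes <- function(H, c0, times) {
  H <- unclass(H)
  if (!all(is.finite(Re(H)) & is.finite(Im(H)))) stop("H must be finite")
  e <- eigen(H, symmetric = FALSE)
  a0 <- solve(e$vectors, c0)
  amps <- vapply(times, function(t)
    drop(e$vectors %*% (exp(-1i * e$values * t) * a0)),
    complex(length(c0)))
  amps <- if (is.null(dim(amps))) matrix(amps, ncol = 1) else t(amps)
  list(times = times, amplitudes = amps,
       survival = rowSums(Mod(amps)^2))
}
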