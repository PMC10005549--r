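# Scripted analyses: subradiance scaling with emitter number, the
# (d, z) subradiance landscape of a double ring, rotation-angle sweeps with
# avoided-crossing detection, and the LH2 three-band / size-sweep analyses.

polarization_angles <- function(polarization = c("transverse", "tangential",
                                                 "radial")) {
  switch(match.arg(polarization),
         transverse = c(theta = 0, phi = 0),
         tangential = c(theta = pi / 2, phi = 0),
         radial = c(theta = pi / 2, phi = pi / 2))
}

min_gamma_of <- function(spectrum) {
  i <- which.min(spectrum$modes$gamma)
  spectrum$modes[i, , drop = FALSE]
}

ring_spectrum <- function(N, d, z = 0, delta = 0, polarization = "transverse",
                          double = FALSE) {
  ang <- polarization_angles(polarization)
  s1 <- ring_spec(N = N, d = d, z = 0, theta = ang["theta"], phi = ang["phi"])
  specs <- if (double) {
    s2 <- ring_spec(N = N, d = d, z = z, delta = delta,
                    theta = ang["theta"], phi = ang["phi"])
    list(s1, s2)
  } else list(s1)
  bloch_eigenmodes(bloch_blocks(build_stack(specs)))
}

#' Subradiance scaling with emitter number
#'
#' For a fixed lattice constant d (ring radius grows with N), computes the
#' most subradiant collective decay rate versus N for (i) a double ring of N
#' emitters per ring at vertical separation z, (ii) a single ring of N
#' emitters, and (iii) a single ring of 2N emitters (same density), together
#' with log-linear fits quantifying the exponential suppression.
#'
#' @param N_list integer vector of per-ring emitter numbers (each >= 3).
#' @param d_over_lambda lattice constant [lambda].
#' @param z_over_lambda vertical ring separation [lambda].
#' @param polarization "transverse", "tangential" or "radial".
#' @return list of class \code{sweep_result}: \code{$data} with columns N and
#'   the three min decay rates, \code{$fits} with slope, intercept and R^2 of
#'   \code{log(min gamma) ~ N} per configuration.
#' @export
subradiance_scaling <- function(N_list, d_over_lambda = 1 / 3,
                                z_over_lambda = 0.009,
                                polarization = "transverse") {
  N_list <- as.integer(N_list)
  if (any(N_list < 3L)) stop("N must be >= 3")
  if (any(diff(N_list) <= 0)) stop("N_list must be strictly increasing")
  rows <- lapply(N_list, function(N) {
    g_double <- min_gamma_of(ring_spectrum(N, d_over_lambda, z_over_lambda,
                                           polarization = polarization,
                                           double = TRUE))$gamma
    g_single <- min_gamma_of(ring_spectrum(N, d_over_lambda,
                                           polarization = polarization))$gamma
    g_single2N <- min_gamma_of(ring_spectrum(2L * N, d_over_lambda,
                                             polarization = polarization))$gamma
    data.frame(N = N, gamma_double = g_double, gamma_single = g_single,
               gamma_single_2N = g_single2N)
  })
  dat <- do.call(rbind, rows)
  fit_one <- function(y) {
    f <- stats::lm(log(y) ~ dat$N)
    c(slope = unname(stats::coef(f)[2]),
      intercept = unname(stats::coef(f)[1]),
      r_squared = summary(f)$r.squared)
  }
  fits <- rbind(double = fit_one(dat$gamma_double),
                single = fit_one(dat$gamma_single),
                single_2N = fit_one(dat$gamma_single_2N))
  structure(list(data = dat, fits = as.data.frame(fits)),
            class = "sweep_result")
}

#' Subradiance landscape of a double ring over (d, z)
#'
#' Most subradiant decay rate of two identical non-rotated rings of N
#' emitters, as a function of lattice constant and inter-ring distance,
#' together with the (|m|, parity) label of the minimizing mode.
#'
#' @param d_grid,z_grid strictly increasing grids [lambda].
#' @param N emitters per ring.
#' @param polarization dipole orientation.
#' @return \code{sweep_result} with \code{$data}: one row per grid point with
#'   \code{min_gamma}, \code{abs_m}, \code{parity}.
#' @export
subradiance_landscape <- function(d_grid, z_grid, N = 9L,
                                  polarization = "transverse") {
  if (any(diff(d_grid) <= 0) || any(diff(z_grid) <= 0))
    stop("grids must be strictly increasing")
  ang <- polarization_angles(polarization)
  rows <- list()
  for (d in d_grid) {
    for (z in z_grid) {
      blocks <- bloch_blocks(build_stack(list(
        ring_spec(N = N, d = d, z = 0, theta = ang["theta"], phi = ang["phi"]),
        ring_spec(N = N, d = d, z = z, theta = ang["theta"],
                  phi = ang["phi"]))))
      best <- NULL
      for (b in blocks) {
        e <- block_eigen(b)
        for (k in 1:2) {
          gam <- e$gamma[k]
          if (is.null(best) || gam < best$gam) {
            v <- e$vectors[, k]
            parity <- if (Re(v[1] * Conj(v[2])) >= 0) "sym" else "antisym"
            best <- list(gam = gam, m = b$m, parity = parity)
          }
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        d_over_lambda = d, z_over_lambda = z, min_gamma = best$gam,
        abs_m = abs(best$m), parity = best$parity)
    }
  }
  structure(list(data = do.call(rbind, rows)), class = "sweep_result")
}

#' Rotation-angle sweep of a two-ring Bloch block
#'
#' For a two-ring stack, sweeps the rigid rotation delta of the second ring
#' and tracks the two eigenvalue branches of the 2x2 angular-momentum-m Bloch
#' block. Branches are connected by continuity (maximal eigenvector overlap
#' between adjacent grid points); the relative inter-ring phase eta is
#' reported where the off-diagonal coupling is nonzero.
#'
#' @param spec1,spec2 \code{ring_spec}s of the two rings (delta of
#'   \code{spec2} is overridden by the sweep).
#' @param m angular momentum in the canonical set.
#' @param delta_grid strictly increasing rotation angles [rad].
#' @return \code{sweep_result} with \code{$data}: columns \code{delta},
#'   \code{omega_1, gamma_1, omega_2, gamma_2} (continuity-tracked branches),
#'   \code{gap} (|Re difference|), \code{eta}, \code{degenerate} flag.
#' @export
delta_sweep <- function(spec1, spec2, m, delta_grid) {
  if (any(diff(delta_grid) <= 0)) stop("delta_grid must be strictly increasing")
  if (!(m %in% canonical_m(spec1$N))) stop("m outside the canonical set")
  prev_vec <- NULL
  rows <- list()
  for (delta in delta_grid) {
    s2 <- spec2
    s2$delta <- delta
    blocks <- bloch_blocks(build_stack(list(spec1, s2)))
    b <- blocks[[match(m, vapply(blocks, `[[`, 1, "m"))]]
    e <- block_eigen(b)
    v <- e$vectors
    ord <- 1:2
    degenerate <- FALSE
    if (!is.null(prev_vec)) {
      # continuity: assign branches to maximize overlap with previous step
      ov <- Mod(t(Conj(prev_vec)) %*% v)^2
      if (ov[1, 1] + ov[2, 2] < ov[1, 2] + ov[2, 1]) ord <- 2:1
      if (abs(e$omega[1] - e$omega[2]) + abs(e$gamma[1] - e$gamma[2]) < 1e-12)
        degenerate <- TRUE
    } else {
      ord <- order(e$omega)
    }
    prev_vec <- v[, ord, drop = FALSE]
    eta <- if (Mod(b$gtilde[1, 2]) > 0)
      relative_phase_eta(b$gtilde[1, 2]) else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      delta = delta,
      omega_1 = e$omega[ord[1]], gamma_1 = e$gamma[ord[1]],
      omega_2 = e$omega[ord[2]], gamma_2 = e$gamma[ord[2]],
      gap = abs(e$omega[1] - e$omega[2]),
      eta = eta, degenerate = degenerate)
  }
  structure(list(data = do.call(rbind, rows), m = m,
                 spec1 = spec1, spec2 = spec2),
            class = "sweep_result")
}

#' Locate the avoided crossing of a rotation sweep
#'
#' Finds the interior minimum of the real-part gap between the two tracked
#' branches and refines it by a local three-point quadratic interpolation.
#'
#' @param sweep result of \code{\link{delta_sweep}}.
#' @return list with \code{delta_c} (NA if the gap is monotone over the
#'   grid), \code{gap_min}, \code{crossing} logical, and the relative phase
#'   eta just before and after \code{delta_c}.
#' @export
find_avoided_crossing <- function(sweep) {
  d <- sweep$data
  i <- which.min(d$gap)
  if (i == 1L || i == nrow(d))
    return(list(delta_c = NA_real_, gap_min = d$gap[i], crossing = FALSE,
                eta_before = NA_real_, eta_after = NA_real_))
  # quadratic through the bracketing triple
  xs <- d$delta[(i - 1):(i + 1)]
  ys <- d$gap[(i - 1):(i + 1)]
  co <- stats::coef(stats::lm(ys ~ xs + I(xs^2)))
  delta_c <- if (is.na(co[3]) || co[3] <= 0) d$delta[i] else
    unname(-co[2] / (2 * co[3]))
  if (delta_c < xs[1] || delta_c > xs[3]) delta_c <- d$delta[i]
  list(delta_c = delta_c, gap_min = d$gap[i], crossing = TRUE,
       eta_before = d$eta[i - 1], eta_after = d$eta[i + 1])
}

#' Rotation angle of maximal subradiance
#'
#' Sweeps the relative rotation delta of a two-ring stack and records the
#' most subradiant decay rate over all angular momenta at each angle. The
#' reported optimum is the deepest INTERIOR local minimum of the profile:
#' the sweep boundaries delta -> 0 (and delta -> 2*pi/N for identical
#' rings) continuously approach the aligned, unrotated configuration,
#' whose ultra-dark antisymmetric modes are a separate regime, not a
#' property of the rotation. For interleaved rings the minimum sits at
#' delta = pi/N, where the sites of one ring fall midway between those of
#' the other; the inter-ring phase there satisfies |eta| ~ pi/2.
#'
#' @param spec1,spec2 \code{ring_spec}s (delta of \code{spec2} is swept).
#' @param delta_grid strictly increasing rotation angles.
#' @return \code{sweep_result} with \code{$data} (delta, min_gamma, m of the
#'   minimizing mode, eta of its block) and \code{$optimum}: list with
#'   \code{delta_min}, \code{gamma_min}, \code{m}, \code{eta}.
#' @export
delta_subradiance_minimum <- function(spec1, spec2,
                                      delta_grid = seq(1e-3, 2 * pi /
                                                         spec1$N - 1e-3,
                                                       length.out = 121)) {
  if (any(diff(delta_grid) <= 0)) stop("delta_grid must be strictly increasing")
  rows <- list()
  for (delta in delta_grid) {
    s2 <- spec2
    s2$delta <- delta
    blocks <- bloch_blocks(build_stack(list(spec1, s2)))
    best <- NULL
    for (b in blocks) {
      e <- block_eigen(b)
      k <- which.min(e$gamma)
      if (is.null(best) || e$gamma[k] < best$gamma)
        best <- list(gamma = e$gamma[k], m = b$m,
                     eta = if (Mod(b$gtilde[1, 2]) > 0)
                       relative_phase_eta(b$gtilde[1, 2]) else NA_real_)
    }
    rows[[length(rows) + 1]] <- data.frame(
      delta = delta, min_gamma = best$gamma, m = best$m, eta = best$eta)
  }
  dat <- do.call(rbind, rows)
  g <- dat$min_gamma
  n <- length(g)
  cand <- which(g[2:(n - 1)] <= g[1:(n - 2)] & g[2:(n - 1)] <= g[3:n]) + 1L
  # topographic prominence: both flanks must rise by >= `prominence` before
  # any lower value (or the boundary) occurs; filters out shallow dips at
  # the level of the numerical noise floor of ultra-subradiant rates
  prominence <- 10
  side_ok <- function(i, step) {
    hi <- g[i]
    j <- i + step
    while (j >= 1 && j <= n && g[j] >= g[i]) {
      hi <- max(hi, g[j])
      j <- j + step
    }
    hi / g[i] >= prominence
  }
  cand <- cand[vapply(cand, function(i) side_ok(i, -1L) && side_ok(i, 1L),
                      TRUE)]
  opt <- if (length(cand) == 0) {
    list(delta_min = NA_real_, gamma_min = NA_real_, m = NA_integer_,
         eta = NA_real_)
  } else {
    i <- cand[which.min(g[cand])]
    list(delta_min = dat$delta[i], gamma_min = g[i], m = dat$m[i],
         eta = dat$eta[i])
  }
  structure(list(data = dat, optimum = opt), class = "sweep_result")
}

lh2_band_table <- function(array, ref_detuning = 0) {
  sp <- bloch_eigenmodes(bloch_blocks(array), ref_detuning = ref_detuning)
  cbind(sp$modes, as.data.frame(sp$populations))
}

#' Three-band structure of the LH2 motif
#'
#' Diagonalizes the 27-emitter LH2 array per angular momentum m, yielding
#' three bands (branch index = energy order). Also returns the uncoupled
#' reference, in which each of the three component rings is diagonalized in
#' isolation (inter-component couplings absent), with one-hot populations.
#'
#' @param params LH2 structural parameter set (see \code{\link{lh2_params}}).
#' @param alpha overall size factor applied to the geometry.
#' @param ref_detuning reference transition frequency [Gamma0].
#' @return \code{sweep_result} with \code{$coupled} and \code{$uncoupled}
#'   band tables (columns m, branch, omega, gamma, pop_component_1..3).
#' @export
lh2_bands <- function(params = lh2_params(), alpha = 1, ref_detuning = 0) {
  arr <- scale_geometry(lh2_geometry(params), alpha)
  coupled <- lh2_band_table(arr, ref_detuning)
  # uncoupled reference: each component ring alone
  comp_names <- c("b850a", "b850b", "b800")
  unc_rows <- list()
  for (k in seq_along(comp_names)) {
    p <- params[[comp_names[k]]]
    spec <- ring_spec(N = params$N, R = p$R_nm / params$lambda_nm * alpha,
                      z = p$z_nm / params$lambda_nm * alpha,
                      delta = p$offset_rad, theta = p$theta_rad,
                      phi = p$phi_rad, detuning = p$detuning_Gamma0)
    sp <- bloch_eigenmodes(bloch_blocks(build_ring(spec)),
                           ref_detuning = ref_detuning)
    pops <- matrix(0, nrow(sp$modes), 3)
    pops[, k] <- 1
    colnames(pops) <- paste0("pop_component_", 1:3)
    unc_rows[[k]] <- cbind(sp$modes, component = k, as.data.frame(pops))
  }
  structure(list(coupled = coupled, uncoupled = do.call(rbind, unc_rows),
                 alpha = alpha),
            class = "sweep_result")
}

#' Size sweep of the LH2 motif
#'
#' Rescales the whole LH2 geometry by a factor alpha around its nominal size
#' and follows, for each requested angular momentum, the highest (third)
#' band's energy and ring populations. Locates the crossing scale alpha_c at
#' which the third band's occupation swaps between the B850 pair and the
#' B800 ring (populations equal, linear interpolation between bracketing
#' grid points).
#'
#' @param params LH2 structural parameter set.
#' @param alpha_grid strictly increasing size factors (around 1).
#' @param m_list angular momenta to follow.
#' @return \code{sweep_result} with \code{$data} (per alpha and m: third-band
#'   omega, B850-summed and B800 populations) and \code{$alpha_c} per m (NA
#'   if no crossing in range).
#' @export
size_sweep <- function(params = lh2_params(),
                       alpha_grid = seq(0.6, 1.2, 0.01),
                       m_list = c(1, 4)) {
  if (any(diff(alpha_grid) <= 0))
    stop("alpha_grid must be strictly increasing")
  rows <- list()
  for (alpha in alpha_grid) {
    bands <- lh2_bands(params, alpha = alpha)$coupled
    for (m in m_list) {
      b3 <- bands[bands$m == m & bands$branch == 3, ]
      rows[[length(rows) + 1]] <- data.frame(
        alpha = alpha, m = m, omega_3 = b3$omega, gamma_3 = b3$gamma,
        pop_b850 = b3$pop_component_1 + b3$pop_component_2,
        pop_b800 = b3$pop_component_3)
    }
  }
  dat <- do.call(rbind, rows)
  alpha_c <- vapply(m_list, function(m) {
    d <- dat[dat$m == m, ]
    h <- d$pop_b800 - d$pop_b850
    s <- which(h[-1] * h[-length(h)] < 0)
    if (length(s) == 0) return(NA_real_)
    i <- s[1]
    d$alpha[i] + (0 - h[i]) * (d$alpha[i + 1] - d$alpha[i]) /
      (h[i + 1] - h[i])
  }, 1.0)
  names(alpha_c) <- paste0("m", m_list)
  structure(list(data = dat, alpha_c = alpha_c), class = "sweep_result")
}
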