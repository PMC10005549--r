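test_that("dense eigenmodes reproduce closed two-level results", {
  # single emitter: one mode at Omega = 0, Gamma = Gamma0
  one <- build_ring(ring_spec(N = 2, R = 0.2))
  one$positions <- one$positions[1, , drop = FALSE]
  one$dipoles <- one$dipoles[1, , drop = FALSE]
  one$detunings <- 0; one$cell <- 0L; one$component <- 1L; one$N <- 1L
  sp1 <- full_eigenmodes(effective_hamiltonian(one))
  expect_equal(sp1$modes$omega, 0)
  expect_equal(sp1$modes$gamma, 1)
  # two parallel transverse dipoles: rates Gamma0 +/- Gamma12,
  # shifts +/- Omega12 (2x2 analytic diagonalization)
  d <- 0.23
  cp <- coupling_pair(c(0, 0, 0), c(0, 0, 1), c(d, 0, 0), c(0, 0, 1))
  pair <- build_ring(ring_spec(N = 2, d = d, theta = 0))
  sp2 <- full_eigenmodes(effective_hamiltonian(pair))
  expect_equal(sort(sp2$modes$gamma), sort(c(1 + cp$gamma, 1 - cp$gamma)),
               tolerance = 1e-12)
  expect_equal(sort(sp2$modes$omega), sort(c(cp$omega, -cp$omega)),
               tolerance = 1e-12)
  # purely coherent H (no dissipative part attached): all rates zero
  Hre <- matrix(c(0, 0.5, 0.5, 0), 2, 2) + 0i
  spc <- full_eigenmodes(Hre)
  expect_equal(spc$modes$gamma, c(0, 0))
})

test_that("Bloch reduction equals dense diagonalization on symmetric arrays", {
  # N=2 single ring: blocks are the 2-point DFT G0 +/- G1
  two <- build_ring(ring_spec(N = 2, R = 0.2, theta = 0.7, phi = 0.3))
  H <- unclass(effective_hamiltonian(two))
  bl <- bloch_blocks(two)
  vals <- sapply(bl, function(b) b$gtilde[1, 1])
  expect_equal(sort(Re(vals)), sort(Re(c(H[1, 1] + H[1, 2],
                                         H[1, 1] - H[1, 2]))))
  # property: multiset equivalence over a battery of geometries
  set.seed(99)
  geoms <- list(
    build_ring(ring_spec(N = 3, R = 0.11, theta = 1.0, phi = 0.4)),
    build_ring(ring_spec(N = 9, d = 0.05, theta = pi / 2)),
    build_ring(ring_spec(N = 20, d = 0.05)),
    build_stack(list(ring_spec(N = 9, R = 0.05),
                     ring_spec(N = 9, R = 0.05, z = 0.025))),
    build_stack(list(ring_spec(N = 9, R = 0.05, theta = pi / 2),
                     ring_spec(N = 9, R = 0.05, z = 0.005, delta = 0.1,
                               theta = pi / 2))),
    build_stack(list(ring_spec(N = 9, R = 0.05, theta = pi / 2),
                     ring_spec(N = 9, R = 0.045, z = 0, delta = pi / 9,
                               theta = pi / 2))),
    lh2_geometry())
  for (arr in geoms) {
    dense <- full_eigenmodes(effective_hamiltonian(arr))
    bloch <- bloch_eigenmodes(bloch_blocks(arr))
    scale <- max(1, max(abs(dense$modes$omega)))
    expect_same_spectrum(dense$modes, bloch$modes, tol = 1e-9 * scale)
    # trace conservation
    expect_equal(sum(bloch$modes$gamma), n_emitters(arr),
                 tolerance = 1e-9)
    expect_gt(min(bloch$modes$gamma), -1e-9)
    # populations sum to one
    expect_equal(unname(rowSums(bloch$populations)),
                 rep(1, nrow(bloch$modes)))
  }
})

test_that("spectra are invariant under rigid rotation about z", {
  a <- 0.8347  # arbitrary global rotation
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  arr <- build_stack(list(ring_spec(N = 7, R = 0.2, theta = 0.5, phi = 1.1),
                          ring_spec(N = 7, R = 0.31, z = 0.15, delta = 0.2,
                                    theta = 1.2)))
  rot <- arr
  rot$positions <- arr$positions %*% t(Rz)
  rot$dipoles <- arr$dipoles %*% t(Rz)
  sp <- bloch_eigenmodes(bloch_blocks(arr))
  spr <- bloch_eigenmodes(bloch_blocks(rot))
  expect_same_spectrum(sp$modes, spr$modes, tol = 1e-9)
})

test_that("bloch_blocks rejects arrays that break the symmetry", {
  arr <- build_ring(ring_spec(N = 6, R = 0.3))
  arr$detunings[2] <- 0.5  # per-emitter detuning breaks the circulant form
  expect_error(bloch_blocks(arr), "circulant|symmetry")
})

test_that("canonical m-set covers (-N/2, N/2]", {
  expect_equal(canonical_m(9), -4:4)
  expect_equal(canonical_m(20), -9:10)
  expect_equal(sort(unique((canonical_m(12) %% 12))), 0:11)
})

test_that("small-ring closed forms: effective dipole and bright rates", {
  # transverse: only m = 0 bright with |p_eff|^2 = N
  ring <- ring_spec(N = 12, R = 0.02, theta = 0)
  ed <- effective_dipole_dicke(ring, 0)
  expect_equal(ed$gamma, 12)
  expect_equal(Mod(ed$p_eff), c(0, 0, sqrt(12)))
  for (m in c(1, -1, 3, 6))
    expect_lt(effective_dipole_dicke(ring, m)$gamma, 1e-20)
  # tangential: only m = +/-1 bright with N/2
  tang <- ring_spec(N = 12, R = 0.02, theta = pi / 2)
  expect_equal(effective_dipole_dicke(tang, 1)$gamma, 6)
  expect_equal(effective_dipole_dicke(tang, -1)$gamma, 6)
  expect_lt(effective_dipole_dicke(tang, 0)$gamma, 1e-20)
  # mixed polarization: N cos^2(theta) at m=0, (N/2) sin^2(theta) at m=1
  mix <- ring_spec(N = 12, R = 0.02, theta = 0.6, phi = 0.3)
  expect_equal(effective_dipole_dicke(mix, 0)$gamma, 12 * cos(0.6)^2,
               tolerance = 1e-12)
  expect_equal(effective_dipole_dicke(mix, 1)$gamma, 6 * sin(0.6)^2,
               tolerance = 1e-12)
})

test_that("exact bright-mode rates converge to the closed forms as R -> 0", {
  N <- 8; theta <- 0.6
  err <- vapply(c(0.05, 0.02, 0.008), function(R) {
    sp <- bloch_eigenmodes(bloch_blocks(build_ring(
      ring_spec(N = N, R = R, theta = theta))))
    g0 <- sp$modes$gamma[sp$modes$m == 0]
    g1 <- sp$modes$gamma[sp$modes$m == 1]
    max(abs(g0 - N * cos(theta)^2) / (N * cos(theta)^2),
        abs(g1 - N / 2 * sin(theta)^2) / (N / 2 * sin(theta)^2))
  }, 1.0)
  expect_true(all(diff(err) < 0))  # monotone convergence
  expect_lt(err[3], 0.01)
})

test_that("cosine band approximates the small-ring dispersion", {
  ring <- ring_spec(N = 20, d = 0.05, theta = pi / 2)
  ms <- canonical_m(20)
  approx <- cosine_band(ring, ms)
  expect_equal(approx, rev(cosine_band(ring, rev(-ms))))  # even in m
  expect_equal(sum(approx), 0, tolerance = 1e-10)
  exact <- bloch_eigenmodes(bloch_blocks(build_ring(ring)))$modes
  # band edges (m = 0 and m = N/2): nearest-neighbour truncation is good to
  # ~20 percent at this ring size (beyond-neighbour couplings are not
  # negligible at d = 0.05 lambda)
  for (m in c(0, 10)) {
    ex <- exact$omega[exact$m == m]
    expect_lt(abs(cosine_band(ring, m) - ex) / abs(ex), 0.25)
  }
})

test_that("light line separates radiant from guided modes", {
  expect_equal(light_line_m(ring_spec(N = 100, d = 1 / 3)), 100 / 3)
  expect_equal(light_line_m(ring_spec(N = 20, d = 0.05)), 1)
  # quasi-chain: brightest radial mode close to (just inside) the light line
  sp <- bloch_eigenmodes(bloch_blocks(build_ring(
    ring_spec(N = 100, d = 1 / 3, theta = pi / 2, phi = pi / 2))))
  m_bright <- abs(sp$modes$m[which.max(sp$modes$gamma)])
  m0 <- 100 / 3
  expect_true(m_bright >= m0 - 4 && m_bright <= m0)
  # guided (sub-single-emitter) modes exist only for d < lambda/2:
  # all |m| > m0 modes are subradiant here
  guided <- sp$modes$gamma[abs(sp$modes$m) > m0]
  expect_true(all(guided < 1))
  # a sparse ring (d > lambda/2) supports no strongly guided branch
  sp2 <- bloch_eigenmodes(bloch_blocks(build_ring(
    ring_spec(N = 30, d = 0.6, theta = pi / 2, phi = pi / 2))))
  expect_gt(min(sp2$modes$gamma), 1e-3)
})

test_that("symmetric_split matches block eigenvalues for identical rings", {
  st <- build_stack(list(ring_spec(N = 9, R = 0.05, theta = pi / 2),
                         ring_spec(N = 9, R = 0.05, z = 0.025,
                                   theta = pi / 2)))
  for (b in bloch_blocks(st)) {
    ss <- symmetric_split(b$gtilde)
    ev <- eigen(b$gtilde, only.values = TRUE)$values
    expect_equal(sort(Re(ev)), sort(c(ss$omega_plus, ss$omega_minus)),
                 tolerance = 1e-10)
    expect_equal(sort(-2 * Im(ev)), sort(c(ss$gamma_plus, ss$gamma_minus)),
                 tolerance = 1e-10)
    # the +/- rates bracket twice the single-ring rate
    expect_equal(ss$gamma_plus + ss$gamma_minus,
                 -4 * Im(b$gtilde[1, 1]), tolerance = 1e-12)
  }
  # refuses blocks of non-identical rings
  st2 <- build_stack(list(ring_spec(N = 9, R = 0.05),
                          ring_spec(N = 9, R = 0.04, z = 0.02)))
  expect_error(symmetric_split(bloch_blocks(st2)[[1]]$gtilde),
               "identical")
})

test_that("relative inter-ring phase follows the off-diagonal coupling", {
  # aligned identical rings deep in the small-ring regime: the coherent
  # coupling dominates the off-diagonal, so eta ~ 0 or pi (up to the small
  # dissipative imaginary part, Gamma_inter/2|Omega_inter| ~ 1e-5 here)
  st <- build_stack(list(ring_spec(N = 9, R = 0.05),
                         ring_spec(N = 9, R = 0.05, z = 0.005)))
  for (b in bloch_blocks(st)) {
    eta <- relative_phase_eta(b$gtilde[1, 2])
    expect_true(abs(eta) < 1e-4 || abs(abs(eta) - pi) < 1e-4)
  }
  expect_error(relative_phase_eta(0 + 0i), "undefined|vanishes")
})

test_that("mode_overlap resolves dense eigenmodes into Bloch waves", {
  st <- build_stack(list(ring_spec(N = 9, R = 0.05),
                         ring_spec(N = 9, R = 0.05, z = 0.025)))
  dn <- full_eigenmodes(effective_hamiltonian(st))
  ov <- mode_overlap(dn$vectors[, 1], st)
  expect_equal(sum(ov$overlap), 1, tolerance = 1e-9)
  # most subradiant mode of a small double ring: pure |m| = 4 antisymmetric
  top <- ov[which.max(ov$overlap), ]
  expect_equal(top$abs_m, 4)
  expect_equal(top$parity, "antisym")
  expect_gt(top$overlap, 1 - 1e-6)
  expect_error(mode_overlap(dn$vectors[1:5, 1], st), "length")
})

test_that("amplitude propagation follows the non-Hermitian evolution", {
  # single emitter: survival e^(-Gamma0 t)
  H1 <- matrix(-0.5i, 1, 1)
  pr <- propagate_amplitudes(H1, 1 + 0i, c(0, 0.5, 1, 2))
  expect_equal(pr$survival, exp(-c(0, 0.5, 1, 2)), tolerance = 1e-12)
  # coherent-only H conserves the norm; PSD dissipation never increases it
  arr <- build_ring(ring_spec(N = 5, R = 0.1))
  cm <- coupling_matrices(arr)
  c0 <- rep(1 / sqrt(5), 5) + 0i
  ts <- seq(0, 3, 0.25)
  herm <- propagate_amplitudes(cm$omega + 0i, c0, ts)
  expect_equal(herm$survival, rep(1, length(ts)), tolerance = 1e-9)
  full <- propagate_amplitudes(unclass(effective_hamiltonian(arr)), c0, ts)
  expect_true(all(diff(full$survival) <= 1e-12))
})
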