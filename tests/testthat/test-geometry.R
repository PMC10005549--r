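test_that("ring_spec validates parameters and derives the lattice constant", {
  s <- ring_spec(N = 9, R = 0.05)
  expect_equal(lattice_constant(s), 2 * 0.05 * sin(pi / 9))
  expect_lt(lattice_constant(s), 2 * s$R)
  # R from d inversion: exact chord relation (not the circumference
  # approximation N d / 2 pi)
  s2 <- ring_spec(N = 100, d = 1 / 3)
  expect_equal(s2$R, (1 / 3) / (2 * sin(pi / 100)), tolerance = 1e-12)
  expect_equal(lattice_constant(s2), 1 / 3, tolerance = 1e-12)
  expect_error(ring_spec(N = 1, R = 0.1), "N must be")
  expect_error(ring_spec(N = 9), "exactly one")
  expect_error(ring_spec(N = 9, R = 0.1, d = 0.1), "exactly one")
  expect_error(ring_spec(N = 9, R = NaN), "non-finite|R must be")
})

test_that("build_ring places emitters and dipoles per the angle convention", {
  # transverse: theta = 0 forces e_z regardless of phi
  r <- build_ring(ring_spec(N = 20, R = 0.3, theta = 0, phi = 1.23))
  expect_equal(r$dipoles, matrix(rep(c(0, 0, 1), each = 20), 20, 3))
  # tangential: theta = pi/2, phi = 0 gives the local e_phi
  r2 <- build_ring(ring_spec(N = 9, R = 0.1, theta = pi / 2, phi = 0))
  gam <- 2 * pi * (0:8) / 9
  expect_equal(r2$dipoles, cbind(-sin(gam), cos(gam), 0), tolerance = 1e-12)
  expect_equal(r2$positions[, 1], 0.1 * cos(gam))
  # all dipoles unit norm
  expect_equal(rowSums(r2$dipoles^2), rep(1, 9))
  # lattice constant equals the brute-force nearest-neighbour distance
  D <- as.matrix(dist(r2$positions))
  diag(D) <- Inf
  expect_equal(min(D), lattice_constant(ring_spec(N = 9, R = 0.1)),
               tolerance = 1e-12)
})

test_that("build_stack concatenates rings and enforces a common N", {
  s1 <- ring_spec(N = 9, R = 0.05)
  s2 <- ring_spec(N = 9, R = 0.05, z = 0.025)
  st <- build_stack(list(s1, s2))
  expect_equal(n_emitters(st), 18)
  expect_equal(st$n_cell, 2L)
  # cell i pairs emitter i of ring 1 with emitter i of ring 2
  for (l in c(0L, 4L)) {
    i1 <- which(st$cell == l & st$component == 1L)
    i2 <- which(st$cell == l & st$component == 2L)
    expect_equal(st$positions[i1, 1:2], st$positions[i2, 1:2])
  }
  # delta = pi/N puts ring-2 sites at the angular midpoints of ring 1
  st2 <- build_stack(list(s1, ring_spec(N = 9, R = 0.05, z = 0.02,
                                        delta = pi / 9)))
  p <- st2$positions[st2$cell == 0L & st2$component == 2L, ]
  expect_equal(atan2(p[2], p[1]), pi / 9, tolerance = 1e-12)
  expect_error(build_stack(list(s1, ring_spec(N = 8, R = 0.05, z = 0.02))),
               "same N")
})

test_that("built arrays satisfy the N-fold rotation invariant", {
  set.seed(42)
  for (k in 1:10) {
    arr <- random_stack()
    expect_lt(check_nfold_symmetry(arr), 1e-10)
  }
  # corrupting one position breaks the invariant
  arr <- build_stack(list(ring_spec(N = 7, R = 0.2),
                          ring_spec(N = 7, R = 0.3, z = 0.1)))
  arr$positions[3, 1] <- arr$positions[3, 1] + 1e-6
  expect_error(check_nfold_symmetry(arr), "violates")
})

test_that("scale_geometry rescales positions only", {
  arr <- build_stack(list(ring_spec(N = 6, R = 0.1, theta = 0.4, phi = 0.2),
                          ring_spec(N = 6, R = 0.14, z = 0.22,
                                    theta = 1.1, detuning = 2)))
  expect_equal(scale_geometry(arr, 1), arr)
  half <- scale_geometry(arr, 0.5)
  expect_equal(as.matrix(dist(half$positions)),
               as.matrix(dist(arr$positions)) / 2, tolerance = 1e-12)
  expect_equal(half$dipoles, arr$dipoles)
  expect_equal(half$detunings, arr$detunings)
  expect_error(scale_geometry(arr, 0), "alpha")
  expect_error(scale_geometry(arr, -1), "alpha")
})

test_that("lh2_geometry builds the 27-emitter 9-fold motif", {
  arr <- lh2_geometry()
  expect_equal(n_emitters(arr), 27)
  expect_equal(arr$n_cell, 3L)
  expect_equal(arr$N, 9L)
  expect_lt(check_nfold_symmetry(arr), 1e-10)
  # B800 detuning large and positive
  expect_true(all(arr$detunings[arr$component == 3L] > 1e6))
  p9 <- lh2_params()
  p9$N <- 8L
  expect_error(lh2_geometry(p9), "9-fold")
})

test_that("degenerate LH2 limit reduces to a single-ring spectrum", {
  # three coincident-radius components at offsets 2*pi*k/27 and zero
  # detuning form one uniform 27-ring; its 9-fold Bloch spectrum must match
  # the 27-fold single-ring spectrum
  p <- lh2_params()
  for (k in 1:3) {
    nm <- c("b850a", "b850b", "b800")[k]
    p[[nm]]$R_nm <- 2.6
    p[[nm]]$z_nm <- 0
    p[[nm]]$offset_rad <- 2 * pi * (k - 1) / 27
    p[[nm]]$theta_rad <- 0
    p[[nm]]$phi_rad <- 0
    p[[nm]]$detuning_Gamma0 <- 0
  }
  arr3 <- lh2_geometry(p)
  sp3 <- bloch_eigenmodes(bloch_blocks(arr3))
  ring27 <- build_ring(ring_spec(N = 27, R = 2.6 / 850, theta = 0))
  sp27 <- bloch_eigenmodes(bloch_blocks(ring27))
  expect_same_spectrum(sp3$modes, sp27$modes,
                       tol = 1e-9 * max(1, max(abs(sp27$modes$omega))))
})
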