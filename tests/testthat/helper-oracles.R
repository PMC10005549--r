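# Frozen independent oracle values for pair couplings, computed with a
# 40-digit arbitrary-precision evaluation of the Green's-tensor projection
# (series-free): separation along x, dipole pairs
#   zz: (0,0,1)-(0,0,1)   xx: (1,0,0)-(1,0,0)
#   mix: (0.6,0,0.8)-(0,0.8,0.6)
pair_oracle <- local({
  txt <- "
sep pair omega gamma
1e-4 zz 3023580756.2815922 0.99999992104316646
1e-4 xx -6047163899.8868596 0.99999996052158295
1e-4 mix 1451318763.0151643 0.4799999621007199
1e-3 zz 3023521.6717759321 0.99999210433317781
1e-3 xx -6047282.0712541285 0.99999605216380579
1e-3 mix 1451290.4024524474 0.47999621007992535
5e-3 zz 24176.723039089636 0.99980261834841221
5e-3 xx -48401.169001099767 0.99990130743482163
5e-3 mix 11604.827058763025 0.47990525680723786
1e-2 zz 3017.630707746434 0.99921059861864948
1e-2 xx -6059.0875485679468 0.99960527148222497
1e-2 mix 1448.4627397182883 0.47962108733695175
0.05 zz 23.082541374161999 0.98036490410154343
0.05 xx -50.706043120167941 0.99016512104731104
0.05 mix 11.07961985959776 0.47057515396874085
0.5 zz 0.21454376381294339 -0.15198177546350666
0.5 xx 0.048377301649799234 0.30396355092701331
0.5 mix 0.10298100663021283 -0.072951252222483195"
  read.table(text = txt, header = TRUE, colClasses =
               c("numeric", "character", "numeric", "numeric"))
})

oracle_dipoles <- list(
  zz = list(p1 = c(0, 0, 1), p2 = c(0, 0, 1)),
  xx = list(p1 = c(1, 0, 0), p2 = c(1, 0, 0)),
  mix = list(p1 = c(0.6, 0, 0.8), p2 = c(0, 0.8, 0.6)))

# random N-fold symmetric single- or multi-ring stack
random_stack <- function(n_rings = sample(1:3, 1)) {
  N <- sample(3:10, 1)
  specs <- lapply(seq_len(n_rings), function(k)
    ring_spec(N = N,
              R = runif(1, 0.03, 1.2),
              z = runif(1, 0, 0.8) * (k - 1),
              delta = runif(1, 0, 2 * pi / N),
              theta = runif(1, 0, pi),
              phi = runif(1, 0, 2 * pi),
              detuning = runif(1, -5, 5)))
  build_stack(specs)
}

# complex eigenvalue multiset comparison: sorted lexicographically
expect_same_spectrum <- function(modes_a, modes_b, tol = 1e-9) {
  va <- complex(real = modes_a$omega, imaginary = modes_a$gamma)
  vb <- complex(real = modes_b$omega, imaginary = modes_b$gamma)
  oa <- order(Re(va), Im(va))
  ob <- order(Re(vb), Im(vb))
  expect_lt(max(Mod(va[oa] - vb[ob])), tol)
}
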