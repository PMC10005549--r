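---
title: "Collective optical modes of concentric emitter nanorings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective optical modes of concentric emitter nanorings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringexciton)
```

## The model

A two-level quantum emitter with transition wavelength $\lambda$ decays at
the vacuum rate $\Gamma_0$. When several emitters sit within a wavelength of
one another, the exchange of virtual and real photons couples them: each
pair $(i,j)$ acquires a coherent coupling $\Omega_{ij}$ (a collective Lamb
shift) and a dissipative coupling $\Gamma_{ij}$ (correlated decay). Both are
projections of the free-space dyadic Green's tensor $G(r,\omega_0)$ onto the
dipole orientations $\hat p_i$,

$$\Omega_{ij} = -\tfrac{3\pi\Gamma_0}{k_0}\,
  \mathrm{Re}\,[\hat p_i \cdot G(r_i - r_j,\omega_0)\cdot \hat p_j],\qquad
  \Gamma_{ij} = \tfrac{6\pi\Gamma_0}{k_0}\,
  \mathrm{Im}\,[\hat p_i \cdot G(r_i - r_j,\omega_0)\cdot \hat p_j],$$

with $k_0 = 2\pi/\lambda$. In the weak-excitation (linear-optics) regime at
most one excitation is present and the dynamics, after dropping the
population-recycling term of the master equation (it only feeds the ground
state), are generated by the effective non-Hermitian Hamiltonian

$$H = \mathrm{diag}(\Delta_i) + \Omega - \tfrac{i}{2}\Gamma .$$

Each right eigenpair $(\lambda_k, v_k)$ defines a collective mode with
frequency shift $\mathrm{Re}\,\lambda_k$ and decay rate
$-2\,\mathrm{Im}\,\lambda_k$. Rates below $\Gamma_0$ are subradiant, above
it superradiant. Everything in the package is expressed in natural units:
lengths in $\lambda$ (so $k_0 = 2\pi$), rates, shifts and detunings in
$\Gamma_0$, $\hbar = 1$.

Dipole orientations are parameterized in the local ring frame,
$\hat p = \sin\theta\cos\phi\,\hat e_\phi + \sin\theta\sin\phi\,\hat e_r +
\cos\theta\,\hat e_z$: $\theta = 0$ is transverse (out-of-plane)
polarization, $\theta = \pi/2$ with $\phi = 0$ tangential and with
$\phi = \pi/2$ radial. (A frequently seen alternative convention swaps
$\sin\theta \leftrightarrow \cos\theta$; with this package's convention the
small-ring bright-mode rates read $N\Gamma_0\cos^2\theta$ at $m = 0$ and
$\tfrac{N}{2}\Gamma_0\sin^2\theta$ at $m = \pm 1$.)

## Bloch reduction

For geometries with an $N$-fold rotational symmetry — a single ring, or any
stack of concentric rings sharing one $N$ — the couplings depend only on the
cell separation $\ell = j - i \pmod N$, so $H$ is block-circulant in the
cell index. A discrete Fourier transform over cells block-diagonalizes it:
for each integer angular momentum $m$ the dynamics reduce to the
$n_{\rm cell}\times n_{\rm cell}$ matrix

$$\tilde G_m^{\alpha\beta} = \sum_{\ell=0}^{N-1} e^{i 2\pi m \ell/N}\,
  G_\ell^{\alpha\beta},$$

where $\alpha,\beta$ run over the components of the unit cell (one site per
ring). The package takes the canonical $m$-set as the integers in
$(-N/2,\,N/2]$; for odd $N$ this is $0,\pm1,\dots,\pm(N-1)/2$, and for even
$N$ it resolves the ambiguity of which band-edge label to keep (a single
$m = N/2$). `bloch_blocks()` verifies the circulant structure numerically
before reducing and refuses arrays that break the symmetry; the tolerance is
relative to the coupling scale, because geometries with detunings and
couplings of order $10^6$–$10^7\,\Gamma_0$ carry floating-point rounding of
that order times machine epsilon.

Dense diagonalization (`full_eigenmodes()`) is retained as the reference
path; the equality of the two spectra on every supported geometry is part of
the test suite.

## Numerical choices

**Small separations.** $\Gamma_{ij}$ is an $O(1)$ difference of $O(1/x^3)$
terms in $x = k_0 r$. Below $x = 10^{-2}$ (configurable) the imaginary
kernels are evaluated by truncated Taylor series; direct evaluation loses
about $x^{-2}$ digits to cancellation, which matters precisely at the
molecular-complex scale $x \sim 10^{-2}$.

**Ultra-subradiant rates.** For an exact right eigenvector, $H v = \lambda
v$ implies $-2\,\mathrm{Im}\,\lambda = v^\dagger \Gamma v / \lVert v
\rVert^2$ (the coherent part has a real expectation value). The package
computes decay rates through this positive-semidefinite quadratic form
rather than from the eigenvalue's imaginary part: a general eigensolver has
backward error $\sim\varepsilon\lVert H\rVert$, which at coherent couplings
of $10^4$–$10^5\,\Gamma_0$ would swamp rates of $10^{-12}\,\Gamma_0$. The
quadratic form is exact to first order in the eigenvector error and keeps
rates nonnegative.

**Rotation sweeps.** Branches of a two-ring Bloch block are connected across
a rotation sweep by maximal eigenvector overlap between adjacent grid
points; the avoided-crossing angle is the interior minimum of the real-part
gap, refined by a three-point quadratic fit (grid default 400 points).
The angle of maximal subradiance is reported as the deepest *interior*
local minimum of the most-subradiant-rate profile, with a topographic
prominence filter (both flanks must rise tenfold): the sweep boundaries
$\delta \to 0,\ 2\pi/N$ approach the aligned, unrotated stack, whose
ultra-dark antisymmetric modes are a separate regime, and prominence
filtering suppresses spurious dips at the numerical noise floor. The
relative inter-ring phase $\eta = \mathrm{atan2}(\mathrm{Im}\,\tilde
G_m^{12}, \mathrm{Re}\,\tilde G_m^{12})$ flips sign with which ring carries
the rotation, so only $|\eta|$ is physically meaningful in summaries.

**Scaling fits.** The most subradiant rate of a ring alternates between
parity classes of $N$: even $N$ supports a single Brillouin-edge mode
$m = N/2$, odd $N$ a $\pm(N-1)/2$ pair, and the two classes sit on slightly
different exponential envelopes. Log-linear fits of rate versus $N$ are
therefore run within one parity class (the default sweep uses even $N$);
mixing classes drops $R^2$ from $>0.999$ to $\sim 0.90$ without changing
the slopes materially.

**Degeneracies.** $\pm m$ pairs are exactly degenerate for unrotated
geometries; all cross-path comparisons are made between eigenvalue
multisets, never between eigenvectors within a degenerate pair.

## Closed-form limits

Two limits anchor the numerics. In the small-ring (Dicke) regime all
separations are far below $\lambda$ and mode $m$ radiates like a single
effective dipole $p_{m,\rm eff} = N^{-1/2}\sum_\ell e^{i2\pi m\ell/N}\hat
p_\ell$ with rate $|p_{m,\rm eff}|^2\,\Gamma_0$
(`effective_dipole_dicke()`); the coherent band approaches $2\Omega_d
\cos(2\pi m/N)$ with $\Omega_d$ the nearest-neighbour coupling
(`cosine_band()`). These are asymptotic statements: at $N = 20$,
$d = 0.05\lambda$ (ring radius $0.16\lambda$) the exact $m=0$ transverse
rate is $13.1\,\Gamma_0$, not $N\Gamma_0 = 20\,\Gamma_0$ — the closed forms
converge only as the radius shrinks further, which the test suite verifies
directly. In the opposite quasi-chain limit (large dense ring) the light
line $m_0 = N d/\lambda$ separates radiant from guided modes; the brightest
radially polarized mode sits just inside it (at $N = 100$, $d = \lambda/3$:
$|m| = 30$ against $m_0 = 33.3$), and guided subradiant branches require
$d < \lambda/2$.

## The LH2 fixture

The light-harvesting antenna LH2 of purple bacteria hosts its
bacteriochlorophyll pigments on a 9-fold symmetric scaffold: two closely
spaced B850 components (18 pigments absorbing near 850 nm) and a
vertically offset B800 ring (9 pigments, bluer by roughly $10^7\,\Gamma_0$
in these units). The package ships a **synthetic** parameter set
(`lh2_params()`): radii of 2.6–3.1 nm, inter-pigment spacings near 0.9 nm,
mostly in-plane and roughly alternating dipoles, and a B800 offset chosen
such that at the nominal size the upper B850-derived band sits just below
the B800 band. These values are plausible in scale but are **not** fitted
to crystallographic coordinates; every analysis built on the fixture is
qualitative/structural (band counts, bright-mode positions, population
crossings), never a numerical reproduction of the real complex.

What the fixture does reproduce: the strong hybridization of the two B850
components into a bright low band (bright modes only at $m = \pm 1$, the
fingerprint of in-plane polarization in the small-ring regime) and a darker
high band; the near-decoupling of the distant B800 ring; and the
near-critical size behaviour — under a global rescaling $R_i \to \alpha
R_i$ the third band's occupation swaps from the B850 pair to the B800 ring
at $\alpha_c(m{=}1) \approx 0.996$, with $\alpha_c(m{=}4) \approx 0.71$
moving away from unity as $m$ grows. The crossing scale $\alpha_c$ is
defined as the equality point of the summed-B850 and B800 occupations of
the third band, linearly interpolated between grid points.

```{r lh2, eval = FALSE}
lb <- lh2_bands()
subset(lb$coupled, m == 1)
size_sweep(alpha_grid = seq(0.6, 1.15, 0.01))$alpha_c
```

## What the experiments compute

```{r experiments, eval = FALSE}
# exponential subradiance suppression vs emitter number (even-N sweep)
subradiance_scaling(seq(6, 14, 2))

# (d, z) landscape of the most subradiant mode of a double ring, N = 9
subradiance_landscape(seq(0.06, 1, length.out = 25),
                      seq(0.06, 1, length.out = 25))

# rotation sweep of the m = 4 branches, avoided crossing
cfg <- fixture("rotated_pair_stacked")
sw <- delta_sweep(cfg$specs[[1]], cfg$specs[[2]], m = 4,
                  delta_grid = seq(1e-4, 2 * pi / 18, length.out = 400))
find_avoided_crossing(sw)
```

Problem sizes are chosen for interactive use: rings up to $N = 200$
emitters diagonalize densely in well under a second, the 25×25 landscape
takes a few seconds through the Bloch path, and the 400-point rotation
sweeps are sub-minute. The scaling sweep uses $N \in \{6,\dots,14\}$ per
ring; the exponential law is already unambiguous there ($R^2 > 0.99$
within a parity class).

## Known limitations

- Single-excitation physics only: no multi-excitation manifolds, driven
  steady states, or quantum jumps.
- Free-space Green's tensor only: no interfaces, cavities or media.
- Real dipole orientation vectors only; circular polarizations are
  rejected.
- Phonons and static disorder are absent; the ultra-deep subradiance of
  perfect geometries (rates down to $10^{-12}\,\Gamma_0$) is an idealized
  upper bound on lifetime, not a prediction for a soft molecular
  environment.
- The LH2 parameter set is a labeled synthetic stand-in (see above);
  conclusions drawn from it are structural, not quantitative.
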