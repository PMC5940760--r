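# Orientationally averaged scattering intensities of simple uniform-density
# bodies. Amplitudes are normalized so that A(0) equals the (contrast-weighted)
# particle volume, hence I(0) = V^2 in arbitrary units.

# sphere amplitude factor phi(x) = 3 (sin x - x cos x) / x^3, phi(0) = 1
.phi_sphere <- function(x) {
  out <- rep(1, length(x))
  big <- abs(x) > 1e-4
  xb <- x[big]
  out[big] <- 3 * (sin(xb) - xb * cos(xb)) / xb^3
  small <- !big
  out[small] <- 1 - x[small]^2 / 10
  out
}

# Gauss-Legendre nodes/weights on [a, b]
.gauss_legendre <- function(n, a = 0, b = 1) {
  gl <- pracma::gaussLegendre(n, a, b)
  list(x = gl$x, w = gl$w)
}

# solid sphere, radius r
.intensity_sphere <- function(q, r) {
  v <- 4 / 3 * pi * r^3
  (v * .phi_sphere(q * r))^2
}

# ellipsoid of revolution, semi-axes (a, a, c); u = cos(angle to symmetry axis)
.intensity_ellipsoid <- function(q, a, c, n_nodes = 64) {
  gl <- .gauss_legendre(n_nodes, 0, 1)
  v <- 4 / 3 * pi * a^2 * c
  acc <- numeric(length(q))
  for (j in seq_along(gl$x)) {
    reff <- sqrt(a^2 * (1 - gl$x[j]^2) + c^2 * gl$x[j]^2)
    acc <- acc + gl$w[j] * .phi_sphere(q * reff)^2
  }
  v^2 * acc
}

# concentric two-density sphere: outer radius ro at relative density 1,
# core radius ri at relative density rho_in (rho_in = 0 gives a hollow shell)
.intensity_shell <- function(q, ro, ri, rho_in = 0) {
  vo <- 4 / 3 * pi * ro^3
  vi <- 4 / 3 * pi * ri^3
  amp <- vo * .phi_sphere(q * ro) - (1 - rho_in) * vi * .phi_sphere(q * ri)
  amp^2
}

# torus (ring), tube radius a revolved at major radius rc about the z axis.
# Axially symmetric amplitude: A(q, gamma) = int_-a^a cos(q_z z) *
#   2 pi [R_out J1(q_r R_out) - R_in J1(q_r R_in)] / q_r dz,
# with R_in/out = rc -/+ sqrt(a^2 - z^2); orientational average over gamma.
.intensity_torus <- function(q, rc, a, n_gamma = 40, n_z = 17) {
  glu <- .gauss_legendre(n_gamma, 0, 1)       # u = cos(gamma)
  glz <- .gauss_legendre(n_z, 0, a)           # z >= 0, integrand even in z
  half <- sqrt(pmax(a^2 - glz$x^2, 0))
  r_out <- rc + half
  r_in <- rc - half
  acc <- numeric(length(q))
  for (ju in seq_along(glu$x)) {
    sg <- sqrt(1 - glu$x[ju]^2)               # sin(gamma)
    amp <- numeric(length(q))
    for (jz in seq_along(glz$x)) {
      qr <- q * sg
      qz <- q * glu$x[ju]
      radial <- ifelse(qr > 1e-9,
                       (r_out[jz] * besselJ(qr * r_out[jz], 1) -
                          r_in[jz] * besselJ(qr * r_in[jz], 1)) / qr,
                       (r_out[jz]^2 - r_in[jz]^2) / 2)
      amp <- amp + 2 * glz$w[jz] * cos(qz * glz$x[jz]) * 2 * pi * radial
    }
    acc <- acc + glu$w[ju] * amp^2
  }
  acc
}

# Debye scattering function of a Gaussian chain with radius of gyration rg;
# returned relative to I(0) = 1: I(x)/I(0) = 2 (e^-x - 1 + x) / x^2, x = (s rg)^2
.intensity_debye <- function(q, rg) {
  x <- (q * rg)^2
  out <- rep(1, length(q))
  big <- x > 1e-5
  out[big] <- 2 * (exp(-x[big]) - 1 + x[big]) / x[big]^2
  out[!big] <- 1 - x[!big] / 3
  out
}

# dispatch the base (monodisperse) intensity for a particle spec
.base_intensity <- function(spec, q) {
  geo <- spec$geometry
  switch(spec$shape_class,
    "compact" = .intensity_sphere(q, geo$r),
    "extended" = .intensity_ellipsoid(q, geo$a, geo$c),
    "flat" = .intensity_ellipsoid(q, geo$a, geo$c),
    "ring" = .intensity_torus(q, geo$rc, geo$a),
    "compact-hollow" = .intensity_shell(q, geo$ro, geo$ri, geo$rho_in),
    "hollow-sphere" = .intensity_shell(q, geo$ro, geo$ri, 0),
    "random-chain" = .intensity_debye(q, geo$rg) * (spec$mm / .rho_protein)^2,
    abort(sprintf("unsupported geometry '%s'", spec$shape_class))
  )
}
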