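# Independent oracles used across the suite. These deliberately avoid the
# package's own integration/fitting code paths: closed forms where they
# exist, dense brute-force quadrature or Monte Carlo where they do not.

# closed-form sphere intensity (normalized amplitude), I(0) = 1
oracle_sphere_intensity <- function(s, R) {
  x <- s * R
  (3 * (sin(x) - x * cos(x)) / x^3)^2
}

# exact-Guinier-form profile: I(s) = i0 exp(-s^2 rg^2 / 3)
guinier_form_profile <- function(rg = 20, i0 = 100, n = 200, s_max = 1.3 / rg) {
  s <- seq(s_max / n, s_max, length.out = n)
  saxs_profile(s, i0 * exp(-s^2 * rg^2 / 3))
}

# a guinier_fit stand-in with exactly known parameters
exact_guinier <- function(rg, i0) {
  structure(list(rg = rg, i0 = i0, fit_first = 1L, fit_last = 5L,
                 quality = 1, srg_last = NA_real_, weighted = FALSE, n = 5L),
            class = "guinier_fit")
}

# Monte-Carlo radius of gyration of a torus (tube radius a, major radius rc):
# sample uniformly over the solid of revolution (angle weighting by the
# distance from the axis) and take the RMS distance from the centroid.
oracle_torus_rg_mc <- function(rc, a, n = 40000, seed = 99) {
  withr::with_seed(seed, {
    # rejection-sample (r, psi) in the tube cross-section with weight rc + r cos(psi)
    m <- 0L
    r <- psi <- numeric(0)
    while (m < n) {
      rr <- a * sqrt(runif(2 * n))
      pp <- runif(2 * n, 0, 2 * pi)
      keep <- runif(2 * n) < (rc + rr * cos(pp)) / (rc + a)
      r <- c(r, rr[keep]); psi <- c(psi, pp[keep])
      m <- length(r)
    }
    r <- r[1:n]; psi <- psi[1:n]
    phi <- runif(n, 0, 2 * pi)
    rho <- rc + r * cos(psi)
    x <- rho * cos(phi); y <- rho * sin(phi); z <- r * sin(psi)
    sqrt(mean(x^2 + y^2 + z^2))
  })
}

# toy feature table emulating an ideal solid-sphere family; used to exercise
# training/persistence plumbing without generating profiles
toy_sphere_features <- function(n = 1200, seed = 7) {
  withr::with_seed(seed, {
    mm <- exp(runif(n, log(7), log(300)))
    v <- mm / 0.83e-3
    r <- (3 * v / (4 * pi))^(1 / 3)
    rg <- sqrt(3 / 5) * r
    vc <- v / (2 * pi * 1.5 * r)
    tibble::tibble(
      condition = "ideal", mm = mm, rg = rg, i0 = v^2, quality = 1,
      qp = 2 * pi^2 * v, vp = v * exp(rnorm(n, 0, 0.02)),
      vc = vc * exp(rnorm(n, 0, 0.02)), lc = 1.5 * r,
      vprime_3 = 11.0 + rnorm(n, 0, 0.02),
      vprime_4 = 10.73 + rnorm(n, 0, 0.02),
      vprime_5 = 10.02 + rnorm(n, 0, 0.02),
      vprime_mow = 1.13 * v * exp(rnorm(n, 0, 0.02)),
      s_upper_used = 8 / rg, truncated = FALSE
    )
  })
}
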