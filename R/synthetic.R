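#' Particle specification for the synthetic corpus
#'
#' Defines one model particle by its shape class, molecular mass and derived
#' geometry. The seven shape classes mirror the categories a SAXS shape
#' classifier distinguishes: compact (solid sphere), extended (prolate
#' ellipsoid), flat (oblate ellipsoid), ring (torus), compact-hollow
#' (concentric two-density sphere), hollow-sphere (spherical shell) and
#' random-chain (Gaussian chain, Debye scattering function).
#'
#' For solid shapes the geometry is sized so that the material volume equals
#' `mm / rho` with `rho` = 0.83e-3 kDa per cubic Angstrom (the average mass
#' density of an unmodified protein). Random chains carry no meaningful
#' uniform-density volume; their radius of gyration follows the empirical
#' denatured-protein scaling law `Rg = 2.54 N^0.522` Angstrom with
#' `N = 1000 mm / 110` residues, which places chain sizes in the same range
#' as the solid shapes.
#'
#' @param shape_class One of `"compact"`, `"extended"`, `"flat"`, `"ring"`,
#'   `"compact-hollow"`, `"hollow-sphere"`, `"random-chain"`.
#' @param mm Molecular mass, kDa.
#' @param aspect Shape anisometry: axial ratio `c/a` for ellipsoids
#'   (default 4 extended, 0.25 flat), major/tube radius ratio for the torus
#'   (default 3), cavity fraction `ri/ro` for shells (default 0.5
#'   compact-hollow, 0.75 hollow-sphere). Ignored for compact and chain.
#' @param rho_in Relative core density of the compact-hollow class,
#'   default 0.5.
#' @return An object of class `particle_spec`: a list with `shape_class`,
#'   `mm` (kDa), `volume` (cubic Angstrom; `NA` for chains) and `geometry`.
#' @examples
#' particle_spec("compact", 94)   # a ~30 A sphere
#' @export
particle_spec <- function(shape_class, mm, aspect = NULL, rho_in = 0.5) {
  classes <- c("compact", "extended", "flat", "ring", "compact-hollow",
               "hollow-sphere", "random-chain")
  shape_class <- match.arg(shape_class, classes)
  if (!is.finite(mm) || mm <= 0) abort("mm must be > 0")
  if (shape_class == "random-chain") {
    n_res <- 1000 * mm / 110
    geometry <- list(rg = 2.54 * n_res^0.522)
    volume <- NA_real_
  } else {
    volume <- mm / .rho_protein
    geometry <- switch(shape_class,
      "compact" = list(r = (3 * volume / (4 * pi))^(1 / 3)),
      "extended" = {
        ar <- aspect %||% 4
        if (ar <= 1) abort("extended aspect (c/a) must be > 1")
        a <- (3 * volume / (4 * pi * ar))^(1 / 3)
        list(a = a, c = ar * a)
      },
      "flat" = {
        ar <- aspect %||% 0.25
        if (ar >= 1 || ar <= 0) abort("flat aspect (c/a) must be in (0, 1)")
        a <- (3 * volume / (4 * pi * ar))^(1 / 3)
        list(a = a, c = ar * a)
      },
      "ring" = {
        t <- aspect %||% 3
        if (t <= 1) abort("ring aspect (rc/a) must be > 1")
        a <- (volume / (2 * pi^2 * t))^(1 / 3)
        list(rc = t * a, a = a)
      },
      "compact-hollow" = {
        f <- aspect %||% 0.5
        if (f <= 0 || f >= 1) abort("cavity fraction must be in (0, 1)")
        vo <- volume / (1 - (1 - rho_in) * f^3)
        ro <- (3 * vo / (4 * pi))^(1 / 3)
        list(ro = ro, ri = f * ro, rho_in = rho_in)
      },
      "hollow-sphere" = {
        f <- aspect %||% 0.75
        if (f <= 0 || f >= 1) abort("cavity fraction must be in (0, 1)")
        vo <- volume / (1 - f^3)
        ro <- (3 * vo / (4 * pi))^(1 / 3)
        list(ro = ro, ri = f * ro)
      }
    )
  }
  structure(list(shape_class = shape_class, mm = mm, volume = volume,
                 geometry = geometry),
            class = "particle_spec")
}

#' Noise-free scattering profile of a model particle
#'
#' Evaluates the orientationally averaged intensity of the particle on a
#' uniform grid (default: 1001 points up to 0.6 1/Angstrom, the conventional
#' setting for simulated protein curves). A small Gaussian polydispersity of
#' the overall size (default 3%, 9-node quadrature over the size distribution)
#' smears the exact form-factor zeros of the high-symmetry shapes, which would
#' otherwise make `log I` undefined at isolated points; it is applied through
#' the exact similarity scaling \eqn{I(q; xR) = x^6 I(xq; R)} evaluated on an
#' extended base grid. Chains (no zeros) are never smeared.
#'
#' @param spec A [particle_spec()].
#' @param s_max Upper end of the grid, 1/Angstrom.
#' @param n_points Number of grid points.
#' @param s_min Lower end of the grid; default `s_max / 1000`.
#' @param poly Relative width of the size polydispersity; 0 disables smearing.
#' @return A [saxs_profile()] (no sigma column values).
#' @export
ideal_profile <- function(spec, s_max = 0.6, n_points = 1001, s_min = NULL,
                          poly = 0.03) {
  stopifnot(inherits(spec, "particle_spec"))
  s_min <- s_min %||% (s_max / 1000)
  s <- seq(s_min, s_max, length.out = n_points)
  if (spec$shape_class == "random-chain" || poly <= 0) {
    intens <- .base_intensity(spec, s)
  } else {
    m <- 9L
    xj <- 1 + poly * qnorm((seq_len(m) - 0.5) / m)
    q_ext <- seq(s_min * min(xj) * 0.999, s_max * max(xj) * 1.001,
                 length.out = max(2048L, 2L * n_points))
    i_ext <- .base_intensity(spec, q_ext)
    intens <- numeric(n_points)
    for (x in xj) {
      intens <- intens + x^6 * approx(q_ext, i_ext, xout = x * s)$y / m
    }
  }
  saxs_profile(s, intens,
               label = sprintf("%s_%.4gkDa", spec$shape_class, spec$mm))
}

#' Add simulated counting noise to a profile
#'
#' Builds the deterministic error template
#' \eqn{\sigma(s) = a\sqrt{I(s) + c\,I_0}} (with \eqn{c = 10^{-3}} fixing the
#' high-angle noise floor and \eqn{I_0} the largest tabulated intensity),
#' scales `a` so that the profile's signal-to-noise ratio -- defined as the
#' median of the intensity column divided by the median of the error column --
#' equals `target_snr` exactly, then perturbs each intensity by an independent
#' Gaussian draw of standard deviation \eqn{\sigma(s)}. This reproduces the
#' characteristic growth of relative noise at higher angles. The template is
#' written into the sigma column; it depends only on the input profile, so
#' different seeds share identical sigmas.
#'
#' @param profile An ideal [saxs_profile()].
#' @param target_snr Target median signal-to-noise ratio (> 0); the study
#'   levels are 32, 11, 4, 2 and 1.
#' @param seed Integer seed making the draw reproducible.
#' @param floor_frac High-angle noise-floor constant `c`, default 1e-3.
#' @return A `saxs_profile` with perturbed intensities and populated sigma.
#' @export
add_noise <- function(profile, target_snr, seed, floor_frac = 1e-3) {
  validate_saxs_profile(profile)
  if (!is.finite(target_snr) || target_snr <= 0) abort("target_snr must be > 0")
  intens <- profile$intensity
  i0 <- max(intens)
  template <- sqrt(pmax(intens, 0) + floor_frac * i0)
  a <- median(intens) / (target_snr * median(template))
  sigma <- a * template
  noisy <- withr::with_seed(as.integer(seed),
                            intens + rnorm(length(intens), 0, sigma))
  saxs_profile(profile$s, noisy, sigma,
               label = sprintf("%s_snr%g", profile_label(profile), target_snr))
}

#' Emulate mismatched buffer subtraction
#'
#' Averages the intensity over the high-angle window `s` in \[0.4, 0.6\]
#' 1/Angstrom (where incorrect background subtraction is most visible) to get
#' `I_average`, then shifts the whole curve by a constant offset: oversubtracted
#' buffers remove `fraction * I_average` at every `s`, under-subtraction adds
#' it. Sigmas are unchanged. Under- followed by over-subtraction at the same
#' fraction restores the original profile.
#'
#' @param profile A [saxs_profile()] reaching 0.6 1/Angstrom.
#' @param fraction Offset as a fraction of `I_average`; the study levels are
#'   0.1, 0.2, 0.4, 0.6 and 0.9.
#' @param direction `"over"` (subtract) or `"under"` (add).
#' @param window High-angle averaging window, 1/Angstrom.
#' @param i_average Reference high-angle average; defaults to the input
#'   profile's own. Pass the unshifted profile's value to stack offsets
#'   relative to one reference (under- then over-subtraction at the same
#'   fraction of the same `i_average` restores the original curve exactly).
#' @return A `saxs_profile` with the constant offset applied.
#' @export
buffer_mismatch <- function(profile, fraction, direction = c("over", "under"),
                            window = c(0.4, 0.6), i_average = NULL) {
  validate_saxs_profile(profile)
  direction <- match.arg(direction)
  if (max(profile$s) < window[2] * (1 - 1e-9))
    abort(sprintf("profile ends at s = %.3g, before %.3g: cannot average the high-angle window",
                  max(profile$s), window[2]))
  in_win <- profile$s >= window[1] & profile$s <= window[2]
  i_avg <- i_average %||% mean(profile$intensity[in_win])
  offset <- fraction * i_avg * if (direction == "over") -1 else 1
  saxs_profile(profile$s, profile$intensity + offset,
               if (has_sigma(profile)) profile$sigma else NULL,
               label = sprintf("%s_%s%g", profile_label(profile), direction, fraction))
}

#' Sample random particle specifications
#'
#' Draws particle specs with molecular masses log-uniform over `mm_range`,
#' one batch per shape class with class counts `ceiling(n_per_class * weight)`.
#' Shape anisometry is drawn uniformly over a realistic band per class:
#' extended axial ratio 2.5-6, flat 0.15-0.35, ring radius ratio 2-4,
#' compact-hollow cavity 0.4-0.6, hollow-sphere cavity 0.65-0.85.
#'
#' @param n_per_class Base number of particles per shape class.
#' @param mm_range Mass range in kDa, default `c(7, 300)`.
#' @param class_weights Named multipliers on `n_per_class`; the default doubles
#'   the compact class, mirroring the skew toward globular proteins in
#'   structural databases.
#' @return A tibble with `id`, `shape_class`, `mm` and a `spec` list-column.
#' @export
sample_particles <- function(n_per_class, mm_range = c(7, 300),
                             class_weights = c(compact = 2)) {
  classes <- c("compact", "extended", "flat", "ring", "compact-hollow",
               "hollow-sphere", "random-chain")
  weights <- setNames(rep(1, length(classes)), classes)
  weights[names(class_weights)] <- class_weights
  aspect_band <- list(
    "compact" = NULL, "random-chain" = NULL,
    "extended" = c(2.5, 6), "flat" = c(0.15, 0.35), "ring" = c(2, 4),
    "compact-hollow" = c(0.4, 0.6), "hollow-sphere" = c(0.65, 0.85)
  )
  rows <- purrr::map(classes, function(cl) {
    n <- ceiling(n_per_class * weights[[cl]])
    mm <- exp(runif(n, log(mm_range[1]), log(mm_range[2])))
    band <- aspect_band[[cl]]
    aspect <- if (is.null(band)) rep(list(NULL), n) else as.list(runif(n, band[1], band[2]))
    tibble(shape_class = cl, mm = mm,
           spec = purrr::map2(mm, aspect, ~ particle_spec(cl, .x, aspect = .y)))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, id = dplyr::row_number(), .before = 1)
}

#' Build a synthetic training/test corpus
#'
#' Generates the full study corpus: random particles per shape class
#' ([sample_particles()]), an ideal profile for each, a random particle-level
#' train/test split, and the corruption variants -- training profiles at the
#' four milder noise levels (the harshest level is withheld from training),
#' test profiles under all 16 conditions: ideal, the five noise levels, and
#' the ten buffer-mismatch variants (five fractions, over and under) applied
#' to the particle's SNR = 4 profile.
#'
#' @inheritParams sample_particles
#' @param split Fraction of particles assigned to the training set.
#' @param seed Integer seed; the whole corpus (specs, splits, noise draws) is
#'   reproducible from it.
#' @param snr_train,snr_test Noise levels for the two splits.
#' @param mismatch_fractions Buffer-mismatch fractions applied to the test
#'   split.
#' @param s_max,n_points,poly Passed to [ideal_profile()].
#' @return A list with tibbles `train` and `test` (columns `id`,
#'   `shape_class`, `mm`, `condition`, `snr`, `mismatch_fraction`,
#'   `mismatch_direction`, `profile`) and the generation `params`.
#' @export
build_corpus <- function(n_per_class = 100, mm_range = c(7, 300), split = 0.7,
                         seed = 1, class_weights = c(compact = 2),
                         snr_train = c(32, 11, 4, 2),
                         snr_test = c(32, 11, 4, 2, 1),
                         mismatch_fractions = c(0.1, 0.2, 0.4, 0.6, 0.9),
                         s_max = 0.6, n_points = 1001, poly = 0.03) {
  if (n_per_class < 50) abort("n_per_class must be >= 50")
  if (mm_range[2] / mm_range[1] <= 1.5) abort("degenerate mm_range")
  withr::local_seed(as.integer(seed))
  particles <- sample_particles(n_per_class, mm_range, class_weights)
  n <- nrow(particles)
  n_train <- round(split * n)
  train_ids <- sort(sample.int(n, n_train))
  particles$split <- ifelse(particles$id %in% train_ids, "train", "test")
  particles$profile <- purrr::map(particles$spec, ideal_profile,
                                  s_max = s_max, n_points = n_points, poly = poly)
  noise_seed_pool <- sample.int(.Machine$integer.max - 1L, n * 8L)
  seed_for <- function(id, k) noise_seed_pool[(id - 1L) * 8L + k]

  expand_rows <- function(p, is_train) {
    snrs <- if (is_train) snr_train else snr_test
    base <- tibble(
      id = p$id, shape_class = p$shape_class, mm = p$mm,
      condition = "ideal", snr = NA_real_,
      mismatch_fraction = NA_real_, mismatch_direction = NA_character_,
      profile = list(p$profile)
    )
    noisy <- purrr::imap(snrs, function(snr, k) {
      prof <- add_noise(p$profile, snr, seed_for(p$id, k))
      tibble(id = p$id, shape_class = p$shape_class, mm = p$mm,
             condition = paste0("snr", snr), snr = snr,
             mismatch_fraction = NA_real_, mismatch_direction = NA_character_,
             profile = list(prof))
    })
    out <- dplyr::bind_rows(base, dplyr::bind_rows(noisy))
    if (!is_train) {
      base4 <- out$profile[[which(out$snr == 4)[1]]]
      mis <- purrr::map(mismatch_fractions, function(f) {
        purrr::map(c("over", "under"), function(d) {
          tibble(id = p$id, shape_class = p$shape_class, mm = p$mm,
                 condition = paste0(d, f), snr = 4,
                 mismatch_fraction = f, mismatch_direction = d,
                 profile = list(buffer_mismatch(base4, f, d)))
        })
      })
      out <- dplyr::bind_rows(out, dplyr::bind_rows(purrr::flatten(mis)))
    }
    out
  }

  split_rows <- function(which_split) {
    sel <- particles[particles$split == which_split, ]
    dplyr::bind_rows(purrr::map(seq_len(nrow(sel)), function(i) {
      expand_rows(list(id = sel$id[i], shape_class = sel$shape_class[i],
                       mm = sel$mm[i], profile = sel$profile[[i]]),
                  is_train = which_split == "train")
    }))
  }

  list(train = split_rows("train"), test = split_rows("test"),
       params = list(n_per_class = n_per_class, mm_range = mm_range,
                     split = split, seed = seed, snr_train = snr_train,
                     snr_test = snr_test,
                     mismatch_fractions = mismatch_fractions,
                     s_max = s_max, n_points = n_points, poly = poly))
}
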