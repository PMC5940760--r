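#' Molecular mass from the Porod volume
#'
#' Converts the excluded (Porod) volume to a mass by the fixed empirical
#' specific volume of proteins: `MM [Da] = Vp [A^3] / 1.37`.
#'
#' @param invariants A one-row tibble from [saxs_invariants()] or
#'   [porod_invariant()] (needs column `vp`).
#' @return A one-row tibble `mm` (kDa; `NA` on failure) and `flag`.
#' @export
estimate_mm_qp <- function(invariants) {
  vp <- invariants$vp[1]
  if (!is.finite(vp) || vp <= 0)
    return(tibble(mm = NA_real_, flag = "no Porod volume"))
  tibble(mm = vp / 1.37 / 1000, flag = NA_character_)
}

#' Fit the MoW apparent-volume correction
#'
#' The apparent volume `V'` obtained by integrating the normalized intensity
#' only up to a finite `s_max` underestimates the true volume in a
#' size-dependent way. This fits the correction as a single log-log affine
#' law, `log V_true = a log V' + b`, on a training set of profiles with known
#' mass (`V_true = MM / rho`, `rho` = 0.83e-3 kDa per cubic Angstrom). The
#' fit is robust (least absolute deviations): like the field's published
#' correction factors it is a globular-protein law, so strongly non-globular
#' outliers must not tilt it.
#'
#' @param training A data frame with columns `vprime` (apparent volume at
#'   `s_max`, cubic Angstrom) and `mm` (true mass, kDa). At least 200 usable
#'   rows spanning at least 1.5 decades of mass are required.
#' @param s_max The integration limit the apparent volumes were computed at,
#'   1/Angstrom; stored so the model is only applied at matching range.
#' @return An object of class `mow_correction` with elements `a`, `b`,
#'   `s_max`, `n`.
#' @export
fit_mow_correction <- function(training, s_max = 0.3) {
  stopifnot(is.data.frame(training), all(c("vprime", "mm") %in% names(training)))
  ok <- is.finite(training$vprime) & training$vprime > 0 &
    is.finite(training$mm) & training$mm > 0
  training <- training[ok, ]
  if (nrow(training) < 200)
    abort(sprintf("MoW correction needs >= 200 usable training profiles (got %d)",
                  nrow(training)))
  if (diff(range(log10(training$mm))) < 1.5)
    abort("MoW correction training masses must span >= 1.5 decades")
  v_true <- training$mm / .rho_protein
  co <- .l1_line(log(training$vprime), log(v_true))
  if (!is.finite(co[2]) || co[2] <= 0)
    abort("degenerate apparent-volume spread: cannot fit correction")
  structure(list(a = co[2], b = co[1], s_max = s_max, n = nrow(training)),
            class = "mow_correction")
}

#' Molecular mass by the MoW corrected-volume route
#'
#' Integrates the `I/I(0)`-normalized curve up to the model's `s_max` to get
#' the apparent volume `V'`, applies the trained log-log correction to obtain
#' the volume `V`, and converts to mass with the protein density
#' 0.83e-3 kDa per cubic Angstrom.
#'
#' @param profile A [saxs_profile()].
#' @param guinier A `guinier_fit` for the profile.
#' @param coeffs A trained [fit_mow_correction()] model.
#' @return A one-row tibble `mm` (kDa; `NA` on failure) and `flag`.
#' @export
estimate_mm_mow <- function(profile, guinier, coeffs) {
  if (!inherits(coeffs, "mow_correction"))
    abort("MoW correction model is not trained")
  if (max(profile$s) < coeffs$s_max * (1 - 1e-9))
    return(tibble(mm = NA_real_, flag = "range"))
  if (coeffs$s_max * guinier$rg < 3)
    return(tibble(mm = NA_real_, flag = "range"))
  vprime <- tryCatch(.mow_apparent_volume(profile, guinier, coeffs$s_max),
                     error = function(e) NA_real_)
  if (!is.finite(vprime) || vprime <= 0)
    return(tibble(mm = NA_real_, flag = "apparent volume failed"))
  v <- exp(coeffs$b + coeffs$a * log(vprime))
  tibble(mm = .rho_protein * v, flag = NA_character_)
}

# robust straight-line fit y = b + a x by L1 (least absolute deviations),
# solved by iteratively reweighted least squares. Empirical mass-volume
# calibration laws in this field are globular-protein laws; the median fit
# centres the dominant (globular) population instead of compromising toward
# strongly non-globular outliers (chains, thin shells).
.l1_line <- function(x, y, iter = 20L, eps = 1e-6) {
  w <- rep(1, length(x))
  co <- c(0, 0)
  for (i in seq_len(iter)) {
    fit <- lm(y ~ x, weights = w)
    new_co <- unname(coef(fit))
    if (max(abs(new_co - co)) < 1e-10) break
    co <- new_co
    r <- abs(y - fit$fitted.values)
    w <- 1 / pmax(r, eps * stats::sd(y))
  }
  co
}

#' Fit the volume-of-correlation power law
#'
#' The ratio \eqn{Q_R = V_c^2 / R_g} is proportional to the molecular mass on
#' a log-log plot. This fits `MM = (Q_R / c)^k` in log space on a training
#' set with known masses, by least absolute deviations (the relation is an
#' empirical globular-protein law; robust fitting keeps chain-like outliers
#' from tilting it).
#'
#' @param training A data frame with columns `qr` (\eqn{V_c^2/R_g}, cubic
#'   Angstrom) and `mm` (kDa); at least 50 usable rows.
#' @return An object of class `vc_powerlaw` with elements `c`, `k`, `n`.
#' @export
fit_vc_powerlaw <- function(training) {
  stopifnot(is.data.frame(training), all(c("qr", "mm") %in% names(training)))
  ok <- is.finite(training$qr) & training$qr > 0 &
    is.finite(training$mm) & training$mm > 0
  training <- training[ok, ]
  if (nrow(training) < 50)
    abort(sprintf("Vc power law needs >= 50 usable training profiles (got %d)",
                  nrow(training)))
  co <- .l1_line(log(training$qr), log(training$mm))
  k <- co[2]
  if (!is.finite(k) || k <= 0) abort("degenerate Q_R spread: cannot fit power law")
  structure(list(c = exp(-co[1] / k), k = k, n = nrow(training)),
            class = "vc_powerlaw")
}

#' Molecular mass from the volume of correlation
#'
#' @param invariants A one-row tibble with column `vc` (square Angstrom).
#' @param guinier A `guinier_fit` (supplies Rg).
#' @param powerlaw A trained [fit_vc_powerlaw()] model.
#' @return A one-row tibble `mm` (kDa; `NA` on failure) and `flag`.
#' @export
estimate_mm_vc <- function(invariants, guinier, powerlaw) {
  if (!inherits(powerlaw, "vc_powerlaw"))
    abort("Vc power law is not trained")
  vc <- invariants$vc[1]
  rg <- if (is.null(guinier)) NA_real_ else guinier$rg
  if (!is.finite(rg) || rg <= 0)
    return(tibble(mm = NA_real_, flag = "no Rg"))
  if (!is.finite(vc) || vc <= 0)
    return(tibble(mm = NA_real_, flag = "no Vc"))
  qr <- vc^2 / rg
  tibble(mm = (qr / powerlaw$c)^powerlaw$k, flag = NA_character_)
}

#' Build the size-and-shape nearest-neighbour index
#'
#' Populates the four-dimensional size-and-shape space
#' `(V'_3, V'_4, V'_5, log Rg)` with training particles of known mass. The
#' coordinates are z-scored (with Rg log-transformed first) so that the
#' Euclidean metric is not dominated by any single axis.
#'
#' @param training A data frame with columns `vprime_3`, `vprime_4`,
#'   `vprime_5`, `rg` and `mm` (all finite, `mm > 0`).
#' @param k Number of neighbours averaged by [estimate_mm_ss()], default 5.
#' @return An object of class `shape_space_index`.
#' @export
build_shape_index <- function(training, k = 5L) {
  need <- c("vprime_3", "vprime_4", "vprime_5", "rg", "mm")
  stopifnot(is.data.frame(training), all(need %in% names(training)))
  m <- cbind(training$vprime_3, training$vprime_4, training$vprime_5,
             log(training$rg))
  ok <- rowSums(!is.finite(m)) == 0 & is.finite(training$mm) & training$mm > 0
  m <- m[ok, , drop = FALSE]
  masses <- training$mm[ok]
  if (nrow(m) < k) abort("shape-space index needs at least k points")
  center <- colMeans(m)
  scale <- apply(m, 2, stats::sd)
  scale[scale == 0] <- 1
  structure(list(points = sweep(sweep(m, 2, center), 2, scale, "/"),
                 masses = masses, center = center, scale = scale,
                 k = as.integer(k)),
            class = "shape_space_index")
}

# z-score query coordinates (rows: v3, v4, v5, rg) against an index
.ss_standardize <- function(index, v3, v4, v5, rg) {
  q <- cbind(v3, v4, v5, log(rg))
  sweep(sweep(q, 2, index$center), 2, index$scale, "/")
}

# inverse-distance-weighted kNN mass for a matrix of standardized queries
.ss_knn <- function(index, q, exclude_self = FALSE, eps = 1e-9) {
  k <- index$k
  vapply(seq_len(nrow(q)), function(i) {
    if (any(!is.finite(q[i, ]))) return(NA_real_)
    d <- sqrt(colSums((t(index$points) - q[i, ])^2))
    ord <- order(d)
    if (exclude_self) ord <- ord[-1]
    if (length(ord) < k) return(NA_real_)
    sel <- ord[seq_len(k)]
    if (d[sel[1]] < eps) return(index$masses[sel[1]])  # exact match short-circuit
    w <- 1 / (d[sel] + eps)
    sum(w * index$masses[sel]) / sum(w)
  }, numeric(1))
}

#' Molecular mass by size-and-shape nearest neighbours
#'
#' Places the query at its `(V'_3, V'_4, V'_5, log Rg)` coordinates,
#' standardized by the index, and returns the inverse-distance-weighted mean
#' mass of the `k` nearest training particles. With `exclude_self = TRUE` the
#' single nearest neighbour is skipped (ranks 2 to k+1), which prevents a
#' training particle from acting as its own neighbour during validation.
#'
#' @param invariants A one-row tibble with `vprime_3`, `vprime_4`, `vprime_5`.
#' @param guinier A `guinier_fit` (supplies Rg).
#' @param index A [build_shape_index()] object.
#' @param exclude_self Skip the nearest neighbour, default `FALSE`.
#' @return A one-row tibble `mm` (kDa; `NA` on failure) and `flag`.
#' @export
estimate_mm_ss <- function(invariants, guinier, index, exclude_self = FALSE) {
  if (!inherits(index, "shape_space_index"))
    abort("shape-space index is not built")
  rg <- if (is.null(guinier)) NA_real_ else guinier$rg
  v <- c(invariants$vprime_3[1], invariants$vprime_4[1], invariants$vprime_5[1])
  if (!is.finite(rg) || rg <= 0 || any(!is.finite(v)))
    return(tibble(mm = NA_real_, flag = "missing coordinates"))
  q <- .ss_standardize(index, v[1], v[2], v[3], rg)
  mm <- .ss_knn(index, q, exclude_self = exclude_self)
  if (!is.finite(mm))
    return(tibble(mm = NA_real_, flag = "fewer than k usable neighbours"))
  tibble(mm = mm, flag = NA_character_)
}

#' @export
print.mow_correction <- function(x, ...) {
  cat(sprintf("<mow_correction: log V = %.4f log V' + %.4f (s_max = %g 1/A, n = %d)>\n",
              x$a, x$b, x$s_max, x$n))
  invisible(x)
}

#' @export
print.vc_powerlaw <- function(x, ...) {
  cat(sprintf("<vc_powerlaw: MM = (QR / %.4g)^%.4f (n = %d)>\n", x$c, x$k, x$n))
  invisible(x)
}

#' @export
print.shape_space_index <- function(x, ...) {
  cat(sprintf("<shape_space_index: %d points, k = %d>\n",
              nrow(x$points), x$k))
  invisible(x)
}
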