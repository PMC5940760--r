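# Analytic integrals of the Guinier form I(s) = i0 * exp(-s^2 rg^2 / 3) from
# 0 to s1; used to close the untabulated low-angle gap of every invariant.
# int_0^s1 s^2 e^(-a s^2) ds  and  int_0^s1 s e^(-a s^2) ds, a = rg^2/3.
.guinier_int_s2 <- function(i0, rg, s1) {
  a <- rg^2 / 3
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  i0 * (sqrt(pi) / (4 * a^1.5) * erf(sqrt(a) * s1) - s1 * exp(-a * s1^2) / (2 * a))
}
.guinier_int_s1 <- function(i0, rg, s1) {
  a <- rg^2 / 3
  i0 * (1 - exp(-a * s1^2)) / (2 * a)
}

# trapezoidal integral of y(x) from x[1] up to x_cut (interpolating the last
# partial panel); x_cut beyond the grid integrates to the end.
.trapz_to <- function(x, y, x_cut) {
  if (x_cut >= x[length(x)]) return(pracma::trapz(x, y))
  if (x_cut <= x[1]) return(0)
  k <- findInterval(x_cut, x)
  full <- if (k >= 2) pracma::trapz(x[1:k], y[1:k]) else 0
  y_cut <- y[k] + (y[k + 1] - y[k]) * (x_cut - x[k]) / (x[k + 1] - x[k])
  full + 0.5 * (y[k] + y_cut) * (x_cut - x[k])
}

#' Porod invariant and excluded volume
#'
#' Computes the Porod invariant \eqn{Q_p = \int_0^\infty s^2 I(s)\,ds} and the
#' excluded (Porod) volume \eqn{V_p = 2\pi^2 I(0)/Q_p}. The integral is
#' assembled from three pieces: the untabulated low-angle gap integrated
#' analytically with the Guinier form, the trapezoidal integral of the data up
#' to \eqn{s_{cut}} where \eqn{s_{cut} R_g = } `s_rg_cut`, and an analytic
#' Porod tail. Under the Porod law \eqn{I \sim K/s^4} the cumulative
#' invariant approaches its limit as \eqn{Q(s) = Q_\infty - K/s}; the tail is
#' obtained by fitting that form over the last 55% of the integrated range by
#' least squares and taking \eqn{Q_\infty - Q(s_{cut})}. Fitting the
#' cumulative rather than the pointwise \eqn{s^4 I(s)} self-averages the
#' form-factor oscillation and damps noise. Profiles ending before
#' \eqn{s R_g =} `s_rg_cut` are integrated to their end, the tail still
#' applied, and flagged `truncated`.
#'
#' @param profile A [saxs_profile()].
#' @param guinier A `guinier_fit` for the same profile (supplies Rg and I(0)).
#' @param s_rg_cut Dimensionless upper integration limit on `s * Rg`,
#'   default 8.
#' @return A one-row tibble with `qp`, `vp` (cubic Angstrom), `s_upper_used`
#'   and `truncated`.
#' @export
porod_invariant <- function(profile, guinier, s_rg_cut = 8) {
  s <- profile$s; intens <- profile$intensity
  s_target <- s_rg_cut / guinier$rg
  truncated <- s_target > s[length(s)] * (1 + 1e-9)
  s_cut <- min(s_target, s[length(s)])
  q_head <- .guinier_int_s2(guinier$i0, guinier$rg, s[1])
  q_mid <- .trapz_to(s, s^2 * intens, s_cut)
  # Porod tail: extrapolate the cumulative invariant Q(s) ~ Qinf - K/s over
  # the last 55% of the integrated range
  qcum <- pracma::cumtrapz(s, s^2 * intens)
  in_tail <- which(s >= 0.45 * s_cut & s <= s_cut)
  q_tail <- 0
  if (length(in_tail) >= 10) {
    co <- qr.coef(qr(cbind(1, -1 / s[in_tail])), qcum[in_tail])
    q_tail <- co[1] - q_mid
  } else if (length(in_tail) >= 2) {
    q_tail <- median(s[in_tail]^4 * intens[in_tail]) / s_cut
  }
  qp <- q_head + q_mid + q_tail
  if (!is.finite(qp) || qp <= 0)
    abort("Porod invariant is not positive (pathological over-subtraction?)")
  tibble(qp = qp, vp = 2 * pi^2 * guinier$i0 / qp,
         s_upper_used = s_cut, truncated = truncated)
}

#' Volume of correlation
#'
#' Computes \eqn{V_c = I(0) / \int_0^{s_{upper}} s I(s)\,ds} (units: square
#' Angstrom), with the same analytic Guinier closing of the low-angle gap as
#' [porod_invariant()]. No high-angle tail is added: the convergence of the
#' integrand is the method's own premise.
#'
#' @inheritParams porod_invariant
#' @param s_upper Upper integration limit in 1/Angstrom (default 0.3; pass
#'   `max(profile$s)` to use the full curve).
#' @return A one-row tibble with `vc` and `s_upper_used`.
#' @export
volume_of_correlation <- function(profile, guinier, s_upper = 0.3) {
  s <- profile$s
  if (s[length(s)] < s_upper * (1 - 1e-9))
    abort(sprintf("profile ends at s = %.3g, before s_upper = %.3g", s[length(s)], s_upper))
  denom <- .guinier_int_s1(guinier$i0, guinier$rg, s[1]) +
    .trapz_to(s, s * profile$intensity, s_upper)
  if (!is.finite(denom) || denom <= 0)
    abort("volume of correlation: integrated intensity is not positive")
  tibble(vc = guinier$i0 / denom, s_upper_used = min(s_upper, s[length(s)]))
}

#' Apparent volumes on the normalized Kratky scale
#'
#' On the dimensionless axis \eqn{x = s R_g} with intensities normalized to
#' \eqn{I(0) = 1}, computes \eqn{Q'(x_{max}) = \int_0^{x_{max}} x^2 I(x)\,dx}
#' and the apparent volume \eqn{V' = 2\pi^2 / Q'} at the cutoffs
#' \eqn{x_{max} = 3, 4, 5}. The V' triplet is a pure shape descriptor:
#' identical particles at different scales give identical triplets.
#'
#' @inheritParams porod_invariant
#' @param cutoffs Dimensionless cutoffs, default `c(3, 4, 5)`.
#' @return A one-row tibble `vprime_3`, `vprime_4`, `vprime_5` (dimensionless,
#'   monotone non-increasing in the cutoff).
#' @export
apparent_volumes <- function(profile, guinier, cutoffs = c(3, 4, 5)) {
  x <- profile$s * guinier$rg
  if (x[length(x)] < max(cutoffs))
    abort(sprintf("profile reaches s*Rg = %.2f < %g: insufficient range for V'",
                  x[length(x)], max(cutoffs)))
  inorm <- profile$intensity / guinier$i0
  head_int <- .guinier_int_s2(1, 1, x[1]) # Guinier form on the x-axis has rg = 1
  vals <- vapply(cutoffs, function(xm) {
    qprime <- head_int + .trapz_to(x, x^2 * inorm, xm)
    2 * pi^2 / qprime
  }, numeric(1))
  out <- as_tibble(as.list(setNames(vals, paste0("vprime_", cutoffs))))
  out
}

# Dimensional apparent volume used by the MoW route: Q' integrated on the
# I/I(0)-normalized curve up to s_max (1/A), V' = 2 pi^2 / Q' in A^3.
.mow_apparent_volume <- function(profile, guinier, s_max = 0.3) {
  s <- profile$s
  if (s[length(s)] < s_max * (1 - 1e-9))
    abort(sprintf("profile ends at s = %.3g, before s_max = %.3g", s[length(s)], s_max))
  qprime <- .guinier_int_s2(1, guinier$rg, s[1]) +
    .trapz_to(s, s^2 * profile$intensity / guinier$i0, s_max)
  if (!is.finite(qprime) || qprime <= 0)
    abort("apparent volume: integrated intensity is not positive")
  2 * pi^2 / qprime
}

#' All scattering invariants of a profile
#'
#' Convenience wrapper computing the Guinier parameters (if not supplied),
#' the Porod invariant and volume, the volume of correlation, the correlation
#' length \eqn{l_c = V_p / (2\pi V_c)}, the normalized-Kratky V' triplet and
#' the dimensional MoW apparent volume, as one tidy row. Individual stages
#' that fail on a given profile yield `NA` in their columns.
#'
#' @inheritParams porod_invariant
#' @param guinier Optional precomputed `guinier_fit`; default runs
#'   [auto_guinier()].
#' @param s_upper_vc Integration limit for the volume of correlation,
#'   1/Angstrom.
#' @param mow_s_max Integration limit for the MoW apparent volume, 1/Angstrom.
#' @return A one-row tibble with columns `rg`, `i0`, `quality`, `qp`, `vp`,
#'   `vc`, `lc`, `vprime_3`, `vprime_4`, `vprime_5`, `vprime_mow`,
#'   `s_upper_used`, `truncated`.
#' @export
saxs_invariants <- function(profile, guinier = NULL, s_upper_vc = 0.3,
                            mow_s_max = 0.3, s_rg_cut = 8) {
  g <- guinier %||% tryCatch(auto_guinier(profile), error = function(e) NULL)
  na_row <- tibble(rg = NA_real_, i0 = NA_real_, quality = NA_real_,
                   qp = NA_real_, vp = NA_real_, vc = NA_real_, lc = NA_real_,
                   vprime_3 = NA_real_, vprime_4 = NA_real_, vprime_5 = NA_real_,
                   vprime_mow = NA_real_, s_upper_used = NA_real_, truncated = NA)
  if (is.null(g)) return(na_row)
  por <- tryCatch(porod_invariant(profile, g, s_rg_cut), error = function(e) NULL)
  vc <- tryCatch(volume_of_correlation(profile, g, s_upper_vc)$vc,
                 error = function(e) NA_real_)
  vpr <- tryCatch(apparent_volumes(profile, g), error = function(e) NULL)
  vmow <- tryCatch(.mow_apparent_volume(profile, g, mow_s_max),
                   error = function(e) NA_real_)
  vp <- if (is.null(por)) NA_real_ else por$vp
  tibble(
    rg = g$rg, i0 = g$i0, quality = g$quality,
    qp = if (is.null(por)) NA_real_ else por$qp,
    vp = vp,
    vc = vc,
    lc = if (is.finite(vp) && is.finite(vc) && vc > 0) vp / (2 * pi * vc) else NA_real_,
    vprime_3 = if (is.null(vpr)) NA_real_ else vpr$vprime_3,
    vprime_4 = if (is.null(vpr)) NA_real_ else vpr$vprime_4,
    vprime_5 = if (is.null(vpr)) NA_real_ else vpr$vprime_5,
    vprime_mow = vmow,
    s_upper_used = if (is.null(por)) NA_real_ else por$s_upper_used,
    truncated = if (is.null(por)) NA else por$truncated
  )
}
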