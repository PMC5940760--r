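#' Guinier fit over a fixed window
#'
#' Fits the Guinier law \eqn{\ln I(s) = \ln I(0) - s^2 R_g^2/3} by (weighted)
#' least squares of \eqn{\ln I} on \eqn{s^2} over the requested index window.
#' When the profile carries sigmas the points are weighted by
#' \eqn{(I/\sigma)^2}, the propagated precision of \eqn{\ln I}.
#'
#' @param profile A [saxs_profile()].
#' @param window Integer pair `c(first, last)` of point indices to fit;
#'   must contain at least 5 strictly positive intensities.
#' @param max_srg Classical Guinier validity bound on `s[last] * rg`;
#'   exceeding it triggers a warning (the automatic search in
#'   [auto_guinier()] enforces it instead).
#' @return An object of class `guinier_fit` with elements `rg` (Angstrom),
#'   `i0`, `fit_first`, `fit_last`, `quality` (R-squared of the fit, clamped
#'   to \[0, 1\]) and `srg_last`.
#' @examples
#' s <- seq(0.002, 0.06, length.out = 60)
#' p <- saxs_profile(s, 100 * exp(-s^2 * 20^2 / 3))
#' guinier_fit(p, c(1, 60))$rg
#' @export
guinier_fit <- function(profile, window, max_srg = 1.3) {
  validate_saxs_profile(profile)
  stopifnot(length(window) == 2)
  i1 <- as.integer(window[1]); i2 <- as.integer(window[2])
  if (i1 < 1 || i2 > nrow(profile) || i2 - i1 + 1L < 5L)
    abort("Guinier window must lie inside the profile and contain >= 5 points")
  idx <- i1:i2
  intens <- profile$intensity[idx]
  if (any(intens <= 0))
    abort("Guinier window contains non-positive intensities")
  w <- if (has_sigma(profile)) (intens / profile$sigma[idx])^2 else rep(1, length(idx))
  fit <- .wls_line(profile$s[idx]^2, log(intens), w)
  if (!is.finite(fit$slope) || fit$slope >= 0)
    abort("no Guinier decay: fitted slope is not negative")
  rg <- sqrt(-3 * fit$slope)
  out <- structure(list(
    rg = rg, i0 = exp(fit$intercept),
    fit_first = i1, fit_last = i2,
    quality = min(max(fit$r2, 0), 1),
    srg_last = profile$s[i2] * rg,
    weighted = has_sigma(profile),
    n = length(idx)
  ), class = "guinier_fit")
  if (out$srg_last > max_srg * (1 + 1e-9))
    warn(sprintf("Guinier window extends to s*Rg = %.2f (> %.2f)",
                 out$srg_last, max_srg))
  out
}

#' Automatic Guinier analysis
#'
#' Searches for a low-angle window satisfying the classical validity bound
#' `s * Rg <= max_srg`, suitable for noisy data where the true radius of
#' gyration is unknown. The window end is iterated to self-consistency
#' (shrunk until the bound holds for the fitted Rg) and a small set of
#' trimmed start points is scored by the weighted-fit R-squared penalized by
#' window shortness; ties go to the longer, lower-angle window.
#'
#' @param profile A [saxs_profile()].
#' @param min_window Preferred minimum window length (falls back to 5 when
#'   the validity region is shorter).
#' @param max_srg Guinier validity bound, default 1.3.
#' @return A `guinier_fit` object; errors when no window of at least 5
#'   positive points with a negative slope exists (callers typically record
#'   the profile's estimates as absent in that case).
#' @export
auto_guinier <- function(profile, min_window = 10L, max_srg = 1.3) {
  validate_saxs_profile(profile)
  s <- profile$s; intens <- profile$intensity
  n <- nrow(profile)
  # usable prefix: stop before the first non-positive intensity
  first_bad <- which(intens <= 0)[1]
  n_use <- if (is.na(first_bad)) n else first_bad - 1L
  if (n_use < 5L) abort("no usable Guinier region: fewer than 5 positive low-angle points")
  w_all <- if (has_sigma(profile)) (intens / profile$sigma)^2 else rep(1, n)

  fit_window <- function(i1, i2) {
    idx <- i1:i2
    f <- .wls_line(s[idx]^2, log(intens[idx]), w_all[idx])
    f$i1 <- i1; f$i2 <- i2
    f
  }

  best_over_starts <- function(last) {
    len_min <- if (last >= min_window) min_window else 5L
    starts <- unique(pmin(c(1L, 3L, 6L, 10L, 15L, 21L), last - len_min + 1L))
    starts <- starts[starts >= 1L]
    best <- NULL
    for (i1 in starts) {
      f <- fit_window(i1, last)
      if (!is.finite(f$slope) || f$slope >= 0) next
      len <- last - i1 + 1L
      f$score <- min(max(f$r2, 0), 1) - 0.05 * (1 - len / last)
      if (is.null(best) || f$score > best$score + 1e-12) best <- f
    }
    best
  }

  last <- n_use
  seen <- integer(0)
  fit <- NULL
  for (iter in 1:20) {
    cand <- best_over_starts(last)
    if (is.null(cand)) {
      # shrink blindly and retry once before giving up
      if (last > 10L) { last <- max(5L, last %/% 2L); next }
      abort("no Guinier decay: no window of >= 5 positive points with negative slope")
    }
    fit <- cand
    rg <- sqrt(-3 * fit$slope)
    ok <- s[1:n_use] * rg <= max_srg
    new_last <- if (any(ok)) max(which(ok)) else 0L
    new_last <- max(new_last, fit$i1 + 4L)
    new_last <- min(new_last, n_use)
    if (new_last == last || new_last %in% seen) break
    seen <- c(seen, last)
    last <- new_last
  }
  if (is.null(fit) || fit$slope >= 0)
    abort("no Guinier decay: automatic window search failed")
  rg <- sqrt(-3 * fit$slope)
  structure(list(
    rg = rg, i0 = exp(fit$intercept),
    fit_first = fit$i1, fit_last = fit$i2,
    quality = min(max(fit$r2, 0), 1),
    srg_last = s[fit$i2] * rg,
    weighted = has_sigma(profile),
    n = fit$i2 - fit$i1 + 1L
  ), class = "guinier_fit")
}

# weighted least-squares line y = a + b x; returns slope, intercept, r2
.wls_line <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  dx <- x - mx; dy <- y - my
  sxx <- sum(w * dx * dx); sxy <- sum(w * dx * dy); syy <- sum(w * dy * dy)
  slope <- sxy / sxx
  r2 <- if (syy <= .Machine$double.eps * abs(my)^2 * length(y)) 1 else sxy^2 / (sxx * syy)
  list(slope = slope, intercept = my - slope * mx, r2 = r2)
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("<guinier_fit: Rg = %.3f A, I(0) = %.4g, window [%d, %d], s*Rg(last) = %.2f, quality = %.3f>\n",
              x$rg, x$i0, x$fit_first, x$fit_last, x$srg_last, x$quality))
  invisible(x)
}
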