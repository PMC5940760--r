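#' Tidy a Guinier fit
#'
#' @param x A `guinier_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `rg`, `i0`, `fit_first`, `fit_last`,
#'   `srg_last`, `quality`.
#' @export
tidy.guinier_fit <- function(x, ...) {
  tibble(rg = x$rg, i0 = x$i0, fit_first = x$fit_first, fit_last = x$fit_last,
         srg_last = x$srg_last, quality = x$quality)
}

#' @rdname tidy.guinier_fit
#' @export
glance.guinier_fit <- function(x, ...) tidy.guinier_fit(x, ...)

#' Tidy a mass posterior: one row per hypothesis bin
#'
#' @param x An `mm_posterior`.
#' @param ... Unused.
#' @return A tibble with `bin`, `mm_lo`, `mm_hi`, `mm_center`, `posterior`.
#' @export
tidy.mm_posterior <- function(x, ...) {
  e <- x$bins$edges
  tibble(bin = seq_along(x$posterior),
         mm_lo = e[-length(e)], mm_hi = e[-1],
         mm_center = x$bins$centers, posterior = x$posterior)
}

#' One-row summary of a mass posterior
#'
#' @param x An `mm_posterior`.
#' @param ... Unused.
#' @return A one-row tibble with the MAP mass, its probability score, the
#'   credibility interval and the number of contributing methods.
#' @export
glance.mm_posterior <- function(x, ...) {
  tibble(map_mm = x$map_mm, map_probability = x$map_probability,
         ci_low = x$ci_low, ci_high = x$ci_high, ci_mass = x$ci_mass,
         n_methods = x$n_methods)
}

#' Tidy the trained estimator coefficients of a pipeline
#'
#' @param x An `mm_pipeline`.
#' @param ... Unused.
#' @return A tibble with one row per trained coefficient.
#' @export
tidy.mm_pipeline <- function(x, ...) {
  dplyr::bind_rows(
    tibble(component = "mow", term = c("a", "b"),
           estimate = c(x$mow$a, x$mow$b)),
    tibble(component = "vc_powerlaw", term = c("c", "k"),
           estimate = c(x$vc_powerlaw$c, x$vc_powerlaw$k))
  )
}

#' One-row summary of a trained pipeline
#'
#' @param x An `mm_pipeline`.
#' @param ... Unused.
#' @return A one-row tibble with bin count, training size, index size.
#' @export
glance.mm_pipeline <- function(x, ...) {
  tibble(n_bins = x$bins$n_bins, n_train = x$meta$n_train,
         n_index = nrow(x$ss_index$points), k = x$ss_index$k)
}
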