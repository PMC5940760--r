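#' Build the adaptive molecular-mass binning
#'
#' Discretizes the mass axis for the Bayesian calculation. The central 90% of
#' the empirical log-mass distribution is partitioned into equal-count
#' (quantile) bins -- emphasizing a uniform structure count per bin, so bins
#' are narrowest where training masses are densest -- while the bottom and top
#' 5% tails are partitioned into equal-width (linear) bins to limit the loss
#' of precision at the extremes. The axis is clamped at 0.7 kDa and 1300 kDa:
#' any mass outside maps to the first or last bin.
#'
#' @param training_masses Numeric vector of at least 1000 masses, kDa.
#' @param n_bins Total number of bins, default 100.
#' @param clamp Outermost edges, kDa.
#' @param tail_frac Fraction of the distribution (each side) binned linearly.
#' @param tail_bins Number of bins allocated to each linear tail, default 10%
#'   of `n_bins`. The tails cover sparse mass ranges with few training
#'   structures; giving each tail a larger bin share than its 5% mass share
#'   keeps the tail bins narrow enough that a one-bin slip stays comparable
#'   to the central binned-error resolution.
#' @return An object of class `mm_binning`: list with `edges`
#'   (length `n_bins + 1`, strictly increasing) and `centers` (geometric mean
#'   of each bin's edges).
#' @export
build_bins <- function(training_masses, n_bins = 100L, clamp = c(0.7, 1300),
                       tail_frac = 0.05, tail_bins = NULL) {
  m <- training_masses[is.finite(training_masses) & training_masses > 0]
  if (length(m) < 1000)
    abort(sprintf("binning needs >= 1000 training masses (got %d)", length(m)))
  m <- pmin(pmax(m, clamp[1]), clamp[2])
  n_tail <- tail_bins %||% max(2L, round(0.10 * n_bins))
  n_central <- n_bins - 2L * n_tail
  if (n_central < 10L) abort("n_bins too small for the tail allocation")
  qs <- exp(quantile(log(m), probs = seq(tail_frac, 1 - tail_frac,
                                         length.out = n_central + 1L),
                     names = FALSE, type = 7))
  if (qs[1] <= clamp[1] || qs[length(qs)] >= clamp[2])
    abort("training masses reach the clamp edges; widen the clamp or trim the data")
  low <- seq(clamp[1], qs[1], length.out = n_tail + 1L)
  high <- seq(qs[length(qs)], clamp[2], length.out = n_tail + 1L)
  edges <- c(low[-(n_tail + 1L)], qs, high[-1])
  if (any(diff(edges) <= 0))
    abort("degenerate mass distribution: bin edges are not strictly increasing")
  structure(list(edges = edges,
                 centers = sqrt(edges[-1] * edges[-length(edges)]),
                 n_bins = as.integer(n_bins)),
            class = "mm_binning")
}

#' Map masses to bins
#'
#' @param mm Numeric vector of masses, kDa; values outside the clamp range
#'   are assigned to the first/last bin.
#' @param bins An [build_bins()] `mm_binning`.
#' @return Integer bin indices in `1:n_bins`.
#' @export
mm_bin <- function(mm, bins) {
  stopifnot(inherits(bins, "mm_binning"))
  findInterval(mm, bins$edges, all.inside = TRUE)
}

#' @export
print.mm_binning <- function(x, ...) {
  cat(sprintf("<mm_binning: %d bins over [%.3g, %.3g] kDa>\n",
              x$n_bins, x$edges[1], x$edges[length(x$edges)]))
  invisible(x)
}

#' Fit a likelihood table for one estimator
#'
#' Builds the conditional probability table `P(truth bin | evidence bin)` from
#' training pairs of (estimated mass, true mass): a 2-D histogram of the
#' binned pairs plus a Laplace pseudo-count of one in every cell (so no bin
#' has zero probability), each evidence row normalized to sum to 1. Rows for
#' evidence bins never observed in training are therefore uniform.
#'
#' @param pairs A data frame with columns `estimate` and `truth` (kDa);
#'   absent (`NA`) estimates are skipped.
#' @param bins An `mm_binning`.
#' @param method Identifier stored with the table.
#' @return An object of class `mm_likelihood`: list with `method`, `table`
#'   (`n_bins` x `n_bins` matrix, rows = evidence bins) and `n_pairs`.
#' @export
fit_likelihood <- function(pairs, bins, method = "mm") {
  stopifnot(is.data.frame(pairs), all(c("estimate", "truth") %in% names(pairs)))
  ok <- is.finite(pairs$estimate) & is.finite(pairs$truth) &
    pairs$estimate > 0 & pairs$truth > 0
  if (!any(ok)) abort("no usable (estimate, truth) pairs")
  n <- bins$n_bins
  e_bin <- mm_bin(pairs$estimate[ok], bins)
  t_bin <- mm_bin(pairs$truth[ok], bins)
  counts <- matrix(0, n, n)
  for (i in seq_along(e_bin)) counts[e_bin[i], t_bin[i]] <- counts[e_bin[i], t_bin[i]] + 1
  counts <- counts + 1  # Laplace pseudo-count
  structure(list(method = method, table = counts / rowSums(counts),
                 n_pairs = sum(ok)),
            class = "mm_likelihood")
}

#' @export
print.mm_likelihood <- function(x, ...) {
  cat(sprintf("<mm_likelihood '%s': %d x %d table from %d pairs>\n",
              x$method, nrow(x$table), ncol(x$table), x$n_pairs))
  invisible(x)
}

#' Bayesian posterior over binned mass hypotheses
#'
#' Combines the available per-method mass estimates into a posterior by the
#' product rule: for each hypothesis bin `H`,
#' `P(H | E) proportional to prior(H) * prod_m P(E_m | H)` over the methods
#' whose estimate is present -- an absent method simply contributes nothing.
#' The accumulation is done in log space to avoid underflow. The point
#' estimate is the centre of the maximum a posteriori bin (ties broken toward
#' the lowest mass), reported with the bin's posterior mass as probability
#' score and the credibility interval from [credible_interval()].
#'
#' @param evidence A one-row data frame (or named list/vector) holding the
#'   per-method estimates in kDa, named as in `tables` (canonically `mm_qp`,
#'   `mm_mow`, `mm_vc`, `mm_ss`); `NA` marks an absent method.
#' @param tables Named list of [fit_likelihood()] tables, one per method.
#' @param bins The `mm_binning` the tables were built on.
#' @param prior Probability vector over bins (sums to 1), or `NULL` for the
#'   uniform prior.
#' @param ci_mass Credibility-interval target mass, default 0.90.
#' @return An object of class `mm_posterior`: list with `posterior`
#'   (probability vector), `map_mm`, `map_probability`, `ci_low`, `ci_high`,
#'   `ci_mass`, `n_methods`, `bins`.
#' @export
mm_posterior <- function(evidence, tables, bins, prior = NULL, ci_mass = 0.90) {
  stopifnot(inherits(bins, "mm_binning"))
  n <- bins$n_bins
  if (is.null(prior)) prior <- rep(1 / n, n)
  if (length(prior) != n || abs(sum(prior) - 1) > 1e-6)
    abort("prior must be a probability vector over the hypothesis bins")
  ev <- if (is.data.frame(evidence)) as.list(evidence[1, ]) else as.list(evidence)
  lp <- log(prior)
  n_used <- 0L
  for (m in names(tables)) {
    v <- suppressWarnings(as.numeric(ev[[m]]))
    if (length(v) != 1 || !is.finite(v) || v <= 0) next
    lp <- lp + log(tables[[m]]$table[mm_bin(v, bins), ])
    n_used <- n_used + 1L
  }
  if (n_used == 0L) abort("no evidence: all method estimates are absent")
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  map_idx <- which.max(p)  # which.max takes the first maximum: lowest-mass bin
  ci <- credible_interval(p, bins, mass = ci_mass)
  structure(list(posterior = p, map_mm = bins$centers[map_idx],
                 map_probability = p[map_idx],
                 ci_low = ci$ci_low, ci_high = ci$ci_high, ci_mass = ci_mass,
                 n_methods = n_used, bins = bins),
            class = "mm_posterior")
}

#' Credibility interval of a binned posterior
#'
#' Accumulates bins in decreasing posterior order until the target mass is
#' reached (a highest-posterior-density set) and reports the contiguous
#' envelope of the accumulated set: the smallest lower edge and largest upper
#' edge. The MAP bin is always contained.
#'
#' @param posterior Probability vector over the bins (sums to 1).
#' @param bins An `mm_binning`.
#' @param mass Target probability mass, default 0.90.
#' @return A one-row tibble with `ci_low`, `ci_high` (kDa) and
#'   `mass_covered` (the accumulated mass, at least `mass`).
#' @export
credible_interval <- function(posterior, bins, mass = 0.90) {
  stopifnot(inherits(bins, "mm_binning"))
  if (abs(sum(posterior) - 1) > 1e-6)
    abort("posterior must sum to 1")
  ord <- order(posterior, decreasing = TRUE)
  cum <- cumsum(posterior[ord])
  take <- ord[seq_len(which(cum >= mass - 1e-12)[1])]
  tibble(ci_low = bins$edges[min(take)],
         ci_high = bins$edges[max(take) + 1L],
         mass_covered = cum[length(take)])
}

#' Forward a posterior as the next frame's prior
#'
#' For sequentially collected frames (SEC-SAXS, time slicing) the uniform
#' prior of frame `n` may be replaced by the posterior of frame `n - 1`. The
#' forwarded distribution is mixed with a small uniform floor so that a bin
#' driven to (near) zero probability by one frame can recover in later ones.
#'
#' @param previous An `mm_posterior` from the previous frame.
#' @param floor Uniform mixing weight, default 0.01.
#' @return A probability vector usable as the `prior` of [mm_posterior()].
#' @export
forward_prior <- function(previous, floor = 0.01) {
  stopifnot(inherits(previous, "mm_posterior"))
  p <- previous$posterior
  (1 - floor) * p + floor / length(p)
}

#' @export
print.mm_posterior <- function(x, ...) {
  cat(sprintf("<mm_posterior: MAP = %.4g kDa (p = %.3f), %d%% CI [%.4g, %.4g] kDa, %d method(s)>\n",
              x$map_mm, x$map_probability, round(100 * x$ci_mass),
              x$ci_low, x$ci_high, x$n_methods))
  invisible(x)
}
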