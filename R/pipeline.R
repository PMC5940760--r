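#' Per-profile feature extraction over a corpus
#'
#' Runs the automatic Guinier analysis and all scattering invariants on every
#' profile of a corpus tibble (one list-column of [saxs_profile()] objects),
#' returning the input with the feature columns of [saxs_invariants()] bound
#' on. Profiles on which a stage fails get `NA` features -- downstream
#' estimators then record the affected method as absent, exactly as happens
#' with problematic experimental data.
#'
#' @param corpus A tibble with a `profile` list-column.
#' @param s_upper_vc,mow_s_max,s_rg_cut Passed to [saxs_invariants()].
#' @return `corpus` with the invariant columns appended.
#' @export
corpus_features <- function(corpus, s_upper_vc = 0.3, mow_s_max = 0.3,
                            s_rg_cut = 8) {
  stopifnot(is.data.frame(corpus), "profile" %in% names(corpus))
  feats <- purrr::map(corpus$profile, function(p) {
    saxs_invariants(p, s_upper_vc = s_upper_vc, mow_s_max = mow_s_max,
                    s_rg_cut = s_rg_cut)
  })
  dplyr::bind_cols(corpus, dplyr::bind_rows(feats))
}

#' Per-profile mass evidence from precomputed features
#'
#' Applies the four estimators to every row of a feature table (the output of
#' [corpus_features()]), vectorized. The size-and-shape look-up uses
#' `exclude_self = TRUE` when scoring the very particles that populate the
#' index (the training split), so a particle never acts as its own neighbour.
#'
#' @param features A tibble with the [saxs_invariants()] columns.
#' @param pipeline A trained [train_mm_pipeline()] object (or a list with
#'   `mow`, `vc_powerlaw`, `ss_index`).
#' @param exclude_self Passed to the size-and-shape look-up.
#' @return `features` with columns `mm_qp`, `mm_mow`, `mm_vc`, `mm_ss` (kDa,
#'   `NA` where a method is absent).
#' @export
corpus_evidence <- function(features, pipeline, exclude_self = FALSE) {
  n <- nrow(features)
  mm_qp <- ifelse(is.finite(features$vp) & features$vp > 0,
                  features$vp / 1.37 / 1000, NA_real_)

  mow <- pipeline$mow
  ok_mow <- is.finite(features$vprime_mow) & features$vprime_mow > 0 &
    is.finite(features$rg) & (mow$s_max * features$rg >= 3)
  mm_mow <- rep(NA_real_, n)
  mm_mow[ok_mow] <- .rho_protein *
    exp(mow$b + mow$a * log(features$vprime_mow[ok_mow]))

  pl <- pipeline$vc_powerlaw
  ok_vc <- is.finite(features$vc) & features$vc > 0 &
    is.finite(features$rg) & features$rg > 0
  mm_vc <- rep(NA_real_, n)
  qr <- features$vc[ok_vc]^2 / features$rg[ok_vc]
  mm_vc[ok_vc] <- (qr / pl$c)^pl$k

  idx <- pipeline$ss_index
  mm_ss <- rep(NA_real_, n)
  ok_ss <- is.finite(features$vprime_3) & is.finite(features$vprime_4) &
    is.finite(features$vprime_5) & is.finite(features$rg) & features$rg > 0
  if (any(ok_ss)) {
    q <- .ss_standardize(idx, features$vprime_3[ok_ss], features$vprime_4[ok_ss],
                         features$vprime_5[ok_ss], features$rg[ok_ss])
    mm_ss[ok_ss] <- .ss_knn(idx, q, exclude_self = exclude_self)
  }
  dplyr::mutate(features, mm_qp = mm_qp, mm_mow = mm_mow, mm_vc = mm_vc,
                mm_ss = mm_ss)
}

#' Train the full consensus pipeline on a synthetic corpus
#'
#' Fits every data-driven component from the training split of a corpus
#' produced by [build_corpus()] and [corpus_features()]:
#' the MoW volume correction and the Vc power law (on the noise-free
#' profiles), the size-and-shape index (noise-free coordinates of the
#' training particles), the adaptive mass binning (all training rows), and
#' one likelihood table per method from the (estimate, truth) pairs of the
#' whole training split -- noise-free plus the training noise levels -- with
#' the size-and-shape estimates computed under self-exclusion.
#'
#' @param features_train The training split with [corpus_features()] columns
#'   (must include `mm`, the true mass, and `condition`).
#' @param n_bins Number of mass bins, default 100.
#' @param k Neighbour count of the size-and-shape method, default 5.
#' @param mow_s_max Integration limit the MoW apparent volumes used.
#' @return An object of class `mm_pipeline`: list with `bins`, `tables`
#'   (named list: `mm_qp`, `mm_mow`, `mm_vc`, `mm_ss`), `mow`, `vc_powerlaw`,
#'   `ss_index`, `meta`.
#' @export
train_mm_pipeline <- function(features_train, n_bins = 100L, k = 5L,
                              mow_s_max = 0.3) {
  stopifnot(is.data.frame(features_train),
            all(c("mm", "condition", "rg", "vp", "vc", "vprime_3",
                  "vprime_mow") %in% names(features_train)))
  ideal <- features_train[features_train$condition == "ideal", ]
  mow <- fit_mow_correction(
    tibble(vprime = ideal$vprime_mow, mm = ideal$mm), s_max = mow_s_max)
  vc_powerlaw <- fit_vc_powerlaw(
    tibble(qr = ideal$vc^2 / ideal$rg, mm = ideal$mm))
  ss_index <- build_shape_index(ideal, k = k)
  bins <- build_bins(features_train$mm, n_bins = n_bins)

  partial <- list(mow = mow, vc_powerlaw = vc_powerlaw, ss_index = ss_index)
  ev <- corpus_evidence(features_train, partial, exclude_self = TRUE)
  tables <- purrr::map(
    setNames(c("mm_qp", "mm_mow", "mm_vc", "mm_ss"),
             c("mm_qp", "mm_mow", "mm_vc", "mm_ss")),
    function(m) fit_likelihood(tibble(estimate = ev[[m]], truth = ev$mm),
                               bins, method = m))
  structure(list(bins = bins, tables = tables, mow = mow,
                 vc_powerlaw = vc_powerlaw, ss_index = ss_index,
                 meta = list(n_train = nrow(features_train),
                             n_bins = as.integer(n_bins), k = as.integer(k),
                             mow_s_max = mow_s_max,
                             schema = "saxsmm/pipeline/1")),
            class = "mm_pipeline")
}

#' Consensus posteriors for a table of evidence rows
#'
#' Runs [mm_posterior()] on every row of an evidence table (the output of
#' [corpus_evidence()]), collecting the MAP estimate, probability score and
#' credibility interval per row. Rows where every method is absent yield `NA`
#' (the profile is recorded as wholly unusable).
#'
#' @param evidence A tibble with columns `mm_qp`, `mm_mow`, `mm_vc`, `mm_ss`.
#' @param pipeline A trained `mm_pipeline`.
#' @param prior Optional prior probability vector (default uniform).
#' @param ci_mass Credibility-interval mass, default 0.90.
#' @return `evidence` with columns `map_mm`, `map_probability`, `ci_low`,
#'   `ci_high`, `n_methods` appended.
#' @export
corpus_posteriors <- function(evidence, pipeline, prior = NULL, ci_mass = 0.90) {
  methods <- names(pipeline$tables)
  out <- purrr::map(seq_len(nrow(evidence)), function(i) {
    ev <- as.list(evidence[i, methods, drop = FALSE])
    post <- tryCatch(
      mm_posterior(ev, pipeline$tables, pipeline$bins, prior = prior,
                   ci_mass = ci_mass),
      error = function(e) NULL)
    if (is.null(post)) {
      tibble(map_mm = NA_real_, map_probability = NA_real_,
             ci_low = NA_real_, ci_high = NA_real_, n_methods = 0L)
    } else {
      tibble(map_mm = post$map_mm, map_probability = post$map_probability,
             ci_low = post$ci_low, ci_high = post$ci_high,
             n_methods = post$n_methods)
    }
  })
  dplyr::bind_cols(evidence, dplyr::bind_rows(out))
}

#' Consensus mass estimate for a single profile
#'
#' End-to-end convenience route: automatic Guinier analysis, invariants, the
#' four estimators and the Bayesian combination for one scattering profile.
#'
#' @param object A trained `mm_pipeline`.
#' @param profile A [saxs_profile()] (or a data frame with `s`, `intensity`,
#'   optionally `sigma`).
#' @param prior Optional prior probability vector (e.g. from
#'   [forward_prior()]).
#' @param ci_mass Credibility-interval mass.
#' @param ... Unused.
#' @return An `mm_posterior`, with the per-method evidence attached as
#'   attribute `"evidence"`.
#' @export
predict.mm_pipeline <- function(object, profile, prior = NULL, ci_mass = 0.90,
                                ...) {
  if (!inherits(profile, "saxs_profile")) profile <- as_saxs_profile(profile)
  feats <- saxs_invariants(profile, mow_s_max = object$meta$mow_s_max)
  ev <- corpus_evidence(feats, object, exclude_self = FALSE)
  post <- mm_posterior(ev[, c("mm_qp", "mm_mow", "mm_vc", "mm_ss")],
                       object$tables, object$bins, prior = prior,
                       ci_mass = ci_mass)
  attr(post, "evidence") <- ev
  post
}

#' @export
print.mm_pipeline <- function(x, ...) {
  cat(sprintf("<mm_pipeline: %d bins, methods [%s], trained on %d profiles>\n",
              x$bins$n_bins, paste(names(x$tables), collapse = ", "),
              x$meta$n_train))
  invisible(x)
}
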