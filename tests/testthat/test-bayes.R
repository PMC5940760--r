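make_masses <- function(n = 5000, seed = 11) {
  withr::with_seed(seed, pmin(pmax(exp(rnorm(n, log(40), 0.9)), 1), 1200))
}

# a small hand-built binning for arithmetic tests
toy_bins <- function(edges = c(0.7, 10, 20, 40, 80, 1300)) {
  structure(list(edges = edges,
                 centers = sqrt(edges[-1] * edges[-length(edges)]),
                 n_bins = length(edges) - 1L),
            class = "mm_binning")
}

test_that("adaptive binning: equal central counts, narrow bins at the mode, clamps", {
  m <- make_masses()
  bins <- build_bins(m, n_bins = 100L)
  expect_equal(length(bins$edges), 101L)
  expect_true(all(diff(bins$edges) > 0))
  expect_equal(bins$edges[1], 0.7)
  expect_equal(bins$edges[101], 1300)
  # central quantile bins hold equal counts (to rounding)
  n_tail <- 10L
  central <- (n_tail + 1L):(100L - n_tail)
  counts <- table(factor(mm_bin(m, bins), levels = 1:100))[central]
  expect_lte(diff(range(counts)), max(2, 0.02 * median(counts)))
  # narrowest log-width bins sit near the 40 kDa mode
  logw <- diff(log(bins$edges))
  expect_lt(abs(log(bins$centers[which.min(logw[central]) + n_tail]) -
                  log(40)), log(2))
  # clamp rule
  expect_equal(mm_bin(0.5, bins), 1L)
  expect_equal(mm_bin(2000, bins), 100L)
  expect_error(build_bins(m[1:500]), ">= 1000")
})

test_that("every positive mass maps to exactly one bin; bins tile the range", {
  bins <- build_bins(make_masses())
  probe <- exp(seq(log(0.1), log(5000), length.out = 500))
  idx <- mm_bin(probe, bins)
  expect_true(all(idx >= 1 & idx <= bins$n_bins))
  inside <- probe > 0.7 & probe < 1300
  expect_true(all(bins$edges[idx[inside]] <= probe[inside] + 1e-12))
  expect_true(all(probe[inside] <= bins$edges[idx[inside] + 1L] + 1e-12))
})

test_that("likelihood tables: diagonal mode, uniform unseen rows, unit row sums", {
  bins <- build_bins(make_masses(), n_bins = 60L)
  m <- make_masses(3000, seed = 2)
  tab <- fit_likelihood(tibble::tibble(estimate = m, truth = m), bins)
  expect_true(all(abs(rowSums(tab$table) - 1) < 1e-9))
  expect_true(all(tab$table > 0))
  seen <- unique(mm_bin(m, bins))
  for (e in seen[1:10])
    expect_equal(which.max(tab$table[e, ]), e)
  unseen <- setdiff(1:60, seen)
  if (length(unseen))
    expect_equal(unname(tab$table[unseen[1], ]), rep(1 / 60, 60))
  expect_error(fit_likelihood(tibble::tibble(estimate = NA_real_, truth = 1),
                              bins), "no usable")
})

test_that("posterior matches brute-force enumeration of the product rule", {
  bins <- toy_bins()
  n <- bins$n_bins
  withr::local_seed(5)
  tables <- purrr::map(setNames(paste0("m", 1:4), paste0("m", 1:4)), function(m) {
    t <- matrix(runif(n * n, 0.2, 2), n, n)
    structure(list(method = m, table = t / rowSums(t), n_pairs = 1L),
              class = "mm_likelihood")
  })
  prior <- runif(n); prior <- prior / sum(prior)
  evidence <- list(m1 = 15, m2 = 30, m3 = 55, m4 = 7)  # bins 2, 3, 4, 1
  post <- mm_posterior(evidence, tables, bins, prior = prior)
  brute <- prior *
    tables$m1$table[2, ] * tables$m2$table[3, ] *
    tables$m3$table[4, ] * tables$m4$table[1, ]
  brute <- brute / sum(brute)
  expect_lt(max(abs(post$posterior - brute)), 1e-12)
  expect_equal(sum(post$posterior), 1, tolerance = 1e-9)
  expect_equal(post$map_mm, bins$centers[which.max(brute)])
})

test_that("posterior is order-invariant and ignores absent methods", {
  bins <- toy_bins()
  n <- bins$n_bins
  withr::local_seed(6)
  tables <- purrr::map(setNames(paste0("m", 1:4), paste0("m", 1:4)), function(m) {
    t <- matrix(runif(n * n, 0.2, 2), n, n)
    structure(list(method = m, table = t / rowSums(t), n_pairs = 1L),
              class = "mm_likelihood")
  })
  ev <- list(m1 = 15, m2 = NA_real_, m3 = 55, m4 = 7)
  p1 <- mm_posterior(ev, tables, bins)
  p2 <- mm_posterior(ev, tables[c(3, 1, 4, 2)], bins)
  expect_equal(p1$posterior, p2$posterior, tolerance = 1e-12)
  expect_equal(p1$n_methods, 3L)
  # dropping the absent method entirely changes nothing
  p3 <- mm_posterior(ev[c("m1", "m3", "m4")], tables[c("m1", "m3", "m4")], bins)
  expect_equal(p1$posterior, p3$posterior, tolerance = 1e-12)
  expect_error(mm_posterior(list(m1 = NA_real_), tables["m1"], bins),
               "no evidence")
})

test_that("uninformative and delta evidence give the expected posteriors", {
  bins <- toy_bins()
  n <- bins$n_bins
  unif <- structure(list(method = "u", table = matrix(1 / n, n, n),
                         n_pairs = 1L), class = "mm_likelihood")
  p <- mm_posterior(list(u = 30), list(u = unif), bins)
  expect_equal(p$posterior, rep(1 / n, n), tolerance = 1e-12)
  expect_equal(p$map_mm, bins$centers[1])  # tie broken toward lowest mass
  expect_equal(c(p$ci_low, p$ci_high), c(0.7, 1300))  # 5 x 0.2 needs all bins
  delta <- matrix(0, n, n); delta[, 3] <- 1
  dt <- structure(list(method = "d", table = delta, n_pairs = 1L),
                  class = "mm_likelihood")
  pd <- mm_posterior(list(d = 30), list(d = dt), bins)
  expect_equal(pd$map_mm, bins$centers[3])
  expect_equal(pd$map_probability, 1)
  expect_equal(pd$ci_low, bins$edges[3])
  expect_equal(pd$ci_high, bins$edges[4])
})

test_that("credibility interval: point mass, uniform, unimodal cases", {
  bins <- build_bins(make_masses())
  n <- bins$n_bins
  point <- rep(0, n); point[42] <- 1
  ci <- credible_interval(point, bins)
  expect_equal(ci$ci_low, bins$edges[42])
  expect_equal(ci$ci_high, bins$edges[43])
  unif <- rep(1 / n, n)
  ciu <- credible_interval(unif, bins)
  expect_gte(ciu$mass_covered, 0.9)
  expect_gte(sum(bins$edges >= ciu$ci_low & bins$edges <= ciu$ci_high) - 1, 90)
  gauss <- exp(-0.5 * ((1:n - 30) / 5)^2); gauss <- gauss / sum(gauss)
  cig <- credible_interval(gauss, bins)
  expect_lte(cig$ci_low, bins$centers[30])
  expect_gte(cig$ci_high, bins$centers[30])
  expect_error(credible_interval(unif * 2, bins), "sum to 1")
})

test_that("prior forwarding sharpens consistent evidence and keeps a floor", {
  bins <- build_bins(make_masses(), n_bins = 60L)
  m <- make_masses(3000, seed = 3)
  est <- m * exp(rnorm(3000, 0, 0.1))
  tab <- fit_likelihood(tibble::tibble(estimate = est, truth = m), bins)
  prior <- NULL
  map_mass <- numeric(5)
  for (frame in 1:5) {
    post <- mm_posterior(list(mm = 50), list(mm = tab), bins, prior = prior)
    map_mass[frame] <- post$map_probability
    prior <- forward_prior(post)
  }
  expect_true(all(diff(map_mass) >= -1e-12))
  expect_true(all(prior >= 0.01 / bins$n_bins - 1e-15))
  # forwarding a uniform posterior is the uniform prior
  unif_post <- structure(list(posterior = rep(1 / 60, 60)),
                         class = "mm_posterior")
  expect_equal(forward_prior(unif_post), rep(1 / 60, 60), tolerance = 1e-12)
})
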