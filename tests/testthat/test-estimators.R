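test_that("Porod-route mass is Vp / 1.37 Da, reported in kDa", {
  expect_equal(estimate_mm_qp(tibble::tibble(vp = 1.37))$mm, 0.001,
               tolerance = 1e-12)
  out <- estimate_mm_qp(tibble::tibble(vp = 113097.3))  # R = 30 sphere
  expect_equal(out$mm, 82.552, tolerance = 1e-4)
  absent <- estimate_mm_qp(tibble::tibble(vp = NA_real_))
  expect_true(is.na(absent$mm))
  expect_match(absent$flag, "Porod")
})

test_that("MoW correction recovers the identity and rejects bad training", {
  mm <- exp(seq(log(5), log(500), length.out = 300))
  ident <- tibble::tibble(vprime = mm / 0.83e-3, mm = mm)
  fit <- fit_mow_correction(ident)
  expect_equal(fit$a, 1, tolerance = 1e-6)
  expect_equal(fit$b, 0, tolerance = 1e-5)
  expect_error(fit_mow_correction(ident[1:10, ]), ">= 200")
  narrow <- tibble::tibble(vprime = rep(1e5, 300) * exp(rnorm(300, 0, 1e-3)),
                           mm = rep(80, 300) * exp(rnorm(300, 0, 1e-3)))
  expect_error(fit_mow_correction(narrow), "decades")
})

test_that("the fitted MoW correction reduces the error of the raw V' route", {
  radii <- seq(15, 55, length.out = 250)
  feats <- purrr::map(radii, function(R) {
    V <- 4 / 3 * pi * R^3
    p <- ideal_profile(particle_spec("compact", 0.83e-3 * V), poly = 0)
    saxs_invariants(p)
  })
  feats <- dplyr::bind_rows(feats)
  mm_true <- 0.83e-3 * 4 / 3 * pi * radii^3
  fit <- fit_mow_correction(tibble::tibble(vprime = feats$vprime_mow,
                                           mm = mm_true))
  raw_err <- abs(0.83e-3 * feats$vprime_mow / mm_true - 1)
  cor_err <- abs(0.83e-3 * exp(fit$b + fit$a * log(feats$vprime_mow)) /
                   mm_true - 1)
  expect_lt(median(cor_err), median(raw_err))
  expect_lt(median(cor_err), 0.05)
})

test_that("MoW declines out-of-range profiles with a range flag", {
  p <- ideal_profile(particle_spec("compact", 94), poly = 0)
  g <- auto_guinier(p)
  fit <- structure(list(a = 1, b = 0, s_max = 0.3, n = 500),
                   class = "mow_correction")
  small <- structure(list(a = 1, b = 0, s_max = 0.1, n = 500),
                     class = "mow_correction")
  # rg ~ 23 A: s_max = 0.1 gives s_max * rg < 3
  expect_identical(estimate_mm_mow(p, g, small)$flag, "range")
  expect_true(is.finite(estimate_mm_mow(p, g, fit)$mm))
  expect_error(estimate_mm_mow(p, g, list(a = 1)), "not trained")
})

test_that("Vc power law: exact recovery and the k = 1 linear form", {
  qr <- exp(seq(log(100), log(1e5), length.out = 120))
  mm <- (qr / 25)^1.3
  fit <- fit_vc_powerlaw(tibble::tibble(qr = qr, mm = mm))
  expect_equal(fit$k, 1.3, tolerance = 1e-9)
  expect_equal(fit$c, 25, tolerance = 1e-6)
  lin <- structure(list(c = 10, k = 1, n = 100), class = "vc_powerlaw")
  g <- exact_guinier(rg = 20, i0 = 1)
  m1 <- estimate_mm_vc(tibble::tibble(vc = 300), g, lin)$mm
  m2 <- estimate_mm_vc(tibble::tibble(vc = 600), g, lin)$mm
  expect_equal(m2 / m1, 4, tolerance = 1e-12)  # doubling vc quadruples Q_R
  absent <- estimate_mm_vc(tibble::tibble(vc = NA_real_), g, lin)
  expect_true(is.na(absent$mm))
})

test_that("size-and-shape look-up handles exact matches, ties and self-exclusion", {
  train <- tibble::tibble(
    vprime_3 = c(10, 12, 10, 11, 10.5, 11.5),
    vprime_4 = c(9, 11, 9, 10, 9.5, 10.5),
    vprime_5 = c(8, 10, 8, 9, 8.5, 9.5),
    rg = c(20, 40, 20, 30, 25, 35),
    mm = c(20, 40, 20, 30, 25, 35)
  )
  idx2 <- build_shape_index(train[c(1, 2), ], k = 2L)
  # query standing exactly on training point 1 returns its mass
  g20 <- exact_guinier(20, 1)
  hit <- estimate_mm_ss(tibble::tibble(vprime_3 = 10, vprime_4 = 9,
                                       vprime_5 = 8), g20, idx2)
  expect_equal(hit$mm, 20, tolerance = 1e-12)
  # query equidistant from a 20 and a 40 kDa point averages to 30
  gmid <- exact_guinier(sqrt(20 * 40), 1)
  mid <- estimate_mm_ss(tibble::tibble(vprime_3 = 11, vprime_4 = 10,
                                       vprime_5 = 9), gmid, idx2)
  expect_equal(mid$mm, 30, tolerance = 1e-9)
  # self-exclusion skips the coincident nearest neighbour (points 1 and 3 tie)
  idx6 <- build_shape_index(train, k = 2L)
  excl <- estimate_mm_ss(tibble::tibble(vprime_3 = 10, vprime_4 = 9,
                                        vprime_5 = 8), g20, idx6,
                         exclude_self = TRUE)
  expect_equal(excl$mm, 20, tolerance = 1e-9)  # duplicate point still matches
  # fewer than k usable neighbours is reported as absent with a flag
  idx_tiny <- build_shape_index(train[1:3, ], k = 2L)
  idx_tiny$k <- 5L
  short <- estimate_mm_ss(tibble::tibble(vprime_3 = 10, vprime_4 = 9,
                                         vprime_5 = 8), g20, idx_tiny,
                          exclude_self = TRUE)
  expect_true(is.na(short$mm))
  expect_match(short$flag, "neighbours")
  miss <- estimate_mm_ss(tibble::tibble(vprime_3 = NA_real_, vprime_4 = 9,
                                        vprime_5 = 8), g20, idx6)
  expect_true(is.na(miss$mm))
})

test_that("estimators increase monotonically with sphere size", {
  radii <- c(18, 24, 30, 38, 46)
  feats <- dplyr::bind_rows(purrr::map(radii, function(R) {
    p <- ideal_profile(particle_spec("compact", 0.83e-3 * 4 / 3 * pi * R^3),
                       poly = 0)
    saxs_invariants(p)
  }))
  mm_qp <- feats$vp / 1.37 / 1000
  qr <- feats$vc^2 / feats$rg
  expect_true(all(diff(mm_qp) > 0))
  expect_true(all(diff(qr) > 0))
  expect_true(all(diff(feats$rg) > 0))
})
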