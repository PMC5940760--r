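test_that("the unsmeared compact profile is the closed-form sphere intensity", {
  V <- 4 / 3 * pi * 30^3
  sp <- particle_spec("compact", 0.83e-3 * V)
  expect_equal(sp$geometry$r, 30, tolerance = 1e-12)
  p <- ideal_profile(sp, poly = 0)
  expect_lt(max(abs(p$intensity / V^2 - oracle_sphere_intensity(p$s, 30))),
            1e-10)
})

test_that("the random-chain profile follows the Debye function with I(0) limit 1", {
  sp <- particle_spec("random-chain", 40)
  p <- ideal_profile(sp)
  rg <- sp$geometry$rg
  x <- (p$s * rg)^2
  debye <- 2 * (exp(-x) - 1 + x) / x^2
  expect_lt(max(abs(p$intensity / max(p$intensity) /
                      (debye / debye[1]) - 1)), 1e-8)
  expect_equal(saxsmm:::.intensity_debye(0, rg), 1, tolerance = 1e-12)
})

test_that("torus radius of gyration matches Monte-Carlo pair-distance sampling", {
  sp <- particle_spec("ring", 100, aspect = 3)
  rc <- sp$geometry$rc; a <- sp$geometry$a
  rg_mc <- oracle_torus_rg_mc(rc, a)
  p <- ideal_profile(sp, s_max = 0.2, n_points = 2000, poly = 0)
  g <- auto_guinier(p)
  expect_lt(abs(g$rg / rg_mc - 1), 0.01)
})

test_that("noise model hits the target SNR exactly and honours the seed contract", {
  p <- ideal_profile(particle_spec("compact", 94))
  for (snr in c(32, 1)) {
    noisy <- add_noise(p, snr, seed = 12)
    expect_equal(median(p$intensity) / median(noisy$sigma), snr,
                 tolerance = 1e-12)
  }
  n1 <- add_noise(p, 4, seed = 12)
  n2 <- add_noise(p, 4, seed = 12)
  n3 <- add_noise(p, 4, seed = 13)
  expect_identical(n1$intensity, n2$intensity)
  expect_false(identical(n1$intensity, n3$intensity))
  expect_identical(n1$sigma, n3$sigma)  # template is deterministic
})

test_that("rg survives heavy noise in most seeds", {
  R <- 30; rg_true <- sqrt(3 / 5) * R
  p <- ideal_profile(particle_spec("compact", 0.83e-3 * 4 / 3 * pi * R^3))
  ok <- vapply(1:100, function(seed) {
    g <- tryCatch(auto_guinier(add_noise(p, 1, seed)), error = function(e) NULL)
    !is.null(g) && abs(g$rg / rg_true - 1) < 0.15
  }, logical(1))
  expect_gte(mean(ok), 0.80)
})

test_that("buffer mismatch is a pure offset: identity at 0, exact inverse", {
  p <- add_noise(ideal_profile(particle_spec("compact", 94)), 4, seed = 5)
  same <- buffer_mismatch(p, 0, "over")
  expect_equal(same$intensity, p$intensity, tolerance = 1e-15)
  i_avg <- mean(p$intensity[p$s >= 0.4 & p$s <= 0.6])
  round_trip <- buffer_mismatch(buffer_mismatch(p, 0.4, "under"), 0.4, "over",
                                i_average = i_avg)
  expect_lt(max(abs(round_trip$intensity - p$intensity)) /
              max(abs(p$intensity)), 1e-12)
  expect_identical(round_trip$sigma, p$sigma)
  short <- ideal_profile(particle_spec("compact", 94), s_max = 0.3)
  expect_error(buffer_mismatch(short, 0.4, "over"), "high-angle")
})

test_that("generator volumes agree with the Porod route for near-globular bodies", {
  # unsmeared curves: the exact analytic volume is the reference
  for (spec in list(particle_spec("compact", 60),
                    particle_spec("compact", 200),
                    particle_spec("extended", 90, aspect = 2.5))) {
    p <- ideal_profile(spec, poly = 0)
    inv <- saxs_invariants(p)
    expect_lt(abs(inv$vp / spec$volume - 1), 0.03,
              label = sprintf("%s %.0f kDa", spec$shape_class, spec$mm))
  }
  # the default 3% size polydispersity perturbs the compact volume by ~1%
  pd <- saxs_invariants(ideal_profile(particle_spec("compact", 94)))
  expect_lt(abs(pd$vp / particle_spec("compact", 94)$volume - 1), 0.03)
})

test_that("corpus construction honours the split, condition set and round-trip", {
  corpus <- build_corpus(n_per_class = 50, seed = 21, n_points = 301)
  n_particles <- length(unique(c(corpus$train$id, corpus$test$id)))
  expect_equal(n_particles, 400)  # 7 classes x 50, compact doubled
  expect_equal(length(unique(corpus$train$id)), round(0.7 * 400))
  expect_length(intersect(unique(corpus$train$id), unique(corpus$test$id)), 0)
  # training: ideal + 4 milder noise levels; harshest level withheld
  expect_setequal(unique(corpus$train$condition),
                  c("ideal", "snr32", "snr11", "snr4", "snr2"))
  # test: exactly 16 condition variants per particle
  per_particle <- table(corpus$test$id)
  expect_true(all(per_particle == 16))
  expect_setequal(unique(corpus$test$condition),
                  c("ideal", "snr32", "snr11", "snr4", "snr2", "snr1",
                    paste0("over", c(0.1, 0.2, 0.4, 0.6, 0.9)),
                    paste0("under", c(0.1, 0.2, 0.4, 0.6, 0.9))))
  # reproducible under the seed
  corpus2 <- build_corpus(n_per_class = 50, seed = 21, n_points = 301)
  expect_equal(corpus2$test$mm, corpus$test$mm, tolerance = 1e-12)
  expect_equal(corpus2$test$profile[[7]]$intensity,
               corpus$test$profile[[7]]$intensity, tolerance = 1e-12)
  # every corpus profile round-trips through the text format
  path <- withr::local_tempfile(fileext = ".dat")
  prof <- corpus$test$profile[[3]]
  write_profile(prof, path)
  back <- read_profile(path)
  expect_lt(max(abs(back$intensity - prof$intensity) /
                  pmax(abs(prof$intensity), 1e-12)), 1e-6)
})
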