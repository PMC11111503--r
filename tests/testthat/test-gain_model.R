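test_that("gain equals 1 at t = 0 for random parameters and matches the direct form", {
  set.seed(101)
  for (i in 1:200) {
    d <- runif(1, 0, 5)
    sx <- runif(1, 0, 20)
    sy <- runif(1, 0, 20)
    gp <- gain_params(d, sx, sy)
    expect_equal(gamma_gain(0, gp), 1, tolerance = 1e-14)
    # moderate arguments where the naive two-term form is overflow-free
    tt <- runif(5, 0, 3)
    expect_equal(gamma_gain(tt, gp), gamma_direct(tt, d, sx, sy),
                 tolerance = 1e-12)
  }
})

test_that("zero slope gives constant unit gain; large-t limit matches closed form", {
  gp0 <- gain_params(d = 2, sx = 0, sy = 7)
  expect_equal(gamma_gain(c(0, 0.5, 1, 5, 100), gp0), rep(1, 5))
  # t -> inf limit: sy + (1 + (1 - sy) e^{-sx d}) / (1 + e^{-sx d})
  d <- 1; sx <- 2; sy <- 3
  lim <- sy + (1 + (1 - sy) * exp(-sx * d)) / (1 + exp(-sx * d))
  expect_equal(gamma_gain(1000, gain_params(d, sx, sy)), lim,
               tolerance = 1e-12)
  # overflow-safe for huge slope-time products
  expect_true(is.finite(gamma_gain(1e6, gain_params(1, 20, 5))))
})

test_that("gain is non-decreasing in t for sx >= 0, sy >= 1", {
  set.seed(7)
  tgrid <- seq(0, 5, by = 0.01)
  for (i in 1:25) {
    gp <- gain_params(runif(1, 0, 3), runif(1, 0, 15), runif(1, 1, 15))
    expect_true(all(diff(gamma_gain(tgrid, gp)) >= -1e-12))
  }
})

test_that("gain parameters are validated", {
  expect_error(gain_params(NA, 1, 1), "finite")
  expect_error(gain_params(0, -1, 1), "sx")
  expect_error(gamma_gain(Inf, gain_params(0, 1, 1)), "finite")
})

test_that("only the four canonical cases are constructible", {
  flags <- lapply(c("I", "II", "III", "IV"), model_case)
  expect_equal(
    vapply(flags, function(f) paste(f$gain_on_drift, f$gain_on_noise,
                                    f$noise_depends_on_coherence), ""),
    c("TRUE TRUE TRUE", "TRUE TRUE FALSE", "FALSE TRUE FALSE",
      "TRUE FALSE FALSE")
  )
  expect_equal(model_case("iv")$label, "IV")
  expect_equal(model_case(2)$label, "II")
  expect_error(model_case("V"), "unknown")
})

test_that("drift and noise follow the case flags", {
  mk <- function(case) model_spec(case, k = 2, sigma0 = 0.5, d = 0.3, sx = 4,
                                  sy = 3, t_res_mean = 0.3, t_res_sd = 0.05)
  tgrid <- seq(0, 2, by = 0.25)

  # zero coherence: zero drift regardless of gain
  expect_equal(drift_rate(tgrid, 0, mk("I")), rep(0, length(tgrid)))
  # gain identity at t = 0
  expect_equal(drift_rate(0, 0.5, mk("I")), 1.0)
  # case III: drift constant in t; others vary with t
  expect_equal(drift_rate(tgrid, 0.5, mk("III")), rep(1, length(tgrid)))
  # coherence-dependent noise doubles the variance at |c| = 1 (case I)
  expect_equal(noise_sd(0, 1, mk("I")), 0.5 * sqrt(2))
  expect_equal(noise_sd(0, -1, mk("I")), 0.5 * sqrt(2))
  for (case in c("II", "III", "IV")) {
    expect_equal(noise_sd(0, 1, mk(case)), 0.5)
  }
  # case IV: noise constant in t
  expect_equal(noise_sd(tgrid, 0.3, mk("IV")), rep(0.5, length(tgrid)))
  expect_error(drift_rate(0, 1.5, mk("I")), "coherence")
})

test_that("case flags fully determine time variation (finite differences)", {
  tgrid <- seq(0.1, 3, by = 0.1)
  for (case in c("I", "II", "III", "IV")) {
    spec <- model_spec(case, k = 2, sigma0 = 1, d = 0.3, sx = 4, sy = 3,
                       t_res_mean = 0.3, t_res_sd = 0.05)
    dvar <- max(abs(diff(drift_rate(tgrid, 0.5, spec))))
    nvar <- max(abs(diff(noise_sd(tgrid, 0.5, spec))))
    expect_equal(dvar > 1e-8, spec$case$gain_on_drift, label = case)
    expect_equal(nvar > 1e-8, spec$case$gain_on_noise, label = case)
  }
})

test_that("sx = 0 collapses the model to the standard time-constant DDM", {
  spec <- model_spec("I", k = 3, sigma0 = 1, d = 1, sx = 0, sy = 5,
                     t_res_mean = 0.3, t_res_sd = 0.05)
  tgrid <- seq(0, 5, by = 0.5)
  expect_equal(drift_rate(tgrid, 0.4, spec), rep(1.2, length(tgrid)))
  expect_equal(noise_sd(tgrid, 0.4, spec),
               rep(sqrt(1.4), length(tgrid)))
})

test_that("every case has exactly seven free parameters with fixed Z and x0", {
  for (case in c("I", "II", "III", "IV")) {
    spec <- model_spec(case, k = 1, sigma0 = 1, d = 0.5, sx = 1, sy = 1,
                       t_res_mean = 0.2, t_res_sd = 0.1)
    expect_length(free_params(spec), 7)
    expect_identical(spec$Z, 1)
    expect_identical(spec$x0, 0)
  }
  b <- default_bounds()
  expect_length(b$lower, 7)
  expect_length(b$upper, 7)
  expect_true(all(b$upper > b$lower))
})

test_that("model spec validation and JSON round trip", {
  expect_error(model_spec("I", k = 1, sigma0 = 0, d = 0, sx = 1, sy = 1,
                          t_res_mean = 0.1, t_res_sd = 0.1), "sigma0")
  expect_error(model_spec("I", k = 1, sigma0 = 1, d = 0, sx = 1, sy = 1,
                          t_res_mean = -1, t_res_sd = 0.1), "t_res_mean")
  spec <- model_spec("III", k = 4.25, sigma0 = 0.75, d = 0.125, sx = 6.5,
                     sy = 2.25, t_res_mean = 0.3125, t_res_sd = 0.0625)
  path <- withr::local_tempfile(fileext = ".json")
  spec_to_json(spec, path)
  back <- spec_from_json(path)
  expect_identical(free_params(back), free_params(spec))
  expect_identical(back$case$label, "III")
  # string round trip too
  expect_identical(free_params(spec_from_json(spec_to_json(spec))),
                   free_params(spec))
  # round trip through a free-parameter vector
  expect_identical(free_params(spec_from_params(free_params(spec), "III")),
                   free_params(spec))
})
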