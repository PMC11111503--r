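grid_default <- solver_grid()

test_that("solver grid validates its inputs", {
  expect_error(solver_grid(dt = 0), "dt")
  expect_error(solver_grid(dt = 0.013), "integer")
  expect_error(solver_grid(nx = 200), "odd")
  g <- solver_grid(dt = 0.005, t_max = 4)
  expect_equal(g$nt, 800L)
})

test_that("zero drift gives symmetric boundary densities and accuracy 0.5", {
  f <- solve_fptd(case_preset("II"), 0, grid_default)
  expect_lt(max(abs(f$f_upper - f$f_lower)), 1e-6)
  spec <- case_preset("II")
  s <- summarize_rt(convolve_residual(f, spec))
  expect_equal(s$accuracy, 0.5, tolerance = 1e-9)
  expect_equal(s$mean_rt_correct, s$mean_rt_error, tolerance = 1e-9)
})

test_that("constant-gain solver matches closed-form accuracy and mean decision time", {
  for (mu in c(1, 1.5)) {
    for (sig in c(0.8, 1.2)) {
      spec <- model_spec("IV", k = mu, sigma0 = sig, d = 0, sx = 0, sy = 1,
                         t_res_mean = 0, t_res_sd = 0)
      f <- solve_fptd(spec, 1, grid_default)
      mass_u <- sum(f$f_upper) * f$dt
      mass_l <- sum(f$f_lower) * f$dt
      acc <- mass_u / (mass_u + mass_l)
      mdt <- sum(f$t * (f$f_upper + f$f_lower)) * f$dt / (mass_u + mass_l)
      expect_equal(acc, ddm_accuracy_closed_form(mu, sig), tolerance = 1e-3)
      expect_equal(mdt, ddm_mean_dt_closed_form(mu, sig), tolerance = 1e-2)
    }
  }
})

test_that("probability is conserved on all shipped presets", {
  specs <- c(lapply(c("I", "II", "III", "IV"), case_preset),
             lapply(c("rat_like", "monkey_like", "human_like"),
                    function(lb) species_preset(lb)$spec))
  for (spec in specs) {
    for (cc in c(0, 0.1, 0.5)) {
      f <- solve_fptd(spec, cc, grid_default)
      total <- sum(f$f_upper + f$f_lower) * f$dt + f$survival
      expect_equal(total, 1, tolerance = 1e-3)
      expect_true(all(f$f_upper >= 0))
      expect_true(all(f$f_lower >= 0))
    }
  }
})

test_that("halving dt and dx leaves accuracy essentially unchanged", {
  fine <- solver_grid(dt = 0.005, t_max = 5, nx = 403)
  for (case in c("II", "IV")) {
    spec <- case_preset(case)
    acc <- function(g) {
      f <- solve_fptd(spec, 0.1, g)
      sum(f$f_upper) / sum(f$f_upper + f$f_lower)
    }
    expect_equal(acc(grid_default), acc(fine), tolerance = 5e-4)
  }
})

test_that("residual convolution preserves per-boundary mass and shifts means", {
  spec <- case_preset("II")
  f <- solve_fptd(spec, 0.1, grid_default)
  rt <- convolve_residual(f, spec)
  expect_equal(sum(rt$p_correct_rt) * rt$dt, sum(f$f_upper) * f$dt,
               tolerance = 1e-6)
  expect_equal(sum(rt$p_error_rt) * rt$dt, sum(f$f_lower) * f$dt,
               tolerance = 1e-6)
  expect_true(all(rt$p_correct_rt >= 0))

  # sd = 0: pure shift by the mean residual time
  spec0 <- model_spec("II", k = 10, sigma0 = 1, d = 0.35, sx = 6, sy = 3,
                      t_res_mean = 0.3, t_res_sd = 0)
  rt0 <- convolve_residual(solve_fptd(spec0, 0.1, grid_default), spec0)
  shift <- round(0.3 / grid_default$dt)
  expect_equal(rt0$p_correct_rt[(shift + 1):grid_default$nt],
               solve_fptd(spec0, 0.1, grid_default)$f_upper[
                 1:(grid_default$nt - shift)],
               tolerance = 1e-9)

  # Gaussian residual adds its mean to the mean RT (truncation negligible)
  spec1 <- model_spec("IV", k = 1, sigma0 = 1, d = 0, sx = 0, sy = 1,
                      t_res_mean = 0.3, t_res_sd = 0.05)
  f1 <- solve_fptd(spec1, 1, grid_default)
  mdt <- sum(f1$t * f1$f_upper) / sum(f1$f_upper)
  s1 <- summarize_rt(convolve_residual(f1, spec1))
  expect_equal(s1$mean_rt_correct, mdt + 0.3, tolerance = 2e-3)
})

test_that("constant gain equalizes correct and error mean RTs", {
  for (k in c(2, 6)) {
    spec <- model_spec("I", k = k, sigma0 = 1, d = 0.5, sx = 0, sy = 3,
                       t_res_mean = 0.3, t_res_sd = 0.05)
    s <- summarize_rt(convolve_residual(solve_fptd(spec, 0.2, grid_default),
                                        spec))
    expect_equal(s$mean_rt_correct, s$mean_rt_error, tolerance = 1e-2)
  }
})

test_that("gain placement dissociates error-vs-correct RT ordering", {
  s3 <- summarize_rt(convolve_residual(
    solve_fptd(case_preset("III"), 0.2, grid_default), case_preset("III")))
  s4 <- summarize_rt(convolve_residual(
    solve_fptd(case_preset("IV"), 0.2, grid_default), case_preset("IV")))
  # rising gain on noise only: late decisions are more error-prone
  expect_gt(s3$mean_rt_error, s3$mean_rt_correct)
  # rising gain on drift only: late decisions are more correct
  expect_lt(s4$mean_rt_error, s4$mean_rt_correct)
})

test_that("RT distribution exports to CSV with its exact numbers", {
  spec <- case_preset("I")
  rt <- convolve_residual(solve_fptd(spec, 0.1, grid_default), spec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_rt_dist(rt, path)
  back <- read.csv(path)
  expect_equal(back$t, rt$t)
  expect_equal(back$p_correct_rt, rt$p_correct_rt)
  expect_equal(back$p_error_rt, rt$p_error_rt)
})
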