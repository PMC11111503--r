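test_that("Kruskal-Wallis matches the hand-ranked example and handles edge cases", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  # ranks 1..6, rank sums 6 and 15: H = 12/42 * (36/3 + 225/3) - 21
  expect_equal(kw$H, 12 / 42 * (36 / 3 + 225 / 3) - 21, tolerance = 1e-10)
  expect_equal(kw$df, 1)
  # identical observations: defined as H = 0, p = 1
  kw0 <- kruskal_wallis(list(rep(2, 4), rep(2, 4)))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p_value, 1)
  # permutation of group order leaves H unchanged
  g <- list(a = c(3, 1, 4), b = c(1, 5, 9), c = c(2, 6, 5))
  expect_equal(kruskal_wallis(g)$H, kruskal_wallis(rev(g))$H)
  expect_error(kruskal_wallis(list(1:3)), "length")
  expect_error(kruskal_wallis(list(numeric(0), 1:3)), "non-empty")
})

test_that("Kruskal-Wallis H matches a brute-force rank oracle on random instances", {
  set.seed(2024)
  for (i in 1:60) {
    ng <- sample(2:4, 1)
    groups <- lapply(seq_len(ng), function(j) {
      round(runif(sample(2:4, 1), 0, 5), 1) # coarse values induce ties
    })
    if (length(unique(unlist(groups))) == 1) next
    expect_equal(kruskal_wallis(groups)$H, kw_brute_force(groups),
                 tolerance = 1e-10)
  }
})

test_that("Tukey HSD reports all pairs with family-wise adjusted p-values", {
  set.seed(5)
  base <- rnorm(18)
  four_same <- list(a = base, b = base, c = base, d = base)
  tk <- tukey_hsd(four_same)
  expect_equal(nrow(tk), 6) # 4 choose 2
  expect_true(all(tk$p_adj > 0.05))
  expect_true(all(tk$p_adj >= 0 & tk$p_adj <= 1))

  sep <- list(lo = rnorm(18, 0, 1), hi = rnorm(18, 10, 1))
  tk2 <- tukey_hsd(sep)
  expect_lt(tk2$p_adj[1], 0.05)
  expect_equal(tk2$diff[1], mean(sep$hi) - mean(sep$lo), tolerance = 1e-9)
  # independent studentized-range cross-check of the adjusted p-value
  n <- 18
  s2 <- (stats::var(sep$lo) + stats::var(sep$hi)) / 2
  q <- abs(mean(sep$hi) - mean(sep$lo)) / sqrt(s2 / n)
  expect_equal(tk2$p_adj[1], stats::ptukey(q, 2, 2 * (n - 1),
                                           lower.tail = FALSE),
               tolerance = 1e-6)
  expect_error(tukey_hsd(list(a = 1, b = c(1, 2))), ">= 2")
})

test_that("normalize_params maps ranges to [0, 1] with 0.5 for constants", {
  s1 <- model_spec("I", k = 1, sigma0 = 1, d = 0.2, sx = 2, sy = 1,
                   t_res_mean = 0.3, t_res_sd = 0.05)
  s2 <- model_spec("II", k = 3, sigma0 = 1, d = 0.6, sx = 8, sy = 4,
                   t_res_mean = 0.2, t_res_sd = 0.05)
  s3 <- model_spec("III", k = 2, sigma0 = 1, d = 0.4, sx = 5, sy = 2,
                   t_res_mean = 0.25, t_res_sd = 0.05)
  m <- normalize_params(list(I = s1, II = s2, III = s3))
  expect_equal(dim(m), c(3, 7))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(unname(m[, "k"]), c(0, 1, 0.5))       # endpoints and midpoint
  expect_equal(unname(m[, "sigma0"]), rep(0.5, 3))   # constant parameter
  expect_equal(unname(m[, "t_res_sd"]), rep(0.5, 3))
  # monotone: larger raw value gives larger normalized value
  expect_true(all(order(m[, "sy"]) == order(c(1, 4, 2))))
})

fake_fits <- function(label, sq, aic_shift = 0) {
  runs <- tibble::tibble(
    run = seq_along(sq), seed = seq_along(sq),
    neg_log_lik = 50 + seq_along(sq) + aic_shift,
    aic = 14 + 2 * (50 + seq_along(sq) + aic_shift),
    sq_error = sq, converged = TRUE
  )
  par <- free_params(case_preset(label))
  runs <- dplyr::bind_cols(runs, tibble::as_tibble(as.list(par)))
  structure(list(case = model_case(label), runs = runs,
                 specs = rep(list(case_preset(label)), length(sq)),
                 best = which.min(sq), best_spec = case_preset(label)),
            class = "ddm_fits")
}

test_that("compare_cases ranks by mean squared error with stable ties", {
  set.seed(9)
  noise <- rnorm(6, 0, 0.001)
  fits <- list(
    I = fake_fits("I", 0.05 + noise),
    II = fake_fits("II", 0.05 + noise),
    III = fake_fits("III", 0.08 + noise),
    IV = fake_fits("IV", 0.01 + noise)
  )
  rep <- compare_cases(fits)
  expect_s3_class(rep, "ddm_comparison")
  expect_equal(rep$best_case, "IV")
  expect_setequal(rep$ranking$case, c("I", "II", "III", "IV"))
  expect_equal(nrow(rep$tukey_sq_error), 6)
  # identical samples for I and II: stable-sorted by label
  expect_equal(rep$ranking$case[2:3], c("I", "II"))
  # permuting a case's samples does not change the ranking
  fits2 <- fits
  fits2$III$runs$sq_error <- rev(fits2$III$runs$sq_error)
  expect_equal(compare_cases(fits2)$ranking$case, rep$ranking$case)
  expect_error(compare_cases(fits["I"]), "at least 2")
})

test_that("identical squared-error distributions give omnibus p = 1", {
  sq <- c(0.02, 0.03, 0.04, 0.05, 0.06, 0.07)
  fits <- list(I = fake_fits("I", sq), II = fake_fits("II", sq),
               III = fake_fits("III", sq), IV = fake_fits("IV", sq))
  rep <- compare_cases(fits)
  expect_equal(rep$kruskal_sq_error$p_value, 1, tolerance = 1e-9)
  expect_true(all(rep$tukey_sq_error$p_adj > 0.05))
  # comparison report serializes
  path <- withr::local_tempfile(fileext = ".json")
  write_comparison(rep, path)
  doc <- jsonlite::fromJSON(path)
  expect_equal(doc$ranking$case, rep$ranking$case)
  txt <- withr::local_tempfile(fileext = ".txt")
  write_comparison(rep, txt)
  expect_true(any(grepl("best case", readLines(txt))))
})
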