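test_that("the proportion recursion conserves mass and hits closed forms", {
  params <- default_parameters()
  # no recruitment: everyone stays Prebreeder
  none <- parameter_set(
    phi = params$phi, p = params$p, delta = params$delta,
    psi = function(d) ifelse(paste0(d$from, d$to) == "PB", 0,
                             params$psi(d)),
    hr = params$hr, rh = params$rh)
  pr0 <- state_proportions(psi_schedule(none, "north"), 4, 20)
  expect_equal(pr0$P, rep(1, nrow(pr0)))
  expect_equal(pr0$B + pr0$J + pr0$N, rep(0, nrow(pr0)))

  # north recruitment schedule: cumulative recruitment by age 8 is
  # 1 - 0.9 * 0.485^4 (one age-3 step at 0.100 then 0.515 per year)
  pr <- state_proportions(psi_schedule(params, "north"), 4, 25)
  expect_equal(pr$P[pr$age == 8], 0.9 * 0.485^4, tolerance = 1e-12)
  expect_true(1 - pr$P[pr$age == 8] > 0.95)
  expect_equal(rowSums(pr[, c("P", "B", "J", "N")]), rep(1, nrow(pr)),
               tolerance = 1e-12)
  # J and N appear only after B is reachable
  expect_equal(pr$J[1], 0)
  expect_equal(pr$N[1], 0)
})

test_that("the recursion equals matrix-power propagation for random psi", {
  for (seed in 1:10) {
    params <- random_params(seed + 400)
    psif <- psi_schedule(params, "north")
    pr <- state_proportions(psif, 4, 30, const_after = 25)
    vec <- c(1, 0, 0, 0)
    for (a in 3:29) {
      vec <- drop(vec %*% psif(min(a, 25)))
      i <- match(a + 1, pr$age)
      if (!is.na(i))
        expect_equal(unlist(pr[i, c("P", "B", "J", "N")]), vec,
                     tolerance = 1e-12, ignore_attr = TRUE)
    }
    expect_equal(rowSums(pr[, c("P", "B", "J", "N")]), rep(1, nrow(pr)),
                 tolerance = 1e-12)
  }
})

test_that("the recursion matches large-sample chain simulation", {
  params <- random_params(99)
  psif <- psi_schedule(params, "north")
  pr <- state_proportions(psif, 4, 12)
  n <- 2e5
  emp <- simulate_chains(psif, 4, 12, n, seed = 123)
  expected <- unlist(pr[pr$age == 12, c("P", "B", "J", "N")])
  mc_se <- sqrt(pmax(expected * (1 - expected), 1e-12) / n)
  expect_true(all(abs(emp - expected) <= 3 * mc_se + 1e-12))
})

test_that("3-week pup survival composes weekly rates", {
  expect_equal(pup_survival_3wk(1, 1), 1)
  expect_equal(pup_survival_3wk(0.9, 0.95), 0.7695)
  expect_error(pup_survival_3wk(0, 0.9), "positive")
  # monotone in each argument
  expect_true(pup_survival_3wk(0.95, 0.9) > pup_survival_3wk(0.9, 0.9))
  expect_true(pup_survival_3wk(0.9, 0.95) > pup_survival_3wk(0.9, 0.9))
})

test_that("maternal-age trends calibrate to the published endpoints", {
  tr <- calibrate_linear_trend(0.76, 0.96)
  f <- function(a) maternal_age_trend("linear", tr, a)
  expect_equal(f(5), 0.76, tolerance = 1e-12)
  expect_equal(f(20), 0.96, tolerance = 1e-12)
  # constant form is flat
  expect_equal(maternal_age_trend("constant", 0.9, c(5, 12, 20)),
               rep(0.9, 3))
  # logit-linear and probability-linear agree at the endpoints and stay
  # within ~0.04 of each other in between (largest gap near the midpoint)
  trp <- calibrate_linear_trend(0.76, 0.96, scale = "prob")
  ages <- 5:20
  d <- abs(maternal_age_trend("linear", tr, ages) -
             maternal_age_trend("linear", trp, ages, scale = "prob"))
  expect_lt(max(d), 0.04)
  expect_equal(d[c(1, length(d))], c(0, 0), tolerance = 1e-12)
  # ages outside 5-20 are clamped with a warning
  expect_warning(v <- maternal_age_trend("linear", tr, 25), "clamped")
  expect_equal(v, 0.96, tolerance = 1e-12)
  expect_error(maternal_age_trend("cubic", 1, 10), "arg")
  # class forms
  expect_equal(maternal_age_trend("two-class", c(0.8, 0.9), c(6, 10)),
               c(0.8, 0.9))
  expect_equal(
    maternal_age_trend("three-class", c(0.8, 0.9, 0.85), c(6, 10, 18)),
    c(0.8, 0.9, 0.85))
  sp <- maternal_age_trend("spline", c("5" = 0.76, "12" = 0.9, "20" = 0.96),
                           c(5, 12, 20))
  expect_equal(sp, c(0.76, 0.9, 0.96), tolerance = 1e-12)
})

test_that("the neonatal correction divides by age-specific pup survival", {
  params <- default_parameters()
  pr <- state_proportions(psi_schedule(params, "south"), 5, 25)
  # identity survival: no change
  same <- correct_neonatal(pr, function(a) rep(1, length(a)))
  expect_equal(same$B_corrected, pr$B)
  # printed arithmetic: 0.38 / 0.76 = 0.50
  one <- pr[1, ]; one$B <- 0.38
  expect_equal(correct_neonatal(one, function(a) 0.76)$B_corrected, 0.5)
  zero <- pr[1, ]; zero$B <- 0
  expect_equal(correct_neonatal(zero, function(a) 0.8)$B_corrected, 0)
  expect_error(correct_neonatal(pr, function(a) rep(0, length(a))),
               "positive")
  # under the increasing calibrated trend the correction factor shrinks
  # with maternal age
  tr <- calibrate_linear_trend()
  cr <- correct_neonatal(pr, function(a)
    suppressWarnings(maternal_age_trend("linear", tr, a)))
  ratio <- cr$B_corrected / cr$B
  expect_true(all(diff(ratio) <= 1e-12))
  expect_true(all(cr$B_corrected >= cr$B))
})

test_that("bootstrap intervals are seed-deterministic and calibrated", {
  fake <- list(coefficients = c(mu = 0.3), vcov = matrix(1, 1, 1))
  ci <- bootstrap_derived_ci(fake, function(b) c(x = b[[1]]),
                             n_draws = 20000, seed = 5)
  ci2 <- bootstrap_derived_ci(fake, function(b) c(x = b[[1]]),
                              n_draws = 20000, seed = 5)
  expect_identical(ci, ci2)
  expect_equal(ci$lower, 0.3 - 1.96, tolerance = 0.05)
  expect_equal(ci$upper, 0.3 + 1.96, tolerance = 0.05)
  # zero covariance: width zero at the point estimate
  fake0 <- list(coefficients = c(mu = 0.3), vcov = matrix(0, 1, 1))
  ci0 <- bootstrap_derived_ci(fake0, function(b) c(x = b[[1]]),
                              n_draws = 1000, seed = 1)
  expect_equal(ci0$lower, 0.3)
  expect_equal(ci0$upper, 0.3)
  # failing derive draws beyond 1% abort
  expect_error(
    bootstrap_derived_ci(fake, function(b) if (b[[1]] > 0.3) stop("x")
                         else c(x = b[[1]]), n_draws = 500, seed = 1),
    "bootstrap draws failed")
})
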