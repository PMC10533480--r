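# Fitting, model selection, and the fitted-model utilities.

test_that("with perfect detection fitted psi equals observed frequencies", {
  # perfect-observation histories over three annual occasions: the MLE of
  # each multinomial transition row is the observed frequency (closed form)
  os <- build_occasion_structure(2001, 2003, 2001:2003)
  n <- 120
  an <- data.frame(animal_id = sprintf("A%03d", 1:n), cohort_year = 1997,
                   natal_rookery = "Forrester")
  set.seed(7)
  truth <- c(PB = 0.6, BJ = 0.3, BN = 0.1)
  s1 <- rep("P", n)
  step <- function(s) vapply(s, function(x)
    switch(x,
           P = sample(c("B", "P"), 1, prob = c(truth["PB"], 1 - truth["PB"])),
           B = sample(c("J", "N", "B"), 1,
                      prob = c(truth["BJ"], truth["BN"],
                               1 - truth["BJ"] - truth["BN"])),
           J = "J", N = "N"), character(1))
  s2 <- step(s1); s3 <- step(s2)
  code_of <- c(P = 1L, B = 2L, J = 3L, N = 1L)   # P/N can only be coded u
  codes <- cbind(0L, code_of[s2], code_of[s3])
  ch <- mvcjs:::capture_histories(codes, rep(1L, n), an, os)
  spec <- model_spec(
    phi = ~1, p = ~1, delta = ~1,
    psi = list(PB = ~1, BJ = ~1, BN = ~1, JB = ~1, JN = ~1, NB = ~1),
    hr = ~1, rh = ~1,
    fixed = list(list(par = "phi", cond = ~TRUE, value = 1),
                 list(par = "p", cond = ~TRUE, value = 1),
                 list(par = "delta", cond = ~TRUE, value = 1),
                 list(par = "hr", cond = ~TRUE, value = 0),
                 list(par = "rh", cond = ~TRUE, value = 0),
                 list(par = "psi", pair = "JB", cond = ~TRUE, value = 0),
                 list(par = "psi", pair = "JN", cond = ~TRUE, value = 0),
                 list(par = "psi", pair = "NB", cond = ~TRUE, value = 0)))
  fit <- suppressWarnings(fit_mvcjs(spec, ch, n_starts = 1,
                                    hessian = FALSE))
  pred <- predict_psi(fit, data.frame(age = 8, region = "south",
                                      cohort_class = "new", year = 2001))
  # empirical frequencies pooled over both intervals (the closed-form MLE
  # for a transition probability shared across years)
  f_pb <- (sum(s2[s1 == "P"] == "B") + sum(s3[s2 == "P"] == "B")) /
    (sum(s1 == "P") + sum(s2 == "P"))
  f_bj <- mean(s3[s2 == "B"] == "J")
  f_bn <- mean(s3[s2 == "B"] == "N")
  expect_equal(pred$PB, f_pb, tolerance = 1e-4)
  expect_equal(pred$BJ, f_bj, tolerance = 1e-4)
  expect_equal(pred$BN, f_bn, tolerance = 1e-4)
})

test_that("a single-state collapse recovers the binomial resighting MLE", {
  # one within-year period, survival 1, no transitions or movement: each of
  # the two post-release rookery days is an independent Bernoulli(p) and
  # the MLE is the observed proportion (the CJS closed form with phi = 1)
  os <- build_occasion_structure(2005, 2005)
  n <- 200
  an <- data.frame(animal_id = sprintf("B%03d", 1:n), cohort_year = 2005,
                   natal_rookery = "Hazy")
  set.seed(11)
  p_true <- 0.4
  seen <- matrix(rbinom(2 * n, 1, p_true), n, 2)
  codes <- cbind(0L, seen, 0L)
  ch <- mvcjs:::capture_histories(codes, rep(1L, n), an, os)
  spec <- model_spec(
    phi = ~1, p = ~1, delta = ~1,
    psi = list(PB = ~1, BJ = ~1, BN = ~1, JB = ~1, JN = ~1, NB = ~1),
    hr = ~1, rh = ~1,
    fixed = list(list(par = "rh", cond = ~TRUE, value = 0),
                 list(par = "hr", cond = ~TRUE, value = 0),
                 list(par = "delta", cond = ~TRUE, value = 1),
                 list(par = "phi", cond = ~TRUE, value = 1),
                 list(par = "psi", pair = "PB", cond = ~TRUE, value = 0),
                 list(par = "psi", pair = "BJ", cond = ~TRUE, value = 0),
                 list(par = "psi", pair = "BN", cond = ~TRUE, value = 0),
                 list(par = "psi", pair = "JB", cond = ~TRUE, value = 0),
                 list(par = "psi", pair = "JN", cond = ~TRUE, value = 0),
                 list(par = "psi", pair = "NB", cond = ~TRUE, value = 0)))
  fit <- suppressWarnings(fit_mvcjs(spec, ch, n_starts = 1,
                                    hessian = FALSE))
  p_hat <- plogis(coef(fit)[["p:(Intercept)"]])
  expect_equal(p_hat, mean(seen), tolerance = 1e-5)
})

test_that("the AIC identity, table ordering and near-tie flag hold", {
  f <- function(ll, k) structure(list(logLik = ll, npar = k,
                                      AIC = -2 * ll + 2 * k,
                                      data_id = c(1, 1, 1)),
                                 class = "mvcjs_fit")
  fits <- list(big = f(-100, 6), small = f(-100, 5))
  tab <- aic_table(fits)
  expect_equal(tab$model, c("small", "big"))
  expect_equal(tab$dAIC, c(0, 2))
  expect_true(tab$preferred[1])
  expect_false(tab$preferred[2])
  expect_equal(AIC(fits$big), 212)
  # single fit
  tab1 <- aic_table(fits["big"])
  expect_equal(tab1$dAIC, 0)
  # mixed datasets are rejected
  other <- f(-90, 5); other$data_id <- c(2, 1, 1)
  expect_error(aic_table(list(f(-100, 5), other)), "different datasets")
})

test_that("Akaike weights follow the closed form and sum to one", {
  expect_error(aic_weights(list()), "empty")
  expect_equal(unname(aic_weights(c(100))), 1)
  w <- aic_weights(c(100, 102))
  expect_equal(unname(w), c(0.7311, 0.2689), tolerance = 1e-4)
  expect_equal(sum(w), 1)
  expect_equal(unname(aic_weights(c(50, 50))), c(0.5, 0.5))
})

test_that("the generating model wins AIC selection against overfitting", {
  # simulated truth has no region effect on J transitions; the generating
  # spec should beat a larger spec adding one (or tie within the near-tie
  # band and be preferred on parameters)
  scen <- recovery_scenario(21, n_per = 30, last_year = 2012)
  ch <- simulate_population(scen)$truth$histories
  s0 <- recovery_spec()
  s1 <- s0
  s1$psi$JB <- ~region
  s1$psi$NB <- ~region
  f0 <- suppressWarnings(fit_mvcjs(s0, ch, n_starts = 1, hessian = FALSE))
  f1 <- suppressWarnings(fit_mvcjs(s1, ch, n_starts = 1, hessian = FALSE))
  tab <- aic_table(list(generating = f0, extra = f1))
  expect_true(tab$preferred[tab$model == "generating"])
})
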