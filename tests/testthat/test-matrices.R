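rookery_occ <- list(year = 2008, within = 1, type = "rookery_day")

test_that("emission matrices encode detection and state uncertainty", {
  params <- default_parameters()
  E <- emission_matrix(params, rookery_occ,
                       list(age = 8, nr = "Forrester", sb = FALSE))
  expect_equal(rowSums(E), rep(1, 9))
  # With-Pup at Forrester: p = 0.456, delta_B = 0.34
  expect_equal(E[state_index("B", "R"), ],
               c(1 - 0.456, 0.456 * 0.66, 0.456 * 0.34, 0),
               tolerance = 1e-12, ignore_attr = TRUE)
  # Prebreeder 4+ and No-Dependent emit only 0 / u
  expect_equal(unname(E[state_index("P", "R"), 3:4]), c(0, 0))
  expect_equal(unname(E[state_index("N", "R"), 3:4]), c(0, 0))
  # haulout states cannot be seen at a rookery occasion
  for (r in c("P", "B", "J", "N"))
    expect_equal(unname(E[state_index(r, "H"), 1]), 1)
  # Dead emits "not seen" with certainty
  expect_equal(unname(E[mvcjs:::DEAD, ]), c(1, 0, 0, 0))

  # p = 0 everywhere: every live row emits 0 with probability 1
  p0 <- parameter_set(phi = params$phi, p = function(d) rep(0, nrow(d)),
                      delta = params$delta, psi = params$psi,
                      hr = params$hr, rh = params$rh)
  E0 <- emission_matrix(p0, rookery_occ,
                        list(age = 8, nr = "Hazy", sb = FALSE))
  expect_equal(unname(E0[, 1]), rep(1, 9))

  # with delta = 1 the uncertain code is impossible for B/J states
  d1 <- parameter_set(phi = params$phi, p = params$p,
                      delta = function(d) rep(1, nrow(d)), psi = params$psi,
                      hr = params$hr, rh = params$rh)
  E1 <- emission_matrix(d1, rookery_occ,
                        list(age = 8, nr = "Hazy", sb = FALSE))
  expect_equal(unname(E1[state_index("B", "R"), 2]), 0)
  expect_equal(unname(E1[state_index("J", "R"), 2]), 0)
})

test_that("transition matrices apply survival, psi and movement in order", {
  params <- default_parameters()
  os <- build_occasion_structure(2007, 2009)
  iv <- os$intervals
  # all flags false (rookery day 1 -> day 2): identity
  T_id <- transition_matrix(params, iv[1, ],
                            list(age = 8, nr = "Forrester",
                                 cohort_class = "new"))
  expect_equal(T_id, diag(9))
  # between-year interval, Table-2 arithmetic: N -> B pooled over location
  Tb <- transition_matrix(params, iv[iv$between_year, ][1, ],
                          list(age = 8, nr = "Forrester",
                               cohort_class = "new"))
  expect_equal(rowSums(Tb), rep(1, 9))
  expect_equal(sum(Tb[state_index("N", "R"), c(2, 6)]), 0.93 * 0.857,
               tolerance = 1e-12)
  # inadmissible transitions are structural zeros
  for (cc in c("new", "old")) {
    ps <- psi_matrix(params, list(age = 10, region = "north",
                                  cohort_class = cc, year = 2008))
    expect_equal(rowSums(ps), rep(1, 4), ignore_attr = TRUE)
    expect_equal(unname(ps["P", c("J", "N")]), c(0, 0))
    expect_equal(unname(ps[c("B", "J", "N"), "P"]), c(0, 0, 0))
    expect_equal(unname(ps["N", "J"]), 0)
  }
  # rookery-to-haulout movement only on the day-3 -> haulout interval
  w34 <- which(iv$movement_RtoH_allowed)[1]
  Tm <- transition_matrix(params, iv[w34, ],
                          list(age = 8, nr = "Forrester",
                               cohort_class = "new"))
  expect_equal(unname(Tm[state_index("B", "R"), state_index("B", "H")]),
               0.009)
  expect_equal(unname(Tm[state_index("B", "H"), state_index("B", "H")]), 1)
  expect_equal(rowSums(Tm), rep(1, 9))
})

test_that("all matrix rows are stochastic across random parameter sets", {
  os <- build_occasion_structure(2003, 2006, 2003:2004)
  for (seed in 1:25) {
    params <- random_params(seed)
    cov <- list(age = sample(0:20, 1), nr = sample(mvcjs:::ROOKERIES, 1),
                sb = sample(c(TRUE, FALSE), 1),
                cohort_class = sample(c("old", "new"), 1))
    t <- sample(nrow(os$occasions), 1)
    E <- emission_matrix(params, os$occasions[t, ], cov)
    expect_true(max(abs(rowSums(E) - 1)) < 1e-12)
    expect_true(all(E >= 0))
    k <- sample(nrow(os$intervals), 1)
    T9 <- transition_matrix(params, os$intervals[k, ], cov)
    expect_true(max(abs(rowSums(T9) - 1)) < 1e-12)
    expect_true(all(T9 >= 0))
    expect_equal(unname(T9[mvcjs:::DEAD, mvcjs:::DEAD]), 1)
  }
})

test_that("a psi row that would exceed 1 is rejected", {
  params <- default_parameters()
  bad <- parameter_set(
    phi = params$phi, p = params$p, delta = params$delta,
    psi = function(d) rep(0.6, nrow(d)),    # B row: 0.6 + 0.6 > 1
    hr = params$hr, rh = params$rh)
  expect_error(psi_row(bad, "B", list(age = 8, region = "north",
                                      cohort_class = "new", year = 2008)),
               "exceeds 1")
})
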