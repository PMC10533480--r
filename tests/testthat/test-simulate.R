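test_that("the simulator is seed-deterministic", {
  scen <- recovery_scenario(9, n_per = 5, last_year = 2008)
  s1 <- simulate_population(scen)
  s2 <- simulate_population(scen)
  expect_identical(s1$sightings, s2$sightings)
  expect_identical(s1$truth$states, s2$truth$states)
  s3 <- simulate_population(scen, seed = 10)
  expect_false(identical(s1$truth$states, s3$truth$states))
})

test_that("perfect detection shows every animal at every rookery day", {
  perfect <- parameter_set(
    phi = function(d) rep(1, nrow(d)),
    p = function(d) rep(1, nrow(d)),
    delta = function(d) rep(1, nrow(d)),
    psi = recovery_params()$psi,
    hr = function(d) rep(1, nrow(d)),
    rh = function(d) rep(0, nrow(d)))
  os <- build_occasion_structure(2005, 2008)
  coh <- data.frame(cohort_year = 2005, natal_rookery = "WhiteSisters",
                    n = 20)
  sim <- simulate_population(simulation_scenario(perfect, os, coh,
                                                 seed = 3, triad_rate = 0))
  ch <- sim$truth$histories
  occ <- os$occasions
  rook <- which(occ$type == "rookery_day")
  for (a in seq_len(nrow(ch$animals))) {
    after <- rook[rook > ch$release[a]]
    expect_true(all(ch$codes[a, after] != 0L))
  }
  # definitive codes whenever the state is observable: B and J states are
  # always resolved, P and N yield the uncertain code
  st <- sim$truth$states
  expected <- c(P = 1L, B = 2L, J = 3L, N = 1L)
  for (t in rook) {
    live <- which(!is.na(st[, t]) & st[, t] <= 8L & ch$release < t)
    expect_equal(ch$codes[live, t],
                 unname(expected[state_repro(st[live, t])]))
  }
})

test_that("empirical transition frequencies match the generating psi", {
  scen <- recovery_scenario(13, n_per = 250, last_year = 2012) # 5000 females
  sim <- simulate_population(scen)
  st <- sim$truth$states
  occ <- scen$structure$occasions
  yrs <- unique(occ$year)
  lastocc <- vapply(yrs, function(y) max(which(occ$year == y)), integer(1))
  from <- character(0); to <- character(0)
  for (k in seq_len(length(yrs) - 1L)) {
    s1 <- st[, lastocc[k]]; s2 <- st[, lastocc[k + 1L]]
    ok <- !is.na(s1) & !is.na(s2) & s1 <= 8L & s2 <= 8L
    from <- c(from, state_repro(s1[ok]))
    to <- c(to, state_repro(s2[ok]))
  }
  check <- function(f, t, p_true) {
    n <- sum(from == f)
    phat <- mean(to[from == f] == t)
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(phat - p_true), 3 * se + 1e-12)
  }
  check("N", "B", 0.857)
  check("J", "B", 0.483)
  check("J", "N", 0.188)
  check("B", "J", 0.25)
  # structural zeros never occur
  expect_equal(sum(from == "N" & to == "J"), 0)
  expect_equal(sum(from != "P" & to == "P"), 0)
})

test_that("the study-calibrated scenario reproduces its seed values", {
  scen <- scenario_from_paper_defaults()
  d <- data.frame(from = "N", to = "B", age = 8, region = "north",
                  cohort_class = "new", year = 2008)
  expect_equal(scen$params$psi(d), 0.857)
  for (f in c("P", "B", "J", "N"))
    expect_equal(sum(psi_row(scen$params, f,
                             list(age = 8, region = "south",
                                  cohort_class = "new", year = 2008))), 1)
  expect_equal(scen$params$hr(data.frame(repro = "B", age = 9,
                                         year = 2008)), 0.829)
  expect_equal(nrow(scen$cohorts), 14)   # marked release groups
  expect_equal(sum(scen$cohorts$n), 1262)
  # the scenario's recursion puts peak-age pup production in a plausible
  # band
  pr <- state_proportions(psi_schedule(scen$params, "north"), 4, 25)
  expect_gt(pr$B[pr$age == 12], 0.5)
  expect_lt(pr$B[pr$age == 12], 0.75)
})

test_that("heatwave effects lower survival and pup production", {
  base <- default_parameters(pmh_effects = FALSE)
  pmh <- default_parameters(pmh_effects = TRUE)
  d <- data.frame(age = 10, nr = "Forrester", region = "south",
                  year = 2015, repro = "B")
  expect_lt(pmh$phi(data.frame(d[1:4], year = 2014, repro = "B")),
            base$phi(data.frame(d[1:4], year = 2014, repro = "B")))
  dpsi <- data.frame(from = "N", to = "B", age = 10, region = "south",
                     cohort_class = "new", year = 2016)
  expect_lt(pmh$psi(dpsi), base$psi(dpsi))
  dpsi$year <- 2010
  expect_equal(pmh$psi(dpsi), base$psi(dpsi))
})
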