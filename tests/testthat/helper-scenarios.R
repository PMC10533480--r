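# Shared fixtures: generating truths, matching specifications, and the
# independent oracles used across the suite.  Everything is built in code.

# --- compact generating truth used for fitting / recovery experiments -----

recovery_params <- function() {
  pg <- c(juvR = 0.35, wpR = 0.50, wjR = 0.30, ndR = 0.45, pbR = 0.40,
          juvH = 0.30, pnH = 0.55, bjH = 0.28)
  parameter_set(
    phi = function(d)
      unname(c(a0 = 0.57, a1 = 0.76, a2 = 0.86, a3_15 = 0.93,
               a16_17 = 0.87, a18p = 0.78)[as.character(phi_age_class(d$age))]),
    p = function(d) unname(pg[as.character(d$group)]),
    delta = function(d) ifelse(d$repro == "B", 0.40, 0.56),
    psi = function(d) {
      key <- paste0(d$from, d$to)
      rec <- ifelse(d$region == "north",
                    ifelse(d$age < 3, 0, ifelse(d$age == 3, 0.100, 0.515)),
                    ifelse(d$age < 4, 0, ifelse(d$age == 4, 0.264, 0.515)))
      v <- numeric(nrow(d))
      v[key == "PB"] <- rec[key == "PB"]
      v[key == "BJ"] <- 0.25
      v[key == "BN"] <- 0.05
      v[key == "JB"] <- 0.483
      v[key == "JN"] <- 0.188
      v[key == "NB"] <- 0.857
      unname(v)
    },
    hr = function(d) rep(0.75, nrow(d)),
    rh = function(d) rep(0.15, nrow(d)))
}

# link-scale truth under the cell-mean specification below
recovery_truth_beta <- function() {
  c(qlogis(c(0.57, 0.76, 0.86, 0.93)),
    qlogis(c(0.35, 0.50, 0.30, 0.45, 0.40, 0.30, 0.55, 0.28)),
    qlogis(c(0.40, 0.56)),
    qlogis(c(0.100, 0.264, 0.515)),
    log(0.25 / 0.70), log(0.05 / 0.70),
    log(0.483 / 0.329), log(0.188 / 0.329),
    log(0.857 / 0.143),
    qlogis(0.75), qlogis(0.15))
}

recovery_spec <- function() {
  model_spec(
    phi = ~0 + ac, p = ~0 + group, delta = ~0 + repro,
    psi = list(
      PB = ~0 + I(as.numeric(region == "north" & age == 3)) +
        I(as.numeric(region == "south" & age == 4)) +
        I(as.numeric((region == "north" & age >= 4) |
                       (region == "south" & age >= 5))),
      BJ = ~1, BN = ~1, JB = ~1, JN = ~1, NB = ~1),
    hr = ~1, rh = ~1,
    fixed = list(
      list(par = "psi", pair = "PB", cond = ~age < 3, value = 0),
      list(par = "psi", pair = "PB", cond = ~region == "south" & age == 3,
           value = 0)))
}

recovery_scenario <- function(seed, n_per = 50, last_year = 2015) {
  os <- build_occasion_structure(2001, last_year, 2001:2004)
  coh <- expand.grid(cohort_year = 2001:2005,
                     natal_rookery = mvcjs:::ROOKERIES, stringsAsFactors = FALSE)
  coh$n <- n_per
  simulation_scenario(recovery_params(), os, coh, seed = seed,
                      triad_rate = 0)
}

# --- random admissible parameter sets (constant in covariates) ------------

random_params <- function(seed) {
  set.seed(seed)
  pg <- setNames(runif(8, 0.1, 0.9), mvcjs:::RESIGHT_GROUPS)
  dB <- runif(1, 0.2, 0.9); dJ <- runif(1, 0.2, 0.9)
  phi <- runif(1, 0.5, 0.98)
  row_b <- as.numeric(c(stats::rbeta(1, 2, 4), stats::rbeta(1, 1, 8)))
  row_b <- row_b / max(1.2, sum(row_b) * 1.3)     # keep stay positive
  row_j <- as.numeric(c(stats::rbeta(1, 2, 3), stats::rbeta(1, 1, 6)))
  row_j <- row_j / max(1.2, sum(row_j) * 1.3)
  pb <- runif(1, 0.05, 0.7); nb <- runif(1, 0.1, 0.9)
  hr <- runif(1); rh <- runif(1)
  parameter_set(
    phi = function(d) rep(phi, nrow(d)),
    p = function(d) unname(pg[as.character(d$group)]),
    delta = function(d) ifelse(d$repro == "B", dB, dJ),
    psi = function(d) {
      key <- paste0(d$from, d$to)
      v <- numeric(nrow(d))
      v[key == "PB"] <- pb
      v[key == "BJ"] <- row_b[1]; v[key == "BN"] <- row_b[2]
      v[key == "JB"] <- row_j[1]; v[key == "JN"] <- row_j[2]
      v[key == "NB"] <- nb
      v
    },
    hr = function(d) rep(hr, nrow(d)),
    rh = function(d) rep(rh, nrow(d)))
}

# --- independent oracles ---------------------------------------------------

# per-animal matrices via the single-matrix constructors (independent of the
# batched likelihood path)
animal_matrices <- function(params, ch, a) {
  os <- ch$structure
  an <- ch$animals[a, ]
  rel <- ch$release[a]
  nocc <- ncol(ch$codes)
  Ts <- lapply(seq_len(nocc - 1L), function(k)
    transition_matrix(params, os$intervals[k, ],
                      list(age = max(0, os$intervals$year[k] - an$cohort_year),
                           nr = an$natal_rookery,
                           cohort_class = an$cohort_class)))
  Es <- lapply(seq_len(nocc), function(t)
    emission_matrix(params, os$occasions[t, ],
                    list(age = max(0, os$occasions$year[t] - an$cohort_year),
                         nr = an$natal_rookery, sb = ch$sb[a, t])))
  list(Ts = Ts, Es = Es, rel = rel)
}

# exhaustive hidden-path enumeration of one animal's likelihood
brute_loglik <- function(params, ch, a) {
  m <- animal_matrices(params, ch, a)
  nocc <- ncol(ch$codes)
  if (m$rel >= nocc) return(0)
  L <- nocc - m$rel
  paths <- as.matrix(expand.grid(rep(list(1:9), L)))
  pr <- rep(1, nrow(paths))
  prev <- rep(state_index("P", "R"), nrow(paths))
  for (j in seq_len(L)) {
    t <- m$rel + j
    pr <- pr * m$Ts[[t - 1L]][cbind(prev, paths[, j])]
    pr <- pr * m$Es[[t]][cbind(paths[, j], ch$codes[a, t] + 1L)]
    prev <- paths[, j]
  }
  log(sum(pr))
}

# sample a random small instance (structure, params, 1-3 animals with codes
# drawn from the true process via the single-matrix path)
random_instance <- function(seed) {
  set.seed(seed)
  os <- switch(sample(4, 1),
               build_occasion_structure(2005, 2005),
               build_occasion_structure(2003, 2005, 2003:2004),
               build_occasion_structure(2001, 2004, 2001:2004),
               build_occasion_structure(2004, 2005, 2004))
  params <- random_params(seed + 1000L)
  n <- sample(1:3, 1)
  cohort <- sample(c(1998:2001), n, replace = TRUE)
  nr <- sample(mvcjs:::ROOKERIES, n, replace = TRUE)
  nocc <- nrow(os$occasions)
  release <- sample(seq_len(nocc), n, replace = TRUE)
  animals <- data.frame(animal_id = paste0("X", seq_len(n)),
                        cohort_year = cohort, natal_rookery = nr)
  codes <- matrix(0L, n, nocc)
  ch0 <- mvcjs:::capture_histories(codes, release, animals, os)
  for (a in seq_len(n)) {
    m <- animal_matrices(params, ch0, a)
    s <- state_index("P", "R")
    t <- release[a]
    while (t < nocc) {
      t <- t + 1L
      s <- sample(9, 1, prob = m$Ts[[t - 1L]][s, ])
      # recompute emissions with the sb implied by codes so far
      sbt <- {
        occ <- os$occasions
        occ$type[t] == "rookery_day" && occ$within[t] > 1L &&
          any(codes[a, occ$year == occ$year[t] & occ$type == "rookery_day" &
                      occ$within < occ$within[t]] != 0L)
      }
      E <- emission_matrix(params, os$occasions[t, ],
                           list(age = max(0, os$occasions$year[t] - cohort[a]),
                                nr = nr[a], sb = sbt))
      codes[a, t] <- sample(4, 1, prob = E[s, ]) - 1L
    }
  }
  list(params = params,
       ch = mvcjs:::capture_histories(codes, release, animals, os))
}

# empirical chain-state distribution oracle for the proportion recursion
simulate_chains <- function(psifun, a0, max_age, n_chains, seed) {
  set.seed(seed)
  state <- rep(1L, n_chains)                  # everyone Prebreeder
  for (a in (a0 - 1L):(max_age - 1L)) {
    m <- psifun(a)
    newstate <- state
    for (f in 1:4) {
      idx <- which(state == f)
      if (length(idx))
        newstate[idx] <- sample(4, length(idx), replace = TRUE,
                                prob = m[f, ])
    }
    state <- newstate
  }
  tabulate(state, 4) / n_chains
}

write_sightings_fixture <- function(dir = tempdir()) {
  sg <- data.frame(
    animal_id = c("F01", "F01", "F02"),
    date = c("2008-06-25", "2008-06-30", "2008-07-10"),
    site_id = c("Forrester", "Forrester", "haulout_1"),
    site_type = c("R", "R", "H"),
    evidence = c("suckle", "none", "none"),
    photo_confirmed = c(1, 1, 1))
  an <- data.frame(animal_id = c("F01", "F02"),
                   cohort_year = c(2001, 2002),
                   natal_rookery = c("Forrester", "WhiteSisters"))
  sp <- file.path(dir, "sightings.csv"); ap <- file.path(dir, "animals.csv")
  write.csv(sg, sp, row.names = FALSE)
  write.csv(an, ap, row.names = FALSE)
  list(sightings = sp, animals = ap, sg = sg, an = an)
}
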