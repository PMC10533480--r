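#' Define a simulation scenario
#'
#' A scenario bundles a generating [parameter_set()], an occasion structure,
#' release cohorts, and the bookkeeping knobs of the generative model.
#'
#' @param params the generating truth, a [parameter_set()].
#' @param structure an [build_occasion_structure()] result.
#' @param cohorts data frame with `cohort_year`, `natal_rookery`, `n`
#'   (release sizes per cohort and rookery).
#' @param calendar the [survey_calendar()] used to stamp sighting dates.
#' @param seed integer; fully determines the simulation output.
#' @param triad_rate per female-year probability that a With-Juvenile female
#'   simultaneously attends a newborn pup (a "triad"), in which case her
#'   detected offspring may be recorded as a pup; exercises the encoder's
#'   replacement rule.  Default 0.02.
#' @param old_entry_year study-era entry year for the 1994-1995 cohorts:
#'   survivors to this year enter the dataset in the pseudo-Prebreeder state
#'   at its first occasion.
#' @return list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(params, structure, cohorts,
                                calendar = survey_calendar(), seed = 1L,
                                triad_rate = 0.02, old_entry_year = 2005L) {
  stopifnot(inherits(params, "parameter_set"),
            inherits(structure, "occasion_structure"),
            all(c("cohort_year", "natal_rookery", "n") %in% names(cohorts)),
            all(cohorts$n >= 0), triad_rate >= 0, triad_rate <= 1)
  new_c <- cohorts$cohort_year[cohorts$cohort_year > 1995]
  if (length(new_c) && any(!new_c %in% structure$years))
    stop("cohort year(s) not covered by the occasion structure: ",
         paste(setdiff(new_c, structure$years), collapse = ", "))
  structure(list(params = params, structure = structure,
                 cohorts = cohorts[cohorts$n > 0, , drop = FALSE],
                 calendar = calendar, seed = as.integer(seed),
                 triad_rate = triad_rate,
                 old_entry_year = as.integer(old_entry_year)),
            class = "simulation_scenario")
}

#' Simulate a marked population through the full generative model
#'
#' Each female is released in the (Prebreeder, rookery) state at her release
#' occasion; hidden states propagate by the between-occasion transition
#' matrices (survival, reproductive transitions, movement) and observations
#' are drawn from the emission matrices (state-dependent resighting,
#' imperfect offspring detection), with the seen-before-this-year covariate
#' updated sequentially.  Old-cohort females run the survival schedule from
#' birth; survivors to `old_entry_year` enter as pseudo-Prebreeders at its
#' first occasion with a guaranteed entry sighting.
#'
#' @param scenario a [simulation_scenario()].
#' @param seed overrides `scenario$seed` if given.
#' @return list with `sightings` and `animals` data frames (the encoder's
#'   input schema), and `truth`: hidden `states` (n x occasions; 9 = dead,
#'   NA before release), the simulator's own occasion-aligned `codes`
#'   matrix, `release` indices, and `histories` (the truth encoded directly
#'   as a `capture_histories` object, bypassing the record path).
#' @export
simulate_population <- function(scenario, seed = scenario$seed) {
  set.seed(seed)
  params <- scenario$params
  os <- scenario$structure
  occ <- os$occasions
  nocc <- nrow(occ)
  coh <- scenario$cohorts
  animals <- data.frame(
    animal_id = character(0), cohort_year = integer(0),
    natal_rookery = character(0))
  for (i in seq_len(nrow(coh)))
    animals <- rbind(animals, data.frame(
      animal_id = sprintf("%s%d_%03d", substr(coh$natal_rookery[i], 1, 2),
                          coh$cohort_year[i], seq_len(coh$n[i])),
      cohort_year = coh$cohort_year[i],
      natal_rookery = coh$natal_rookery[i]))
  n <- nrow(animals)
  animals$region <- natal_region(animals$natal_rookery)

  st <- make_strata(os, sort(unique(animals$cohort_year)),
                    sort(unique(animals$natal_rookery)))
  vals <- values_from_params(params, st)
  E <- build_emission_array(vals$pv, vals$dB, vals$dJ, st$estrat$occtype)
  Tarr <- build_transition_array(vals$phiv, vals$psiv, vals$hrv, vals$rhv,
                                 st$tstrat)

  # release occasions; old-cohort females must first survive to entry
  release <- rep(NA_integer_, n)
  new_idx <- which(animals$cohort_year > 1995)
  release[new_idx] <- first_occasion_of_year(
    os, animals$cohort_year[new_idx])
  old_idx <- which(animals$cohort_year <= 1995)
  if (length(old_idx)) {
    entry_occ <- first_occasion_of_year(os, scenario$old_entry_year)
    if (is.na(entry_occ))
      stop("old_entry_year not covered by the occasion structure")
    for (a in old_idx) {
      yrs <- animals$cohort_year[a]:(scenario$old_entry_year - 1L)
      s_ann <- check_prob(params$phi(data.frame(
        age = yrs - animals$cohort_year[a], nr = animals$natal_rookery[a],
        region = animals$region[a], year = yrs, repro = "P")), "phi")
      if (all(runif(length(s_ann)) < s_ann)) release[a] <- entry_occ
    }
  }

  states <- matrix(NA_integer_, n, nocc)
  codes <- matrix(0L, n, nocc)
  alive_rel <- !is.na(release)
  states[cbind(which(alive_rel), release[alive_rel])] <-
    state_index("P", "R")
  seen_rook <- rep(FALSE, n)       # seen earlier this year at a rookery
  sbmat <- matrix(FALSE, n, nocc)
  for (t in seq_len(nocc)) {
    if (t > 1L && occ$year[t] != occ$year[t - 1L]) seen_rook[] <- FALSE
    if (t > 1L) {
      act <- which(alive_rel & release < t)
      if (length(act)) {
        tid <- transition_id(st, t - 1L, animals$cohort_year[act],
                             animals$natal_rookery[act])
        pr <- matrix(0, length(act), N_STATES)
        for (j in seq_len(N_STATES))
          pr[, j] <- Tarr[cbind(tid, states[act, t - 1L], j)]
        states[act, t] <- sample_categorical(pr, runif(length(act)))
      }
    }
    obs_now <- which(alive_rel & release < t & !is.na(states[, t]))
    if (length(obs_now)) {
      sbmat[obs_now, t] <- occ$type[t] == "rookery_day" &
        occ$within[t] > 1L & seen_rook[obs_now]
      eid <- emission_id(st, t, animals$cohort_year[obs_now],
                         animals$natal_rookery[obs_now], sbmat[obs_now, t])
      pr <- matrix(0, length(obs_now), 4L)
      for (c in 1:4) pr[, c] <- E[cbind(eid, states[obs_now, t], c)]
      codes[obs_now, t] <- sample_categorical(pr, runif(length(obs_now))) - 1L
    }
    if (occ$type[t] == "rookery_day") seen_rook[codes[, t] != 0L] <- TRUE
  }

  # evidence records; triad years may record pup evidence for J females
  ev <- matrix("", n, nocc)
  ev[codes == 1L] <- "none"
  ev[codes == 2L] <- "pup"
  ev[codes == 3L] <- "juvenile"
  if (scenario$triad_rate > 0) {
    for (y in unique(occ$year)) {
      cols <- which(occ$year == y)
      jdet <- which(rowSums(codes[, cols, drop = FALSE] == 3L) > 0L)
      if (!length(jdet)) next
      triad <- jdet[runif(length(jdet)) < scenario$triad_rate]
      for (a in triad) {
        jc <- cols[codes[a, cols] == 3L]
        flip <- jc[runif(length(jc)) < 0.5]
        ev[a, flip] <- "pup"
      }
    }
  }
  # the simulator's own code matrix follows the recording rules: codes from
  # evidence, then the yearly triad replacement
  sim_codes <- matrix(0L, n, nocc)
  sim_codes[ev == "none"] <- 1L
  sim_codes[ev == "pup"] <- 2L
  sim_codes[ev == "juvenile"] <- 3L
  for (y in unique(occ$year)) {
    cols <- which(occ$year == y)
    sub <- sim_codes[, cols, drop = FALSE]
    both <- rowSums(sub == 2L) > 0L & rowSums(sub == 3L) > 0L
    if (any(both)) {
      tmp <- sub[both, , drop = FALSE]
      tmp[tmp == 2L] <- 3L
      sub[both, ] <- tmp
      sim_codes[, cols] <- sub
    }
  }

  sightings <- sim_records(ev, animals, os, scenario$calendar, states,
                           release, old_idx)
  kept <- alive_rel
  hist_codes <- sim_codes[kept, , drop = FALSE]
  rel_k <- release[kept]
  hist_codes[cbind(seq_len(sum(kept)), rel_k)] <- 0L
  truth <- list(states = states, codes = sim_codes, release = release,
                histories = capture_histories(
                  hist_codes, rel_k, animals[kept, , drop = FALSE], os))
  list(sightings = sightings, animals = animals[, c(
    "animal_id", "cohort_year", "natal_rookery")], truth = truth)
}

# Stamp dated sighting records from the evidence matrix.
sim_records <- function(ev, animals, os, calendar, states, release,
                        old_idx) {
  occ <- os$occasions
  recs <- list()
  widx <- which(ev != "", arr.ind = TRUE)
  if (nrow(widx)) {
    a <- widx[, 1]; t <- widx[, 2]
    at_H <- state_loc(states[widx]) == "H"
    date <- occasion_date(os, calendar, t, at_H)
    recs[[1]] <- data.frame(
      animal_id = animals$animal_id[a], date = date,
      site_id = ifelse(at_H, "haulout_1", animals$natal_rookery[a]),
      site_type = ifelse(at_H, "H", "R"),
      evidence = ev[widx], photo_confirmed = 1L)
  }
  # guaranteed study-era entry sighting for surviving old-cohort females
  ent <- old_idx[!is.na(release[old_idx])]
  if (length(ent)) {
    t <- release[ent]
    recs[[length(recs) + 1L]] <- data.frame(
      animal_id = animals$animal_id[ent],
      date = occasion_date(os, calendar, t, rep(FALSE, length(t))),
      site_id = animals$natal_rookery[ent], site_type = "R",
      evidence = "none", photo_confirmed = 1L)
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(animal_id = character(0), date = as.Date(character(0)),
               site_id = character(0), site_type = character(0),
               evidence = character(0), photo_confirmed = integer(0))
  out[order(out$animal_id, out$date), , drop = FALSE]
}

occasion_date <- function(os, calendar, t, at_H) {
  occ <- os$occasions
  mmdd <- character(length(t))
  for (k in seq_along(t)) {
    ty <- as.character(occ$type[t[k]])
    mmdd[k] <- if (ty == "annual_pool") {
      if (at_H[k]) "07-20" else "07-01"
    } else if (ty == "haulout_pool") "07-10" else
      calendar$rookery_windows[[occ$within[t[k]]]][1]
  }
  as.Date(paste0(occ$year[t], "-", mmdd))
}
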