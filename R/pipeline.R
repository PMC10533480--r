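#' Default estimation structure
#'
#' A compact but identifiable model specification mirroring the structure
#' of the generating scenario: six-age-class survival; resighting by the
#' eight state/location groups with a natal-rookery contrast for With-Pup
#' females and a seen-before effect; offspring detection by state and
#' pooled rookery group; recruitment by region and recruitment-age class
#' (with the old-cohort entry rate kept separate and the south age-3
#' recruitment fixed to 0); constant With-Juvenile / No-Dependent rows; a
#' region contrast on With-Pup:With-Juvenile; movement by the five
#' state/age groups.
#'
#' @return a [model_spec()].
#' @export
default_model_spec <- function() {
  model_spec(
    phi = ~ac,
    p = ~group + I(occtype == "annual_pool") +
      I(group == "wpR" & nr == "Hazy") +
      I(group == "wpR" & nr == "WhiteSisters") +
      I(group == "wpR" & nr == "GravesRocks") +
      I(group == "wjR" & region == "north") +
      I(group %in% c("pbR", "juvR") & region == "north") +
      I(group == "wjR" & sb) + I(group == "ndR" & sb) +
      I(group == "pbR" & sb) + I(group == "juvR" & sb),
    delta = ~repro + I(repro == "B" & nr2 == "Hazy") +
      I(repro == "B" & nr2 == "North"),
    psi = list(
      PB = ~0 + I(as.numeric(cohort_class == "old")) +
        I(as.numeric(cohort_class == "new" & region == "north" &
                       age == 3)) +
        I(as.numeric(cohort_class == "new" & region == "south" &
                       age == 4)) +
        I(as.numeric(cohort_class == "new" &
                       ((region == "north" & age >= 4) |
                          (region == "south" & age >= 5)))),
      BJ = ~region, BN = ~1, JB = ~1, JN = ~1, NB = ~1),
    hr = ~mgroup, rh = ~mgroup,
    fixed = list(
      list(par = "psi", pair = "PB",
           cond = ~cohort_class == "new" & age < 3, value = 0),
      list(par = "psi", pair = "PB",
           cond = ~cohort_class == "new" & region == "south" & age == 3,
           value = 0),
      list(par = "p", cond = ~year <= 2001, value = 0)))
}

#' Derived birth-proportion function of the coefficient vector
#'
#' Factory for the `derive` argument of [bootstrap_derived_ci()]: maps a
#' coefficient vector to the age-specific proportions With-Pup for one
#' region via the transition recursion.
#'
#' @param fit a `mvcjs_fit`.
#' @param region `"north"` or `"south"`.
#' @param first_recruit_age,max_age recursion span.
#' @param year reference year.
#' @return function of `beta` returning the named `B_i` vector.
#' @export
derive_birth_proportions <- function(fit, region,
                                     first_recruit_age = if (region ==
                                       "north") 4 else 5,
                                     max_age = 25, year = 2008) {
  force(fit); force(region)
  ages <- (first_recruit_age - 1):(max_age - 1)
  nd <- data.frame(age = ages, region = region, cohort_class = "new",
                   year = year)
  function(beta) {
    pred <- predict_psi(fit, nd, beta)
    arr <- array(0, c(length(ages), 4L, 4L),
                 dimnames = list(ages, REPRO_STATES, REPRO_STATES))
    arr[, "P", "B"] <- pred$PB; arr[, "P", "P"] <- pred$PP
    arr[, "B", "J"] <- pred$BJ; arr[, "B", "N"] <- pred$BN
    arr[, "B", "B"] <- pred$BB
    arr[, "J", "B"] <- pred$JB; arr[, "J", "N"] <- pred$JN
    arr[, "J", "J"] <- pred$JJ
    arr[, "N", "B"] <- pred$NB; arr[, "N", "N"] <- pred$NN
    pr <- state_proportions(arr, first_recruit_age, max_age,
                            const_after = max_age)
    setNames(pr$B, paste0("B", pr$age))
  }
}

spec_from_config <- function(sc) {
  f <- function(x) if (is.null(x)) ~1 else as.formula(x)
  fx <- lapply(sc$fixed, function(m)
    list(par = m$par, pair = m$pair, cond = as.formula(m$cond),
         value = m$value))
  model_spec(phi = f(sc$phi), p = f(sc$p), delta = f(sc$delta),
             psi = lapply(setNames(names(PSI_PAIRS), names(PSI_PAIRS)),
                          function(pr) f(sc$psi[[pr]])),
             hr = f(sc$hr), rh = f(sc$rh), fixed = fx)
}

#' Run the full analysis pipeline
#'
#' Drives simulate (optional) -> encode -> fit (one or many specifications)
#' -> AIC table -> derived proportions -> bootstrap -> Leslie projection,
#' writing every artifact plus a manifest (seeds, versions, config hash)
#' under `out_dir`.  Any stage failure aborts with the stage name; partial
#' outputs are left in place.
#'
#' @param config named list (or path to a YAML file) with entries: `seed`;
#'   `out_dir`; `scenario` (list passed to [scenario_from_paper_defaults()],
#'   plus optional `scale` shrinking cohort sizes, or `sightings` /
#'   `animals` CSV paths to skip simulation); `specs` (named list of
#'   [model_spec()] objects, or formula-string lists as in
#'   `spec_from_config`; default [default_model_spec()]); `n_boot`
#'   (bootstrap draws, 0 to skip); `leslie` (list: `survival` schedule,
#'   `female_fraction`, `convention`); `derive_region`.
#' @return invisible list with the fitted models, AIC table, derived
#'   proportions and projection summary.
#' @export
run_pipeline <- function(config) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  out <- config$out_dir %||% stop("config needs an out_dir")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log_lines <- character()
  note <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  sc_cfg <- config$scenario %||% list()
  if (!is.null(sc_cfg$sightings)) {
    dat <- stage("read", read_sightings(sc_cfg$sightings, sc_cfg$animals))
    structure_ <- stage("structure", build_occasion_structure(
      sc_cfg$first_year %||% 2001, sc_cfg$last_year %||% 2019,
      sc_cfg$pool_years %||% 2001:2004))
    sightings <- dat$sightings; animals <- dat$animals
  } else {
    scen <- stage("scenario", {
      structure_ <- build_occasion_structure(
        sc_cfg$first_year %||% 2001, sc_cfg$last_year %||% 2019,
        sc_cfg$pool_years %||% 2001:2004)
      cohorts <- default_cohorts()
      if (!is.null(sc_cfg$scale))
        cohorts$n <- pmax(1L, as.integer(round(cohorts$n * sc_cfg$scale)))
      cohorts <- cohorts[cohorts$cohort_year %in% c(1994, 1995,
                                                    structure_$years), ]
      scenario_from_paper_defaults(
        seed = seed, pmh_effects = isTRUE(sc_cfg$pmh_effects),
        structure = structure_, cohorts = cohorts)
    })
    sim <- stage("simulate", simulate_population(scen))
    sightings <- sim$sightings; animals <- sim$animals
    write.csv(sightings, file.path(out, "sightings.csv"), row.names = FALSE)
    write.csv(animals, file.path(out, "animals.csv"), row.names = FALSE)
    note("simulate: ", nrow(animals), " females, ", nrow(sightings),
         " sighting records")
  }
  ch <- stage("encode", encode_histories(sightings, animals, structure_))
  write_histories(ch, file.path(out, "histories.txt"))
  note("encode: ", nrow(ch$animals), " capture histories over ",
       ncol(ch$codes), " occasions")

  specs <- config$specs %||% list(base = default_model_spec())
  specs <- lapply(specs, function(s)
    if (inherits(s, "model_spec")) s else spec_from_config(s))
  fits <- list()
  for (nm in names(specs)) {
    fits[[nm]] <- stage(paste0("fit:", nm),
                        fit_mvcjs(specs[[nm]], ch,
                                  n_starts = config$n_starts %||% 3L,
                                  jitter_seed = seed))
    write_coefficients(fits[[nm]],
                       file.path(out, paste0("coefficients_", nm, ".csv")))
    note("fit ", nm, ": logLik ", format(fits[[nm]]$logLik, digits = 8),
         ", AIC ", format(fits[[nm]]$AIC, digits = 8))
  }
  tab <- stage("select", aic_table(fits))
  write.csv(tab, file.path(out, "aic_table.csv"), row.names = FALSE)
  best <- fits[[tab$model[1]]]

  region <- config$derive_region %||% "north"
  a0 <- if (region == "north") 4 else 5
  props <- stage("derive", {
    ps <- as_parameter_set(best)
    pr <- state_proportions(psi_schedule(ps, region), a0, 25,
                            region = region, year_context = "average")
    correct_neonatal(pr, function(a)
      maternal_age_trend("linear", calibrate_linear_trend(), a))
  })
  n_boot <- config$n_boot %||% 0L
  if (n_boot > 0) {
    ci <- stage("bootstrap", bootstrap_derived_ci(
      best, derive_birth_proportions(best, region, a0), n_draws = n_boot,
      seed = seed))
    props$B_lower <- ci$lower[match(paste0("B", props$age), ci$quantity)]
    props$B_upper <- ci$upper[match(paste0("B", props$age), ci$quantity)]
  }
  write_proportions(props, file.path(out,
                                     paste0("proportions_", region, ".csv")))

  les_cfg <- config$leslie %||% list()
  surv <- les_cfg$survival %||%
    c(0.57, 0.76, 0.86, rep(0.93, 13), 0.87, 0.87, rep(0.78, 8))
  natal <- numeric(26)
  natal[props$age + 1L] <- props$B
  sched <- vital_schedule(surv, natal,
                          female_fraction = les_cfg$female_fraction %||% 0.5)
  proj <- stage("project", leslie_projection(
    sched, convention = les_cfg$convention %||% "log"))
  jsonlite::write_json(
    list(lambda = proj$lambda, r = proj$r, convention = proj$convention,
         female_fraction = proj$female_fraction,
         matrix_rowsum_digest = sum(proj$matrix)),
    file.path(out, "leslie.json"), auto_unbox = TRUE, digits = NA)
  note("project: lambda ", format(proj$lambda, digits = 6), ", r ",
       format(proj$r, digits = 4))

  manifest <- list(
    package_version = as.character(utils::packageVersion("mvcjs")),
    r_version = R.version.string,
    seed = seed,
    config = config[setdiff(names(config), "specs")],
    config_md5 = if (!is.null(cfg_path))
      unname(tools::md5sum(cfg_path)) else NA,
    artifacts = as.list(tools::md5sum(
      list.files(out, full.names = TRUE, pattern = "\\.(csv|txt|json)$"))),
    log = log_lines,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(fits = fits, aic = tab, proportions = props,
                 projection = proj))
}
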