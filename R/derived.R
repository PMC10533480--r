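#' Age-specific reproductive-state proportions
#'
#' Propagates the proportions of females alive at each age that are
#' Prebreeders (P), With-Pup (B), With-Juvenile (J) and No-Dependent (N)
#' through the between-year transition probabilities.  At the first
#' recruitment age `a0` the initialisation is `B = psi(P:B, a0-1 to a0)`,
#' `P = 1 - B`, `J = N = 0` (With-Juvenile and No-Dependent are reachable
#' only through With-Pup).  Subsequent ages follow the recursion
#' \deqn{P_i = P_{i-1}\psi_{P:P};\quad
#'       B_i = P_{i-1}\psi_{P:B} + B_{i-1}\psi_{B:B} + J_{i-1}\psi_{J:B} +
#'             N_{i-1}\psi_{N:B};}
#' \deqn{J_i = B_{i-1}\psi_{B:J} + J_{i-1}\psi_{J:J};\quad
#'       N_i = B_{i-1}\psi_{B:N} + J_{i-1}\psi_{J:N} + N_{i-1}\psi_{N:N}.}
#' Transition rows are held constant beyond `const_after`.
#'
#' @param psi age-indexed transition rows: either a function
#'   `psi(age_from)` returning a 4x4 row-stochastic matrix over P, B, J, N,
#'   or a 3-d array `[age_from, 4, 4]` with `dimnames[[1]]` the from-ages.
#' @param first_recruit_age first age with nonzero recruitment probability
#'   into With-Pup (>= 3).
#' @param max_age last age to propagate (default 25).
#' @param const_after hold transition rows constant after this age.
#' @param region,year_context optional labels carried through.
#' @return data frame of class `state_proportions` with columns `age`, `P`,
#'   `B`, `J`, `N` (rows sum to 1).
#' @export
state_proportions <- function(psi, first_recruit_age, max_age = 25,
                              const_after = 25, region = NA_character_,
                              year_context = NA_character_) {
  if (first_recruit_age < 3) stop("first_recruit_age must be >= 3")
  if (max_age < first_recruit_age) stop("max_age below first_recruit_age")
  psifun <- if (is.function(psi)) {
    function(a) psi(min(a, const_after))
  } else {
    ages <- as.integer(dimnames(psi)[[1]])
    function(a) {
      a <- min(a, const_after)
      i <- match(a, ages)
      if (is.na(i)) stop("no psi row for from-age ", a)
      m <- psi[i, , ]
      dimnames(m) <- list(REPRO_STATES, REPRO_STATES)
      m
    }
  }
  check_row <- function(m, a) {
    if (any(abs(rowSums(m) - 1) > 1e-8))
      stop("psi rows for from-age ", a, " do not sum to 1")
    m
  }
  a0 <- first_recruit_age
  m <- check_row(psifun(a0 - 1), a0 - 1)
  cur <- c(P = 1 - m["P", "B"], B = m["P", "B"], J = 0, N = 0)
  out <- matrix(NA_real_, max_age - a0 + 1L, 4L,
                dimnames = list(NULL, REPRO_STATES))
  out[1L, ] <- cur
  if (max_age > a0) for (i in (a0 + 1L):max_age) {
    m <- check_row(psifun(i - 1L), i - 1L)
    cur <- c(P = cur[["P"]] * m["P", "P"],
             B = cur[["P"]] * m["P", "B"] + cur[["B"]] * m["B", "B"] +
                 cur[["J"]] * m["J", "B"] + cur[["N"]] * m["N", "B"],
             J = cur[["B"]] * m["B", "J"] + cur[["J"]] * m["J", "J"],
             N = cur[["B"]] * m["B", "N"] + cur[["J"]] * m["J", "N"] +
                 cur[["N"]] * m["N", "N"])
    out[i - a0 + 1L, ] <- cur
  }
  res <- data.frame(age = a0:max_age, out)
  attr(res, "region") <- region
  attr(res, "year_context") <- year_context
  class(res) <- c("state_proportions", "data.frame")
  res
}

#' Age-indexed transition rows from a parameter set
#'
#' Convenience wrapper turning a [parameter_set()] (a generating truth or a
#' fitted model via [as_parameter_set()]) into the `psi(age)` function that
#' [state_proportions()] consumes.
#'
#' @param params a [parameter_set()].
#' @param region `"north"` or `"south"`.
#' @param year reference year for year-varying transition structures.
#' @param cohort_class `"new"` (default) or `"old"`.
#' @return function of the from-age returning a 4x4 transition matrix.
#' @export
psi_schedule <- function(params, region, year = 2008,
                         cohort_class = "new") {
  function(age) psi_matrix(params, list(age = age, region = region,
                                        cohort_class = cohort_class,
                                        year = year))
}

#' Early pup survival to three weeks
#'
#' Survival of a pup from birth to ~3 weeks of age, composed of two weekly
#' survival rates for weeks 0-2 and one for the third week:
#' `phi_wk12^2 * phi_wk3`.
#'
#' @param phi_wk12 weekly survival, weeks 0-2 (in (0,1]).
#' @param phi_wk3 survival over the third week (in (0,1]).
#' @return the 3-week survival probability.
#' @examples
#' pup_survival_3wk(0.9, 0.95)   # 0.7695
#' @export
pup_survival_3wk <- function(phi_wk12, phi_wk3) {
  if (any(phi_wk12 <= 0) || any(phi_wk3 <= 0))
    stop("weekly survival must be positive (it divides birth probabilities)")
  if (any(phi_wk12 > 1) || any(phi_wk3 > 1))
    stop("weekly survival above 1")
  phi_wk12^2 * phi_wk3
}

#' Maternal-age trend in early pup survival
#'
#' Evaluates a maternal-age trend for 3-week pup survival over ages 5-20
#' (ages outside that span are clamped, with a warning).  Supported forms:
#' `constant`, `two-class` (ages 5-7 vs 8+), `three-class` (5-7, 8-15, 16+),
#' `linear`, `quadratic` (polynomials in age on the chosen scale) and
#' `spline` (natural interpolation through supplied knot values).
#'
#' @param form trend form.
#' @param coefficients numeric coefficients: class values for the class
#'   forms; polynomial coefficients (intercept first) for `linear` /
#'   `quadratic`; for `spline`, values at knot ages given as names.
#' @param age maternal ages.
#' @param scale `"logit"` (default) or `"prob"`: the scale on which the
#'   polynomial forms are linear.
#' @return vector of 3-week pup survival probabilities.
#' @export
maternal_age_trend <- function(form = c("linear", "constant", "two-class",
                                        "three-class", "quadratic",
                                        "spline"),
                               coefficients, age, scale = c("logit", "prob")) {
  form <- match.arg(form)
  scale <- match.arg(scale)
  if (any(age < 5 | age > 20)) {
    warning("maternal age outside 5-20; clamped")
    age <- pmin(pmax(age, 5), 20)
  }
  lin <- function(eta) if (scale == "logit") plogis(eta) else eta
  out <- switch(form,
    constant = rep(coefficients[1], length(age)),
    "two-class" = ifelse(age <= 7, coefficients[1], coefficients[2]),
    "three-class" = ifelse(age <= 7, coefficients[1],
                    ifelse(age <= 15, coefficients[2], coefficients[3])),
    linear = lin(coefficients[1] + coefficients[2] * age),
    quadratic = lin(coefficients[1] + coefficients[2] * age +
                      coefficients[3] * age^2),
    spline = {
      ka <- as.numeric(names(coefficients))
      if (anyNA(ka)) stop("spline coefficients must be named by knot age")
      eta <- if (scale == "logit") qlogis(coefficients) else coefficients
      lin(stats::spline(ka, eta, xout = age, method = "natural")$y)
    })
  unname(check_prob(out, "pup survival trend"))
}

#' Calibrate the linear maternal-age trend from its endpoints
#'
#' Returns `linear`-form coefficients such that the trend passes through
#' the supplied survival values at ages 5 and 20 (the published range is
#' 0.76 to 0.96).
#'
#' @param phi5,phi20 3-week pup survival at maternal ages 5 and 20.
#' @param scale see [maternal_age_trend()].
#' @return coefficient vector `c(intercept, slope)`.
#' @export
calibrate_linear_trend <- function(phi5 = 0.76, phi20 = 0.96,
                                   scale = c("logit", "prob")) {
  scale <- match.arg(scale)
  y <- if (scale == "logit") qlogis(c(phi5, phi20)) else c(phi5, phi20)
  slope <- (y[2] - y[1]) / 15
  c(intercept = y[1] - 5 * slope, slope = slope)
}

#' Correct birth proportions for neonatal mortality
#'
#' The proportion With-Pup at the end of the pupping season understates the
#' true birth probability by the pups lost in their first ~3 weeks.  The
#' corrected value divides by the maternal-age-specific 3-week pup
#' survival: `B_corrected(i) = B(i) / phi_pup3wk(i)`.
#'
#' @param props a [state_proportions()] result.
#' @param pup_surv function of maternal age returning 3-week pup survival
#'   in (0,1].
#' @return `props` with a `B_corrected` column; values exceeding 1 are kept
#'   but flagged with a warning (a miscalibrated survival curve).
#' @export
correct_neonatal <- function(props, pup_surv) {
  s <- pup_surv(props$age)
  if (any(!is.finite(s)) || any(s <= 0))
    stop("pup survival must be positive at every age")
  props$B_corrected <- props$B / s
  if (any(props$B_corrected > 1))
    warning("corrected birth probability exceeds 1 at some ages; ",
            "check the pup-survival calibration")
  props
}

#' Parametric-bootstrap intervals for derived quantities
#'
#' Draws coefficient vectors from the multivariate normal distribution with
#' mean the maximum-likelihood estimate and covariance the inverse of the
#' negative log-likelihood Hessian (on the link scale, so every draw maps to
#' valid probabilities), pushes each draw through `derive`, and returns
#' percentile intervals.
#'
#' @param fit a `mvcjs_fit` (needs `vcov`), or a list with `coefficients`
#'   and `vcov`.
#' @param derive function of a coefficient vector returning a named numeric
#'   vector of derived quantities.
#' @param n_draws number of bootstrap draws (>= 1000 for production use).
#' @param seed integer; fully determines the result.
#' @param level confidence level (default 0.95).
#' @return data frame with `quantity`, `estimate`, `lower`, `upper`,
#'   `n_failed` attribute counting dropped draws (an error if > 1% fail).
#' @export
bootstrap_derived_ci <- function(fit, derive, n_draws = 1000L, seed = 1L,
                                 level = 0.95) {
  beta <- fit$coefficients
  Sigma <- fit$vcov
  if (is.null(Sigma)) stop("fit has no covariance matrix")
  eg <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values))) {
    warning("covariance not positive semidefinite; nearest-PSD repair")
    ev <- pmax(eg$values, 0)
    Sigma <- eg$vectors %*% (ev * t(eg$vectors))
  }
  set.seed(seed)
  draws <- MASS::mvrnorm(n_draws, mu = beta, Sigma = Sigma)
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = n_draws)
  est <- derive(beta)
  vals <- matrix(NA_real_, n_draws, length(est))
  failed <- 0L
  for (i in seq_len(n_draws)) {
    v <- tryCatch(derive(draws[i, ]), error = function(e) NULL)
    if (is.null(v)) failed <- failed + 1L else vals[i, ] <- v
  }
  if (failed > 0.01 * n_draws)
    stop("more than 1% of bootstrap draws failed (", failed, "/",
         n_draws, ")")
  a <- (1 - level) / 2
  qs <- apply(vals, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE)
  out <- data.frame(quantity = names(est) %||% seq_along(est),
                    estimate = unname(est),
                    lower = qs[1, ], upper = qs[2, ])
  attr(out, "n_failed") <- failed
  rownames(out) <- NULL
  out
}

#' Export derived proportions
#'
#' @param props a [state_proportions()] (optionally with `B_corrected`).
#' @param path output CSV path.
#' @return the written table, invisibly.
#' @export
write_proportions <- function(props, path) {
  tab <- as.data.frame(props)
  tab$region <- attr(props, "region")
  tab$year_context <- attr(props, "year_context")
  write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
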