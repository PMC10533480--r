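#' Real-scale parameter set
#'
#' A `parameter_set` bundles the five parameter classes of the
#' multivariate-state model as vectorised functions of covariates, on the
#' probability scale.  It is the common currency between the simulator, the
#' matrix constructors and the likelihood: fitted models expose one, and
#' scenarios supply the generating truth as one.
#'
#' Each component is a function of a single data-frame argument and must
#' return a numeric vector of probabilities, one per row:
#' \describe{
#'   \item{phi}{annual survival; columns `age`, `nr`, `region`, `year`,
#'     `repro` (age and reproductive state at the start of the interval).}
#'   \item{p}{resighting probability; columns `group` (see
#'     [resight_group()]), `nr`, `region`, `sb` (seen earlier that year at a
#'     rookery), `year`, `occtype`, `age`, `repro`, `loc`.}
#'   \item{delta}{conditional offspring (state) detection given the female
#'     was sighted; columns `repro` (`"B"` or `"J"`), `nr`, `region`,
#'     `occtype`.}
#'   \item{psi}{between-year reproductive-state transition probability for
#'     the admissible non-stay pairs; columns `from`, `to`, `age` (age at the
#'     start of the interval), `region`, `cohort_class` (`"old"`/`"new"`),
#'     `year`.  Stay probabilities are the row complements.}
#'   \item{hr}{haulout-to-rookery movement on between-year intervals, indexed
#'     by the state occupied in the destination year; columns `repro`, `age`
#'     (destination-year age), `year`.}
#'   \item{rh}{rookery-to-haulout movement between within-year occasions 3
#'     and 4; columns `repro`, `age`, `year`.}
#' }
#'
#' @param phi,p,delta,psi,hr,rh vectorised functions as described.
#' @return list of class `parameter_set`.
#' @export
parameter_set <- function(phi, p, delta, psi, hr, rh) {
  ps <- list(phi = phi, p = p, delta = delta, psi = psi, hr = hr, rh = rh)
  for (nm in names(ps))
    if (!is.function(ps[[nm]])) stop("component '", nm, "' must be a function")
  structure(ps, class = "parameter_set")
}

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < -1e-12) || any(x > 1 + 1e-12))
    stop("probability outside [0,1] for ", what,
         " (bad parameterisation or fixed-value mask)")
  pmin(pmax(x, 0), 1)
}

#' Reproductive-state transition row
#'
#' Evaluates the between-year transition probabilities out of one
#' reproductive state, including the stay probability computed as the
#' complement of the admissible moves (multinomial rows must sum to 1).
#' Structural zeros (P to J or N; B, J or N back to P; N to J) are exact.
#'
#' @param params a [parameter_set()].
#' @param from reproductive state `"P","B","J","N"`.
#' @param covars list or one-row data frame with `age`, `region`,
#'   `cohort_class`, `year`.
#' @return named numeric vector of length 4 over destinations P, B, J, N.
#' @export
psi_row <- function(params, from, covars) {
  dest <- switch(from, P = "B", B = c("J", "N"), J = c("B", "N"), N = "B")
  d <- data.frame(from = from, to = dest,
                  age = covars$age, region = covars$region,
                  cohort_class = covars$cohort_class, year = covars$year)
  pr <- check_prob(params$psi(d), paste0("psi ", from, ":*"))
  row <- setNames(numeric(4), REPRO_STATES)
  row[dest] <- pr
  s <- sum(pr)
  if (s > 1 + 1e-9) stop("psi row for '", from, "' exceeds 1 (sum = ", s, ")")
  row[from] <- max(0, 1 - s)
  row
}

#' Full 4x4 reproductive transition matrix
#'
#' @inheritParams psi_row
#' @return 4x4 row-stochastic matrix over P, B, J, N.
#' @export
psi_matrix <- function(params, covars) {
  m <- t(vapply(REPRO_STATES, function(f) psi_row(params, f, covars),
                numeric(4)))
  dimnames(m) <- list(REPRO_STATES, REPRO_STATES)
  m
}

#' Emission matrix for one occasion
#'
#' Probability of each observation code (0, u, B, J) given the hidden state,
#' for one animal-occasion.  Dead emits "not seen" with certainty, as does a
#' live state whose location stratum does not match the occasion type
#' (rookery states at haulout occasions and vice versa; annual pooled
#' occasions observe both strata).  For observable With-Pup / With-Juvenile
#' states the definitive code requires both a sighting (p) and offspring
#' detection (delta); a sighting without offspring detection yields "u".
#' Prebreeder and No-Dependent states are unobservable beyond "u".
#'
#' @param params a [parameter_set()].
#' @param occasion one-row slice of `structure$occasions` (or list with
#'   `year`, `within`, `type`).
#' @param covars list with `age`, `nr` (natal rookery), `sb` (logical).
#' @return 9x4 row-stochastic matrix, rows the hidden states, columns the
#'   codes `0,u,B,J`.
#' @export
emission_matrix <- function(params, occasion, covars) {
  E <- matrix(0, N_STATES, 4,
              dimnames = list(NULL, OBS_CODES))
  E[DEAD, 1] <- 1
  type <- as.character(occasion$type)
  region <- natal_region(covars$nr)
  for (l in LOCATIONS) {
    observable <- switch(type,
                         rookery_day = l == "R",
                         haulout_pool = l == "H",
                         annual_pool = TRUE)
    for (r in REPRO_STATES) {
      s <- state_index(r, l)
      if (!observable) { E[s, 1] <- 1; next }
      d <- data.frame(group = resight_group(r, l, covars$age),
                      nr = covars$nr, region = region, sb = covars$sb,
                      year = occasion$year, occtype = type,
                      age = covars$age, repro = r, loc = l)
      p <- check_prob(params$p(d), "p")
      if (r %in% c("B", "J")) {
        del <- check_prob(params$delta(
          data.frame(repro = r, nr = covars$nr, region = region,
                     occtype = type)), "delta")
        E[s, 1] <- 1 - p
        E[s, 2] <- p * (1 - del)
        E[s, if (r == "B") 3 else 4] <- p * del
      } else {
        E[s, 1] <- 1 - p
        E[s, 2] <- p
      }
    }
  }
  E
}

#' Transition matrix for one between-occasion interval
#'
#' On between-year intervals each live row applies, in order: survival (with
#' 1 - phi to the absorbing Dead state), the reproductive-state transition,
#' and haulout-to-rookery movement indexed by the destination-year state.
#' Within a year survival is 1 and the reproductive block is the identity;
#' rookery-to-haulout movement acts only on the interval between within-year
#' occasions 3 and 4.  All other within-year intervals are the identity.
#'
#' @param params a [parameter_set()].
#' @param interval one-row slice of `structure$intervals`.
#' @param covars list with `age` (at the interval start), `nr`,
#'   `cohort_class`.
#' @return 9x9 row-stochastic matrix over the hidden states.
#' @export
transition_matrix <- function(params, interval, covars) {
  T9 <- diag(N_STATES)
  region <- natal_region(covars$nr)
  if (interval$between_year) {
    cv <- list(age = covars$age, region = region,
               cohort_class = covars$cohort_class, year = interval$year)
    psim <- psi_matrix(params, cv)
    phi <- check_prob(params$phi(
      data.frame(age = covars$age, nr = covars$nr, region = region,
                 year = interval$year, repro = REPRO_STATES)), "phi")
    hr <- if (interval$movement_HtoR_allowed) {
      check_prob(params$hr(
        data.frame(repro = REPRO_STATES, age = covars$age + 1,
                   year = interval$year)), "hr")
    } else rep(0, 4)
    T9[] <- 0
    for (l in 1:2) for (ri in 1:4) {
      s <- (l - 1L) * 4L + ri
      for (rj in 1:4) {
        pj <- phi[ri] * psim[ri, rj]
        if (l == 1L) {            # rookery stays rookery between years
          T9[s, rj] <- pj
        } else {                  # haulout may return to a rookery
          T9[s, rj] <- pj * hr[rj]
          T9[s, 4L + rj] <- pj * (1 - hr[rj])
        }
      }
      T9[s, DEAD] <- 1 - phi[ri]
    }
    T9[DEAD, DEAD] <- 1
  } else if (interval$movement_RtoH_allowed) {
    rh <- check_prob(params$rh(
      data.frame(repro = REPRO_STATES, age = covars$age,
                 year = interval$year)), "rh")
    for (ri in 1:4) {
      T9[ri, ri] <- 1 - rh[ri]
      T9[ri, 4L + ri] <- rh[ri]
    }
  }
  T9
}
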