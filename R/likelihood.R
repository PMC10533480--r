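# Batch machinery for the forward-algorithm likelihood.
#
# Emission and transition matrices are shared across animals within covariate
# strata: an emission stratum is (occasion, cohort, natal rookery, sb) and a
# transition stratum is (interval, cohort, natal rookery).  All strata are
# enumerated up front; each likelihood evaluation fills two flat arrays of
# matrices and per-animal integer maps select the right stratum per occasion.

make_strata <- function(structure, cohorts, rookeries) {
  occ <- structure$occasions
  iv <- structure$intervals
  nocc <- nrow(occ)
  es <- expand.grid(sb = c(FALSE, TRUE), nr = rookeries, cohort = cohorts,
                    occ = seq_len(nocc), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  es$year <- occ$year[es$occ]
  es$within <- occ$within[es$occ]
  es$occtype <- as.character(occ$type)[es$occ]
  es$age <- pmax(0L, es$year - es$cohort)
  es$region <- natal_region(es$nr)
  ts <- expand.grid(nr = rookeries, cohort = cohorts,
                    interval = seq_len(nrow(iv)), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  ts$year <- iv$year[ts$interval]
  ts$between <- iv$between_year[ts$interval]
  ts$w34 <- iv$movement_RtoH_allowed[ts$interval]
  ts$hr_ok <- iv$movement_HtoR_allowed[ts$interval]
  ts$age <- pmax(0L, ts$year - ts$cohort)
  ts$region <- natal_region(ts$nr)
  ts$cohort_class <- ifelse(ts$cohort <= 1995, "old", "new")
  list(estrat = es, tstrat = ts,
       cohorts = cohorts, rookeries = rookeries, nocc = nocc)
}

# 1-based stratum ids from components (must mirror the expand.grid order).
emission_id <- function(st, occ, cohort, nr, sb) {
  ci <- match(cohort, st$cohorts)
  ri <- match(nr, st$rookeries)
  nC <- length(st$cohorts); nR <- length(st$rookeries)
  as.integer(sb) + 1L + 2L * ((ri - 1L) + nR * ((ci - 1L) + nC * (occ - 1L)))
}

transition_id <- function(st, interval, cohort, nr) {
  ci <- match(cohort, st$cohorts)
  ri <- match(nr, st$rookeries)
  nC <- length(st$cohorts); nR <- length(st$rookeries)
  ri + length(st$rookeries) * ((ci - 1L) + nC * (interval - 1L))
}

# Evaluate a parameter_set over the strata tables, giving the flat value
# vectors the array builders consume.
values_from_params <- function(params, st) {
  es <- st$estrat; ts <- st$tstrat
  nE <- nrow(es); nT <- nrow(ts)
  grid <- expand.grid(loc = LOCATIONS, repro = REPRO_STATES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pv <- matrix(0, nE, 8L)
  for (k in seq_len(8L)) {
    r <- grid$repro[k]; l <- grid$loc[k]
    d <- data.frame(group = resight_group(rep(r, nE), rep(l, nE), es$age),
                    nr = es$nr, region = es$region, sb = es$sb,
                    year = es$year, occtype = es$occtype, age = es$age,
                    repro = r, loc = l)
    pv[, state_index(r, l)] <- check_prob(params$p(d), "p")
  }
  dB <- check_prob(params$delta(
    data.frame(repro = "B", nr = es$nr, region = es$region,
               occtype = es$occtype)), "delta B")
  dJ <- check_prob(params$delta(
    data.frame(repro = "J", nr = es$nr, region = es$region,
               occtype = es$occtype)), "delta J")
  phiv <- matrix(vapply(REPRO_STATES, function(r)
    check_prob(params$phi(
      data.frame(age = ts$age, nr = ts$nr, region = ts$region,
                 year = ts$year, repro = r)), "phi"), numeric(nT)),
    nT, 4L)
  pairs <- strsplit(PSI_PAIRS, ":", fixed = TRUE)
  psiv <- matrix(vapply(pairs, function(pr)
    check_prob(params$psi(
      data.frame(from = pr[1], to = pr[2], age = ts$age, region = ts$region,
                 cohort_class = ts$cohort_class, year = ts$year)),
      "psi"), numeric(nT)), nT, 6L)
  colnames(psiv) <- names(PSI_PAIRS)
  hrv <- matrix(vapply(REPRO_STATES, function(r)
    check_prob(params$hr(
      data.frame(repro = r, age = ts$age + 1, year = ts$year)), "hr"),
    numeric(nT)), nT, 4L)
  rhv <- matrix(vapply(REPRO_STATES, function(r)
    check_prob(params$rh(
      data.frame(repro = r, age = ts$age, year = ts$year)), "rh"),
    numeric(nT)), nT, 4L)
  list(pv = pv, dB = dB, dJ = dJ, phiv = phiv, psiv = psiv,
       hrv = hrv, rhv = rhv)
}

# Assemble the nE x 9 x 4 emission array from stratum value vectors.
build_emission_array <- function(pv, dB, dJ, occtype) {
  nE <- length(occtype)
  A <- array(0, c(nE, N_STATES, 4L))
  A[, DEAD, 1L] <- 1
  obs_ok <- cbind(R = occtype %in% c("rookery_day", "annual_pool"),
                  H = occtype %in% c("haulout_pool", "annual_pool"))
  for (l in 1:2) for (ri in 1:4) {
    s <- (l - 1L) * 4L + ri
    m <- obs_ok[, l]
    p <- pv[, s]
    A[!m, s, 1L] <- 1
    A[m, s, 1L] <- 1 - p[m]
    if (ri == 2L) {                       # With-Pup
      A[m, s, 2L] <- p[m] * (1 - dB[m])
      A[m, s, 3L] <- p[m] * dB[m]
    } else if (ri == 3L) {                # With-Juvenile
      A[m, s, 2L] <- p[m] * (1 - dJ[m])
      A[m, s, 4L] <- p[m] * dJ[m]
    } else {                              # Prebreeder / No-Dependent
      A[m, s, 2L] <- p[m]
    }
  }
  A
}

# Assemble the nT x 9 x 9 transition array.  psiv holds the six admissible
# non-stay transition probabilities; stay probabilities are complements.
build_transition_array <- function(phiv, psiv, hrv, rhv, ts) {
  nT <- nrow(ts)
  psim <- array(0, c(nT, 4L, 4L))
  psim[, 1L, 2L] <- psiv[, "PB"]
  psim[, 2L, 3L] <- psiv[, "BJ"]
  psim[, 2L, 4L] <- psiv[, "BN"]
  psim[, 3L, 2L] <- psiv[, "JB"]
  psim[, 3L, 4L] <- psiv[, "JN"]
  psim[, 4L, 2L] <- psiv[, "NB"]
  stay <- cbind(1 - psiv[, "PB"],
                1 - psiv[, "BJ"] - psiv[, "BN"],
                1 - psiv[, "JB"] - psiv[, "JN"],
                1 - psiv[, "NB"])
  if (any(stay < -1e-9))
    stop("a psi row sums to more than 1 under the supplied parameters")
  stay <- pmax(stay, 0)
  for (r in 1:4) psim[, r, r] <- stay[, r]

  A <- array(0, c(nT, N_STATES, N_STATES))
  b <- ts$between
  w <- ts$w34 & !b
  idl <- !b & !w
  A[, DEAD, DEAD] <- 1
  for (s in 1:8) A[idl, s, s] <- 1
  hr_use <- hrv
  hr_use[!ts$hr_ok, ] <- 0
  for (l in 1:2) for (ri in 1:4) {
    s <- (l - 1L) * 4L + ri
    for (rj in 1:4) {
      pj <- phiv[b, ri] * psim[b, ri, rj]
      if (l == 1L) {
        A[b, s, rj] <- pj
      } else {
        A[b, s, rj] <- pj * hr_use[b, rj]
        A[b, s, 4L + rj] <- pj * (1 - hr_use[b, rj])
      }
    }
    A[b, s, DEAD] <- 1 - phiv[b, ri]
  }
  for (ri in 1:4) {
    A[w, ri, ri] <- 1 - rhv[w, ri]
    A[w, ri, 4L + ri] <- rhv[w, ri]
    A[w, 4L + ri, 4L + ri] <- 1
  }
  A
}

# Per-animal stratum index maps.
index_maps <- function(st, animals, sb) {
  n <- nrow(animals)
  nocc <- st$nocc
  eidx <- matrix(0L, n, nocc)
  for (t in seq_len(nocc))
    eidx[, t] <- emission_id(st, t, animals$cohort_year,
                             animals$natal_rookery, sb[, t])
  nint <- nocc - 1L
  tidx <- matrix(0L, n, nint)
  for (k in seq_len(nint))
    tidx[, k] <- transition_id(st, k, animals$cohort_year,
                               animals$natal_rookery)
  list(eidx = eidx, tidx = tidx)
}

forward_from_values <- function(vals, st, ch, maps = NULL) {
  E <- build_emission_array(vals$pv, vals$dB, vals$dJ, st$estrat$occtype)
  Tarr <- build_transition_array(vals$phiv, vals$psiv, vals$hrv, vals$rhv,
                                 st$tstrat)
  # contiguous per-stratum layout for the C++ kernel
  E <- aperm(E, c(2, 3, 1))
  Tarr <- aperm(Tarr, c(2, 3, 1))
  if (is.null(maps)) maps <- index_maps(st, ch$animals, ch$sb)
  forward_loglik(E, dim(E)[3], Tarr, dim(Tarr)[3],
                 ch$codes, maps$eidx, maps$tidx, ch$release,
                 state_index("P", "R"))
}

#' Negative log-likelihood of capture histories
#'
#' Forward-algorithm likelihood of the multivariate-state CJS model,
#' conditioned on each animal's release: the hidden chain starts as a point
#' mass on (Prebreeder, rookery) at the release occasion (for the old
#' 1994-1995 cohorts this is the pseudo-Prebreeder entry state, whose exit is
#' governed by the separate old-cohort recruitment parameter through the
#' `cohort_class` covariate).
#'
#' @param histories a `capture_histories` object (see [encode_histories()]).
#' @param params a [parameter_set()].
#' @param structure the occasion structure; defaults to the one the
#'   histories were encoded on.
#' @return the negative log-likelihood (a single number).  An observation
#'   sequence with probability zero raises an error naming the animal.
#' @export
negative_log_likelihood <- function(histories, params,
                                    structure = histories$structure) {
  ch <- histories
  validate_histories(ch)
  st <- make_strata(structure,
                    sort(unique(ch$animals$cohort_year)),
                    sort(unique(as.character(ch$animals$natal_rookery))))
  vals <- values_from_params(params, st)
  ll <- forward_from_values(vals, st, ch)
  if (any(!is.finite(ll)))
    stop("observation sequence has probability 0 for animal(s): ",
         paste(head(ch$animals$animal_id[!is.finite(ll)], 5), collapse = ", "))
  -sum(ll)
}

validate_histories <- function(ch) {
  stopifnot(inherits(ch, "capture_histories"))
  n <- nrow(ch$animals)
  if (nrow(ch$codes) != n || length(ch$release) != n)
    stop("inconsistent capture_histories object")
  pre <- vapply(seq_len(n), function(a) {
    r <- ch$release[a]
    r > 1L && any(ch$codes[a, seq_len(r - 1L)] != 0L)
  }, logical(1))
  if (any(pre))
    stop("nonzero code before release for animal(s): ",
         paste(head(ch$animals$animal_id[pre], 5), collapse = ", "))
  invisible(ch)
}
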