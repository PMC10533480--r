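#' Model specification
#'
#' A `model_spec` gives one link-scale formula per parameter class, evaluated
#' over class-specific design data (see Details), plus fixed-value masks that
#' override the formula on selected strata.  Survival, resighting, state
#' detection and movement use the logit link; each reproductive transition
#' row uses a multinomial logit with the stay transition as the reference
#' category (stay probabilities are the row complements).
#'
#' Design-data columns available to formulas:
#' \describe{
#'   \item{p}{`group` (eight resighting groups), `nr`, `nr2`, `region`, `sb`,
#'     `year`, `fyear`, `occtype`, `age`, `repro`, `loc`.}
#'   \item{delta}{`repro` (`"B"`/`"J"`), `nr`, `nr2`, `region`, `occtype`.}
#'   \item{phi}{`ac` (six age classes), `nr3`, `region`, `year`, `y1415`,
#'     `y16`, `repro` (reproductive state at the interval start, for
#'     cost-of-reproduction models).}
#'   \item{psi (per pair PB, BJ, BN, JB, JN, NB)}{`age`, `rec_age` (factor
#'     a3/a4/a5p), `region`, `cohort_class`, `year`, `post2014`.}
#'   \item{hr, rh}{`mgroup` (five movement groups), `age`, `year`.}
#' }
#'
#' @param phi,p,delta,hr,rh formulas.
#' @param psi named list of formulas for the six admissible non-stay
#'   transitions `PB, BJ, BN, JB, JN, NB`.
#' @param fixed list of masks; each a list with `par` (component name, one of
#'   `phi, p, delta, hr, rh` or `psi`), optional `pair` (for psi), `cond` (a
#'   one-sided formula evaluated in the component's design data) and `value`
#'   (the fixed real-scale probability).
#' @return list of class `model_spec`.
#' @examples
#' spec <- model_spec(
#'   phi = ~ac, p = ~group, delta = ~repro,
#'   psi = list(PB = ~rec_age, BJ = ~1, BN = ~1, JB = ~1, JN = ~1, NB = ~1),
#'   hr = ~mgroup, rh = ~mgroup,
#'   fixed = list(list(par = "psi", pair = "PB",
#'                     cond = ~region == "south" & age == 3, value = 0)))
#' @export
model_spec <- function(phi = ~1, p = ~1, delta = ~1,
                       psi = list(PB = ~1, BJ = ~1, BN = ~1,
                                  JB = ~1, JN = ~1, NB = ~1),
                       hr = ~1, rh = ~1, fixed = list()) {
  if (!all(names(PSI_PAIRS) %in% names(psi)))
    stop("psi must supply formulas for all of: ",
         paste(names(PSI_PAIRS), collapse = ", "))
  for (fx in fixed) {
    if (!fx$par %in% c("phi", "p", "delta", "psi", "hr", "rh"))
      stop("unknown parameter class in fixed mask: ", fx$par)
    if (fx$par == "psi" && is.null(fx$pair))
      stop("psi masks need a 'pair' entry")
    if (fx$value < 0 || fx$value > 1) stop("fixed value outside [0,1]")
  }
  structure(list(phi = phi, p = p, delta = delta, psi = psi[names(PSI_PAIRS)],
                 hr = hr, rh = rh, fixed = fixed),
            class = "model_spec")
}

eval_mask <- function(cond, frame) {
  ok <- eval(cond[[length(cond)]], frame, environment(cond))
  if (length(ok) == 1L) ok <- rep(ok, nrow(frame))
  if (!is.logical(ok) || length(ok) != nrow(frame))
    stop("mask condition must evaluate to one logical per design row")
  ok & !is.na(ok)
}

# Design frames per component, from the stratum tables.
design_frames <- function(st) {
  es <- st$estrat; ts <- st$tstrat
  grid <- expand.grid(loc = LOCATIONS, repro = REPRO_STATES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(state_index(grid$repro, grid$loc)), ]
  pframe <- do.call(rbind, lapply(seq_len(8L), function(s) {
    r <- grid$repro[s]; l <- grid$loc[s]
    data.frame(group = resight_group(rep(r, nrow(es)), rep(l, nrow(es)),
                                     es$age),
               nr = es$nr, nr2 = nr2_group(es$nr), region = es$region,
               sb = es$sb, year = es$year, fyear = factor(es$year),
               occtype = es$occtype, age = es$age, repro = r, loc = l)
  }))
  dframe <- do.call(rbind, lapply(c("B", "J"), function(r)
    data.frame(repro = r, nr = es$nr, nr2 = nr2_group(es$nr),
               region = es$region, occtype = es$occtype)))
  fframe <- do.call(rbind, lapply(REPRO_STATES, function(r)
    data.frame(ac = droplevels(phi_age_class(ts$age)), nr3 = nr3_group(ts$nr),
               region = ts$region, year = ts$year,
               y1415 = ts$year %in% 2014:2015, y16 = ts$year == 2016,
               repro = r)))
  psiframe <- data.frame(age = ts$age,
                         rec_age = droplevels(
                           factor(ifelse(ts$age <= 3, "a3",
                                  ifelse(ts$age == 4, "a4", "a5p")),
                                  levels = c("a3", "a4", "a5p"))),
                         region = ts$region, cohort_class = ts$cohort_class,
                         year = ts$year, post2014 = ts$year >= 2015)
  hrframe <- do.call(rbind, lapply(REPRO_STATES, function(r)
    data.frame(mgroup = move_group(rep(r, nrow(ts)), ts$age + 1),
               age = ts$age + 1, year = ts$year)))
  rhframe <- do.call(rbind, lapply(REPRO_STATES, function(r)
    data.frame(mgroup = move_group(rep(r, nrow(ts)), ts$age),
               age = ts$age, year = ts$year)))
  list(p = pframe, delta = dframe, phi = fframe, psi = psiframe,
       hr = hrframe, rh = rhframe)
}

# Which psi pairs belong to which from-state row.
PSI_ROWSETS <- list(P = "PB", B = c("BJ", "BN"), J = c("JB", "JN"), N = "NB")

#' Build the estimation design for a model specification
#'
#' Expands the specification's formulas into model matrices over the
#' covariate strata of the data, resolves the fixed-value masks, and defines
#' the coefficient packing used by [fit_mvcjs()].  A rank check per model
#' matrix warns about non-identifiable structures.
#'
#' @param histories a `capture_histories` object.
#' @param spec a [model_spec()].
#' @return list of class `mvcjs_design`.
#' @export
mvcjs_design <- function(histories, spec) {
  ch <- histories
  validate_histories(ch)
  st <- make_strata(ch$structure,
                    sort(unique(ch$animals$cohort_year)),
                    sort(unique(as.character(ch$animals$natal_rookery))))
  frames <- design_frames(st)
  comp_names <- c("phi", "p", "delta", paste0("psi.", names(PSI_PAIRS)),
                  "hr", "rh")
  X <- list(); masks <- list(); xlev <- list(); trms <- list()
  for (comp in comp_names) {
    if (startsWith(comp, "psi.")) {
      pair <- sub("psi\\.", "", comp)
      f <- spec$psi[[pair]]
      frame <- frames$psi
      fx <- Filter(function(m) m$par == "psi" && m$pair == pair, spec$fixed)
    } else {
      f <- spec[[comp]]
      frame <- frames[[comp]]
      fx <- Filter(function(m) m$par == comp, spec$fixed)
    }
    mf <- stats::model.frame(f, frame)
    tt <- attr(mf, "terms")
    Xc <- model.matrix(tt, mf)
    qrX <- qr(Xc)
    if (qrX$rank < ncol(Xc))
      warning("design matrix for '", comp, "' is rank deficient (",
              qrX$rank, " < ", ncol(Xc), "); model may not be identifiable")
    mvec <- rep(NA_real_, nrow(frame))
    for (m in fx) mvec[eval_mask(m$cond, frame)] <- m$value
    X[[comp]] <- Xc
    masks[[comp]] <- mvec
    xlev[[comp]] <- stats::.getXlevels(tt, mf)
    trms[[comp]] <- tt
  }
  npar <- vapply(X, ncol, integer(1))
  offsets <- cumsum(c(0L, npar))[seq_along(npar)]
  names(offsets) <- comp_names
  cn <- unlist(lapply(comp_names, function(cm)
    paste0(cm, ":", colnames(X[[cm]]))), use.names = FALSE)
  structure(list(st = st, frames = frames, X = X, masks = masks,
                 xlevels = xlev, terms = trms, spec = spec,
                 offsets = offsets, npar = npar, coef_names = cn,
                 k = sum(npar), histories = ch,
                 maps = index_maps(st, ch$animals, ch$sb)),
            class = "mvcjs_design")
}

coef_slice <- function(design, beta, comp) {
  o <- design$offsets[[comp]]
  beta[seq_len(design$npar[[comp]]) + o]
}

# Real-scale stratum value vectors from a packed coefficient vector.  With
# extras = TRUE the softmax intermediates needed by the analytic gradient
# are attached.
values_from_beta <- function(design, beta, extras = FALSE) {
  st <- design$st
  nE <- nrow(st$estrat); nT <- nrow(st$tstrat)
  logit_vals <- function(comp) {
    eta <- drop(design$X[[comp]] %*% coef_slice(design, beta, comp))
    v <- plogis(eta)
    m <- design$masks[[comp]]
    v[!is.na(m)] <- m[!is.na(m)]
    v
  }
  pv <- matrix(logit_vals("p"), nE, 8L)
  dv <- matrix(logit_vals("delta"), nE, 2L)
  phiv <- matrix(logit_vals("phi"), nT, 4L)
  hrv <- matrix(logit_vals("hr"), nT, 4L)
  rhv <- matrix(logit_vals("rh"), nT, 4L)

  # per-row multinomial logit for psi, stay as reference; masked-to-zero
  # destinations drop out of the softmax, other fixed values scale the rest.
  expv <- matrix(0, nT, 6L, dimnames = list(NULL, names(PSI_PAIRS)))
  fixv <- matrix(NA_real_, nT, 6L, dimnames = list(NULL, names(PSI_PAIRS)))
  for (pair in names(PSI_PAIRS)) {
    comp <- paste0("psi.", pair)
    eta <- drop(design$X[[comp]] %*% coef_slice(design, beta, comp))
    expv[, pair] <- exp(pmin(eta, 30))
    fixv[, pair] <- design$masks[[comp]]
  }
  psiv <- matrix(0, nT, 6L, dimnames = list(NULL, names(PSI_PAIRS)))
  qv <- matrix(0, nT, 6L, dimnames = list(NULL, names(PSI_PAIRS)))
  stayq <- matrix(0, nT, 4L, dimnames = list(NULL, names(PSI_ROWSETS)))
  fsum <- matrix(0, nT, 4L, dimnames = list(NULL, names(PSI_ROWSETS)))
  for (f in names(PSI_ROWSETS)) {
    prs <- PSI_ROWSETS[[f]]
    ex <- expv[, prs, drop = FALSE]
    fx <- fixv[, prs, drop = FALSE]
    ex[!is.na(fx)] <- 0
    denom <- 1 + rowSums(ex)
    fixsum <- rowSums(fx, na.rm = TRUE)
    q <- ex / denom
    pr <- q * (1 - fixsum)
    pr[!is.na(fx)] <- fx[!is.na(fx)]
    psiv[, prs] <- pr
    qv[, prs] <- q
    stayq[, f] <- 1 / denom
    fsum[, f] <- fixsum
  }
  out <- list(pv = pv, dB = dv[, 1L], dJ = dv[, 2L], phiv = phiv,
              psiv = psiv, hrv = hrv, rhv = rhv)
  if (extras) {
    out$qv <- qv; out$stayq <- stayq; out$fsum <- fsum
  }
  out
}

nll_beta <- function(design, beta) {
  vals <- values_from_beta(design, beta)
  ll <- forward_from_values(vals, design$st, design$histories, design$maps)
  if (any(!is.finite(ll))) return(1e10)
  -sum(ll)
}

# Analytic gradient of nll_beta: reverse-mode through the forward recursion
# (C++ adjoint pass gives d logL / d E and d logL / d T summed over animals)
# followed by the chain rule through the matrix assembly, the links, and the
# design matrices.
grad_beta <- function(design, beta) {
  st <- design$st
  ch <- design$histories
  es <- st$estrat; ts <- st$tstrat
  nE <- nrow(es); nT <- nrow(ts)
  vals <- values_from_beta(design, beta, extras = TRUE)
  E <- build_emission_array(vals$pv, vals$dB, vals$dJ, es$occtype)
  Tarr <- build_transition_array(vals$phiv, vals$psiv, vals$hrv, vals$rhv,
                                 ts)
  E <- aperm(E, c(2, 3, 1)); Tarr <- aperm(Tarr, c(2, 3, 1))
  fb <- forward_backward(E, nE, Tarr, nT, ch$codes, design$maps$eidx,
                         design$maps$tidx, ch$release, state_index("P", "R"))
  if (any(!is.finite(fb$loglik))) return(rep(0, design$k))
  Ebar <- array(fb$Ebar, c(N_STATES, 4L, nE))
  Tbar <- array(fb$Tbar, c(N_STATES, N_STATES, nT))

  # emission entries -> p and delta values
  obs_ok <- cbind(R = es$occtype %in% c("rookery_day", "annual_pool"),
                  H = es$occtype %in% c("haulout_pool", "annual_pool"))
  dpv <- matrix(0, nE, 8L)
  ddB <- numeric(nE); ddJ <- numeric(nE)
  for (l in 1:2) for (ri in 1:4) {
    s <- (l - 1L) * 4L + ri
    m <- obs_ok[, l]
    p <- vals$pv[, s]
    e0 <- Ebar[s, 1L, ]; eu <- Ebar[s, 2L, ]
    if (ri == 2L) {
      eB <- Ebar[s, 3L, ]
      dpv[m, s] <- (-e0 + (1 - vals$dB) * eu + vals$dB * eB)[m]
      ddB[m] <- ddB[m] + (p * (eB - eu))[m]
    } else if (ri == 3L) {
      eJ <- Ebar[s, 4L, ]
      dpv[m, s] <- (-e0 + (1 - vals$dJ) * eu + vals$dJ * eJ)[m]
      ddJ[m] <- ddJ[m] + (p * (eJ - eu))[m]
    } else {
      dpv[m, s] <- (-e0 + eu)[m]
    }
  }

  # transition entries -> phi, psi rows, movement values
  b <- ts$between
  w <- ts$w34 & !b
  hr_use <- vals$hrv
  hr_use[!ts$hr_ok, ] <- 0
  psim <- array(0, c(nT, 4L, 4L))
  psim[, 1L, 2L] <- vals$psiv[, "PB"]
  psim[, 2L, 3L] <- vals$psiv[, "BJ"]
  psim[, 2L, 4L] <- vals$psiv[, "BN"]
  psim[, 3L, 2L] <- vals$psiv[, "JB"]
  psim[, 3L, 4L] <- vals$psiv[, "JN"]
  psim[, 4L, 2L] <- vals$psiv[, "NB"]
  psim[, 1L, 1L] <- 1 - vals$psiv[, "PB"]
  psim[, 2L, 2L] <- 1 - vals$psiv[, "BJ"] - vals$psiv[, "BN"]
  psim[, 3L, 3L] <- 1 - vals$psiv[, "JB"] - vals$psiv[, "JN"]
  psim[, 4L, 4L] <- 1 - vals$psiv[, "NB"]
  dphi <- matrix(0, nT, 4L)
  dpsi <- array(0, c(nT, 4L, 4L))
  dhr <- matrix(0, nT, 4L)
  drh <- matrix(0, nT, 4L)
  for (ri in 1:4) {
    acc_phi <- numeric(sum(b))
    for (rj in 1:4) {
      tb_rr <- Tbar[ri, rj, b]
      tb_hr <- Tbar[4L + ri, rj, b]
      tb_hh <- Tbar[4L + ri, 4L + rj, b]
      hj <- hr_use[b, rj]
      contrib <- tb_rr + tb_hr * hj + tb_hh * (1 - hj)
      dpsi[b, ri, rj] <- vals$phiv[b, ri] * contrib
      acc_phi <- acc_phi + psim[b, ri, rj] * contrib
      dhr[b, rj] <- dhr[b, rj] +
        vals$phiv[b, ri] * psim[b, ri, rj] * (tb_hr - tb_hh)
    }
    dphi[b, ri] <- acc_phi - Tbar[ri, DEAD, b] - Tbar[4L + ri, DEAD, b]
    drh[w, ri] <- Tbar[ri, 4L + ri, w] - Tbar[ri, ri, w]
  }
  dhr[!ts$hr_ok, ] <- 0

  # chain through links and design matrices (note: gradient of -logL)
  g <- numeric(design$k)
  put <- function(comp, dval) {
    o <- design$offsets[[comp]]
    g[seq_len(design$npar[[comp]]) + o] <<-
      -drop(crossprod(design$X[[comp]], dval))
  }
  logit_chain <- function(comp, dv, v) {
    deta <- dv * v * (1 - v)
    deta[!is.na(design$masks[[comp]])] <- 0
    deta
  }
  put("p", logit_chain("p", c(dpv), c(vals$pv)))
  put("delta", logit_chain("delta", c(ddB, ddJ), c(vals$dB, vals$dJ)))
  put("phi", logit_chain("phi", c(dphi), c(vals$phiv)))
  put("hr", logit_chain("hr", c(dhr), c(vals$hrv)))
  put("rh", logit_chain("rh", c(drh), c(vals$rhv)))

  from_of <- c(PB = 1L, BJ = 2L, BN = 2L, JB = 3L, JN = 3L, NB = 4L)
  to_of <- c(PB = 2L, BJ = 3L, BN = 4L, JB = 2L, JN = 4L, NB = 2L)
  for (f in names(PSI_ROWSETS)) {
    prs <- PSI_ROWSETS[[f]]
    fi <- from_of[[prs[1]]]
    wmat <- vapply(prs, function(pr) dpsi[, fi, to_of[[pr]]],
                   numeric(nT))
    wstay <- dpsi[, fi, fi]
    A <- rowSums(wmat * vals$qv[, prs, drop = FALSE]) +
      wstay * vals$stayq[, f]
    for (pr in prs) {
      comp <- paste0("psi.", pr)
      deta <- vals$psiv[, pr] * (wmat[, pr] - A)
      deta[!is.na(design$masks[[comp]])] <- 0
      put(comp, deta)
    }
  }
  g
}
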