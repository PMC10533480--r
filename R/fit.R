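#' Fit a multivariate-state CJS model by maximum likelihood
#'
#' Maximises the forward-algorithm likelihood over the packed link-scale
#' coefficient vector with quasi-Newton (BFGS) iterations and
#' finite-difference gradients, using multiple jittered starts (the best of
#' which is kept), and computes the covariance as the inverse of the
#' finite-difference Hessian at the optimum.  Coefficients whose implied
#' probabilities sit at the parameter-space boundary are flagged and their
#' standard errors reported as `NA` (boundary estimates are unreliable).
#'
#' @param spec a [model_spec()].
#' @param histories a `capture_histories` object.
#' @param start optional numeric start vector (link scale, defaults to 0).
#' @param n_starts number of optimisation starts; starts after the first are
#'   jittered on the link scale (sd 0.25) under `jitter_seed`.
#' @param jitter_seed integer seed for the start jitter.
#' @param hessian compute the Hessian / covariance (default TRUE).
#' @param maxit maximum BFGS iterations per start.
#' @return object of class `mvcjs_fit` with elements `coefficients`,
#'   `logLik`, `AIC`, `npar`, `vcov`, `se`, `boundary`, `convergence`,
#'   `design`.
#' @seealso [aic_table()], [as_parameter_set()], [predict_psi()]
#' @export
fit_mvcjs <- function(spec, histories, start = NULL, n_starts = 3L,
                      jitter_seed = 1L, hessian = TRUE, maxit = 500L) {
  design <- mvcjs_design(histories, spec)
  k <- design$k
  if (is.null(start)) start <- rep(0, k)
  if (length(start) != k) stop("start vector must have length ", k)
  starts <- list(start)
  if (n_starts > 1L) {
    jit <- local({
      set.seed(jitter_seed)
      lapply(seq_len(n_starts - 1L),
             function(i) start + stats::rnorm(k, sd = 0.25))
    })
    starts <- c(starts, jit)
  }
  best <- NULL
  for (s0 in starts) {
    o <- optim(s0, nll_beta, gr = grad_beta, design = design,
               method = "BFGS", control = list(maxit = maxit,
                                               reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (best$convergence != 0L)
    warning("optimiser did not report convergence (code ",
            best$convergence, ")")
  beta <- best$par
  names(beta) <- design$coef_names
  boundary <- abs(beta) > qlogis(1 - 1e-6)
  vcov <- se <- NULL
  if (hessian) {
    H <- optimHess(beta, nll_beta, gr = grad_beta, design = design)
    vcov <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(vcov)) {
      warning("Hessian is singular; covariance from eigen pseudo-inverse")
      eg <- eigen(H, symmetric = TRUE)
      pos <- eg$values > max(eg$values) * 1e-10
      vcov <- eg$vectors[, pos, drop = FALSE] %*%
        (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
    }
    vcov <- (vcov + t(vcov)) / 2
    dimnames(vcov) <- list(design$coef_names, design$coef_names)
    se <- sqrt(pmax(diag(vcov), 0))
    se[boundary] <- NA_real_
  }
  structure(list(spec = spec, design = design, coefficients = beta,
                 logLik = -best$value, npar = k,
                 AIC = 2 * best$value + 2 * k,
                 vcov = vcov, se = se, boundary = boundary,
                 convergence = best$convergence, counts = best$counts,
                 n_animals = nrow(histories$animals),
                 data_id = data_signature(histories)),
            class = "mvcjs_fit")
}

data_signature <- function(ch) {
  c(n = nrow(ch$animals), nocc = ncol(ch$codes),
    codes = sum(ch$codes * seq_len(length(ch$codes)) %% 97))
}

#' @export
print.mvcjs_fit <- function(x, ...) {
  cat("Multivariate-state CJS fit:", x$n_animals, "animals,",
      x$npar, "coefficients\n")
  cat("  logLik:", format(x$logLik, digits = 8),
      " AIC:", format(x$AIC, digits = 8), "\n")
  if (any(x$boundary))
    cat("  boundary coefficients:",
        paste(names(x$coefficients)[x$boundary], collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.mvcjs_fit <- function(object, ...) {
  structure(object$logLik, df = object$npar, class = "logLik")
}

#' @export
coef.mvcjs_fit <- function(object, ...) object$coefficients

#' @export
vcov.mvcjs_fit <- function(object, ...) object$vcov

#' @export
AIC.mvcjs_fit <- function(object, ..., k = 2) {
  -2 * object$logLik + k * object$npar
}

#' AIC model-comparison table
#'
#' Ranks fitted models by AIC.  Models within `delta_prefer` AIC units of
#' the best are annotated: among near-ties the model with fewer parameters
#' is preferred.
#'
#' @param fits list of `mvcjs_fit` objects (fit to identical data).
#' @param delta_prefer near-tie width (default 3).
#' @return data frame with `model`, `npar`, `logLik`, `AIC`, `dAIC`,
#'   `weight`, `preferred`.
#' @export
aic_table <- function(fits, delta_prefer = 3) {
  if (!length(fits)) stop("empty model list")
  if (is.null(names(fits)))
    names(fits) <- paste0("model", seq_along(fits))
  sigs <- vapply(fits, function(f) paste(f$data_id, collapse = "/"),
                 character(1))
  if (length(unique(sigs)) > 1L)
    stop("models were fit to different datasets; AIC is not comparable")
  tab <- data.frame(model = names(fits),
                    npar = vapply(fits, function(f) as.integer(f$npar), integer(1)),
                    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
                    AIC = vapply(fits, function(f) f$AIC, numeric(1)))
  tab <- tab[order(tab$AIC, tab$npar), ]
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab$weight <- aic_weights(fits)[tab$model]
  near <- tab$dAIC < delta_prefer
  tab$preferred <- FALSE
  tab$preferred[near][which.min(tab$npar[near])] <- TRUE
  rownames(tab) <- NULL
  tab
}

#' Akaike weights
#'
#' `w_i = exp(-dAIC_i / 2) / sum_j exp(-dAIC_j / 2)`.
#'
#' @param fits list of `mvcjs_fit` objects, or a numeric vector of AIC
#'   values.
#' @return named numeric weights summing to 1.
#' @export
aic_weights <- function(fits) {
  if (!length(fits)) stop("empty model list")
  aic <- if (is.numeric(fits)) fits
         else vapply(fits, function(f) f$AIC, numeric(1))
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w / sum(w)
}

# Evaluate one component's linear predictor on new data, honouring the
# stored factor levels and fixed-value masks.
component_values <- function(fit, comp, newdata, beta = fit$coefficients) {
  design <- fit$design
  tt <- stats::delete.response(design$terms[[comp]])
  mf <- stats::model.frame(tt, newdata, xlev = design$xlevels[[comp]])
  X <- model.matrix(tt, mf)
  eta <- drop(X %*% coef_slice(design, beta, comp))
  spec <- design$spec
  fx <- if (startsWith(comp, "psi.")) {
    pair <- sub("psi\\.", "", comp)
    Filter(function(m) m$par == "psi" && m$pair == pair, spec$fixed)
  } else Filter(function(m) m$par == comp, spec$fixed)
  mvec <- rep(NA_real_, nrow(newdata))
  for (m in fx) mvec[eval_mask(m$cond, newdata)] <- m$value
  list(eta = eta, fixed = mvec)
}

#' Predicted reproductive-state transition rows
#'
#' Real-scale transition probabilities (including the stay complements) for
#' the covariate rows in `newdata` (columns `age`, `region`, `cohort_class`,
#' `year`; `rec_age` and `post2014` are derived if absent).
#'
#' @param fit a `mvcjs_fit`.
#' @param newdata data frame of covariate rows.
#' @param beta optional coefficient vector (defaults to the MLE; the
#'   bootstrap passes draws through here).
#' @return `newdata` with 10 added columns: the six transition pairs and the
#'   four stay probabilities.
#' @export
predict_psi <- function(fit, newdata, beta = fit$coefficients) {
  nd <- newdata
  if (is.null(nd$rec_age))
    nd$rec_age <- factor(ifelse(nd$age <= 3, "a3",
                         ifelse(nd$age == 4, "a4", "a5p")),
                         levels = c("a3", "a4", "a5p"))
  if (is.null(nd$post2014)) nd$post2014 <- nd$year >= 2015
  expv <- fixv <- matrix(NA_real_, nrow(nd), 6L,
                         dimnames = list(NULL, names(PSI_PAIRS)))
  for (pair in names(PSI_PAIRS)) {
    cv <- component_values(fit, paste0("psi.", pair), nd, beta)
    expv[, pair] <- exp(pmin(cv$eta, 30))
    fixv[, pair] <- cv$fixed
  }
  out <- matrix(0, nrow(nd), 6L, dimnames = list(NULL, names(PSI_PAIRS)))
  stay <- matrix(0, nrow(nd), 4L,
                 dimnames = list(NULL, paste0(REPRO_STATES, REPRO_STATES)))
  for (f in names(PSI_ROWSETS)) {
    prs <- PSI_ROWSETS[[f]]
    ex <- expv[, prs, drop = FALSE]
    fx <- fixv[, prs, drop = FALSE]
    ex[!is.na(fx)] <- 0
    denom <- 1 + rowSums(ex)
    fixsum <- rowSums(fx, na.rm = TRUE)
    pr <- ex / denom * (1 - fixsum)
    pr[!is.na(fx)] <- fx[!is.na(fx)]
    out[, prs] <- pr
    stay[, paste0(f, f)] <- 1 - rowSums(pr)
  }
  cbind(newdata, as.data.frame(out), as.data.frame(stay))
}

# Predicted probability for a logit-link component on new data.
predict_prob <- function(fit, comp, newdata, beta = fit$coefficients) {
  cv <- component_values(fit, comp, newdata, beta)
  v <- plogis(cv$eta)
  v[!is.na(cv$fixed)] <- cv$fixed[!is.na(cv$fixed)]
  v
}

#' Convert a fitted model to a real-scale parameter set
#'
#' Wraps the fitted coefficient vector (or any coefficient vector on the
#' same design, e.g. a bootstrap draw) as a [parameter_set()] so that the
#' simulator, matrix constructors and derived-parameter pipeline can consume
#' fitted models and generating truths interchangeably.
#'
#' @param fit a `mvcjs_fit`.
#' @param beta optional coefficient vector.
#' @return a [parameter_set()].
#' @export
as_parameter_set <- function(fit, beta = fit$coefficients) {
  force(fit); force(beta)
  psi_fun <- function(d) {
    pred <- predict_psi(fit, d, beta)
    pair <- names(PSI_PAIRS)[match(paste0(d$from, d$to),
                                   sub(":", "", PSI_PAIRS))]
    if (anyNA(pair)) stop("inadmissible psi pair requested")
    vapply(seq_len(nrow(d)), function(i) pred[i, pair[i]], numeric(1))
  }
  parameter_set(
    phi = function(d) {
      nd <- data.frame(ac = phi_age_class(d$age), nr3 = nr3_group(d$nr),
                       region = d$region, year = d$year,
                       y1415 = d$year %in% 2014:2015, y16 = d$year == 2016,
                       repro = d$repro)
      predict_prob(fit, "phi", nd, beta)
    },
    p = function(d) {
      nd <- d
      nd$nr2 <- nr2_group(d$nr)
      nd$fyear <- factor(d$year, levels = fit$design$xlevels$p$fyear %||%
                           unique(d$year))
      predict_prob(fit, "p", nd, beta)
    },
    delta = function(d) {
      nd <- d
      nd$nr2 <- nr2_group(d$nr)
      predict_prob(fit, "delta", nd, beta)
    },
    psi = psi_fun,
    hr = function(d) {
      nd <- data.frame(mgroup = move_group(d$repro, d$age),
                       age = d$age, year = d$year)
      predict_prob(fit, "hr", nd, beta)
    },
    rh = function(d) {
      nd <- data.frame(mgroup = move_group(d$repro, d$age),
                       age = d$age, year = d$year)
      predict_prob(fit, "rh", nd, beta)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export fitted coefficients
#'
#' Writes the link-scale coefficient table (estimate, SE, boundary flag) to
#' CSV.
#'
#' @param fit a `mvcjs_fit`.
#' @param path output CSV path.
#' @return the table, invisibly.
#' @export
write_coefficients <- function(fit, path) {
  tab <- data.frame(coefficient = names(fit$coefficients),
                    estimate = unname(fit$coefficients),
                    se = if (is.null(fit$se)) NA_real_ else unname(fit$se),
                    boundary = unname(fit$boundary))
  write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
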