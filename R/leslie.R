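#' Vital-rate schedule for Leslie projection
#'
#' Per-age annual survival and natality to `max_age` (default 30), with
#' rates held constant beyond `const_after` (default 25).  The age-0
#' survival entry is the 3-weeks-to-1-year rate, consistent with a census at
#' marking age (~3 weeks): natality is the proportion of females with a pup
#' at the end of the pupping season, which already absorbs neonatal
#' mortality, so together the two schedules partition the first year without
#' double counting.
#'
#' @param survival numeric vector of annual survival, ages `0..k`.
#' @param natality numeric vector of per-age birth proportions `B_i`, ages
#'   `0..m` (leading zeros for pre-recruitment ages).
#' @param max_age projection age span (default 30).
#' @param const_after hold both schedules constant beyond this age.
#' @param female_fraction proportion of pups that are female (default 0.5;
#'   natality counts pups of both sexes while the matrix tracks females).
#' @return list of class `vital_schedule` with equal-length `age`,
#'   `survival`, `natality` and the `female_fraction`.
#' @export
vital_schedule <- function(survival, natality, max_age = 30,
                           const_after = 25, female_fraction = 0.5) {
  extend <- function(x) {
    x <- c(x, rep(x[min(length(x), const_after + 1L)],
                  max(0L, max_age + 1L - length(x))))
    x[seq_len(max_age + 1L)]
  }
  s <- extend(survival); b <- extend(natality)
  if (any(!is.finite(s)) || any(s < 0 | s > 1))
    stop("survival entries must lie in [0,1]")
  if (any(!is.finite(b)) || any(b < 0 | b > 1))
    stop("natality entries must lie in [0,1]")
  if (female_fraction < 0 || female_fraction > 1)
    stop("female_fraction must lie in [0,1]")
  structure(list(age = 0:max_age, survival = s, natality = b,
                 female_fraction = female_fraction),
            class = "vital_schedule")
}

#' Build a female-based Leslie projection matrix
#'
#' First row: fecundities `f_i = female_fraction * B_i`; subdiagonal: the
#' survival schedule.  Ages run 0..max_age with no open-ended terminal
#' class (survival past the last age is zero).
#'
#' @param schedule a [vital_schedule()].
#' @return the (max_age+1) square projection matrix.
#' @export
build_leslie <- function(schedule) {
  stopifnot(inherits(schedule, "vital_schedule"))
  k <- length(schedule$age)
  M <- matrix(0, k, k)
  M[1, ] <- schedule$female_fraction * schedule$natality
  if (k > 1L)
    M[cbind(2:k, 1:(k - 1))] <- schedule$survival[1:(k - 1)]
  dimnames(M) <- list(schedule$age, schedule$age)
  M
}

#' Asymptotic population growth rate of a projection matrix
#'
#' The dominant eigenvalue (Perron root) of the nonnegative projection
#' matrix, and the instantaneous growth rate on the chosen convention:
#' `r = log(lambda)` (default) or `r = lambda - 1`.
#'
#' @param matrix nonnegative projection matrix.
#' @param convention `"log"` or `"lambda1"`.
#' @return list with `lambda`, `r`, `convention`.
#' @export
growth_rate <- function(matrix, convention = c("log", "lambda1")) {
  convention <- match.arg(convention)
  if (any(matrix < 0)) stop("projection matrix must be nonnegative")
  ev <- eigen(matrix, only.values = TRUE)$values
  lambda <- max(Re(ev[abs(Im(ev)) < 1e-8 * (1 + abs(Re(ev)))]), 0)
  r <- if (convention == "log") {
    if (lambda <= 0) -Inf else log(lambda)
  } else lambda - 1
  list(lambda = lambda, r = r, convention = convention)
}

#' Delta-method confidence interval for the growth rate
#'
#' Sensitivities of the dominant eigenvalue to each vital rate are computed
#' by central finite differences; `var(lambda) = g' Sigma g`; the interval
#' for `r` follows by the transform of the chosen convention (`se(r) =
#' se(lambda)/lambda` under the log convention).
#'
#' @param schedule a [vital_schedule()].
#' @param Sigma covariance matrix of the perturbed vital rates, ordered as
#'   `c(survival[ages], natality[ages])` restricted to `which` entries.
#' @param which integer indices (into the stacked rate vector of length
#'   `2*(max_age+1)`) of the rates Sigma refers to; default all.
#' @param alpha 1 - confidence level.
#' @param convention growth-rate convention, see [growth_rate()].
#' @param h finite-difference step.
#' @return list with `r`, `lower`, `upper`, `se_lambda`, `lambda`.
#' @export
delta_method_ci <- function(schedule, Sigma, which = NULL, alpha = 0.05,
                            convention = c("log", "lambda1"), h = 1e-5) {
  convention <- match.arg(convention)
  k <- length(schedule$age)
  theta <- c(schedule$survival, schedule$natality)
  if (is.null(which)) which <- seq_along(theta)
  Sigma <- as.matrix(Sigma)
  if (nrow(Sigma) != length(which))
    stop("Sigma dimension does not match the selected rates")
  eg <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values), 1)) {
    warning("rate covariance not positive semidefinite; nearest-PSD repair")
    Sigma <- eg$vectors %*% (pmax(eg$values, 0) * t(eg$vectors))
  }
  lam_of <- function(th) {
    sc <- schedule
    sc$survival <- pmin(pmax(th[seq_len(k)], 0), 1)
    sc$natality <- pmin(pmax(th[k + seq_len(k)], 0), 1)
    growth_rate(build_leslie(sc))$lambda
  }
  g <- vapply(which, function(j) {
    up <- theta; up[j] <- theta[j] + h
    dn <- theta; dn[j] <- theta[j] - h
    (lam_of(up) - lam_of(dn)) / (2 * h)
  }, numeric(1))
  lambda <- lam_of(theta)
  v <- drop(t(g) %*% Sigma %*% g)
  se_lambda <- sqrt(max(v, 0))
  z <- qnorm(1 - alpha / 2)
  if (convention == "log") {
    r <- log(lambda)
    se_r <- se_lambda / lambda
  } else {
    r <- lambda - 1
    se_r <- se_lambda
  }
  list(r = round(r, 3), lower = round(r - z * se_r, 3),
       upper = round(r + z * se_r, 3), se_lambda = se_lambda,
       lambda = lambda, convention = convention)
}

#' Project a schedule to its growth-rate summary
#'
#' Convenience wrapper: builds the Leslie matrix and reports `lambda` and
#' `r`.
#'
#' @inheritParams build_leslie
#' @param convention see [growth_rate()].
#' @return list with `matrix`, `lambda`, `r`, `convention`,
#'   `female_fraction`.
#' @export
leslie_projection <- function(schedule, convention = c("log", "lambda1")) {
  M <- build_leslie(schedule)
  gr <- growth_rate(M, convention)
  c(list(matrix = M), gr,
    list(female_fraction = schedule$female_fraction))
}
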