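#' @useDynLib mvcjs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats model.matrix optim optimHess plogis qlogis qnorm quantile
#'   rbinom runif setNames aggregate as.formula terms
#' @importFrom utils read.csv write.csv head
NULL

# Hidden-state space: 4 reproductive states x 2 location strata + absorbing
# Dead.  Index layout is fixed package-wide: states 1..4 are (P,B,J,N) at a
# rookery, 5..8 the same at a haulout, 9 is Dead.
REPRO_STATES <- c("P", "B", "J", "N")
LOCATIONS <- c("R", "H")
N_STATES <- 9L
DEAD <- 9L

# Observation codes per occasion: 0 = not seen, u = seen / state undetermined,
# B = seen with pup, J = seen with juvenile.  Integer codes 0..3.
OBS_CODES <- c("0", "u", "B", "J")

ROOKERIES <- c("Forrester", "Hazy", "WhiteSisters", "GravesRocks")
SOUTH_ROOKERIES <- c("Forrester", "Hazy")

# Admissible between-year reproductive transitions (off-diagonal); everything
# else off-diagonal is a structural zero (P->J, P->N, B->P, J->P, N->P, N->J).
PSI_PAIRS <- c(PB = "P:B", BJ = "B:J", BN = "B:N",
               JB = "J:B", JN = "J:N", NB = "N:B")

#' State-space index helpers
#'
#' Convert between the packed hidden-state index (1..9) and its reproductive
#' state / location components.
#'
#' @param repro character vector over `"P","B","J","N"`.
#' @param loc character vector over `"R","H"`.
#' @param state integer hidden-state index in 1..9.
#' @return `state_index()` returns integer indices; `state_repro()` and
#'   `state_loc()` return the components (`NA` for Dead).
#' @examples
#' state_index("B", "R")   # 2
#' state_repro(6)          # "B"
#' @export
state_index <- function(repro, loc) {
  r <- match(repro, REPRO_STATES)
  l <- match(loc, LOCATIONS)
  if (anyNA(r) || anyNA(l)) stop("unknown reproductive state or location")
  as.integer((l - 1L) * 4L + r)
}

#' @rdname state_index
#' @export
state_repro <- function(state) {
  out <- rep(NA_character_, length(state))
  live <- state >= 1L & state <= 8L
  out[live] <- REPRO_STATES[(state[live] - 1L) %% 4L + 1L]
  out
}

#' @rdname state_index
#' @export
state_loc <- function(state) {
  out <- rep(NA_character_, length(state))
  live <- state >= 1L & state <= 8L
  out[live] <- LOCATIONS[(state[live] - 1L) %/% 4L + 1L]
  out
}

#' Natal region for a rookery
#'
#' Forrester and Hazy are the southern rookeries; White Sisters and Graves
#' Rocks the northern ones.
#'
#' @param rookery character vector of rookery names.
#' @return `"south"` or `"north"` per element.
#' @export
natal_region <- function(rookery) {
  bad <- !rookery %in% ROOKERIES
  if (any(bad)) stop("unknown rookery: ", paste(unique(rookery[bad]), collapse = ", "))
  ifelse(rookery %in% SOUTH_ROOKERIES, "south", "north")
}

# Resighting groups.  Eight groups: at rookeries (1) juvenile females 0-3,
# (2) With-Pup, (3) With-Juvenile, (4) No-Dependent, (5) Prebreeder 4+; at
# haulouts (6) juvenile females 0-3, (7) Prebreeder 4+ or No-Dependent,
# (8) With-Pup or With-Juvenile.  Annual pooled occasions use the animal's
# actual location stratum.
RESIGHT_GROUPS <- c("juvR", "wpR", "wjR", "ndR", "pbR", "juvH", "pnH", "bjH")

#' Resighting group of a live hidden state
#'
#' @param repro reproductive state (`"P","B","J","N"`).
#' @param loc location stratum (`"R"` or `"H"`).
#' @param age age in years at the occasion.
#' @return factor over the eight group labels.
#' @export
resight_group <- function(repro, loc, age) {
  juv <- repro == "P" & age <= 3
  g <- character(length(repro))
  atR <- loc == "R"
  g[atR & juv] <- "juvR"
  g[atR & !juv & repro == "P"] <- "pbR"
  g[atR & repro == "B"] <- "wpR"
  g[atR & repro == "J"] <- "wjR"
  g[atR & repro == "N"] <- "ndR"
  g[!atR & juv] <- "juvH"
  g[!atR & ((repro == "P" & !juv) | repro == "N")] <- "pnH"
  g[!atR & repro %in% c("B", "J")] <- "bjH"
  factor(g, levels = RESIGHT_GROUPS)
}

# Movement groups: juvenile females 0-3, adult Prebreeders 4+, With-Pup,
# With-Juvenile, No-Dependent.
MOVE_GROUPS <- c("juv", "pb4", "wp", "wj", "nd")

#' Movement group of a reproductive state at an age
#'
#' Haulout-to-rookery movement is indexed by the state in the destination
#' year; rookery-to-haulout by the state in the current year.
#'
#' @inheritParams resight_group
#' @return factor over the five movement group labels.
#' @export
move_group <- function(repro, age) {
  g <- ifelse(repro == "P" & age <= 3, "juv",
       ifelse(repro == "P", "pb4",
       ifelse(repro == "B", "wp",
       ifelse(repro == "J", "wj", "nd"))))
  factor(g, levels = MOVE_GROUPS)
}

# survival age classes: 0, 1, 2, 3-15, 16-17, 18+
PHI_AGE_CLASSES <- c("a0", "a1", "a2", "a3_15", "a16_17", "a18p")

#' Survival age class
#'
#' Annual survival is structured over six age classes: 0, 1, 2, 3-15, 16-17
#' and 18+.
#'
#' @param age integer vector of ages.
#' @return factor over the six class labels.
#' @export
phi_age_class <- function(age) {
  cls <- ifelse(age <= 0, "a0",
         ifelse(age == 1, "a1",
         ifelse(age == 2, "a2",
         ifelse(age <= 15, "a3_15",
         ifelse(age <= 17, "a16_17", "a18p")))))
  factor(cls, levels = PHI_AGE_CLASSES)
}

# natal-rookery groupings used by the detection / survival structures:
# nr2 pools the two northern rookeries; nr3 pools the two southern ones.
nr2_group <- function(rookery) {
  factor(ifelse(rookery %in% SOUTH_ROOKERIES, as.character(rookery), "North"),
         levels = c("Forrester", "Hazy", "North"))
}

nr3_group <- function(rookery) {
  factor(ifelse(rookery %in% SOUTH_ROOKERIES, "South", as.character(rookery)),
         levels = c("South", "WhiteSisters", "GravesRocks"))
}
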