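# Capture-history container.  codes is an n x n_occasions integer matrix
# over 0 = not seen, 1 = u, 2 = B, 3 = J (the release occasion itself is
# stored as 0; conceptually it carries the single "P" code).  sb is the
# per-occasion "seen before that year at a rookery" covariate, derived
# deterministically from the codes.
capture_histories <- function(codes, release, animals, structure) {
  stopifnot(nrow(codes) == nrow(animals), length(release) == nrow(animals))
  animals$natal_rookery <- as.character(animals$natal_rookery)
  animals$region <- natal_region(animals$natal_rookery)
  animals$cohort_class <- ifelse(animals$cohort_year <= 1995, "old", "new")
  storage.mode(codes) <- "integer"
  ch <- structure(list(codes = codes, sb = sb_covariate(codes, structure),
                       release = as.integer(release), animals = animals,
                       structure = structure),
                  class = "capture_histories")
  validate_histories(ch)
  ch
}

#' @export
print.capture_histories <- function(x, ...) {
  cat("Capture histories:", nrow(x$animals), "females over",
      ncol(x$codes), "occasions\n")
  cat("  nonzero codes:", sum(x$codes != 0L),
      "(u:", sum(x$codes == 1L), " B:", sum(x$codes == 2L),
      " J:", sum(x$codes == 3L), ")\n")
  invisible(x)
}

# sb: false on the first rookery occasion of a year, true on a later rookery
# occasion iff the female was sighted at a rookery earlier that year.
sb_covariate <- function(codes, structure) {
  occ <- structure$occasions
  sb <- matrix(FALSE, nrow(codes), nrow(occ))
  rook <- which(occ$type == "rookery_day")
  for (t in rook[occ$within[rook] > 1L]) {
    earlier <- which(occ$year == occ$year[t] & occ$type == "rookery_day" &
                       occ$within < occ$within[t])
    sb[, t] <- rowSums(codes[, earlier, drop = FALSE] != 0L) > 0L
  }
  sb
}

#' Read sighting and animal records
#'
#' Sightings CSV columns: `animal_id`, `date` (ISO-8601), `site_id`,
#' `site_type` (`R`/`H`), `evidence` (`none`, `uncertain`, `pup`,
#' `juvenile`; the behavioural synonyms `suckle`/`suckling`/`laying-on`/
#' `reuniting` map to `pup`), `photo_confirmed` (0/1).  Animals CSV columns:
#' `animal_id`, `cohort_year`, `natal_rookery`.
#'
#' @param path sightings CSV path.
#' @param animals animals CSV path, or an equivalent data frame.
#' @param strict drop records that are not photograph-confirmed (default
#'   TRUE, with the dropped count reported).
#' @param year_range admissible study years for sighting dates.
#' @return list with `sightings` and `animals` data frames.
#' @export
read_sightings <- function(path, animals, strict = TRUE,
                           year_range = c(1994, 2019)) {
  if (!file.exists(path)) stop("sightings file not found: ", path)
  sg <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "date", "site_id", "site_type", "evidence",
            "photo_confirmed")
  if (!all(need %in% names(sg)))
    stop("sightings file must have columns: ", paste(need, collapse = ", "))
  an <- if (is.character(animals)) {
    if (!file.exists(animals)) stop("animals file not found: ", animals)
    read.csv(animals, stringsAsFactors = FALSE)
  } else as.data.frame(animals)
  if (!all(c("animal_id", "cohort_year", "natal_rookery") %in% names(an)))
    stop("animals table must have animal_id, cohort_year, natal_rookery")
  bad <- !an$natal_rookery %in% ROOKERIES
  if (any(bad))
    stop("unknown rookery in animals row(s) ",
         paste(head(which(bad), 5), collapse = ", "), ": ",
         paste(unique(an$natal_rookery[bad]), collapse = ", "))
  d <- as.Date(as.character(sg$date), format = "%Y-%m-%d")
  if (anyNA(d))
    stop("unparseable date in sightings row(s): ",
         paste(head(which(is.na(d)), 5), collapse = ", "))
  yr <- as.integer(format(d, "%Y"))
  out_of_study <- yr < year_range[1] | yr > year_range[2]
  if (any(out_of_study))
    stop("sighting date outside study years ", year_range[1], "-",
         year_range[2], " in row(s): ",
         paste(head(which(out_of_study), 5), collapse = ", "))
  st_map <- c(R = "rookery", H = "haulout",
              rookery = "rookery", haulout = "haulout")
  stype <- st_map[sg$site_type]
  if (anyNA(stype))
    stop("unknown site_type in sightings row(s): ",
         paste(head(which(is.na(stype)), 5), collapse = ", "))
  ev_map <- c(none = "none", uncertain = "uncertain", pup = "pup",
              juvenile = "juvenile", suckle = "pup", suckling = "pup",
              "laying-on" = "pup", reuniting = "pup")
  ev <- ev_map[sg$evidence]
  if (anyNA(ev))
    stop("unknown evidence class in sightings row(s): ",
         paste(head(which(is.na(ev)), 5), collapse = ", "))
  sg$date <- d
  sg$site_type <- unname(stype)
  sg$evidence <- unname(ev)
  if (strict) {
    drop <- !(sg$photo_confirmed %in% c(1, TRUE))
    if (any(drop))
      message("dropping ", sum(drop), " non-photo-confirmed record(s)")
    sg <- sg[!drop, , drop = FALSE]
  }
  missing_an <- !sg$animal_id %in% an$animal_id
  if (any(missing_an))
    stop("sightings reference unknown animal(s): ",
         paste(head(unique(sg$animal_id[missing_an]), 5), collapse = ", "))
  list(sightings = sg, animals = an)
}

#' Encode sighting records into multistate capture histories
#'
#' Maps dated sightings onto the occasion structure (via the survey-window
#' calendar), collapses multiple same-occasion sightings to one code
#' (definitive offspring evidence beats an uncertain sighting), applies the
#' triad rule (within a survey year, a female observed with both a pup and a
#' juvenile has her pup evidence replaced by the juvenile code), and handles
#' release conventions: females of the 2001+ cohorts are released in the
#' Prebreeder state at their cohort-year occasion; old-cohort (1994-1995)
#' females enter at their first nonzero code, which is recoded as the
#' release, and are excluded entirely if never sighted in the reproductive-
#' survey era (>= `old_entry_min`).
#'
#' @param records sightings data frame (as from [read_sightings()]).
#' @param animals animals data frame.
#' @param structure an [build_occasion_structure()] result.
#' @param calendar a [survey_calendar()].
#' @param old_entry_min first year of the reproductive-survey era used for
#'   the old-cohort inclusion rule (default 2005).
#' @return a `capture_histories` object.
#' @export
encode_histories <- function(records, animals, structure,
                             calendar = survey_calendar(),
                             old_entry_min = 2005L) {
  an <- as.data.frame(animals)
  an$natal_rookery <- as.character(an$natal_rookery)
  bad <- !an$natal_rookery %in% ROOKERIES
  if (any(bad)) stop("unknown rookery: ",
                     paste(unique(an$natal_rookery[bad]), collapse = ", "))
  occ <- structure$occasions
  nocc <- nrow(occ)
  sg <- as.data.frame(records)
  sg$occ <- occasion_for_date(structure, calendar, sg$date, sg$site_type)
  unmapped <- is.na(sg$occ)
  if (any(unmapped)) {
    warning(sum(unmapped),
            " sighting record(s) fall outside every survey window; dropped")
    sg <- sg[!unmapped, , drop = FALSE]
  }
  code_of <- c(none = 1L, uncertain = 1L, pup = 2L, juvenile = 3L)
  sg$code <- code_of[sg$evidence]
  codes <- matrix(0L, nrow(an), nocc)
  idx <- match(sg$animal_id, an$animal_id)
  # same-occasion collapse: keep the maximum code, definitive over uncertain
  # (B and J at one occasion resolves through the yearly triad rule below)
  for (k in order(sg$code)) codes[idx[k], sg$occ[k]] <- sg$code[k]
  # triad rule, per animal-year
  for (y in unique(occ$year)) {
    cols <- which(occ$year == y)
    sub <- codes[, cols, drop = FALSE]
    both <- rowSums(sub == 2L) > 0L & rowSums(sub == 3L) > 0L
    if (any(both)) {
      tmp <- sub[both, , drop = FALSE]
      tmp[tmp == 2L] <- 3L
      sub[both, ] <- tmp
      codes[, cols] <- sub
    }
  }
  release <- integer(nrow(an))
  keep <- rep(TRUE, nrow(an))
  era_cols <- which(occ$year >= old_entry_min)
  for (a in seq_len(nrow(an))) {
    if (an$cohort_year[a] <= 1995L) {
      nz <- which(codes[a, ] != 0L)
      if (!length(nz) || !any(nz %in% era_cols)) { keep[a] <- FALSE; next }
      release[a] <- nz[1]
    } else {
      r <- first_occasion_of_year(structure, an$cohort_year[a])
      if (is.na(r)) stop("cohort year ", an$cohort_year[a],
                         " not covered by the occasion structure")
      release[a] <- r
    }
    codes[a, seq_len(release[a])] <- 0L   # pre-release and the release "P"
  }
  n_dropped <- sum(!keep)
  if (n_dropped)
    message("excluding ", n_dropped, " old-cohort female(s) never sighted in ",
            old_entry_min, "+")
  capture_histories(codes[keep, , drop = FALSE], release[keep],
                    an[keep, , drop = FALSE], structure)
}

#' Write / read capture histories as a flat file
#'
#' One line per animal: `animal_id`, the code string over `{0,u,B,J,P}` (one
#' character per occasion, `P` at the release), `natal_rookery`,
#' `cohort_year`.  A header line carries the occasion descriptors.
#'
#' @param histories a `capture_histories` object.
#' @param path file path.
#' @return `write_histories` the path, invisibly; `read_histories` a
#'   `capture_histories`.
#' @export
write_histories <- function(histories, path) {
  ch <- histories
  occ <- ch$structure$occasions
  chars <- matrix(OBS_CODES[ch$codes + 1L], nrow(ch$codes))
  chars[cbind(seq_len(nrow(chars)), ch$release)] <- "P"
  tab <- data.frame(animal_id = ch$animals$animal_id,
                    history = apply(chars, 1, paste, collapse = ""),
                    natal_rookery = ch$animals$natal_rookery,
                    cohort_year = ch$animals$cohort_year)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# occasions: ",
                    paste(occ$year, occ$within, substr(occ$type, 1, 1),
                          sep = ".", collapse = " ")), con)
  write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histories
#' @param structure the occasion structure the file was written on.
#' @export
read_histories <- function(path, structure) {
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  chars <- do.call(rbind, strsplit(tab$history, ""))
  if (ncol(chars) != nrow(structure$occasions))
    stop("history length does not match the occasion structure")
  release <- apply(chars == "P", 1, function(z) which(z)[1])
  if (anyNA(release)) stop("history without a release code P")
  codes <- matrix(match(chars, OBS_CODES) - 1L, nrow(chars))
  codes[is.na(codes)] <- 0L   # the P cell
  capture_histories(codes, release,
                    data.frame(animal_id = tab$animal_id,
                               cohort_year = tab$cohort_year,
                               natal_rookery = tab$natal_rookery),
                    structure)
}
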