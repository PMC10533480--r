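#' Build the sampling occasion structure
#'
#' Constructs the mixed occasion structure used throughout: one pooled
#' occasion per year over `annual_pool_years` (all sightings in the survey
#' season condensed to one record), and four occasions per year otherwise
#' (three daily rookery occasions followed by one pooled haulout occasion,
#' the robust-design layout of the reproductive surveys).
#'
#' Between-occasion intervals carry flags: survival and reproductive-state
#' transitions are estimable only on between-year intervals (last occasion of
#' a year to the first of the next); within a year survival is fixed to 1 and
#' the reproductive state cannot change.  Movement from rookery to haulout is
#' possible only between within-year occasions 3 and 4, and from haulout to
#' rookery only on between-year intervals.
#'
#' With the full study span 2001-2019 and pooled years 2001-2004 this yields
#' 4 + 15 * 4 = 64 occasions.  (The source analysis quotes 63 occasions for
#' the same design; the arithmetic from its stated layout gives 64, so the
#' span is left configurable rather than silently adjusted.)
#'
#' @param first_year,last_year integer year range (inclusive).
#' @param annual_pool_years integer vector of years (a leading, contiguous
#'   subset of the range, possibly empty) that contribute a single pooled
#'   occasion.
#' @return An object of class `occasion_structure`: list with `occasions`
#'   (data frame: `year`, `within` 1..4, `type`) and `intervals` (data frame
#'   of flags per between-occasion interval).
#' @examples
#' os <- build_occasion_structure(2001, 2019, 2001:2004)
#' nrow(os$occasions)  # 64
#' @export
build_occasion_structure <- function(first_year, last_year,
                                     annual_pool_years = integer()) {
  if (first_year > last_year) stop("first_year must be <= last_year")
  years <- first_year:last_year
  pool <- as.integer(annual_pool_years)
  if (length(pool)) {
    if (any(!pool %in% years)) stop("annual_pool_years outside year range")
    if (!identical(pool, years[seq_along(pool)]))
      stop("annual_pool_years must be a leading contiguous block of the year range")
  }
  occ <- do.call(rbind, lapply(years, function(y) {
    if (y %in% pool) {
      data.frame(year = y, within = 1L, type = "annual_pool")
    } else {
      data.frame(year = y, within = 1:4,
                 type = c(rep("rookery_day", 3), "haulout_pool"))
    }
  }))
  occ$type <- factor(occ$type,
                     levels = c("rookery_day", "haulout_pool", "annual_pool"))
  rownames(occ) <- NULL
  n <- nrow(occ)
  iv <- data.frame(
    from = seq_len(n - 1L), to = 2:n,
    year = occ$year[-n],
    between_year = occ$year[-1] != occ$year[-n]
  )
  iv$survival_estimable <- iv$between_year
  iv$transition_estimable <- iv$between_year
  iv$movement_HtoR_allowed <- iv$between_year
  iv$movement_RtoH_allowed <- !iv$between_year &
    occ$within[-n] == 3L & occ$within[-1] == 4L
  structure(list(occasions = occ, intervals = iv,
                 years = years, pool_years = pool),
            class = "occasion_structure")
}

#' @export
print.occasion_structure <- function(x, ...) {
  cat("Occasion structure:", nrow(x$occasions), "occasions,",
      length(x$years), "years (", min(x$years), "-", max(x$years), ")\n")
  if (length(x$pool_years))
    cat("  annual pooled occasions:", min(x$pool_years), "-",
        max(x$pool_years), "\n")
  invisible(x)
}

#' First occasion index of a year
#'
#' @param structure an `occasion_structure`.
#' @param year integer year(s).
#' @return integer occasion index (NA if the year is not in the structure).
#' @export
first_occasion_of_year <- function(structure, year) {
  match(year, structure$occasions$year)
}

#' Survey-window calendar
#'
#' The mapping from calendar dates to occasions is a configuration input (the
#' field windows are only loosely bounded, late June to mid July).  Each
#' rookery-day occasion claims a window of dates; the haulout pooled occasion
#' claims any haulout sighting within the season window; annual pooled
#' occasions claim any sighting in the extended May-August window.
#'
#' @param rookery_windows list of 3 character vectors `c(start, end)` as
#'   `"mm-dd"`, one per within-year rookery occasion.
#' @param haulout_window,pool_window character `c(start, end)` as `"mm-dd"`.
#' @return list of class `survey_calendar`.
#' @export
survey_calendar <- function(
    rookery_windows = list(c("06-20", "06-24"), c("06-25", "06-29"),
                           c("06-30", "07-04")),
    haulout_window = c("06-15", "08-15"),
    pool_window = c("05-01", "08-31")) {
  stopifnot(length(rookery_windows) == 3L)
  structure(list(rookery_windows = rookery_windows,
                 haulout_window = haulout_window,
                 pool_window = pool_window),
            class = "survey_calendar")
}

# Map sighting dates to occasion indices.  Vectorised; returns NA for dates
# falling outside every window (callers warn and drop those records).
occasion_for_date <- function(structure, calendar, date, site_type) {
  date <- as.Date(date)
  yr <- as.integer(format(date, "%Y"))
  mmdd <- format(date, "%m-%d")
  occ <- structure$occasions
  out <- rep(NA_integer_, length(date))
  in_win <- function(x, w) x >= w[1] & x <= w[2]
  pool <- yr %in% structure$pool_years
  if (any(pool)) {
    ok <- pool & in_win(mmdd, calendar$pool_window)
    out[ok] <- match(paste(yr[ok], 1L), paste(occ$year, occ$within))
  }
  reg <- !pool & yr %in% structure$years
  if (any(reg)) {
    isR <- site_type %in% c("rookery", "R")
    for (j in 1:3) {
      sel <- reg & isR & in_win(mmdd, calendar$rookery_windows[[j]])
      out[sel] <- match(paste(yr[sel], j), paste(occ$year, occ$within))
    }
    sel <- reg & !isR & in_win(mmdd, calendar$haulout_window)
    out[sel] <- match(paste(yr[sel], 4L), paste(occ$year, occ$within))
  }
  out
}
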