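test_that("sighting files parse, map behaviours, and validate", {
  fx <- write_sightings_fixture()
  out <- read_sightings(fx$sightings, fx$animals)
  expect_equal(nrow(out$sightings), 3)
  expect_equal(nrow(out$animals), 2)
  expect_equal(out$sightings$evidence[1], "pup")   # "suckle" is definitive
  expect_s3_class(out$sightings$date, "Date")

  # strict mode drops non-photo-confirmed records with a count
  sg <- fx$sg; sg$photo_confirmed[2] <- 0
  sp2 <- file.path(tempdir(), "s2.csv")
  write.csv(sg, sp2, row.names = FALSE)
  expect_message(out2 <- read_sightings(sp2, fx$animals),
                 "1 non-photo-confirmed")
  expect_equal(nrow(out2$sightings), 2)

  bad <- fx$sg; bad$date[1] <- "1993-06-01"
  write.csv(bad, sp2, row.names = FALSE)
  expect_error(read_sightings(sp2, fx$animals), "outside study years")
  bad <- fx$sg; bad$site_type[1] <- "Q"
  write.csv(bad, sp2, row.names = FALSE)
  expect_error(read_sightings(sp2, fx$animals), "site_type")
  bad <- fx$sg; bad$date[1] <- "not-a-date"
  write.csv(bad, sp2, row.names = FALSE)
  expect_error(read_sightings(sp2, fx$animals), "unparseable date")
  an <- fx$an; an$natal_rookery[1] <- "Atlantis"
  expect_error(read_sightings(fx$sightings, an), "unknown rookery")
})

test_that("encoding applies the coding rules, sb, and the triad rule", {
  os <- build_occasion_structure(2005, 2006)
  an <- data.frame(animal_id = "A1", cohort_year = 2005,
                   natal_rookery = "Forrester")
  # seen suckling (pup) on rookery day 2 of 2006 only
  sg <- data.frame(animal_id = "A1", date = "2006-06-25",
                   site_id = "Forrester", site_type = "R",
                   evidence = "pup", photo_confirmed = 1)
  ch <- encode_histories(sg, an, os)
  expect_equal(ch$codes[1, 5:8], c(0L, 2L, 0L, 0L))
  expect_false(ch$sb[1, 6])          # first sighting of the year
  expect_true(ch$sb[1, 7])           # seen before day 3

  # pup on day 1 plus juvenile on day 3 of the same year: pup recoded J
  sg2 <- data.frame(animal_id = "A1",
                    date = c("2006-06-20", "2006-06-30"),
                    site_id = "Forrester", site_type = "R",
                    evidence = c("pup", "juvenile"), photo_confirmed = 1)
  ch2 <- encode_histories(sg2, an, os)
  expect_equal(ch2$codes[1, 5:8], c(3L, 0L, 3L, 0L))

  # never resighted: release P then all zero
  ch3 <- encode_histories(sg[0, ], an, os)
  expect_equal(ch3$release, 1L)
  expect_true(all(ch3$codes == 0L))

  # record outside every survey window: warned and dropped
  sg4 <- data.frame(animal_id = "A1", date = "2006-09-20",
                    site_id = "Forrester", site_type = "R",
                    evidence = "none", photo_confirmed = 1)
  expect_warning(ch4 <- encode_histories(sg4, an, os), "dropped")
  expect_true(all(ch4$codes == 0L))
})

test_that("old-cohort females enter at their first code or are excluded", {
  os <- build_occasion_structure(2001, 2006, 2001:2004)
  an <- data.frame(animal_id = c("O1", "O2"), cohort_year = 1994,
                   natal_rookery = "Forrester")
  sg <- data.frame(animal_id = c("O1", "O1", "O2"),
                   date = c("2002-07-01", "2005-06-21", "2003-07-01"),
                   site_id = "Forrester", site_type = "R",
                   evidence = c("none", "pup", "none"),
                   photo_confirmed = 1)
  expect_message(ch <- encode_histories(sg, an, os), "excluding 1")
  expect_equal(nrow(ch$animals), 1)           # O2 never seen >= 2005
  expect_equal(ch$animals$animal_id, "O1")
  # O1's first nonzero (the 2002 pooled record) becomes the release P
  expect_equal(ch$release, 2L)
  expect_equal(ch$codes[1, 2], 0L)
  expect_equal(ch$codes[1, 5], 2L)            # the 2005 pup sighting
  expect_equal(ch$animals$cohort_class, "old")
})

test_that("encoding the simulator's records reproduces its code matrix", {
  scen <- scenario_from_paper_defaults(
    seed = 11, triad_rate = 0.1,
    structure = build_occasion_structure(2001, 2008, 2001:2004),
    cohorts = data.frame(
      cohort_year = c(1994, 2001, 2002, 2003, 2005),
      natal_rookery = c("Forrester", "Forrester", "Hazy", "WhiteSisters",
                        "GravesRocks"),
      n = c(60, 40, 40, 40, 40)))
  sim <- simulate_population(scen)
  truth <- sim$truth$histories
  enc <- encode_histories(sim$sightings, sim$animals, scen$structure)
  expect_identical(enc$codes, truth$codes)
  expect_identical(enc$release, truth$release)
  expect_identical(enc$animals$animal_id, truth$animals$animal_id)
  # nonzero codes never exceed the sighting records per animal
  counts <- table(sim$sightings$animal_id)
  nrec <- as.integer(counts[enc$animals$animal_id])
  nrec[is.na(nrec)] <- 0L
  expect_true(all(rowSums(enc$codes != 0L) <= nrec))
  # sb is monotone within each year (false -> true only)
  occ <- scen$structure$occasions
  for (y in unique(occ$year)) {
    cols <- which(occ$year == y & occ$type == "rookery_day")
    if (length(cols) < 2) next
    d <- enc$sb[, cols[-1], drop = FALSE] - enc$sb[, cols[-length(cols)],
                                                   drop = FALSE]
    expect_true(all(d >= 0))
  }
})

test_that("capture histories survive a file round trip", {
  scen <- recovery_scenario(5, n_per = 4, last_year = 2008)
  ch <- simulate_population(scen)$truth$histories
  path <- file.path(tempdir(), "hist.txt")
  write_histories(ch, path)
  back <- read_histories(path, scen$structure)
  expect_identical(back$codes, ch$codes)
  expect_identical(back$release, ch$release)
  expect_equal(back$animals$cohort_year, ch$animals$cohort_year)
})

test_that("a nonzero code before release is rejected", {
  os <- build_occasion_structure(2005, 2005)
  an <- data.frame(animal_id = "A1", cohort_year = 2005,
                   natal_rookery = "Hazy")
  codes <- matrix(c(1L, 0L, 0L, 0L), 1)
  expect_error(mvcjs:::capture_histories(codes, 2L, an, os),
               "before release")
})
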