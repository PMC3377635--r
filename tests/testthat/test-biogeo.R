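make_records <- function(...) {
  suppressMessages(as_specimen_records(data.frame(...)))$records
}

test_that("the depth-range rule excludes wide trawl intervals, never point records", {
  rec <- make_records(
    record_id = c("pt", "wide", "narrow"),
    genus = "Chrysogorgia",
    depth_min_m = c(500, 100, 570),
    depth_max_m = c(500, 400, 700))
  cur <- curate_records(rec, manual_exclusion_ids = character(0))
  # min=100, max=400: mean 250, range 300 > 125 -> excluded
  expect_equal(cur$curated$excluded_range_rule, c(FALSE, TRUE, FALSE))
  expect_equal(cur$curated$depth_point_m, c(500, 250, 635))
  expect_equal(cur$report$n_retained, 2)
  expect_equal(cur$report$n_input,
               cur$report$n_retained + cur$report$n_excluded_range +
                 cur$report$n_excluded_manual)
})

test_that("manual exclusion takes precedence over the range rule in the report", {
  rec <- make_records(record_id = c("a", "b"), genus = "g",
                      depth_min_m = c(100, 100), depth_max_m = c(400, 400))
  cur <- curate_records(rec, manual_exclusion_ids = "a")
  expect_equal(cur$report$n_excluded_manual, 1)
  expect_equal(cur$report$n_excluded_range, 1)
  expect_equal(cur$report$n_retained, 0)
  expect_equal(sum(cur$curated$n_colonies[!cur$curated$excluded_manual &
                                            !cur$curated$excluded_range_rule]),
               cur$report$n_colonies_retained)
})

test_that("genus depth summaries use Tukey hinges and the 1.5 IQR outlier rule", {
  rec <- make_records(record_id = paste0("r", 1:5), genus = "g",
                      depth_min_m = c(100, 200, 300, 400, 10000),
                      depth_max_m = c(100, 200, 300, 400, 10000))
  s <- genus_depth_summary(curate_records(rec, character(0))$retained)
  expect_equal(s$outliers[[1]], 10000)
  expect_equal(s$median, 300)
  one <- make_records(record_id = "x", genus = "g",
                      depth_min_m = 800, depth_max_m = 800)
  s1 <- genus_depth_summary(curate_records(one, character(0))$retained)
  expect_equal(unlist(s1[, c("depth_min", "lower_hinge", "median",
                             "upper_hinge", "depth_max")], use.names = FALSE),
               rep(800, 5))
})

test_that("five-number summaries agree with the median-of-halves oracle", {
  set.seed(77)
  for (k in 1:25) {
    n <- sample(1:40, 1)
    d <- round(runif(n, 10, 4000), 1)
    rec <- make_records(record_id = paste0("r", seq_len(n)), genus = "g",
                        depth_min_m = d, depth_max_m = d)
    s <- genus_depth_summary(curate_records(rec, character(0))$retained)
    expect_equal(unlist(s[, c("depth_min", "lower_hinge", "median",
                              "upper_hinge", "depth_max")], use.names = FALSE),
                 unname(oracle_hinges(d)))
  }
})

test_that("species depth ranges span records and nest within the genus range", {
  rec <- make_records(
    record_id = paste0("r", 1:5), genus = "Chrysogorgia",
    species = c("sp1", "sp1", "sp1", "sp2", NA),
    depth_min_m = c(600, 1000, 2000, 150, 3000),
    depth_max_m = c(600, 1000, 2000, 150, 3000))
  ret <- curate_records(rec, character(0))$retained
  rng <- species_depth_ranges(ret)
  sp1 <- rng[rng$species == "Chrysogorgia sp1", ]
  expect_equal(c(sp1$depth_lo, sp1$depth_hi, sp1$n_records), c(600, 2000, 3))
  sp2 <- rng[rng$species == "Chrysogorgia sp2", ]
  expect_equal(sp2$depth_lo, sp2$depth_hi)  # single record: zero-width range
  expect_true(all(rng$depth_lo >= min(ret$depth_point_m) &
                    rng$depth_hi <= max(ret$depth_point_m)))
})

test_that("shallow-species counting uses a strict boundary", {
  rng <- data.frame(species = c("a", "b", "c"), genus = "g",
                    depth_lo = c(150, 200, 600), depth_hi = c(700, 900, 950),
                    n_records = 1L)
  res <- species_shallower_than(rng, 200)
  expect_equal(res$count, 1)
  expect_equal(res$species, "a")  # exactly-200 not counted
  expect_equal(species_shallower_than(rng, 100)$count, 0)
})

test_that("diversity profile counts range-through overlap per 100-m bin", {
  rng <- data.frame(species = c("x", "y"), genus = "g",
                    depth_lo = c(150, 50), depth_hi = c(450, 120),
                    n_records = 1L)
  prof <- diversity_profile(rng)
  expect_equal(nrow(prof), 45)
  hit <- function(lo) prof$n_species[prof$bin_lo == lo]
  expect_equal(hit(100), 2)  # both species overlap [100,200)
  expect_equal(hit(0), 1)
  expect_equal(hit(200), 1); expect_equal(hit(400), 1); expect_equal(hit(500), 0)
  # double-counting identity: total bin hits = sum over species of bins spanned
  per_species <- vapply(seq_len(nrow(rng)), function(i) {
    sum(rng$depth_lo[i] < prof$bin_hi & rng$depth_hi[i] >= prof$bin_lo)
  }, numeric(1))
  expect_equal(sum(prof$n_species), sum(per_species))
})

test_that("profiles are order-invariant and monotone under range widening", {
  set.seed(13)
  rng <- data.frame(species = paste0("s", 1:30), genus = "g",
                    depth_lo = runif(30, 0, 3000), n_records = 1L)
  rng$depth_hi <- rng$depth_lo + runif(30, 0, 1500)
  prof <- diversity_profile(rng)
  shuffled <- rng[sample(nrow(rng)), ]
  expect_equal(diversity_profile(shuffled), prof)
  wider <- rng
  wider$depth_lo <- pmax(0.1, wider$depth_lo - 200)
  wider$depth_hi <- wider$depth_hi + 200
  expect_true(all(diversity_profile(wider)$n_species >= prof$n_species))
})

test_that("ranges beyond the terminal bin are counted there, and level mode spans levels", {
  rng <- data.frame(species = "deep", genus = "g",
                    depth_lo = 4600, depth_hi = 4800, n_records = 1L)
  prof <- suppressMessages(diversity_profile(rng))
  expect_equal(prof$n_species[prof$bin_lo == 4400], 1)
  lev <- diversity_profile(
    data.frame(species = "x", genus = "g", depth_lo = 150, depth_hi = 450,
               n_records = 1L), method = "level")
  expect_equal(lev$n_species[lev$bin_lo %in% c(200, 300, 400)], rep(1, 3))
  expect_equal(lev$n_species[lev$bin_lo %in% c(100, 500)], rep(0, 2))
})
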