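test_that("identical band schemas pass rates through unchanged", {
  b <- age_bands(c("0-44", "45-64", "65+"))
  inc <- incidence_table(b, c(0.001, 0.004, 0.02))
  expect_equal(unname(harmonize_bands(b, inc)), c(0.001, 0.004, 0.02))
})

test_that("split bands get the overlap-length-weighted mean rate", {
  pop <- age_bands(c("0-69", "70+"))
  inc <- incidence_table(age_bands(c("0-64", "65-69", "70+")),
                         c(0.001, 0.004, 0.02))
  r <- harmonize_bands(pop, inc)
  expect_equal(unname(r[1]), (65 * 0.001 + 5 * 0.004) / 70)
  expect_equal(unname(r[2]), 0.02)
})

test_that("harmonized rates equal the year-by-year expansion oracle", {
  # oracle: give every single year of age its incidence rate, then average
  # over the years a population band spans (open band closed at the cap)
  year_oracle <- function(pop, inc, cap = 100) {
    ages <- 0:cap
    rate_of_age <- vapply(ages, function(a) {
      i <- which(inc$lower <= a & (is.infinite(inc$upper) | a <= inc$upper))
      inc$rate[i]
    }, numeric(1))
    vapply(seq_len(nrow(pop)), function(i) {
      hi <- if (is.infinite(pop$upper[i])) cap else pop$upper[i]
      mean(rate_of_age[ages >= pop$lower[i] & ages <= hi])
    }, numeric(1))
  }
  set.seed(14)
  for (rep in 1:20) {
    cuts_p <- sort(sample(1:99, sample(2:6, 1)))
    cuts_i <- sort(sample(1:99, sample(2:6, 1)))
    mk <- function(cuts) {
      lo <- c(0, cuts)
      up <- c(cuts - 1, Inf)
      age_bands(c(sprintf("%d-%d", lo[-length(lo)], up[-length(up)]),
                  sprintf("%d+", lo[length(lo)])))
    }
    pop <- mk(cuts_p)
    inc <- incidence_table(mk(cuts_i), round(runif(length(cuts_i) + 1, 0, 0.05), 4))
    expect_equal(unname(harmonize_bands(pop, inc)), year_oracle(pop, inc),
                 tolerance = 1e-12)
  }
})

test_that("band gaps are a hard error in harmonization", {
  pop <- age_bands(c("0-64", "70+"))  # 65-69 missing
  inc <- synthetic_incidence_table()
  expect_error(harmonize_bands(pop, inc), "gap")
  pop2 <- age_bands(c("0-64", "65-84"))  # not open-ended
  expect_error(harmonize_bands(pop2, inc), "open-ended")
})

test_that("stroke projection is the population-weighted rate sum", {
  # 1000 people at 0.002 + 500 at 0.010 = 7 expected strokes
  bands <- age_bands(c("0-64", "65+"))
  df <- data.frame(id = "S1", name = "Only", lat = -33.9, lon = 151,
                   check.names = FALSE)
  df[["0-64"]] <- 1000
  df[["65+"]] <- 500
  sub <- ecrhubs:::suburb_table(df, bands)
  inc <- incidence_table(bands, c(0.002, 0.010))
  pr <- project_strokes(sub, inc)
  expect_equal(pr$per_suburb$strokes, 7.0)
  expect_equal(pr$city_total, 7.0)

  # zero population projects zero strokes
  df0 <- df; df0[["0-64"]] <- 0; df0[["65+"]] <- 0
  pr0 <- project_strokes(ecrhubs:::suburb_table(df0, bands), inc)
  expect_equal(pr0$city_total, 0)

  # linearity: doubling every rate doubles every projection
  inc2 <- incidence_table(bands, 2 * c(0.002, 0.010))
  expect_equal(project_strokes(sub, inc2)$city_total, 2 * pr$city_total)
})

test_that("projection totals are invariant to the hub subset chosen", {
  city <- generate_city(city_gen_spec(n_suburbs = 50, seed = 19))
  pr <- project_strokes(city$suburbs, city$incidence)
  expect_equal(pr$city_total, sum(pr$per_suburb$strokes))
  # with an infinite threshold every catchment suburb is covered, so the
  # per-catchment stroke sums add to the city total for any subset
  for (s in list("H1", c("H2", "H4"), sprintf("H%d", 1:5))) {
    m <- assign_catchments(city$matrix, s)
    cv <- coverage(m, Inf)
    cl <- caseload(m, cv, pr)
    expect_equal(cl$total_covered_strokes, pr$city_total)
  }
})

test_that("caseload reproduces the published per-hub planning arithmetic", {
  # three single-suburb catchments carrying 2837 + 2270 + 4185 = 9292
  # projected strokes, all covered; 15% eligibility over 3 hubs -> 465
  sub <- toy_suburbs(c(2837, 2270, 4185))
  tm <- block_matrix(c(1, 1, 1), own = 10)
  m <- assign_catchments(tm, c("H1", "H2", "H3"))
  cv <- coverage(m, 30)
  pr <- project_strokes(sub, toy_incidence())
  cl <- caseload(m, cv, pr, eligibility = 0.15)
  expect_equal(cl$per_hub$covered_strokes, c(2837, 2270, 4185))
  expect_equal(cl$total_covered_strokes, 9292)
  expect_equal(cl$per_hub_average, 465)

  cl0 <- caseload(m, cv, pr, eligibility = 0)
  expect_equal(cl0$per_hub$eligible, c(0, 0, 0))
  expect_equal(cl0$per_hub_average, 0)
  expect_error(caseload(m, cv, pr, eligibility = 1.2), "\\[0, 1\\]")
})

test_that("per-hub covered strokes equal a brute-force filter-and-sum", {
  city <- generate_city(city_gen_spec(n_suburbs = 45, seed = 23))
  pr <- project_strokes(city$suburbs, city$incidence)
  hubs <- c("H1", "H3", "H5")
  m <- assign_catchments(city$matrix, hubs)
  cv <- coverage(m, 30)
  cl <- caseload(m, cv, pr, eligibility = 0.15)
  a <- m$assignment
  for (h in hubs) {
    ids <- a$suburb_id[a$hub_id == h & a$minutes < 30]
    want <- sum(pr$per_suburb$strokes[pr$per_suburb$suburb_id %in% ids])
    expect_equal(cl$per_hub$covered_strokes[cl$per_hub$hub_id == h], want)
  }
  expect_equal(cl$total_eligible, 0.15 * cl$total_covered_strokes)
})

test_that("published caseload rows sum to their printed totals", {
  expect_equal(sum_model_patients(c(2837, 2270, 4185)), 9292)
  expect_equal(sum_model_patients(c(1647, 1332, 2433)), 5412)
  expect_equal(sum_model_patients(numeric(0)), 0)
  expect_error(sum_model_patients(c(3, -1)), "non-negative")
})
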