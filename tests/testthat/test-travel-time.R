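test_that("haversine distance matches the closed form and is symmetric", {
  expect_equal(haversine_km(-33.9, 151.2, -33.9, 151.2), 0)
  # one degree of longitude on the equator: 6371 * pi / 180 km
  expect_equal(haversine_km(0, 0, 0, 1), 111.195, tolerance = 0.001 / 111.195)
  set.seed(31)
  for (i in 1:100) {
    a <- c(runif(1, -90, 90), runif(1, -180, 180))
    b <- c(runif(1, -90, 90), runif(1, -180, 180))
    expect_identical(haversine_km(a[1], a[2], b[1], b[2]),
                     haversine_km(b[1], b[2], a[1], a[2]))
  }
  expect_error(haversine_km(95, 0, 0, 0), "coordinates")
  expect_error(haversine_km(0, 0, 0, NA), "coordinates")
})

test_that("haversine agrees with an independent geodesy implementation", {
  set.seed(7)
  lat1 <- runif(50, -80, 80); lon1 <- runif(50, -180, 180)
  lat2 <- runif(50, -80, 80); lon2 <- runif(50, -180, 180)
  ours <- haversine_km(lat1, lon1, lat2, lon2)
  ref <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                  r = 6371000) / 1000
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("synthetic travel minutes follow the stated arithmetic", {
  sc0 <- travel_scenario(base_speed_kmh = 40, congestion_multiplier = 1.5,
                         noise_sd_min = 0)
  p <- c(-33.9, 151.2)
  expect_equal(synth_travel_minutes(p, p, sc0), 0)

  # 10 km east on the equator: 10 * 1.3 / 40 * 60 * 1.5 = 29.25 min
  dest <- c(0, 10 / (6371 * pi / 180))
  expect_equal(synth_travel_minutes(c(0, 0), dest, sc0), 29.25,
               tolerance = 1e-9)

  # additive bias shifts the noise-free time by exactly that many minutes
  sc_b <- travel_scenario(base_speed_kmh = 40, congestion_multiplier = 1.5,
                          noise_sd_min = 0, bias_min = 3.5)
  expect_equal(synth_travel_minutes(c(0, 0), dest, sc_b), 29.25 + 3.5)

  # never negative, even when the bias drags the time below zero
  sc_neg <- travel_scenario(noise_sd_min = 0, bias_min = -100)
  expect_equal(synth_travel_minutes(c(0, 0), c(0, 0.01), sc_neg), 0)
})

test_that("noisy travel times are deterministic per (pair, seed)", {
  sc <- travel_scenario(noise_sd_min = 5, seed = 99)
  a <- c(-33.9, 151.2); b <- c(-33.7, 151.0)
  expect_identical(synth_travel_minutes(a, b, sc),
                   synth_travel_minutes(a, b, sc))
  # a different seed gives a different draw, a different pair too
  sc2 <- travel_scenario(noise_sd_min = 5, seed = 100)
  expect_false(synth_travel_minutes(a, b, sc) == synth_travel_minutes(a, b, sc2))
  expect_false(synth_travel_minutes(a, b, sc) ==
                 synth_travel_minutes(a, c(-33.71, 151.0), sc))
  # and the global RNG stream is untouched
  set.seed(1); before <- .Random.seed
  synth_travel_minutes(a, b, sc)
  expect_identical(.Random.seed, before)
})

test_that("noise-free synthetic minutes increase strictly with distance", {
  sc <- travel_scenario(noise_sd_min = 0)
  d <- seq(0.01, 0.5, length.out = 20)
  mins <- vapply(d, function(dd) synth_travel_minutes(c(0, 0), c(0, dd), sc),
                 numeric(1))
  expect_true(all(diff(mins) > 0))
})

test_that("build_travel_matrix covers every pair and matches per-pair calls", {
  city <- generate_city(city_gen_spec(n_suburbs = 20, n_hospitals = 3, seed = 3))
  sc <- travel_scenario(seed = 3)
  tm <- build_travel_matrix(city$suburbs, city$hospitals,
                            synthetic_travel_provider(), sc)
  expect_equal(dim(tm$minutes), c(20, 3))
  expect_equal(length(tm$minutes), 60)
  for (i in c(1, 7, 20)) {
    for (j in 1:3) {
      expect_equal(tm$minutes[i, j],
                   synth_travel_minutes(c(city$suburbs$lat[i], city$suburbs$lon[i]),
                                        c(city$hospitals$lat[j], city$hospitals$lon[j]),
                                        sc))
    }
  }
  # determinism: a fresh provider reproduces the matrix bit for bit
  tm2 <- build_travel_matrix(city$suburbs, city$hospitals,
                             synthetic_travel_provider(), sc)
  expect_identical(tm$minutes, tm2$minutes)
})

test_that("warm cache means zero provider requests on re-run", {
  city <- generate_city(city_gen_spec(n_suburbs = 12, n_hospitals = 3, seed = 4))
  sc <- travel_scenario(seed = 4)
  cache <- withr::local_tempfile(fileext = ".csv")
  p1 <- synthetic_travel_provider()
  tm1 <- build_travel_matrix(city$suburbs, city$hospitals, p1, sc, cache_file = cache)
  expect_equal(provider_stats(p1)$total, 36)
  p2 <- synthetic_travel_provider()
  tm2 <- build_travel_matrix(city$suburbs, city$hospitals, p2, sc, cache_file = cache)
  expect_equal(provider_stats(p2)$total, 0)
  expect_identical(tm1$minutes, tm2$minutes)
})

test_that("the session quota is honoured and total requests equal uncached pairs", {
  city <- generate_city(city_gen_spec(n_suburbs = 20, n_hospitals = 3, seed = 5))
  p <- synthetic_travel_provider(limit = 7)
  build_travel_matrix(city$suburbs, city$hospitals, p, travel_scenario(seed = 5))
  st <- provider_stats(p)
  expect_lte(st$max_session, 7)
  expect_equal(st$total, 60)
  expect_equal(st$sessions, ceiling(60 / 7))
})

test_that("a provider failure yields the unreachable sentinel, not an abort", {
  city <- generate_city(city_gen_spec(n_suburbs = 5, n_hospitals = 2, seed = 6))
  flaky <- travel_provider(function(origin, dest, scenario) {
    if (abs(origin[1] - city$suburbs$lat[2]) < 1e-12) stop("boom")
    synth_travel_minutes(origin, dest, scenario)
  })
  w <- capture_warnings(tm <- build_travel_matrix(city$suburbs, city$hospitals,
                                                  flaky, travel_scenario(seed = 6)))
  expect_true(any(grepl("provider failed on 2 pair", w)))
  expect_true(all(is.na(tm$minutes[2, ])))
  expect_true(all(is.finite(tm$minutes[-2, ])))
})
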