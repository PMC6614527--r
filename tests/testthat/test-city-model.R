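test_that("age-band labels parse to the declared schema", {
  b <- age_bands(c("65+", "0-44", "45-64"))
  expect_equal(b$label, c("0-44", "45-64", "65+"))
  expect_equal(b$lower, c(0, 45, 65))
  expect_equal(b$upper, c(44, 64, Inf))
  expect_error(age_bands(c("0-44", "40-64")), "overlap")
  expect_error(age_bands("elderly"), "unparseable")
  expect_error(age_bands(c("0-64", "65+", "70+")), "open-ended")
})

test_that("suburb reader parses band columns against the declared schema", {
  bands <- age_bands(c("0-64", "65+"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,name,lat,lon,0-64,65+",
               "S1,Alpha,-33.9,151.1,1000,200",
               "S2,Beta,-33.8,151.2,500,80",
               "S3,Gamma,-33.7,151.3,2500,400"), path)
  s <- read_suburbs(path, bands)
  expect_s3_class(s, "suburb_table")
  expect_equal(nrow(s), 3)
  expect_equal(s[["0-64"]], c(1000, 500, 2500))
  expect_equal(attr(s, "bands")$label, c("0-64", "65+"))
})

test_that("suburb reader rejects invalid files with named culprits", {
  bands <- age_bands(c("0-64", "65+"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,name,lat,lon,0-64,65+",
               "S1,Alpha,-33.9,151.1,1000,200",
               "S1,Beta,-33.8,151.2,500,80"), path)
  expect_error(read_suburbs(path, bands), "S1")
  writeLines(c("id,name,lat,lon,0-64,65+,80+",
               "S1,Alpha,-33.9,151.1,1000,200,10"), path)
  expect_error(read_suburbs(path, bands), "80\\+")
  writeLines(c("id,name,lat,lon,0-64,65+",
               "S1,Alpha,-33.9,151.1,-3,200"), path)
  expect_error(read_suburbs(path, bands), "negative")
})

test_that("a generated 226-suburb city round-trips through the CSV writers", {
  city <- generate_city(city_gen_spec(seed = 42))
  dir <- withr::local_tempdir()
  write_city(city, dir)
  back <- read_city(dir, age_bands(names(ecrhubs:::default_age_props())))
  expect_equal(as.data.frame(back$suburbs), as.data.frame(city$suburbs),
               tolerance = 1e-12)
  expect_equal(as.data.frame(back$hospitals), as.data.frame(city$hospitals))
  # minutes are stored at 2 decimals
  expect_equal(back$matrix$minutes, round(city$matrix$minutes, 2))
  expect_equal(back$incidence$rate, city$incidence$rate)
  # a second write/read cycle is exact
  dir2 <- withr::local_tempdir()
  write_city(back, dir2)
  again <- read_city(dir2, age_bands(names(ecrhubs:::default_age_props())))
  expect_identical(again$matrix$minutes, back$matrix$minutes)
})

test_that("wide and long travel encodings load to equal matrices", {
  tm <- rand_matrix(5, 3, seed = 9)
  fw <- withr::local_tempfile(fileext = ".csv")
  fl <- withr::local_tempfile(fileext = ".csv")
  write_travel_matrix(tm, fw, layout = "wide")
  write_travel_matrix(tm, fl, layout = "long")
  mw <- read_travel_matrix(fw, "wide")
  ml <- read_travel_matrix(fl, "long")
  expect_equal(mw$minutes, ml$minutes[rownames(mw$minutes), colnames(mw$minutes)])
})

test_that("travel reader turns bad or absent cells into the unreachable sentinel", {
  fw <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("suburb_id,H1,H2", "S1,10,40", "S2,,12", "S3,-5,33"), fw)
  expect_warning(tm <- read_travel_matrix(fw, "wide"), "unreachable")
  expect_true(is.na(tm$minutes["S2", "H1"]))
  expect_true(is.na(tm$minutes["S3", "H1"]))
  expect_equal(tm$minutes["S1", ], c(H1 = 10, H2 = 40))

  fl <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("suburb_id,hospital_id,minutes",
               "S1,H1,10", "S1,H2,40", "S2,H2,12"), fl)
  expect_warning(tl <- read_travel_matrix(fl, "long"), "unreachable")
  expect_true(is.na(tl$minutes["S2", "H1"]))
})

test_that("travel reader enforces the registries", {
  bands <- age_bands("0+")
  sub <- toy_suburbs(c(1, 2))
  hosp <- ecrhubs:::hospital_table(data.frame(
    id = "H1", name = "A", lat = -33.9, lon = 151, ecr_capable = TRUE))
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("suburb_id,hospital_id,minutes", "S001,H1,10", "SX,H1,12"), f)
  expect_error(read_travel_matrix(f, "long", suburbs = sub, hospitals = hosp),
               "SX")
  writeLines(c("suburb_id,hospital_id,minutes", "S001,H9,10"), f)
  expect_error(read_travel_matrix(f, "long", suburbs = sub, hospitals = hosp),
               "H9")
})

test_that("validate_city reports all violations and passes clean bundles", {
  city <- generate_city(city_gen_spec(n_suburbs = 30, seed = 5))
  expect_length(validate_city(city$suburbs, city$hospitals, city$matrix,
                              city$incidence), 0)

  # drop one suburb row from the matrix
  m2 <- suppressWarnings(travel_matrix(city$matrix$minutes[-1, ],
                                       city$matrix$scenario_label))
  v <- validate_city(city$suburbs, city$hospitals, m2, city$incidence)
  expect_length(v, 1)
  expect_match(v, city$suburbs$id[1])

  # incidence schema with a hole: 65-69 missing
  gap_inc <- incidence_table(age_bands(c("0-44", "45-54", "55-64", "70-84", "85+")),
                             c(1, 1, 1, 1, 1) / 1000)
  v2 <- validate_city(city$suburbs, city$hospitals, city$matrix, gap_inc)
  expect_length(v2, 1)
  expect_match(v2, "65-69")
})

test_that("a bundle passing validation runs the whole pipeline without errors", {
  city <- generate_city(city_gen_spec(n_suburbs = 40, seed = 11))
  expect_length(validate_city(city$suburbs, city$hospitals, city$matrix,
                              city$incidence), 0)
  pr <- project_strokes(city$suburbs, city$incidence)
  sets <- enumerate_hub_sets(city$hospitals$id, 1, 5)
  expect_error(score_hub_sets(city$matrix, sets, 30, pr), NA)
})
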