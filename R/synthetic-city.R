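# run code under a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# integer split of `total` by proportions with largest-remainder rounding:
# floors first, then distributes the leftover units to the largest
# fractional parts (ties to the earlier band) — parts always sum to total
split_largest_remainder <- function(total, props) {
  q <- total * props
  base <- floor(q)
  rem <- as.integer(round(total - sum(base)))
  if (rem > 0) {
    take <- order(-(q - base), seq_along(q))[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

default_age_props <- function() {
  c("0-44" = 0.60, "45-54" = 0.13, "55-64" = 0.11,
    "65-74" = 0.09, "75-84" = 0.05, "85+" = 0.02)
}

#' Illustrative synthetic incidence tables
#'
#' Two age-specific first-ever stroke rate tables of realistic magnitude
#' (rates rise steeply with age, from ~1 per 10,000 person-years under 45
#' to a few per 100 person-years at 85+). Both are synthetic illustrations
#' for running the pipeline offline — they are not measured rates from any
#' incidence study, and real planning work must substitute the local
#' study's table via [read_incidence()] or [incidence_table()].
#'
#' @param variant `"higher"` or `"lower"` — two tables of different overall
#'   level, so analyses can be run against a pair of rate sources.
#' @return An [incidence_table()].
#' @export
synthetic_incidence_table <- function(variant = c("higher", "lower")) {
  variant <- match.arg(variant)
  bands <- age_bands(names(default_age_props()))
  rates <- switch(variant,
    higher = c(0.0001, 0.0015, 0.0030, 0.0070, 0.0150, 0.0250),
    lower  = c(0.00006, 0.0009, 0.0017, 0.0040, 0.0090, 0.0150))
  incidence_table(bands, rates,
                  source_label = paste0("synthetic_", variant))
}

#' Synthetic-city generation settings
#'
#' Declares the shape of a generated metropolitan area. Defaults emulate
#' the setting the pipeline is designed for: 226 population units around
#' five candidate ECR sites, in a ~50 km urban extent, with log-normal
#' suburb populations (median ~8,000) split across six age bands in
#' metro-like proportions.
#'
#' @param n_suburbs Number of population units (>= `n_hospitals`).
#' @param n_hospitals Number of candidate hub sites (>= 1).
#' @param seed Integer seed; the whole bundle is deterministic in it.
#' @param extent_km Diameter of the disc suburb centroids are drawn on.
#' @param pop_meanlog,pop_sdlog Log-normal parameters for suburb totals.
#' @param age_props Named proportions per age band (names form the band
#'   schema); must sum to 1.
#' @param center `c(lat, lon)` of the city centre.
#' @param scenario A [travel_scenario()]; defaults to morning peak seeded
#'   from `seed`.
#' @param incidence An [incidence_table()]; defaults to
#'   `synthetic_incidence_table("higher")`.
#' @return Object of class `city_gen_spec`.
#' @export
city_gen_spec <- function(n_suburbs = 226, n_hospitals = 5, seed = 1L,
                          extent_km = 50, pop_meanlog = log(8000),
                          pop_sdlog = 0.6, age_props = default_age_props(),
                          center = c(-33.87, 151.21),
                          scenario = travel_scenario(seed = seed),
                          incidence = synthetic_incidence_table("higher")) {
  if (n_hospitals < 1 || n_suburbs < n_hospitals) {
    abort("need n_suburbs >= n_hospitals >= 1")
  }
  if (is.null(names(age_props)) || any(!nzchar(names(age_props)))) {
    abort("age_props must be named by band label")
  }
  if (abs(sum(age_props) - 1) > 1e-9) abort("age_props must sum to 1")
  if (extent_km <= 0) abort("extent_km must be positive")
  structure(list(n_suburbs = as.integer(n_suburbs),
                 n_hospitals = as.integer(n_hospitals),
                 seed = as.integer(seed), extent_km = extent_km,
                 pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
                 age_props = age_props, center = center,
                 scenario = scenario, incidence = incidence),
            class = "city_gen_spec")
}

#' Generate a synthetic city bundle
#'
#' Builds a complete, validated analysis bundle with known ground truth:
#' suburb centroids uniform over a disc, log-normal total populations split
#' across the age bands by largest-remainder rounding (band counts always
#' sum to the suburb total), candidate hospitals at k-means cluster centres
#' of the centroids (so sites sit where people are, as real hospitals do),
#' and a peak-hour travel-time matrix from the synthetic provider. The
#' bundle is fully deterministic in `spec$seed`.
#'
#' @param spec A [city_gen_spec()].
#' @return Object of class `ecr_city`: list with `suburbs`, `hospitals`,
#'   `matrix`, `incidence`.
#' @export
generate_city <- function(spec = city_gen_spec()) {
  stopifnot(inherits(spec, "city_gen_spec"))
  km_per_deg <- 6371 * pi / 180
  with_seed(spec$seed, {
    n <- spec$n_suburbs
    r <- spec$extent_km / 2 * sqrt(stats::runif(n))
    th <- 2 * pi * stats::runif(n)
    x <- r * cos(th); y <- r * sin(th)
    lat <- spec$center[1] + y / km_per_deg
    lon <- spec$center[2] + x / (km_per_deg * cos(spec$center[1] * pi / 180))
    total <- pmax(1, round(stats::rlnorm(n, spec$pop_meanlog, spec$pop_sdlog)))
    counts <- t(vapply(total, split_largest_remainder, integer(length(spec$age_props)),
                       props = spec$age_props))
    colnames(counts) <- names(spec$age_props)
    ids <- sprintf("S%03d", seq_len(n))
    sub_df <- data.frame(id = ids, name = paste("Suburb", seq_len(n)),
                         lat = lat, lon = lon, stringsAsFactors = FALSE)
    sub_df <- cbind(sub_df, as.data.frame(counts))
    suburbs <- suburb_table(sub_df, age_bands(names(spec$age_props)))

    km <- stats::kmeans(cbind(x, y), centers = spec$n_hospitals,
                        nstart = 10, iter.max = 100)
    ctr <- km$centers[order(km$centers[, 1]), , drop = FALSE]
    hospitals <- hospital_table(data.frame(
      id = sprintf("H%d", seq_len(spec$n_hospitals)),
      name = paste("Hospital", seq_len(spec$n_hospitals)),
      lat = spec$center[1] + ctr[, 2] / km_per_deg,
      lon = spec$center[2] + ctr[, 1] / (km_per_deg * cos(spec$center[1] * pi / 180)),
      ecr_capable = TRUE, stringsAsFactors = FALSE))

    matrix <- build_travel_matrix(suburbs, hospitals,
                                  synthetic_travel_provider(),
                                  spec$scenario)
    structure(list(suburbs = suburbs, hospitals = hospitals,
                   matrix = matrix, incidence = spec$incidence),
              class = "ecr_city")
  })
}

#' Generate a fixture city with planted coverage fractions
#'
#' Constructs travel times directly (not from distance) so that hub `j`'s
#' catchment contains exactly `catchment_size[j]` suburbs of which
#' `round_half_up(covered_frac[j] * catchment_size[j])` lie strictly within
#' the threshold. Running [assign_catchments()] + [coverage()] on the
#' bundle recovers the planted per-hub fractions and counts exactly, which
#' makes it the fixture of choice for end-to-end recovery tests: statistical
#' realism lives in [generate_city()], exactness lives here.
#'
#' @param covered_frac Per-hub covered fraction in `[0, 1]`.
#' @param catchment_size Per-hub catchment size (>= 1), same length.
#' @param seed Integer seed for the (cosmetic) coordinates and populations.
#' @param threshold Threshold the fractions are planted at, default 30 min.
#' @return An `ecr_city` bundle.
#' @export
generate_known_coverage_city <- function(covered_frac, catchment_size,
                                         seed = 1L, threshold = 30) {
  k <- length(covered_frac)
  if (length(catchment_size) != k || k == 0) {
    abort("covered_frac and catchment_size must be non-empty and equal length")
  }
  if (any(covered_frac < 0 | covered_frac > 1)) abort("covered fractions must lie in [0, 1]")
  if (any(catchment_size < 1)) abort("catchment sizes must be >= 1")
  n <- sum(catchment_size)
  n_cov <- round_half_up(covered_frac * catchment_size)
  props <- default_age_props()
  km_per_deg <- 6371 * pi / 180
  with_seed(seed, {
    hub_of <- rep(seq_len(k), catchment_size)
    minutes <- matrix(threshold + 60 + abs(outer(hub_of, seq_len(k), "-")) * 5,
                      nrow = n, ncol = k)
    covered <- unlist(lapply(seq_len(k), function(j) {
      seq_len(catchment_size[j]) <= n_cov[j]
    }))
    minutes[cbind(seq_len(n), hub_of)] <- ifelse(covered, threshold / 2,
                                                 threshold + 15)
    ids <- sprintf("S%03d", seq_len(n))
    hids <- sprintf("H%d", seq_len(k))
    dimnames(minutes) <- list(ids, hids)

    total <- pmax(1, round(stats::rlnorm(n, log(8000), 0.6)))
    counts <- t(vapply(total, split_largest_remainder, integer(length(props)),
                       props = props))
    colnames(counts) <- names(props)
    hub_lon <- 151 + (seq_len(k) - 1) * 20 / km_per_deg
    sub_df <- data.frame(id = ids, name = paste("Suburb", seq_len(n)),
                         lat = -33.9 + stats::runif(n, -0.02, 0.02),
                         lon = hub_lon[hub_of] + stats::runif(n, -0.02, 0.02),
                         stringsAsFactors = FALSE)
    sub_df <- cbind(sub_df, as.data.frame(counts))
    suburbs <- suburb_table(sub_df, age_bands(names(props)))
    hospitals <- hospital_table(data.frame(
      id = hids, name = paste("Hospital", seq_len(k)),
      lat = -33.9, lon = hub_lon, ecr_capable = TRUE,
      stringsAsFactors = FALSE))
    structure(list(suburbs = suburbs, hospitals = hospitals,
                   matrix = travel_matrix(minutes, "planted"),
                   incidence = synthetic_incidence_table("higher")),
              class = "ecr_city")
  })
}

#' @export
print.ecr_city <- function(x, ...) {
  cat(sprintf("Synthetic city: %d suburbs, %d candidate hospitals, scenario '%s'\n",
              nrow(x$suburbs), nrow(x$hospitals), x$matrix$scenario_label))
  invisible(x)
}

#' Write / read a city bundle as CSV files
#'
#' Writes `suburbs.csv`, `hospitals.csv`, `travel.csv` (long layout) and
#' `incidence.csv` into a directory, in the same formats the individual
#' readers use; `read_city()` loads them back.
#'
#' @param city An `ecr_city`.
#' @param dir Directory (created if needed).
#' @return `write_city()` the directory, invisibly; `read_city()` an
#'   `ecr_city`.
#' @export
write_city <- function(city, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_suburbs(city$suburbs, file.path(dir, "suburbs.csv"))
  write_hospitals(city$hospitals, file.path(dir, "hospitals.csv"))
  write_travel_matrix(city$matrix, file.path(dir, "travel.csv"), layout = "long")
  write_incidence(city$incidence, file.path(dir, "incidence.csv"))
  invisible(dir)
}

#' @rdname write_city
#' @param bands The [age_bands()] schema of `suburbs.csv`.
#' @export
read_city <- function(dir, bands) {
  suburbs <- read_suburbs(file.path(dir, "suburbs.csv"), bands)
  hospitals <- read_hospitals(file.path(dir, "hospitals.csv"))
  matrix <- read_travel_matrix(file.path(dir, "travel.csv"), layout = "long",
                               suburbs = suburbs, hospitals = hospitals)
  incidence <- read_incidence(file.path(dir, "incidence.csv"))
  structure(list(suburbs = suburbs, hospitals = hospitals,
                 matrix = matrix, incidence = incidence),
            class = "ecr_city")
}
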