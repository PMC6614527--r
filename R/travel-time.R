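#' Great-circle distance
#'
#' Haversine distance on a sphere of radius 6371 km (mean Earth radius).
#' Vectorised over coordinates.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in WGS84 decimal degrees.
#' @return Distance in kilometres.
#' @examples
#' haversine_km(0, 0, 0, 1)  # one degree of longitude at the equator
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  r <- 6371
  p <- pi / 180
  dlat <- (lat2 - lat1) * p / 2
  dlon <- (lon2 - lon1) * p / 2
  a <- sin(dlat)^2 + cos(lat1 * p) * cos(lat2 * p) * sin(dlon)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Traffic scenario for the synthetic travel model
#'
#' The synthetic travel model stands in for a routing API: road distance is
#' approximated as great-circle distance times a detour factor, converted to
#' minutes at a free-flow speed, inflated by a congestion multiplier for the
#' named scenario, plus reproducible Gaussian noise. Defaults emulate
#' morning-peak arterial driving in a large metropolitan area: 60 km/h
#' free-flow, detour factor 1.3 (typical road/straight-line ratio), peak
#' congestion multiplier 1.5, noise sd 3 min.
#'
#' @param label Scenario name (e.g. `"morning_peak"`).
#' @param base_speed_kmh Free-flow speed, km/h (> 0).
#' @param congestion_multiplier Travel-time inflation for this scenario
#'   (>= 1; 1 = free flow).
#' @param noise_sd_min Standard deviation of the additive per-pair noise,
#'   minutes (>= 0).
#' @param detour_factor Road-distance / great-circle ratio (>= 1).
#' @param bias_min Optional additive offset in minutes (e.g. an observed
#'   ambulance-vs-API difference); default 0.
#' @param seed Integer seed making the noise reproducible; the seed is part
#'   of the scenario so a matrix is a reproducible artifact.
#' @return Object of class `travel_scenario`.
#' @export
travel_scenario <- function(label = "morning_peak", base_speed_kmh = 60,
                            congestion_multiplier = 1.5, noise_sd_min = 3,
                            detour_factor = 1.3, bias_min = 0, seed = 1L) {
  if (base_speed_kmh <= 0) abort("base_speed_kmh must be positive")
  if (congestion_multiplier < 1) abort("congestion_multiplier must be >= 1")
  if (noise_sd_min < 0) abort("noise_sd_min must be non-negative")
  if (detour_factor < 1) abort("detour_factor must be >= 1")
  structure(list(label = label, base_speed_kmh = base_speed_kmh,
                 congestion_multiplier = congestion_multiplier,
                 noise_sd_min = noise_sd_min, detour_factor = detour_factor,
                 bias_min = bias_min, seed = as.integer(seed)),
            class = "travel_scenario")
}

#' Synthetic peak-hour travel time for one origin-destination pair
#'
#' `minutes = (haversine_km * detour_factor / base_speed_kmh) * 60 *
#' congestion_multiplier + bias + noise`, truncated at 0. The noise term is
#' Gaussian with sd `noise_sd_min`, drawn deterministically from a hash of
#' (origin, destination, scenario seed): the same pair under the same seed
#' always yields the same minutes, and the global RNG stream is untouched.
#'
#' @param origin,dest Length-2 numeric vectors `c(lat, lon)`.
#' @param scenario A [travel_scenario()].
#' @return Travel time in minutes (scalar).
#' @examples
#' sc <- travel_scenario(base_speed_kmh = 40, congestion_multiplier = 1.5,
#'                       noise_sd_min = 0)
#' # ~10 km apart at 40 km/h with detour 1.3 and congestion 1.5
#' synth_travel_minutes(c(0, 0), c(0, 10 / 111.19493), sc)
#' @export
synth_travel_minutes <- function(origin, dest, scenario) {
  stopifnot(inherits(scenario, "travel_scenario"))
  km <- haversine_km(origin[1], origin[2], dest[1], dest[2])
  base <- km * scenario$detour_factor / scenario$base_speed_kmh * 60 *
    scenario$congestion_multiplier
  noise <- 0
  if (scenario$noise_sd_min > 0) {
    key <- sprintf("%.6f|%.6f|%.6f|%.6f|%d", origin[1], origin[2],
                   dest[1], dest[2], scenario$seed)
    u <- hash_unit(key)
    # keep the inverse-normal transform away from 0/1
    u <- pmin(pmax(u, 1e-9), 1 - 1e-9)
    noise <- stats::qnorm(u, mean = 0, sd = scenario$noise_sd_min)
  }
  max(0, base + scenario$bias_min + noise)
}

#' Travel-time providers
#'
#' A provider is the single contract the matrix builder talks to: one
#' request `(origin, dest, scenario) -> minutes or NA`, with a per-session
#' request quota (live routing APIs commonly cap daily queries, e.g. at
#' 2500). [build_travel_matrix()] chunks uncached pairs into sessions of at
#' most `limit` requests and persists results, so a quota-capped provider is
#' never over-asked and warm re-runs issue zero requests. The shipped
#' provider is fully synthetic ([synth_travel_minutes()]); a live-API
#' adapter only needs to supply the same `request` function.
#'
#' @param limit Maximum requests per session (default 2500).
#' @param fun Request function `(origin, dest, scenario) -> minutes`;
#'   defaults to [synth_travel_minutes()].
#' @return Object of class `travel_provider` with request counters
#'   (`total`, `session`, `max_session`, `sessions`) readable via
#'   [provider_stats()].
#' @export
travel_provider <- function(fun = synth_travel_minutes, limit = 2500) {
  if (limit < 1) abort("provider limit must be >= 1")
  counters <- new.env(parent = emptyenv())
  counters$total <- 0L
  counters$session <- 0L
  counters$max_session <- 0L
  counters$sessions <- 1L
  structure(list(fun = fun, limit = as.integer(limit), counters = counters),
            class = "travel_provider")
}

#' @rdname travel_provider
#' @export
synthetic_travel_provider <- function(limit = 2500) {
  travel_provider(synth_travel_minutes, limit = limit)
}

#' @rdname travel_provider
#' @param provider A `travel_provider`.
#' @export
provider_stats <- function(provider) {
  c <- provider$counters
  list(total = c$total, session = c$session,
       max_session = c$max_session, sessions = c$sessions)
}

# one request through the provider, enforcing the session quota;
# build_travel_matrix opens a new session when the quota is exhausted
provider_request <- function(provider, origin, dest, scenario) {
  c <- provider$counters
  if (c$session >= provider$limit) {
    abort("provider session quota exhausted; open a new session")
  }
  c$session <- c$session + 1L
  c$total <- c$total + 1L
  c$max_session <- max(c$max_session, c$session)
  tryCatch(provider$fun(origin, dest, scenario), error = function(e) NA_real_)
}

provider_new_session <- function(provider) {
  c <- provider$counters
  c$session <- 0L
  c$sessions <- c$sessions + 1L
  invisible(provider)
}

#' Build a travel-time matrix through a provider
#'
#' Computes minutes from every suburb centroid to every hospital, caching
#' each result under its `(suburb, hospital, scenario)` key. Cached pairs
#' never reach the provider, so a second run on a warm cache issues zero
#' requests, and uncached pairs are chunked into provider sessions of at
#' most `limit` requests (the cache file is written after every session, so
#' an interrupted run resumes where it stopped). A provider failure on a
#' pair yields the unreachable sentinel with a warning, not an abort.
#'
#' @param suburbs A `suburb_table`.
#' @param hospitals A `hospital_table`.
#' @param provider A [travel_provider()].
#' @param scenario A [travel_scenario()].
#' @param cache_file Optional path to a long-format cache CSV
#'   (`suburb_id,hospital_id,minutes,scenario_label`); read if it exists,
#'   updated after every provider session.
#' @return A [travel_matrix()].
#' @export
build_travel_matrix <- function(suburbs, hospitals, provider = synthetic_travel_provider(),
                                scenario = travel_scenario(), cache_file = NULL) {
  if (nrow(suburbs) == 0 || nrow(hospitals) == 0) {
    abort("suburb and hospital registries must be non-empty")
  }
  cache <- list()
  if (!is.null(cache_file) && file.exists(cache_file)) {
    cc <- utils::read.csv(cache_file, stringsAsFactors = FALSE)
    cc <- cc[cc$scenario_label == scenario$label, , drop = FALSE]
    cache <- stats::setNames(as.list(cc$minutes),
                             paste(cc$suburb_id, cc$hospital_id, sep = "\r"))
  }
  m <- matrix(NA_real_, nrow(suburbs), nrow(hospitals),
              dimnames = list(suburbs$id, hospitals$id))
  pairs <- expand.grid(si = seq_len(nrow(suburbs)), hi = seq_len(nrow(hospitals)),
                       KEEP.OUT.ATTRS = FALSE)
  pairs$key <- paste(suburbs$id[pairs$si], hospitals$id[pairs$hi], sep = "\r")
  hit <- pairs$key %in% names(cache)
  if (any(hit)) {
    m[cbind(pairs$si[hit], pairs$hi[hit])] <- unlist(cache[pairs$key[hit]])
  }
  todo <- which(!hit)
  failed <- 0L
  while (length(todo)) {
    chunk <- todo[seq_len(min(provider$limit, length(todo)))]
    todo <- todo[-seq_along(chunk)]
    for (j in chunk) {
      si <- pairs$si[j]; hi <- pairs$hi[j]
      mins <- provider_request(provider,
                               c(suburbs$lat[si], suburbs$lon[si]),
                               c(hospitals$lat[hi], hospitals$lon[hi]),
                               scenario)
      if (is.na(mins)) failed <- failed + 1L
      m[si, hi] <- mins
      cache[[pairs$key[j]]] <- mins
    }
    if (!is.null(cache_file)) {
      write_cache(cache, scenario$label, cache_file)
    }
    if (length(todo)) provider_new_session(provider)
  }
  if (failed > 0) {
    warning(sprintf("provider failed on %d pair(s); set to unreachable", failed),
            call. = FALSE)
  }
  travel_matrix(m, scenario$label)
}

write_cache <- function(cache, scenario_label, path) {
  keys <- names(cache)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  mins <- unlist(cache, use.names = FALSE)
  df <- data.frame(suburb_id = vapply(parts, `[`, "", 1),
                   hospital_id = vapply(parts, `[`, "", 2),
                   # full precision: a cache hit must reproduce the provider
                   # value bit for bit
                   minutes = sprintf("%.17g", mins),
                   scenario_label = scenario_label)
  df <- df[!is.na(mins), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
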