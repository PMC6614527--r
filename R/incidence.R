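#' Align incidence rates to a population band schema
#'
#' Census population bands and incidence-study bands rarely coincide. The
#' rate applied to a population band is the overlap-length-weighted mean of
#' the incidence rates over the single years of age the band spans (both
#' ends inclusive, so band 0-64 spans 65 years). Open-ended bands are
#' matched to open-ended bands; for weighting, the open band is closed at a
#' cap age (default 100, or one year past the highest finite bound if that
#' is larger) — equivalent to assuming a uniform age distribution within
#' bands up to the cap.
#'
#' @param pop_bands An [age_bands()] schema for the population counts.
#' @param incidence An [incidence_table()].
#' @param cap_age Closing age for the open-ended band during weighting.
#' @return Named numeric vector: one harmonised rate per population band,
#'   in `pop_bands` order.
#' @examples
#' pop <- age_bands(c("0-69", "70+"))
#' inc <- incidence_table(age_bands(c("0-64", "65-69", "70+")),
#'                        c(0.001, 0.004, 0.02))
#' harmonize_bands(pop, inc)  # first band = (65*0.001 + 5*0.004)/70
#' @export
harmonize_bands <- function(pop_bands, incidence, cap_age = 100) {
  stopifnot(inherits(pop_bands, "age_bands"), inherits(incidence, "incidence_table"))
  msg <- bands_gap_message(pop_bands, "population band schema")
  if (!is.null(msg)) abort(msg)
  msg <- bands_gap_message(incidence[, c("label", "lower", "upper")],
                           "incidence band schema")
  if (!is.null(msg)) abort(msg)

  cap <- max(cap_age, pop_bands$lower[nrow(pop_bands)] + 1,
             incidence$lower[nrow(incidence)] + 1,
             max(pop_bands$upper[is.finite(pop_bands$upper)], 0) + 1,
             max(incidence$upper[is.finite(incidence$upper)], 0) + 1)
  close_at <- function(u) ifelse(is.infinite(u), cap, u)
  pu <- close_at(pop_bands$upper)
  iu <- close_at(incidence$upper)

  rates <- vapply(seq_len(nrow(pop_bands)), function(i) {
    lo <- pop_bands$lower[i]; up <- pu[i]
    overlap <- pmax(0, pmin(up, iu) - pmax(lo, incidence$lower) + 1)
    sum(overlap * incidence$rate) / (up - lo + 1)
  }, numeric(1))
  stats::setNames(rates, pop_bands$label)
}

#' Project expected annual strokes per suburb
#'
#' Expected annual first-ever strokes in each suburb: the sum over age
#' bands of population count times the (band-harmonised) incidence rate.
#' The projection is deterministic — an expectation, not a simulation — and
#' does not depend on any hub choice.
#'
#' @param suburbs A `suburb_table`.
#' @param incidence An [incidence_table()].
#' @param cap_age Passed to [harmonize_bands()].
#' @return Object of class `stroke_projection`: list with `per_suburb`
#'   (data frame `suburb_id`, `strokes`), `city_total`, `source_label`.
#' @export
project_strokes <- function(suburbs, incidence, cap_age = 100) {
  stopifnot(inherits(suburbs, "suburb_table"))
  bands <- attr(suburbs, "bands")
  rates <- harmonize_bands(bands, incidence, cap_age = cap_age)
  counts <- as.matrix(as.data.frame(suburbs)[, bands$label, drop = FALSE])
  if (any(counts < 0)) abort("negative population count")
  strokes <- as.numeric(counts %*% rates)
  structure(list(per_suburb = data.frame(suburb_id = suburbs$id,
                                         strokes = strokes,
                                         stringsAsFactors = FALSE),
                 city_total = sum(strokes),
                 source_label = attr(incidence, "source_label")),
            class = "stroke_projection")
}

#' @export
print.stroke_projection <- function(x, ...) {
  cat(sprintf("Stroke projection (%s): %.1f expected strokes/year over %d suburbs\n",
              x$source_label, x$city_total, nrow(x$per_suburb)))
  invisible(x)
}

#' Expected ECR caseload of a hub model
#'
#' Per hub: the projected strokes in the suburbs of its catchment that are
#' covered within the threshold ("population at risk"), and the ECR-eligible
#' share of them. The per-hub average annual caseload is
#' `round_half_up(total_covered_strokes * eligibility / k)` — the planning
#' number for staffing a k-hub configuration.
#'
#' @param model A [assign_catchments()] result.
#' @param cov A [coverage()] report for the same model (supplies the
#'   threshold).
#' @param projection A [project_strokes()] result.
#' @param eligibility Fraction of strokes eligible for ECR, in `[0, 1]`;
#'   default 0.15.
#' @return Object of class `caseload_report`: list with `per_hub` (data
#'   frame `hub_id`, `covered_strokes`, `eligible`), `total_covered_strokes`,
#'   `total_eligible`, `per_hub_average`, `eligibility`, `threshold_minutes`,
#'   `source_label`.
#' @export
caseload <- function(model, cov, projection, eligibility = 0.15) {
  stopifnot(inherits(model, "catchment_model"),
            inherits(cov, "coverage_report"),
            inherits(projection, "stroke_projection"))
  if (!is.numeric(eligibility) || length(eligibility) != 1 ||
      eligibility < 0 || eligibility > 1) {
    abort("eligibility must be a single fraction in [0, 1]")
  }
  a <- model$assignment
  if (!all(a$suburb_id %in% projection$per_suburb$suburb_id)) {
    abort("projection does not cover every assigned suburb")
  }
  strokes <- projection$per_suburb$strokes[
    match(a$suburb_id, projection$per_suburb$suburb_id)]
  covered <- a$minutes < cov$threshold_minutes
  hub <- factor(a$hub_id, levels = model$hub_ids)
  covered_strokes <- as.numeric(tapply(strokes * covered, hub, sum, default = 0))
  per_hub <- data.frame(hub_id = model$hub_ids,
                        covered_strokes = covered_strokes,
                        eligible = covered_strokes * eligibility,
                        stringsAsFactors = FALSE)
  total <- sum(covered_strokes)
  structure(list(per_hub = per_hub,
                 total_covered_strokes = total,
                 total_eligible = total * eligibility,
                 per_hub_average = round_half_up(total * eligibility / length(model$hub_ids)),
                 eligibility = eligibility,
                 threshold_minutes = cov$threshold_minutes,
                 source_label = projection$source_label),
            class = "caseload_report")
}

#' @export
print.caseload_report <- function(x, ...) {
  cat(sprintf("Caseload (%s, eligibility %.0f%%, <%g min): %.0f covered strokes/year, avg %d ECR cases per hub\n",
              x$source_label, 100 * x$eligibility, x$threshold_minutes,
              x$total_covered_strokes, as.integer(x$per_hub_average)))
  print(x$per_hub, row.names = FALSE)
  invisible(x)
}

#' Total patients serviced by a hub model
#'
#' Arithmetic sum of per-hub covered-patient counts, used to validate the
#' totals column of published caseload tables against their own per-hub
#' entries.
#'
#' @param per_hub_counts Non-negative per-hub counts (empty sums to 0).
#' @return The total.
#' @examples
#' sum_model_patients(c(2837, 2270, 4185))  # 9292
#' @export
sum_model_patients <- function(per_hub_counts) {
  if (length(per_hub_counts) == 0) return(0)
  if (any(per_hub_counts < 0)) abort("counts must be non-negative")
  sum(per_hub_counts)
}
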