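#' Assign suburbs to the nearest hub of a chosen subset
#'
#' Hub membership is decided by logical comparison of travel times: each
#' suburb belongs to the catchment of the selected hub with the minimum
#' finite travel time. Ties are broken by hub order in `hub_ids` (first
#' wins), so the partition is deterministic. Suburbs with no finite time to
#' any selected hub are reported as unassignable and excluded from the
#' partition (with a warning).
#'
#' @param matrix A [travel_matrix()].
#' @param hub_ids Non-empty subset of the matrix's hospital ids, in the
#'   order used for tie-breaking.
#' @return Object of class `catchment_model`: list with `hub_ids`,
#'   `assignment` (data frame `suburb_id`, `hub_id`, `minutes`),
#'   `unassignable` (character), `scenario_label`.
#' @export
assign_catchments <- function(matrix, hub_ids) {
  stopifnot(inherits(matrix, "travel_matrix"))
  hub_ids <- as.character(hub_ids)
  if (length(hub_ids) == 0) abort("hub_ids must be non-empty")
  if (anyDuplicated(hub_ids)) abort("duplicate hub ids")
  unknown <- setdiff(hub_ids, matrix$hospital_ids)
  if (length(unknown)) {
    abort("unknown hub id(s): ", paste(sQuote(unknown), collapse = ", "))
  }
  sub <- matrix$minutes[, hub_ids, drop = FALSE]
  reach <- rowSums(is.finite(sub)) > 0
  unassignable <- rownames(sub)[!reach]
  if (length(unassignable)) {
    warning(sprintf("%d suburb(s) unreachable from every selected hub excluded from the partition",
                    length(unassignable)), call. = FALSE)
  }
  sub <- sub[reach, , drop = FALSE]
  # which.max on a logical row-minimum test keeps the first (tie-break by
  # hub order); NAs are +Inf for the comparison
  cmp <- sub
  cmp[is.na(cmp)] <- Inf
  best <- apply(cmp, 1, which.min)
  assignment <- data.frame(suburb_id = rownames(sub),
                           hub_id = hub_ids[best],
                           minutes = cmp[cbind(seq_len(nrow(cmp)), best)],
                           stringsAsFactors = FALSE, row.names = NULL)
  structure(list(hub_ids = hub_ids, assignment = assignment,
                 unassignable = unassignable,
                 scenario_label = matrix$scenario_label),
            class = "catchment_model")
}

#' @export
print.catchment_model <- function(x, ...) {
  cat(sprintf("Catchment model: %d hub(s) [%s], %d suburbs assigned",
              length(x$hub_ids), paste(x$hub_ids, collapse = "/"),
              nrow(x$assignment)))
  if (length(x$unassignable)) cat(sprintf(", %d unassignable", length(x$unassignable)))
  cat("\n")
  tab <- table(factor(x$assignment$hub_id, levels = x$hub_ids))
  cat("  catchment sizes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Within-threshold coverage of a catchment model
#'
#' For each hub, the count and percentage of its catchment's suburbs whose
#' travel time to that hub is strictly below the threshold. The comparison
#' is strict (`minutes < threshold`): a suburb at exactly 30.0 min is not
#' covered under the default. Percentages are reported at 1 decimal with
#' half-up rounding (matching published coverage tables); totals are always
#' computed from raw counts, never from rounded percentages.
#'
#' @param model A [assign_catchments()] result.
#' @param threshold Coverage threshold in minutes (> 0), default 30.
#' @return Object of class `coverage_report`: list with `per_hub` (data
#'   frame `hub_id`, `catchment_count`, `covered_count`, `covered_pct`),
#'   `total_covered`, `total_suburbs` (assignable suburbs),
#'   `threshold_minutes`.
#' @export
coverage <- function(model, threshold = 30) {
  stopifnot(inherits(model, "catchment_model"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    abort("threshold must be a single positive number of minutes")
  }
  a <- model$assignment
  hub <- factor(a$hub_id, levels = model$hub_ids)
  catchment <- as.integer(table(hub))
  covered <- as.integer(tapply(a$minutes < threshold, hub, sum, default = 0L))
  pct <- ifelse(catchment > 0, round_half_up(100 * covered / catchment, 1), NA_real_)
  per_hub <- data.frame(hub_id = model$hub_ids, catchment_count = catchment,
                        covered_count = covered, covered_pct = pct,
                        stringsAsFactors = FALSE)
  structure(list(per_hub = per_hub,
                 total_covered = sum(covered),
                 total_suburbs = nrow(a),
                 threshold_minutes = threshold),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Coverage at <%g min: %d of %d suburbs\n",
              x$threshold_minutes, x$total_covered, x$total_suburbs))
  print(x$per_hub, row.names = FALSE)
  invisible(x)
}

#' Reconstruct a published total from per-hub coverage rows
#'
#' Published coverage tables print, per hub, the covered percentage (1
#' decimal) and the catchment size, plus a total covered count. The total
#' is reconstructed as `sum(round_half_up(pct / 100 * count))`; this is the
#' arithmetic under which the published rows are internally consistent, and
#' is used to validate printed rows.
#'
#' @param covered_pct Percentages in `[0, 100]`, one per hub.
#' @param catchment_count Catchment sizes (suburb counts), one per hub.
#' @return Integer total of covered suburbs.
#' @examples
#' reconstruct_total_from_row(c(83.3, 90.7, 76.6), c(72, 43, 111))  # 184
#' @export
reconstruct_total_from_row <- function(covered_pct, catchment_count) {
  if (length(covered_pct) != length(catchment_count)) {
    abort("covered_pct and catchment_count must have equal length")
  }
  if (any(covered_pct < 0 | covered_pct > 100)) abort("percentages must lie in [0, 100]")
  if (any(catchment_count < 0)) abort("catchment counts must be non-negative")
  as.integer(sum(round_half_up(covered_pct / 100 * catchment_count)))
}
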