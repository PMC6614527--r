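#' Enumerate candidate hub subsets
#'
#' All combinations of the candidate hospitals for every subset size in
#' `k_min:k_max`, in deterministic order: k ascending, and within each k in
#' lexicographic order of the candidates' positions (the order
#' [utils::combn()] produces). With a handful of candidate sites exhaustive
#' enumeration is exact and instant; no heuristic optimiser is involved.
#'
#' @param candidate_ids Character vector of candidate hospital ids.
#' @param k_min,k_max Subset size range, `1 <= k_min <= k_max <= length(candidate_ids)`.
#' @return List of character vectors (one per subset).
#' @examples
#' length(enumerate_hub_sets(LETTERS[1:5], 3, 3))  # choose(5, 3) = 10
#' @export
enumerate_hub_sets <- function(candidate_ids, k_min = 1, k_max = length(candidate_ids)) {
  candidate_ids <- as.character(candidate_ids)
  if (length(candidate_ids) == 0) abort("candidate set must be non-empty")
  if (anyDuplicated(candidate_ids)) abort("duplicate candidate ids")
  if (k_min < 1 || k_min > k_max || k_max > length(candidate_ids)) {
    abort("need 1 <= k_min <= k_max <= number of candidates")
  }
  out <- list()
  for (k in k_min:k_max) {
    out <- c(out, utils::combn(candidate_ids, k, simplify = FALSE))
  }
  out
}

#' Score hub subsets by within-threshold coverage
#'
#' Runs [assign_catchments()] + [coverage()] for every subset and, when a
#' stroke projection is given, totals the population at risk (projected
#' strokes in suburbs covered within the threshold).
#'
#' @param matrix A [travel_matrix()].
#' @param hub_sets List of hub-id subsets, e.g. from [enumerate_hub_sets()].
#' @param threshold Coverage threshold in minutes, default 30.
#' @param projection Optional [project_strokes()] result.
#' @return Data frame of class `model_scores`: one row per subset with
#'   `model_id`, `k`, `hubs` (slash-joined ids), `total_covered_suburbs`,
#'   `total_population_at_risk` (NA without a projection) and
#'   `total_suburbs`; the per-model [coverage()] reports are attached as
#'   attribute `reports`, the threshold as attribute `threshold`.
#' @export
score_hub_sets <- function(matrix, hub_sets, threshold = 30, projection = NULL) {
  if (!length(hub_sets)) abort("hub_sets must be non-empty")
  ks <- lengths(hub_sets)
  idx <- stats::ave(ks, ks, FUN = seq_along)
  reports <- vector("list", length(hub_sets))
  rows <- vector("list", length(hub_sets))
  for (i in seq_along(hub_sets)) {
    model <- assign_catchments(matrix, hub_sets[[i]])
    cov <- coverage(model, threshold)
    reports[[i]] <- cov
    risk <- NA_real_
    if (!is.null(projection)) {
      risk <- covered_population_at_risk(model, projection, threshold)
    }
    rows[[i]] <- data.frame(
      model_id = sprintf("%d-hubs-%d", ks[i], idx[i]),
      k = ks[i],
      hubs = paste(hub_sets[[i]], collapse = "/"),
      total_covered_suburbs = cov$total_covered,
      total_population_at_risk = risk,
      total_suburbs = cov$total_suburbs,
      stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, rows)
  attr(scores, "reports") <- reports
  attr(scores, "threshold") <- threshold
  class(scores) <- c("model_scores", "data.frame")
  scores
}

# total projected strokes over suburbs covered within the threshold
covered_population_at_risk <- function(model, projection, threshold) {
  a <- model$assignment
  covered <- a$suburb_id[a$minutes < threshold]
  sum(projection$per_suburb$strokes[projection$per_suburb$suburb_id %in% covered])
}

#' Rank scored hub models
#'
#' Descending by total covered suburbs; ties by total covered population at
#' risk (descending), then lexicographically by the joined hub ids. The
#' sort is stable, so the ranking is deterministic.
#'
#' @param scores A `model_scores` data frame (see [score_hub_sets()]); any
#'   data frame with columns `hubs`, `total_covered_suburbs` and optionally
#'   `total_population_at_risk` is accepted, which lets published tables be
#'   ranked directly. All rows must share one threshold.
#' @return The scores reordered, with a `rank` column prepended.
#' @export
rank_models <- function(scores) {
  need <- c("hubs", "total_covered_suburbs")
  miss <- setdiff(need, names(scores))
  if (length(miss)) abort("scores missing column(s): ", paste(miss, collapse = ", "))
  thr <- attr(scores, "threshold")
  if (!is.null(scores$threshold_minutes) && length(unique(scores$threshold_minutes)) > 1) {
    abort("cannot rank models scored under different thresholds")
  }
  risk <- scores$total_population_at_risk %||% rep(NA_real_, nrow(scores))
  risk[is.na(risk)] <- -Inf
  ord <- order(-scores$total_covered_suburbs, -risk,
               as.character(scores$hubs), method = "radix")
  ranked <- scores[ord, , drop = FALSE]
  ranked <- cbind(rank = seq_len(nrow(ranked)), ranked)
  rownames(ranked) <- NULL
  attr(ranked, "reports") <- attr(scores, "reports")[ord]
  attr(ranked, "threshold") <- thr
  class(ranked) <- c("model_scores", "data.frame")
  ranked
}

#' Best totals per subset size and their increments
#'
#' For each subset size k, the best total covered suburbs among the scored
#' models, and whether moving to k+1 hubs still gains coverage. A
#' non-positive gain is the planning signal that the extra hub is redundant
#' (its catchment is already absorbed by the others).
#'
#' @param scores A `model_scores` data frame spanning at least two subset
#'   sizes.
#' @return Data frame with `k`, `best_total`, `best_hubs` and `gain`
#'   (best(k) - best(k-1); NA for the smallest k).
#' @export
marginal_gain <- function(scores) {
  if (length(unique(scores$k)) < 2) abort("scores must span at least two subset sizes")
  ks <- sort(unique(scores$k))
  best <- vapply(ks, function(k) max(scores$total_covered_suburbs[scores$k == k]),
                 numeric(1))
  best_hubs <- vapply(ks, function(k) {
    rows <- scores[scores$k == k, , drop = FALSE]
    rows$hubs[which.max(rows$total_covered_suburbs)]
  }, character(1))
  data.frame(k = ks, best_total = best, best_hubs = best_hubs,
             gain = c(NA, diff(best)), stringsAsFactors = FALSE)
}

#' @export
print.model_scores <- function(x, ...) {
  cat(sprintf("Hub-model scores: %d model(s), k in %d..%d\n",
              nrow(x), min(x$k), max(x$k)))
  print(as.data.frame(utils::head(x, 10)), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("  ... %d more\n", nrow(x) - 10))
  invisible(x)
}
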