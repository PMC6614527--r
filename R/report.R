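#' Configuration for a full hub-planning run
#'
#' Bundles every input and tunable of [run_full_analysis()]. The city comes
#' either from a generator spec (`gen_spec`) or from CSV paths (`paths`, a
#' named list with `suburbs`, `hospitals`, `travel`, `incidence` plus the
#' suburb `bands` schema). All randomness flows from the single `seed`.
#'
#' @param gen_spec A [city_gen_spec()], or NULL when reading from files.
#' @param paths Named list of input paths (see above), or NULL.
#' @param threshold Coverage threshold in minutes (> 0), default 30.
#' @param k_min,k_max Hub subset sizes to enumerate; `k_max` defaults to
#'   all candidates.
#' @param eligibility ECR-eligible fraction of strokes, default 0.15.
#' @param extra_incidence Optional list of further [incidence_table()]s
#'   (e.g. a second incidence study) added as extra caseload columns.
#' @param out_dir Output directory.
#' @param seed Integer master seed (overrides `gen_spec$seed`).
#' @return Object of class `run_config`.
#' @export
run_config <- function(gen_spec = NULL, paths = NULL, threshold = 30,
                       k_min = 1, k_max = NULL, eligibility = 0.15,
                       extra_incidence = list(), out_dir = tempfile("ecr_run_"),
                       seed = 1L) {
  if (is.null(gen_spec) == is.null(paths)) {
    abort("give exactly one of gen_spec or paths")
  }
  if (threshold <= 0) abort("threshold must be positive")
  if (eligibility < 0 || eligibility > 1) abort("eligibility must lie in [0, 1]")
  if (!is.null(gen_spec)) {
    gen_spec$seed <- as.integer(seed)
    gen_spec$scenario$seed <- as.integer(seed)
  }
  structure(list(gen_spec = gen_spec, paths = paths, threshold = threshold,
                 k_min = k_min, k_max = k_max, eligibility = eligibility,
                 extra_incidence = extra_incidence, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

# run one pipeline stage, prefixing any error with the stage name
run_stage <- function(stage, code) {
  tryCatch(force(code), error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full hub-planning analysis
#'
#' The whole pipeline in one call: obtain the city bundle, validate it,
#' enumerate and score every hub combination in the k range, rank them,
#' project strokes and caseload, and write the output bundle to
#' `config$out_dir`:
#' \describe{
#'   \item{ranked_models.csv}{`k`, `hub_ids` (semicolon-joined),
#'     `total_suburbs`, `total_population_at_risk`, `rank`.}
#'   \item{coverage_models.csv}{One row per model: per-hospital covered
#'     percentage and catchment size, plus the total covered count
#'     (published-coverage-table layout).}
#'   \item{caseload_models.csv}{One row per model: per-hospital covered
#'     strokes for each incidence source, total suburbs and total patients
#'     per source (published-caseload-table layout).}
#'   \item{catchment_k<k>.geojson}{The top-ranked model of each subset
#'     size, one point feature per suburb with its assigned hub, minutes
#'     and covered flag.}
#'   \item{run_log.txt}{Seed and configuration echo.}
#' }
#' Outputs are deterministic: re-running the same configuration yields
#' byte-identical files.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `city`, `scores` (ranked), `caseloads`,
#'   `files`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  city <- run_stage("load_city", {
    if (!is.null(config$gen_spec)) generate_city(config$gen_spec)
    else {
      p <- config$paths
      suburbs <- read_suburbs(p$suburbs, p$bands)
      hospitals <- read_hospitals(p$hospitals)
      structure(list(suburbs = suburbs, hospitals = hospitals,
                     matrix = read_travel_matrix(p$travel, layout = p$layout %||% "long",
                                                 suburbs = suburbs, hospitals = hospitals),
                     incidence = read_incidence(p$incidence)),
                class = "ecr_city")
    }
  })
  run_stage("validate", {
    v <- validate_city(city$suburbs, city$hospitals, city$matrix, city$incidence)
    if (length(v)) abort(paste(v, collapse = "; "))
  })

  sources <- c(list(city$incidence), config$extra_incidence)
  projections <- run_stage("project_strokes",
    lapply(sources, function(inc) project_strokes(city$suburbs, inc)))

  candidates <- city$hospitals$id[city$hospitals$ecr_capable]
  k_max <- config$k_max %||% length(candidates)
  sets <- run_stage("enumerate", enumerate_hub_sets(candidates, config$k_min, k_max))
  scores <- run_stage("score",
    score_hub_sets(city$matrix, sets, config$threshold, projections[[1]]))
  ranked <- run_stage("rank", rank_models(scores))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  f <- file.path(config$out_dir, "ranked_models.csv")
  utils::write.csv(data.frame(k = ranked$k,
                              hub_ids = gsub("/", ";", ranked$hubs, fixed = TRUE),
                              total_suburbs = ranked$total_covered_suburbs,
                              total_population_at_risk = round(ranked$total_population_at_risk, 2),
                              rank = ranked$rank),
                   f, row.names = FALSE, quote = TRUE)
  files <- c(files, f)

  reports <- attr(scores, "reports")
  models <- lapply(sets, function(s) assign_catchments(city$matrix, s))
  f <- file.path(config$out_dir, "coverage_models.csv")
  utils::write.csv(coverage_table(scores, reports, candidates), f,
                   row.names = FALSE, quote = TRUE)
  files <- c(files, f)

  caseloads <- run_stage("caseload", lapply(seq_along(sets), function(i) {
    lapply(projections, function(pr)
      caseload(models[[i]], reports[[i]], pr, config$eligibility))
  }))
  f <- file.path(config$out_dir, "caseload_models.csv")
  utils::write.csv(caseload_table(scores, reports, caseloads, candidates), f,
                   row.names = FALSE, quote = TRUE)
  files <- c(files, f)

  run_stage("export_geojson", for (k in unique(ranked$k)) {
    top <- which(ranked$k == k)[1]
    i <- match(ranked$model_id[top], scores$model_id)
    f <- file.path(config$out_dir, sprintf("catchment_k%d.geojson", k))
    export_catchment_geojson(models[[i]], reports[[i]], city$suburbs,
                             city$hospitals, path = f)
    files <- c(files, f)
  })

  f <- file.path(config$out_dir, "run_log.txt")
  writeLines(c("ecrhubs full analysis",
               sprintf("seed: %d", config$seed),
               sprintf("threshold_minutes: %g", config$threshold),
               sprintf("k range: %d..%d", config$k_min, k_max),
               sprintf("eligibility: %g", config$eligibility),
               sprintf("city: %d suburbs, %d candidate hospitals",
                       nrow(city$suburbs), length(candidates)),
               sprintf("incidence sources: %s",
                       paste(vapply(projections, `[[`, "", "source_label"),
                             collapse = ", ")),
               sprintf("models scored: %d", nrow(scores))),
             f)
  files <- c(files, f)

  invisible(list(city = city, scores = ranked, caseloads = caseloads,
                 files = files))
}

# one row per model: per-candidate covered_pct / catchment_count, total
coverage_table <- function(scores, reports, candidates) {
  rows <- lapply(seq_len(nrow(scores)), function(i) {
    ph <- reports[[i]]$per_hub
    row <- list(model_id = scores$model_id[i], hubs = scores$hubs[i])
    for (h in candidates) {
      j <- match(h, ph$hub_id)
      row[[paste0(h, "_covered_pct")]] <- if (is.na(j)) NA_real_ else ph$covered_pct[j]
      row[[paste0(h, "_catchment_count")]] <- if (is.na(j)) NA_integer_ else ph$catchment_count[j]
    }
    row$total_suburbs_covered <- reports[[i]]$total_covered
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# one row per model: per-candidate covered strokes for each source, totals
caseload_table <- function(scores, reports, caseloads, candidates) {
  labels <- vapply(caseloads[[1]], `[[`, "", "source_label")
  rows <- lapply(seq_len(nrow(scores)), function(i) {
    row <- list(model_id = scores$model_id[i], hubs = scores$hubs[i])
    for (s in seq_along(labels)) {
      ph <- caseloads[[i]][[s]]$per_hub
      for (h in candidates) {
        j <- match(h, ph$hub_id)
        row[[sprintf("%s_strokes_%s", h, labels[s])]] <-
          if (is.na(j)) 0 else round(ph$covered_strokes[j], 1)
      }
    }
    row$total_suburbs_covered <- reports[[i]]$total_covered
    for (s in seq_along(labels)) {
      row[[sprintf("total_patients_%s", labels[s])]] <-
        round(caseloads[[i]][[s]]$total_covered_strokes, 1)
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export a catchment model as GeoJSON
#'
#' One Point feature per assigned suburb with properties `suburb_id`,
#' `hub_id`, `minutes`, `covered`; unassignable suburbs carry a null hub
#' and `covered = false`; the selected hub hospitals are Point features
#' with `role = "hub"`. The output is a standard FeatureCollection any
#' mapping front-end can consume — a static stand-in for an interactive
#' web map.
#'
#' @param model A [assign_catchments()] result.
#' @param cov The matching [coverage()] report (supplies the threshold).
#' @param suburbs A `suburb_table` (for the centroids).
#' @param hospitals A `hospital_table` (for the hub coordinates).
#' @param path Optional file to write.
#' @return The FeatureCollection as a list (invisibly if written).
#' @export
export_catchment_geojson <- function(model, cov, suburbs, hospitals, path = NULL) {
  stopifnot(inherits(model, "catchment_model"), inherits(cov, "coverage_report"))
  a <- model$assignment
  feat_point <- function(lon, lat, props) {
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(lon, lat)),
         properties = props)
  }
  sub_feats <- lapply(seq_len(nrow(a)), function(i) {
    j <- match(a$suburb_id[i], suburbs$id)
    feat_point(suburbs$lon[j], suburbs$lat[j],
               list(suburb_id = a$suburb_id[i], hub_id = a$hub_id[i],
                    minutes = round(a$minutes[i], 2),
                    covered = a$minutes[i] < cov$threshold_minutes))
  })
  una_feats <- lapply(model$unassignable, function(s) {
    j <- match(s, suburbs$id)
    feat_point(suburbs$lon[j], suburbs$lat[j],
               list(suburb_id = s, hub_id = NA, minutes = NA,
                    covered = FALSE))
  })
  hub_feats <- lapply(model$hub_ids, function(h) {
    j <- match(h, hospitals$id)
    feat_point(hospitals$lon[j], hospitals$lat[j],
               list(hospital_id = h, name = hospitals$name[j], role = "hub"))
  })
  fc <- list(type = "FeatureCollection",
             features = c(sub_feats, una_feats, hub_feats))
  if (!is.null(path)) {
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 6,
                         null = "null", na = "null", pretty = FALSE)
    return(invisible(fc))
  }
  fc
}
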