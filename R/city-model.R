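#' Read a suburb table
#'
#' Reads population units ("suburbs" generically: suburbs, postcodes or any
#' census unit with a centroid) from CSV. The file must have columns
#' `id,name,lat,lon` plus one count column per band of the declared schema;
#' band columns are matched against the schema, never inferred.
#'
#' @param path CSV file path.
#' @param bands An [age_bands()] schema declaring the population bands.
#' @return A data frame of class `suburb_table`: `id`, `name`, `lat`, `lon`
#'   and one integer count column per band label, with the schema attached
#'   as attribute `bands`.
#' @seealso [write_suburbs()], [validate_city()]
#' @export
read_suburbs <- function(path, bands) {
  stopifnot(inherits(bands, "age_bands"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "name", "lat", "lon")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort("suburbs file missing column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(df), c(need, bands$label))
  if (length(extra)) {
    abort("unknown age-band column(s) in suburbs file: ",
          paste(sQuote(extra), collapse = ", "))
  }
  miss_b <- setdiff(bands$label, names(df))
  if (length(miss_b)) {
    abort("suburbs file missing declared band column(s): ",
          paste(sQuote(miss_b), collapse = ", "))
  }
  suburb_table(df[, c(need, bands$label)], bands)
}

# constructor + invariant checks shared by reader and generator
suburb_table <- function(df, bands) {
  df$id <- as.character(df$id)
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup)) abort("duplicate suburb id(s): ", paste(sQuote(dup), collapse = ", "))
  check_coords(df$lat, df$lon, "suburb centroid")
  counts <- as.matrix(df[, bands$label, drop = FALSE])
  if (anyNA(counts) || any(counts < 0)) {
    abort("negative or missing population count in suburbs table")
  }
  rownames(df) <- NULL
  attr(df, "bands") <- bands
  class(df) <- c("suburb_table", "data.frame")
  df
}

#' @rdname read_suburbs
#' @param suburbs A `suburb_table`.
#' @export
write_suburbs <- function(suburbs, path) {
  utils::write.csv(as.data.frame(suburbs), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a candidate-hospital table
#'
#' @param path CSV with columns `id,name,lat,lon,ecr_capable`
#'   (`ecr_capable` logical: can the site be designated a 24/7 ECR hub).
#' @return Data frame of class `hospital_table`.
#' @export
read_hospitals <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "name", "lat", "lon", "ecr_capable")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort("hospitals file missing column(s): ", paste(miss, collapse = ", "))
  hospital_table(df[, need])
}

hospital_table <- function(df) {
  df$id <- as.character(df$id)
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup)) abort("duplicate hospital id(s): ", paste(sQuote(dup), collapse = ", "))
  check_coords(df$lat, df$lon, "hospital")
  df$ecr_capable <- as.logical(df$ecr_capable)
  if (anyNA(df$ecr_capable)) abort("ecr_capable must be TRUE/FALSE")
  rownames(df) <- NULL
  class(df) <- c("hospital_table", "data.frame")
  df
}

#' @rdname read_hospitals
#' @param hospitals A `hospital_table`.
#' @export
write_hospitals <- function(hospitals, path) {
  utils::write.csv(as.data.frame(hospitals), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Age-specific stroke incidence table
#'
#' Annual first-ever stroke rates per person-year by age band. Rates are
#' user-supplied; the package ships two illustrative tables (clearly
#' labelled synthetic) under `inst/extdata/`.
#'
#' @param bands An [age_bands()] schema; must tile ages 0 to open-ended
#'   with no gaps.
#' @param rates Non-negative rate per person-year, one per band.
#' @param source_label Text naming the rate source (e.g. which incidence
#'   study the rates emulate).
#' @return Data frame of class `incidence_table` with columns `label`,
#'   `lower`, `upper`, `rate` and attribute `source_label`.
#' @export
incidence_table <- function(bands, rates, source_label = "unnamed") {
  stopifnot(inherits(bands, "age_bands"))
  if (length(rates) != nrow(bands)) abort("one rate per band required")
  if (anyNA(rates) || any(rates < 0)) abort("incidence rates must be non-negative")
  # gapless coverage of [0, open) is checked where it matters:
  # harmonize_bands() errors, validate_city() reports
  tbl <- as.data.frame(bands)
  tbl$rate <- as.numeric(rates)
  attr(tbl, "source_label") <- source_label
  class(tbl) <- c("incidence_table", "data.frame")
  tbl
}

#' @rdname incidence_table
#' @param path CSV with columns `band_label,rate_per_person_year,source_label`.
#' @export
read_incidence <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("band_label", "rate_per_person_year", "source_label")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort("incidence file missing column(s): ", paste(miss, collapse = ", "))
  ord <- order(as.numeric(sub("^\\s*(\\d+).*$", "\\1", df$band_label)))
  df <- df[ord, , drop = FALSE]
  incidence_table(age_bands(df$band_label), df$rate_per_person_year,
                  source_label = df$source_label[1])
}

#' @rdname incidence_table
#' @param incidence An `incidence_table`.
#' @export
write_incidence <- function(incidence, path) {
  out <- data.frame(band_label = incidence$label,
                    rate_per_person_year = incidence$rate,
                    source_label = attr(incidence, "source_label"))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Travel-time matrix
#'
#' Minutes from every suburb centroid to every candidate hospital under one
#' named traffic scenario. Unreachable pairs are `NA`.
#'
#' @param minutes Numeric matrix, suburbs in rows, hospitals in columns,
#'   with dimnames giving the ids.
#' @param scenario_label Traffic scenario the times were computed under.
#' @return Object of class `travel_matrix`: list with elements `minutes`,
#'   `suburb_ids`, `hospital_ids`, `scenario_label`.
#' @export
travel_matrix <- function(minutes, scenario_label = "unspecified") {
  if (!is.matrix(minutes) || is.null(rownames(minutes)) || is.null(colnames(minutes))) {
    abort("minutes must be a matrix with suburb row names and hospital column names")
  }
  if (anyDuplicated(rownames(minutes)) || anyDuplicated(colnames(minutes))) {
    abort("duplicate ids in travel matrix dimnames")
  }
  fin <- minutes[is.finite(minutes)]
  if (any(fin < 0)) abort("travel times must be non-negative")
  minutes[!is.finite(minutes)] <- NA_real_
  stranded <- rownames(minutes)[rowSums(is.finite(minutes)) == 0]
  if (length(stranded)) {
    warning("suburb(s) unreachable from every hospital: ",
            paste(stranded, collapse = ", "), call. = FALSE)
  }
  structure(list(minutes = minutes,
                 suburb_ids = rownames(minutes),
                 hospital_ids = colnames(minutes),
                 scenario_label = scenario_label),
            class = "travel_matrix")
}

#' @export
print.travel_matrix <- function(x, ...) {
  cat(sprintf("Travel-time matrix: %d suburbs x %d hospitals, scenario '%s'\n",
              length(x$suburb_ids), length(x$hospital_ids), x$scenario_label))
  cat(sprintf("  minutes: median %.1f, range [%.1f, %.1f], %d unreachable pair(s)\n",
              stats::median(x$minutes, na.rm = TRUE),
              min(x$minutes, na.rm = TRUE), max(x$minutes, na.rm = TRUE),
              sum(is.na(x$minutes))))
  invisible(x)
}

#' Read / write a travel-time matrix
#'
#' Two encodings are supported. *Wide*: one row per suburb, first column
#' `suburb_id`, one minutes column per hospital. *Long*: triples
#' `suburb_id,hospital_id,minutes` (an optional `scenario_label` column is
#' accepted and also written, matching the travel-cache file format).
#' Blank or negative cells become the unreachable sentinel (`NA`) with a
#' warning; in long layout, pairs absent from the file are unreachable.
#'
#' @param path CSV file path.
#' @param layout `"wide"` or `"long"`.
#' @param suburbs,hospitals Optional registries; if supplied, ids in the
#'   file that are absent from them are a hard error, and the matrix rows /
#'   columns are completed and ordered to match the registry.
#' @param scenario_label Label for the returned matrix (long files carry
#'   their own; wide files do not).
#' @return A [travel_matrix()].
#' @export
read_travel_matrix <- function(path, layout = c("wide", "long"),
                               suburbs = NULL, hospitals = NULL,
                               scenario_label = "unspecified") {
  layout <- match.arg(layout)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (layout == "wide") {
    if (names(df)[1] != "suburb_id") abort("wide travel file must start with column 'suburb_id'")
    sids <- as.character(df$suburb_id)
    hids <- names(df)[-1]
    m <- as.matrix(df[, -1, drop = FALSE])
    mode(m) <- "numeric"
    dimnames(m) <- list(sids, hids)
  } else {
    need <- c("suburb_id", "hospital_id", "minutes")
    miss <- setdiff(need, names(df))
    if (length(miss)) abort("long travel file missing column(s): ", paste(miss, collapse = ", "))
    if ("scenario_label" %in% names(df) && nrow(df) > 0) {
      scenario_label <- df$scenario_label[1]
    }
    sids <- unique(as.character(df$suburb_id))
    hids <- unique(as.character(df$hospital_id))
    m <- matrix(NA_real_, length(sids), length(hids), dimnames = list(sids, hids))
    m[cbind(match(df$suburb_id, sids), match(df$hospital_id, hids))] <-
      as.numeric(df$minutes)
  }
  if (!is.null(suburbs)) {
    unknown <- setdiff(rownames(m), suburbs$id)
    if (length(unknown)) {
      abort("travel matrix names suburb(s) absent from the registry: ",
            paste(sQuote(unknown), collapse = ", "))
    }
    full <- matrix(NA_real_, length(suburbs$id), ncol(m),
                   dimnames = list(suburbs$id, colnames(m)))
    full[rownames(m), ] <- m
    m <- full
  }
  if (!is.null(hospitals)) {
    unknown <- setdiff(colnames(m), hospitals$id)
    if (length(unknown)) {
      abort("travel matrix names hospital(s) absent from the registry: ",
            paste(sQuote(unknown), collapse = ", "))
    }
    full <- matrix(NA_real_, nrow(m), length(hospitals$id),
                   dimnames = list(rownames(m), hospitals$id))
    full[, colnames(m)] <- m
    m <- full
  }
  n_bad <- sum(is.na(m)) + sum(m < 0, na.rm = TRUE)
  if (n_bad > 0) {
    warning(sprintf("%d blank/negative/absent travel cell(s) set to unreachable", n_bad),
            call. = FALSE)
    m[!is.na(m) & m < 0] <- NA_real_
  }
  suppressWarnings(travel_matrix(m, scenario_label))
}

#' @rdname read_travel_matrix
#' @param matrix A [travel_matrix()].
#' @export
write_travel_matrix <- function(matrix, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  m <- matrix$minutes
  if (layout == "wide") {
    df <- data.frame(suburb_id = rownames(m), round(m, 2),
                     check.names = FALSE, row.names = NULL)
  } else {
    df <- expand.grid(suburb_id = rownames(m), hospital_id = colnames(m),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df$minutes <- round(as.vector(m), 2)
    df$scenario_label <- matrix$scenario_label
    df <- df[!is.na(df$minutes), , drop = FALSE]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Validate a city bundle
#'
#' Checks every cross-table invariant the downstream analysis relies on and
#' reports all violations instead of stopping at the first. An empty report
#' means the bundle is analysis-ready: no downstream precondition can fail.
#'
#' @param suburbs A `suburb_table`.
#' @param hospitals A `hospital_table`.
#' @param matrix A [travel_matrix()].
#' @param incidence An [incidence_table()].
#' @return Character vector of violation messages (class
#'   `city_validation`); `length(.) == 0` means valid.
#' @export
validate_city <- function(suburbs, hospitals, matrix, incidence) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)

  if (anyDuplicated(suburbs$id)) add("duplicate suburb ids")
  if (anyDuplicated(hospitals$id)) add("duplicate hospital ids")
  if (any(suburbs$lat < -90 | suburbs$lat > 90 | suburbs$lon < -180 | suburbs$lon > 180)) {
    add("suburb centroid coordinates out of range")
  }
  bands <- attr(suburbs, "bands")
  counts <- as.matrix(as.data.frame(suburbs)[, bands$label, drop = FALSE])
  if (anyNA(counts) || any(counts < 0)) add("negative/missing population counts")

  for (s in setdiff(suburbs$id, matrix$suburb_ids)) {
    add(sprintf("travel matrix missing suburb %s", sQuote(s)))
  }
  for (s in setdiff(matrix$suburb_ids, suburbs$id)) {
    add(sprintf("travel matrix has unknown suburb %s", sQuote(s)))
  }
  for (h in setdiff(hospitals$id, matrix$hospital_ids)) {
    add(sprintf("travel matrix missing hospital %s", sQuote(h)))
  }
  for (h in setdiff(matrix$hospital_ids, hospitals$id)) {
    add(sprintf("travel matrix has unknown hospital %s", sQuote(h)))
  }
  stranded <- matrix$suburb_ids[rowSums(is.finite(matrix$minutes)) == 0]
  for (s in stranded) add(sprintf("suburb %s unreachable from every hospital", sQuote(s)))

  msg <- bands_gap_message(incidence[, c("label", "lower", "upper")],
                           "incidence band schema")
  if (!is.null(msg)) add(msg)
  if (any(incidence$rate < 0)) add("negative incidence rate")
  pmsg <- bands_gap_message(bands, "population band schema")
  if (!is.null(pmsg)) add(pmsg)

  structure(v, class = "city_validation")
}

#' @export
print.city_validation <- function(x, ...) {
  if (length(x) == 0) {
    cat("City bundle valid: no violations.\n")
  } else {
    cat(sprintf("City bundle has %d violation(s):\n", length(x)))
    cat(paste0("  - ", unclass(x), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
print.suburb_table <- function(x, ...) {
  bands <- attr(x, "bands")
  tot <- sum(as.matrix(as.data.frame(x)[, bands$label, drop = FALSE]))
  cat(sprintf("Suburb table: %d units, %d age bands, total population %s\n",
              nrow(x), nrow(bands), format(tot, big.mark = ",")))
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("  ... %d more rows\n", nrow(x) - 4))
  invisible(x)
}
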