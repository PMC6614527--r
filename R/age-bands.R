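#' Declare an age-band schema
#'
#' Parses band labels of the form `"0-44"`, `"45-54"`, ..., `"85+"` into a
#' schema table. Bands are integer years, both ends inclusive; a trailing
#' `"+"` marks the open-ended band. Census tables and incidence studies use
#' different bands, so a schema is always declared explicitly rather than
#' inferred from file headers; [harmonize_bands()] aligns two schemas.
#'
#' @param labels Character vector of band labels, e.g.
#'   `c("0-64", "65-74", "75+")`.
#' @return A data frame of class `age_bands` with columns `label`, `lower`,
#'   `upper` (`Inf` for the open-ended band), sorted by `lower`.
#' @examples
#' age_bands(c("0-64", "65+"))
#' @export
age_bands <- function(labels) {
  if (length(labels) == 0) abort("age-band schema needs at least one band")
  labels <- as.character(labels)
  if (anyDuplicated(labels)) abort("duplicate age-band labels")
  open <- grepl("^\\s*(\\d+)\\s*\\+\\s*$", labels)
  range <- grepl("^\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", labels)
  bad <- labels[!(open | range)]
  if (length(bad)) {
    abort("unparseable age-band label(s): ", paste(sQuote(bad), collapse = ", "),
          " (expected forms like '45-54' or '85+')")
  }
  lower <- as.numeric(sub("^\\s*(\\d+).*$", "\\1", labels))
  upper <- rep(Inf, length(labels))
  upper[range] <- as.numeric(sub("^\\s*\\d+\\s*-\\s*(\\d+)\\s*$", "\\1",
                                 labels[range]))
  if (any(upper < lower)) abort("age band upper bound below lower bound")
  bands <- data.frame(label = labels, lower = lower, upper = upper,
                      stringsAsFactors = FALSE)
  bands <- bands[order(bands$lower), , drop = FALSE]
  rownames(bands) <- NULL
  if (sum(is.infinite(bands$upper)) > 1) abort("at most one open-ended band allowed")
  for (i in seq_len(nrow(bands) - 1)) {
    if (bands$upper[i] >= bands$lower[i + 1]) {
      abort(sprintf("age bands %s and %s overlap",
                    sQuote(bands$label[i]), sQuote(bands$label[i + 1])))
    }
  }
  class(bands) <- c("age_bands", "data.frame")
  bands
}

# TRUE when the schema tiles [0, Inf) with no gaps: starts at 0, each band
# starts one year after the previous ends, last band open-ended
bands_gapless <- function(bands) {
  if (bands$lower[1] != 0) return(FALSE)
  n <- nrow(bands)
  if (n > 1 && any(bands$lower[-1] != bands$upper[-n] + 1)) return(FALSE)
  is.infinite(bands$upper[n])
}

# describe the first gap for error/validation messages, NULL if gapless
bands_gap_message <- function(bands, what = "band schema") {
  if (bands$lower[1] != 0) {
    return(sprintf("%s does not start at age 0 (first band %s)",
                   what, sQuote(bands$label[1])))
  }
  n <- nrow(bands)
  if (n > 1) {
    brk <- which(bands$lower[-1] != bands$upper[-n] + 1)
    if (length(brk)) {
      i <- brk[1]
      return(sprintf("%s has a gap: ages %d-%d fall between bands %s and %s",
                     what, bands$upper[i] + 1, bands$lower[i + 1] - 1,
                     sQuote(bands$label[i]), sQuote(bands$label[i + 1])))
    }
  }
  if (!is.infinite(bands$upper[n])) {
    return(sprintf("%s is not open-ended (last band %s)",
                   what, sQuote(bands$label[n])))
  }
  NULL
}

#' @export
print.age_bands <- function(x, ...) {
  cat(sprintf("Age-band schema: %d bands (%s)\n", nrow(x),
              paste(x$label, collapse = ", ")))
  invisible(x)
}
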