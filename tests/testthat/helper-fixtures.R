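# shared fixture builders; everything is generated in code, no files

# random travel matrix with optional unreachable cells
rand_matrix <- function(n, m, seed = 1, na_frac = 0, max_min = 60) {
  set.seed(seed)
  mm <- matrix(round(runif(n * m, 1, max_min), 2), n, m,
               dimnames = list(sprintf("S%03d", seq_len(n)),
                               sprintf("H%d", seq_len(m))))
  if (na_frac > 0) {
    drop <- sample(length(mm), floor(na_frac * length(mm)))
    mm[drop] <- NA_real_
    # keep every row reachable
    for (i in which(rowSums(is.finite(mm)) == 0)) mm[i, 1] <- 10
  }
  suppressWarnings(travel_matrix(mm, "test"))
}

# brute-force assignment oracle: explicit per-row loop over hubs,
# independent of the vectorised implementation
brute_assign <- function(minutes, hub_ids) {
  out <- data.frame(suburb_id = character(0), hub_id = character(0),
                    minutes = numeric(0), stringsAsFactors = FALSE)
  for (s in rownames(minutes)) {
    best_hub <- NA_character_
    best_min <- Inf
    for (h in hub_ids) {
      v <- minutes[s, h]
      if (!is.na(v) && v < best_min) {
        best_min <- v
        best_hub <- h
      }
    }
    if (!is.na(best_hub)) {
      out <- rbind(out, data.frame(suburb_id = s, hub_id = best_hub,
                                   minutes = best_min, stringsAsFactors = FALSE))
    }
  }
  out
}

# minimal suburb table: one open-ended band, population = strokes / rate
# under toy_incidence(), so projected strokes per suburb are exact
toy_suburbs <- function(strokes, rate = 0.01) {
  n <- length(strokes)
  bands <- age_bands("0+")
  df <- data.frame(id = sprintf("S%03d", seq_len(n)),
                   name = paste("Suburb", seq_len(n)),
                   lat = -33.9 + seq_len(n) * 0.01, lon = 151 + seq_len(n) * 0.01,
                   stringsAsFactors = FALSE)
  df[["0+"]] <- strokes / rate
  ecrhubs:::suburb_table(df, bands)
}

toy_incidence <- function(rate = 0.01, label = "toy") {
  incidence_table(age_bands("0+"), rate, source_label = label)
}

# k hubs, each with its own fully-covered catchment given by `sizes`
block_matrix <- function(sizes, own = 10, other = 90) {
  n <- sum(sizes)
  k <- length(sizes)
  hub_of <- rep(seq_len(k), sizes)
  mm <- matrix(other, n, k, dimnames = list(sprintf("S%03d", seq_len(n)),
                                            sprintf("H%d", seq_len(k))))
  mm[cbind(seq_len(n), hub_of)] <- own
  travel_matrix(mm, "block")
}

expect_file_identical <- function(a, b) {
  expect_identical(readBin(a, "raw", file.size(a)),
                   readBin(b, "raw", file.size(b)))
}
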