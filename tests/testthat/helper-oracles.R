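# Shared fixtures and independent brute-force oracles.

# One small bundle reused across test files (built once).
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- ground_truth(area_count = 4, births_per_area = 800, seed = 42)
      cache <<- simulate_vital_records(tr, sampling_rate = 0.3,
                                       weight_dispersion = 0.3,
                                       n_women = 2000)
    }
    cache
  }
})

# Brute-force weighted AUC: enumerate every positive-negative pair.
brute_cstat <- function(scores, labels, weights) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  num <- 0; den <- 0
  for (i in pos) for (j in neg) {
    w <- weights[i] * weights[j]
    den <- den + w
    if (scores[i] > scores[j]) num <- num + w
    else if (scores[i] == scores[j]) num <- num + w / 2
  }
  num / den
}

# Brute-force containment for the rectangular tilings the generator makes:
# first (sorted) rectangle whose closed bounds contain the point.
brute_assign_rect <- function(lat, lon, polygons) {
  out <- rep(NA_character_, length(lat))
  for (id in sort(polygons$ids)) {
    ring <- polygons$rings[[id]]
    x0 <- min(ring[, 1]); x1 <- max(ring[, 1])
    y0 <- min(ring[, 2]); y1 <- max(ring[, 2])
    hit <- is.na(out) & lon >= x0 & lon <= x1 & lat >= y0 & lat <= y1
    out[hit] <- id
  }
  out
}

# An intercept-only classifier: predicts one constant probability everywhere.
constant_model <- function(p_target = 0.4, n = 200) {
  y <- c(rep(1, round(n * p_target)), rep(0, n - round(n * p_target)))
  fit_candidate(data.frame(matrix(nrow = n, ncol = 0)), y, rep(1, n),
                "logistic")
}
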