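# Quadratic reference implementations used as independent oracles, plus
# a cache for the heavier fBm fixtures shared across test files.

naive_moving_average <- function(y, n) {
  L <- length(y)
  out <- rep(NA_real_, L)
  for (x in n:L) out[x] <- mean(y[(x - n + 1):x])
  out
}

# literal scan implementing the crossing rule: a strict sign change
# between x and x+1 records x+1; an exact zero records x, with runs of
# zeros collapsed to the first
oracle_crossings <- function(d) {
  cross <- integer(0)
  in_zero_run <- FALSE
  for (i in seq_along(d)) {
    if (d[i] == 0) {
      if (!in_zero_run) cross <- c(cross, i)
      in_zero_run <- TRUE
    } else {
      if (i > 1 && d[i - 1] != 0 && sign(d[i]) * sign(d[i - 1]) < 0)
        cross <- c(cross, i)
      in_zero_run <- FALSE
    }
  }
  cross
}

oracle_clusters <- function(d, cross) {
  if (length(cross) < 2) return(NULL)
  do.call(rbind, lapply(seq_len(length(cross) - 1), function(i) {
    idx <- cross[i]:(cross[i + 1] - 1)
    nz <- d[idx][d[idx] != 0]
    data.frame(start = cross[i], end = cross[i + 1],
               length = cross[i + 1] - cross[i],
               sign = if (length(nz)) ifelse(nz[1] > 0, "above", "below")
                      else "flat",
               area = sum(d[idx]))
  }))
}

# a full-valid-range moving average stand-in so crossing examples can be
# written directly in terms of d = y - ma
fake_ma <- function(y, d) {
  ma <- y - d
  attr(ma, "window") <- 1L
  ma
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# 10 fractional Brownian walks, H = 0.6, L = 2^18 (Hurst / exponent
# consistency checks)
fbm_walks_18 <- function() {
  cached("fbm18", lapply(1:10, function(s) rfbm(2^18, 0.6, seed = s)))
}

# 10 fractional Brownian walks, H = 0.6, L = 2^20 (entropy-curve checks)
fbm_walks_20 <- function() {
  cached("fbm20", lapply(1:10, function(s) rfbm(2^20, 0.6, seed = 100 + s)))
}

pooled_clusters <- function(walks, n) {
  lapply(walks, function(y) extract_clusters(y, moving_average(y, n)))
}

fitted_curve <- function(walks, n, key) {
  cached(key, {
    d <- length_histogram(pooled_clusters(walks, n))
    fit_entropy_decomposition(cluster_entropy_curve(d))
  })
}
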