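# Length distributions, power-law exponent, entropy curves and the
# decomposition S0 + D log l + l/n.

make_cluster_set <- function(lengths, n) {
  cr <- cumsum(c(n, lengths))
  structure(data.frame(start = cr[-length(cr)], end = cr[-1],
                       length = lengths, duration = lengths,
                       sign = rep(c("above", "below"),
                                  length.out = length(lengths)),
                       area = rep(0, length(lengths))),
            class = c("cluster_set", "data.frame"),
            window = as.integer(n), crossings = cr,
            span = c(cr[1], cr[length(cr)]))
}

test_that("length histograms are normalized densities", {
  cs <- make_cluster_set(rep(7L, 40), 16)
  d <- length_histogram(cs)
  expect_identical(sum(d$counts > 0), 1L)
  occ <- d$counts > 0
  expect_equal(d$density[occ] * d$width[occ], 1)
  expect_equal(sum(d$density * d$width), 1)
  # normalization is invariant to bin resolution
  set.seed(7)
  cs2 <- make_cluster_set(1L + rpois(500, 20), 64)
  for (bpo in c(4, 8, 16)) {
    d2 <- length_histogram(cs2, bins_per_octave = bpo)
    expect_equal(sum(d2$density * d2$width), 1, tolerance = 1e-9)
    expect_identical(sum(d2$counts), 500L)
  }
  expect_error(length_histogram(make_cluster_set(integer(0), 4)), "empty")
})

test_that("pooled cluster sets must share the window", {
  a <- make_cluster_set(rep(3L, 10), 8)
  b <- make_cluster_set(rep(3L, 10), 16)
  expect_error(length_histogram(list(a, b)), "same window")
  d <- length_histogram(list(a, a))
  expect_identical(d$total, 20L)
})

test_that("fit_powerlaw_exponent recovers an exact power law", {
  # density proportional to l^-1.5 over three decades
  edges <- log_bin_edges(2000, 8)
  lo <- edges[-length(edges)]; hi <- edges[-1]
  center <- sqrt(lo * pmax(hi - 1, lo))
  counts <- round(1e8 * center^(-1.5) * (hi - lo))
  dist <- length_distribution(counts, edges, n = 4000)
  est <- fit_powerlaw_exponent(dist)
  expect_s3_class(est, "scaling_estimate")
  expect_lt(abs(est$D - 1.5), 0.01)
  expect_identical(unname(coef(est)["H"]), 2 - est$D)
  expect_error(fit_powerlaw_exponent(length_distribution(c(10, 10), 1:3, 4000)),
               "too few occupied bins")
})

test_that("white-noise walk clusters have D close to 2 - 0.5", {
  cs <- pooled_clusters(lapply(1:5, function(s) rfbm(2^17, 0.5, seed = 400 + s)),
                        512)
  est <- fit_powerlaw_exponent(length_histogram(cs))
  expect_lt(abs(est$D - 1.5), 0.12)
})

test_that("uniform density gives a constant surprisal log m", {
  dist <- length_distribution(rep(10L, 8), 1:9, n = 100)
  cv <- cluster_entropy_curve(dist)
  expect_equal(cv$S, rep(log(8), 8))
  # literal per-bin Shannon summand is available behind the flag
  cv2 <- cluster_entropy_curve(dist, form = "summand")
  expect_equal(cv2$S, rep(-(1 / 8) * log(1 / 8), 8))
})

test_that("bins below min_count are omitted from entropy curves", {
  dist <- length_distribution(c(100L, 3L, 50L), 1:4, n = 100)
  cv <- cluster_entropy_curve(dist, min_count = 5)
  expect_length(cv$S, 2)
})

test_that("decomposition fit recovers its own model to 3 decimals", {
  n <- 1000
  edges <- log_bin_edges(16000, 8)
  lo <- edges[-length(edges)]; hi <- edges[-1]
  ell <- sqrt(lo * pmax(hi - 1, lo))
  S0 <- 1; D <- 1.4
  # synthetic curve following the fitted model's structure: ordered
  # regime purely logarithmic, disordered regime with the linear term
  S <- S0 + D * log(ell) + ifelse(ell > n, ell / n, 0)
  cv <- structure(list(n = n, ell = ell, S = S,
                       counts = rep(100L, length(ell)),
                       form = "surprisal", model = NULL),
                  class = "entropy_curve")
  fit <- fit_entropy_decomposition(cv)
  expect_lt(abs(fit$model$S0 - S0), 1e-3)
  expect_lt(abs(fit$model$D - D), 1e-3)
  expect_lt(abs(fit$model$linear_slope - 1 / n), 1e-6)
  expect_length(fit$model$flags, 0)
})

test_that("under-populated regimes yield partial fits with flags", {
  cv <- structure(list(n = 1000, ell = c(6, 8, 10, 14, 20, 30),
                       S = log(c(6, 8, 10, 14, 20, 30)),
                       counts = rep(100L, 6), form = "surprisal",
                       model = NULL),
                  class = "entropy_curve")
  fit <- fit_entropy_decomposition(cv)
  expect_true(any(grepl("disordered regime under-populated",
                        fit$model$flags)))
  expect_true(is.na(fit$model$linear_slope))
  expect_false(is.na(fit$model$D))
})

test_that("source entropy rate reproduces s = 1/n on exact curves", {
  mk <- function(n) {
    edges <- log_bin_edges(16 * n, 8)
    lo <- edges[-length(edges)]; hi <- edges[-1]
    ell <- sqrt(lo * pmax(hi - 1, lo))
    S <- 2 + 1.4 * log(ell) + ifelse(ell > n, ell / n, 0)
    structure(list(n = n, ell = ell, S = S,
                   counts = rep(100L, length(ell)), form = "surprisal",
                   model = NULL),
              class = "entropy_curve")
  }
  # exact synthetic curves make the s ~ 1/n regression fit perfectly,
  # which lm's summary flags with a warning
  rate <- suppressWarnings(source_entropy_rate(lapply(c(500, 1000, 2000), mk)))
  expect_equal(rate$s, 1 / rate$n, tolerance = 1e-6)
  expect_gt(attr(rate, "r.squared"), 0.999)
  expect_error(source_entropy_rate(list(mk(500), mk(1000))), ">= 3")
})

test_that("entropy_collapse aligns curves additively", {
  mk <- function(n, shift) {
    ell <- c(8, 16, 32, 64, 128)
    structure(list(n = n, ell = ell, S = shift + 1.4 * log(ell),
                   counts = rep(100L, 5), form = "surprisal", model = NULL),
              class = "entropy_curve")
  }
  out <- entropy_collapse(list(mk(500, 0), mk(1000, 5), mk(2000, -3)),
                          ell_max = 250)
  expect_lt(out$deviation, 1e-12)
})
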