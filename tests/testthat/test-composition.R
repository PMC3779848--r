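# Per-cluster nucleotide composition, sigma_C and feature correlations.

manual_cluster_set <- function(df, n, span) {
  structure(df, class = c("cluster_set", "data.frame"),
            window = as.integer(n),
            crossings = c(df$start, df$end[nrow(df)]), span = span)
}

test_that("cluster composition counts bases over cluster spans", {
  rec <- seq_record("AACGTTTT")
  cs <- manual_cluster_set(
    data.frame(start = 1L, end = 5L, length = 4L, duration = 4L,
               sign = "above", area = 2),
    n = 2, span = c(1L, 8L))
  cc <- cluster_composition(rec, cs)
  expect_equal(unlist(cc[1, c("A", "C", "G", "T")]),
               c(A = 50, C = 25, G = 25, T = 0))
  expect_error(cluster_composition(rec, manual_cluster_set(
    data.frame(start = 1L, end = 20L, length = 19L, duration = 19L,
               sign = "above", area = 0), 2, c(1L, 8L))),
    "exceed")
})

test_that("ambiguous bases are excluded from percentages and flagged", {
  rec <- seq_record("ANNGNNNN")
  cs <- manual_cluster_set(
    data.frame(start = c(1L, 5L), end = c(5L, 9L),
               length = c(4L, 4L), duration = c(4L, 4L),
               sign = c("above", "below"), area = 0),
    n = 2, span = c(1L, 8L))
  cc <- cluster_composition(rec, cs)
  expect_equal(unlist(cc[1, c("A", "C", "G", "T")]),
               c(A = 50, C = 0, G = 50, T = 0))
  expect_identical(cc$ambiguous, c(2L, 4L))
  expect_true(cc$flagged[2])
  expect_true(all(is.na(cc[2, c("A", "C", "G", "T")])))
})

test_that("length-weighted cluster composition conserves the span composition", {
  rec <- simulate_dna(50000, 0.6, seed = 17)
  w <- dna_walk(rec)
  for (n in c(4, 32)) {
    cs <- extract_clusters(w, moving_average(w, n))
    cc <- cluster_composition(rec, cs)
    weighted <- colSums(as.matrix(cc[, c("A", "C", "G", "T")]) * cc$length) /
      sum(cc$length)
    span <- substr(rec$bases, min(cs$start), max(cs$end) - 1L)
    counts <- base_counts(seq_record(span))
    expect_equal(weighted,
                 100 * counts[c("A", "C", "G", "T")] / sum(counts),
                 tolerance = 1e-12)
  }
})

test_that("sigma_C is zero iff compositions are identical, and is
           invariant under duplicating every cluster", {
  rec <- seq_record(strrep("ACGT", 10))
  cs <- manual_cluster_set(
    data.frame(start = c(1L, 9L, 17L), end = c(9L, 17L, 25L),
               length = rep(8L, 3), duration = rep(8L, 3),
               sign = c("above", "below", "above"), area = 0),
    n = 4, span = c(1L, 40L))
  cc <- cluster_composition(rec, cs)
  s <- composition_sigma(cc, id = "uniform")
  expect_equal(unname(s$sigma), rep(0, 4))
  expect_equal(sum(s$mean), 100)

  rec2 <- simulate_dna(20000, 0.6, seed = 18)
  w2 <- dna_walk(rec2)
  cc2 <- cluster_composition(rec2, extract_clusters(w2, moving_average(w2, 4)))
  s_once <- composition_sigma(cc2)
  s_twice <- composition_sigma(structure(rbind(cc2, cc2),
                                         class = class(cc2), window = 4L))
  expect_equal(s_twice$sigma, s_once$sigma)
  expect_equal(s_twice$mean, s_once$mean)
  expect_gt(max(s_once$sigma), 0)
  expect_error(composition_sigma(cc2[1, ]), "at least 2")
})

test_that("composition_vs_length flags regimes and handles singletons", {
  rec <- simulate_dna(20000, 0.6, seed = 19)
  w <- dna_walk(rec)
  cc <- cluster_composition(rec, extract_clusters(w, moving_average(w, 10)))
  tab <- composition_vs_length(cc)
  expect_true(all(tab$regime[tab$ell <= 10] == "ordered"))
  expect_true(all(tab$regime[tab$ell > 10] == "disordered"))
  singles <- tab$count == 1
  if (any(singles))
    expect_true(all(tab[singles, paste0("sd_", c("A", "C", "G", "T"))] == 0))
  # ordered-regime mean composition tracks the whole-sequence one
  ord <- tab[tab$regime == "ordered", ]
  wmean <- colSums(ord[, paste0("mean_", c("A", "C", "G", "T"))] * ord$count) /
    sum(ord$count)
  counts <- base_counts(rec)
  whole <- 100 * counts[c("A", "C", "G", "T")] / rec$length
  expect_true(all(abs(wmean - whole) < 2))
})

test_that("correlation report respects bounds, symmetry and degeneracy", {
  set.seed(33)
  sig <- data.frame(chromosome = paste0("chr", 1:8),
                    sigma_A = runif(8, 5, 20), sigma_C = runif(8, 5, 20),
                    sigma_G = runif(8, 5, 20), sigma_T = runif(8, 5, 20))
  pooled <- rowMeans(sig[, -1])
  feats <- data.frame(chromosome = sig$chromosome,
                      self = pooled, anti = -pooled, flat = 5)
  rep <- suppressMessages(correlate_features(sig, feats))
  expect_equal(rep$rho[rep$feature == "self" & rep$base == "pooled"], 1)
  expect_equal(rep$rho[rep$feature == "anti" & rep$base == "pooled"], -1)
  expect_true(is.na(rep$rho[rep$feature == "flat" & rep$base == "pooled"]))
  expect_true(all(abs(rep$rho) <= 1, na.rm = TRUE))
})

test_that("the feature report handles a realistic 24-chromosome table", {
  # reference sigma_C values for the 24 human chromosomes (window n = 4,
  # first 10 Mb) against the chromosome lengths: a realistic fixture for
  # the correlation report (pooled plus per-base rows, one feature)
  sigma <- data.frame(
    chromosome = c(1:22, "X", "Y"),
    sigma_A = c(11.01, 14.19, 10.05, 16.56, 19.75, 9.07, 8.58, 4.89, 6.49,
                10.84, 9.12, 17.09, 17.12, 19.53, 16.55, 16.31, 5.06, 20.02,
                17.90, 17.31, 10.84, 8.40, 18.06, 6.19),
    sigma_C = c(10.81, 12.90, 9.43, 12.91, 14.32, 6.33, 8.32, 3.88, 4.97,
                9.04, 8.83, 14.86, 12.01, 13.06, 14.08, 15.60, 5.17, 13.98,
                14.88, 13.86, 7.69, 5.81, 14.09, 6.66),
    sigma_G = c(10.06, 12.43, 8.29, 13.87, 12.76, 7.42, 11.14, 4.33, 4.36,
                7.52, 11.69, 14.13, 13.78, 13.43, 12.54, 15.77, 4.95, 14.10,
                13.99, 14.33, 8.50, 5.53, 14.87, 7.08),
    sigma_T = c(9.68, 14.30, 8.52, 17.79, 16.69, 8.71, 10.21, 4.91, 5.23,
                9.38, 10.87, 15.63, 18.11, 19.26, 16.61, 15.69, 5.67, 18.47,
                17.10, 18.70, 10.81, 8.48, 19.06, 7.47))
  lengths <- data.frame(
    chromosome = c(1:22, "X", "Y"),
    length = c(226217758, 237900011, 195304882, 187941502, 177847050,
               169100547, 155403473, 143332430, 120994158, 131739836,
               131247160, 130304143, 95747346, 88290585, 81927784,
               78990748, 79620483, 74660927, 56038018, 59505758,
               35452914, 35059666, 152580014, 25654723))
  rep <- correlate_features(sigma, lengths)
  expect_identical(nrow(rep), 5L)  # pooled + one row per base
  expect_identical(unique(rep$pairs), 24L)
  expect_true(all(abs(rep$rho) <= 1))
  # correlation is symmetric in its arguments
  rho <- rep$rho[rep$base == "pooled"]
  pooled <- rowMeans(sigma[, -1])
  expect_equal(rho, cor(lengths$length[match(sigma$chromosome,
                                             lengths$chromosome)], pooled))
})
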