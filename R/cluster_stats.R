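# Cluster length distribution P(l, n), cluster entropy S(l, n) and its
# decomposition into ordered (D log l) and disordered (l/n) terms.

log_bin_edges <- function(max_len, bins_per_octave) {
  e <- 2^(seq(0, ceiling(log2(max_len)) + 1, by = 1 / bins_per_octave))
  unique(ceiling(e))
}

#' Construct a cluster length distribution
#'
#' Low-level constructor from integer-snapped bin edges and counts;
#' normally produced by [length_histogram()].  Bin i covers the integer
#' lengths `edges[i] .. edges[i+1] - 1`; the probability density is
#' normalized so that `sum(density * width) == 1`, which makes the
#' log-log slope of the density equal to -D for a power-law
#' `P(l) ~ l^-D`.
#'
#' @param counts integer counts per bin.
#' @param edges increasing integer bin edges (length `length(counts) + 1`).
#' @param n the moving-average window that produced the clusters.
#' @return object of class `"length_distribution"`: list with `n`,
#'   `edges`, `lo`, `hi`, `width`, `center` (geometric mean of the first
#'   and last integer in the bin), `counts`, `density`, `total`.
#' @export
length_distribution <- function(counts, edges, n) {
  stopifnot(length(edges) == length(counts) + 1L, all(diff(edges) > 0),
            all(counts >= 0), sum(counts) > 0)
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  width <- hi - lo
  total <- sum(counts)
  structure(list(n = as.integer(n), edges = edges, lo = lo, hi = hi,
                 width = width, center = sqrt(lo * pmax(hi - 1, lo)),
                 counts = as.integer(counts),
                 density = counts / (total * width), total = total),
            class = "length_distribution")
}

cluster_lengths <- function(cs) {
  if (inherits(cs, "cluster_set")) cs <- list(cs)
  n <- unique(vapply(cs, function(c) attr(c, "window"), numeric(1)))
  if (length(n) != 1L)
    stop("cluster sets to be pooled must share the same window n")
  list(n = n, lengths = unlist(lapply(cs, function(c) c$length)))
}

#' Histogram of cluster lengths
#'
#' Logarithmically binned estimate of the cluster length probability
#' density P(l, n).  Bin edges are a geometric grid (`bins_per_octave`
#' bins per doubling) snapped to integers, so the same grid is shared by
#' every distribution and curves for different n can be compared bin by
#' bin.  A list of cluster sets (e.g. from replicate series or disjoint
#' segments, all with the same n) is pooled into one distribution.
#'
#' @param cs a [cluster_set][extract_clusters] or list of cluster sets
#'   sharing the same window.
#' @param bins_per_octave log-bin resolution (default 8).
#' @return a [length_distribution].
#' @export
length_histogram <- function(cs, bins_per_octave = 8) {
  stopifnot(bins_per_octave >= 1)
  cl <- cluster_lengths(cs)
  if (length(cl$lengths) == 0L) stop("empty cluster set")
  edges <- log_bin_edges(max(cl$lengths), bins_per_octave)
  idx <- findInterval(cl$lengths, edges)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  length_distribution(counts, edges, cl$n)
}

#' @export
print.length_distribution <- function(x, ...) {
  occ <- sum(x$counts > 0)
  cat(sprintf("<length_distribution> n = %d: %d clusters, lengths %d..%d, %d/%d occupied bins\n",
              x$n, x$total, min(x$lo[x$counts > 0]),
              max(x$hi[x$counts > 0] - 1L), occ, length(x$counts)))
  invisible(x)
}

#' Power-law exponent of the cluster length distribution
#'
#' In the scaling regime (lengths below the window-induced cutoff) the
#' cluster length density follows `P(l, n) ~ l^-D` with fractal dimension
#' D = 2 - H.  D is estimated as minus the least-squares slope of log
#' density against log length over occupied bins with
#' `ell_min <= l <= n/omega`; the first few integer lengths sit above the
#' asymptotic power law and are excluded by `ell_min`.
#'
#' @param dist a [length_distribution].
#' @param omega upper regime bound `l <= n/omega` (default 2, a buffer
#'   below the crossover at `l = n`).
#' @param ell_min smallest length entering the fit (default 5).
#' @param min_count occupied-bin threshold (default 5 counts).
#' @return object of class `"scaling_estimate"`: list with `D`, `H`
#'   (= 2 - D), `stderr` (of D), `range` (lengths used) and the `lm` fit.
#' @export
fit_powerlaw_exponent <- function(dist, omega = 2, ell_min = 5, min_count = 5) {
  stopifnot(inherits(dist, "length_distribution"))
  sel <- dist$counts >= min_count & dist$center >= ell_min &
    dist$center <= dist$n / omega
  if (sum(sel) < 5L)
    stop("too few occupied bins (", sum(sel),
         ") in the power-law regime [", ell_min, ", ", dist$n / omega, "]")
  df <- data.frame(ell = dist$center[sel], density = dist$density[sel])
  fit <- lm(log(density) ~ log(ell), data = df)
  D <- -unname(coef(fit)[2])
  structure(list(D = D, H = 2 - D,
                 stderr = unname(summary(fit)$coefficients[2, 2]),
                 range = range(df$ell), fit = fit),
            class = "scaling_estimate")
}

#' @export
print.scaling_estimate <- function(x, ...) {
  cat(sprintf("power-law exponent: D = %.4f (se %.4f), H = 2 - D = %.4f, fit over l in [%.1f, %.1f]\n",
              x$D, x$stderr, x$H, x$range[1], x$range[2]))
  invisible(x)
}

#' @export
coef.scaling_estimate <- function(object, ...) {
  c(D = object$D, H = object$H)
}

#' Cluster entropy curve S(l, n)
#'
#' Shannon entropy of the cluster partition, evaluated per length bin.
#' The default (and recommended) `"surprisal"` form reads the entropy of
#' the microcanonical set of clusters of length l -- mu(l, n)
#' equiprobable states give S = log mu = -log P + const -- so
#' `S(l, n) = -log density(l, n)`, which decomposes as
#' `S0 + D log l + l/n`.  The literal per-bin Shannon summand
#' `-P log P` is available as `form = "summand"` for comparison; it is
#' not n-invariant and does not yield the decomposition.
#'
#' Bins with fewer than `min_count` clusters are omitted (the surprisal
#' of one-count bins is dominated by sampling noise).
#'
#' @param dist a [length_distribution].
#' @param min_count minimum clusters per bin (default 5).
#' @param form `"surprisal"` (default) or `"summand"`.
#' @return object of class `"entropy_curve"`: list with `n`, `ell` (bin
#'   centers), `S` (nats), `counts`, `form` and `model` (`NULL` until
#'   [fit_entropy_decomposition()] is applied).
#' @export
cluster_entropy_curve <- function(dist, min_count = 5,
                                  form = c("surprisal", "summand")) {
  stopifnot(inherits(dist, "length_distribution"))
  form <- match.arg(form)
  sel <- dist$counts >= min_count
  p <- dist$density[sel]
  S <- switch(form, surprisal = -log(p), summand = -p * log(p))
  structure(list(n = dist$n, ell = dist$center[sel], S = S,
                 counts = dist$counts[sel], form = form, model = NULL),
            class = "entropy_curve")
}

#' @export
print.entropy_curve <- function(x, ...) {
  cat(sprintf("<entropy_curve> n = %d: %d bins, l in [%.1f, %.1f] (%s form)\n",
              x$n, length(x$ell), min(x$ell), max(x$ell), x$form))
  if (!is.null(x$model))
    cat(sprintf("  fitted: S0 = %.3f, D = %.3f, linear slope = %.3e (1/n = %.3e)%s\n",
                x$model$S0, x$model$D, x$model$linear_slope, 1 / x$n,
                if (length(x$model$flags))
                  paste0(" [", paste(x$model$flags, collapse = "; "), "]")
                else ""))
  invisible(x)
}

#' Fit the entropy decomposition S0 + D log l + l/n
#'
#' Two-regime fit of an entropy curve.  Ordered regime
#' (`ell_min <= l <= n/regime_factor`): least squares of S on log l gives
#' the intercept S0 and the fractal dimension D.  Disordered regime
#' (`l > n`): after subtracting the fitted logarithmic part, least
#' squares of the remainder on l gives the linear slope, the estimate of
#' the source entropy rate (theoretically 1/n).  The factor-2 buffer
#' between the regimes keeps the crossover region out of both fits.
#'
#' @param curve an [entropy_curve][cluster_entropy_curve].
#' @param regime_factor ordered regime bound `l <= n/regime_factor`
#'   (default 2).
#' @param ell_min smallest length used in the ordered-regime fit
#'   (default 5; see [fit_powerlaw_exponent()]).
#' @return the curve with `model` populated: list with `S0`, `D`,
#'   `linear_slope`, `regime_split`, `flags` (character vector naming any
#'   under-populated regime or out-of-range D) and the two `lm` fits.
#' @export
fit_entropy_decomposition <- function(curve, regime_factor = 2, ell_min = 5) {
  stopifnot(inherits(curve, "entropy_curve"))
  n <- curve$n
  flags <- character(0)
  ord <- curve$ell >= ell_min & curve$ell <= n / regime_factor
  S0 <- D <- NA_real_
  log_fit <- lin_fit <- NULL
  if (sum(ord) >= 4L) {
    log_fit <- lm(S ~ log(ell), data = data.frame(ell = curve$ell[ord],
                                                  S = curve$S[ord]))
    S0 <- unname(coef(log_fit)[1])
    D <- unname(coef(log_fit)[2])
    if (D <= 0.5 || D >= 2.5)
      flags <- c(flags, sprintf("fitted D = %.2f outside (0.5, 2.5)", D))
  } else {
    flags <- c(flags, sprintf("ordered regime under-populated (%d bins)", sum(ord)))
  }
  dis <- curve$ell > n
  slope <- NA_real_
  if (sum(dis) >= 4L && !is.na(D)) {
    rem <- curve$S[dis] - (S0 + D * log(curve$ell[dis]))
    lin_fit <- lm(rem ~ ell, data = data.frame(ell = curve$ell[dis], rem = rem))
    slope <- unname(coef(lin_fit)[2])
  } else {
    flags <- c(flags, sprintf("disordered regime under-populated (%d bins)", sum(dis)))
  }
  curve$model <- list(S0 = S0, D = D, linear_slope = slope,
                      regime_split = n / regime_factor, flags = flags,
                      log_fit = log_fit, lin_fit = lin_fit)
  curve
}

#' Source entropy rate across windows
#'
#' The large-l slope of the entropy curve measures the excess randomness
#' injected by the partition; theory predicts s(n) = 1/n, vanishing as
#' n grows.  Takes entropy curves for at least 3 windows (fitting any
#' curve whose decomposition is missing) and regresses the fitted slopes
#' on 1/n.
#'
#' @param curves list of [entropy_curve][cluster_entropy_curve]s for
#'   distinct n.
#' @param ... passed to [fit_entropy_decomposition()] where needed.
#' @return `data.frame` of class `"entropy_rate"` with columns `n` and
#'   `s`; attributes `fit` (the `lm` of s on 1/n) and `r.squared`.
#' @export
source_entropy_rate <- function(curves, ...) {
  stopifnot(is.list(curves), length(curves) >= 3L)
  curves <- lapply(curves, function(cv) {
    stopifnot(inherits(cv, "entropy_curve"))
    if (is.null(cv$model)) fit_entropy_decomposition(cv, ...) else cv
  })
  tab <- data.frame(n = vapply(curves, `[[`, numeric(1), "n"),
                    s = vapply(curves, function(cv) cv$model$linear_slope,
                               numeric(1)))
  tab <- tab[order(tab$n), ]
  rownames(tab) <- NULL
  ok <- !is.na(tab$s)
  fit <- if (sum(ok) >= 3L) lm(s ~ inv_n, data = data.frame(inv_n = 1 / tab$n[ok],
                                                            s = tab$s[ok]))
         else NULL
  structure(tab, class = c("entropy_rate", "data.frame"), fit = fit,
            r.squared = if (!is.null(fit)) summary(fit)$r.squared else NA_real_)
}

#' @export
print.entropy_rate <- function(x, ...) {
  cat("source entropy rate s(n) (theory: s = 1/n):\n")
  print(data.frame(n = x$n, s = signif(x$s, 4), `1/n` = signif(1 / x$n, 4),
                   check.names = FALSE))
  cat(sprintf("regression of s on 1/n: R^2 = %.4f\n", attr(x, "r.squared")))
  invisible(x)
}

#' Collapse diagnostic for entropy curves
#'
#' In the ordered regime the entropy curves for different n coincide up
#' to the additive constant S0 (the log l^D term does not depend on the
#' partition).  This aligns the curves additively by least squares
#' (subtracting each curve's mean over the common bins) on the shared bin
#' centers with `l < ell_max` and reports the maximum pairwise deviation.
#'
#' @param curves list of [entropy_curve][cluster_entropy_curve]s (same
#'   binning grid).
#' @param ell_max upper length bound of the comparison window; default
#'   `min(n)/2`, the ordered regime of every curve.
#' @return list with `deviation` (max over bins of the aligned range
#'   across curves, in nats) and `table` (per-bin aligned values).
#' @export
entropy_collapse <- function(curves, ell_max = NULL) {
  stopifnot(is.list(curves), length(curves) >= 2L)
  ns <- vapply(curves, `[[`, numeric(1), "n")
  if (is.null(ell_max)) ell_max <- min(ns) / 2
  common <- Reduce(intersect, lapply(curves, function(cv) cv$ell[cv$ell < ell_max]))
  if (length(common) < 2L) stop("fewer than 2 common bins below ell_max")
  m <- vapply(curves, function(cv) cv$S[match(common, cv$ell)],
              numeric(length(common)))
  aligned <- sweep(m, 2, colMeans(m))
  colnames(aligned) <- paste0("n", ns)
  dev <- apply(aligned, 1, function(r) diff(range(r)))
  list(deviation = max(dev),
       table = data.frame(ell = common, aligned, deviation = dev))
}
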