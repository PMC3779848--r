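# The main model-fitting interface: cluster_entropy() and its methods.

#' Fit the cluster-entropy model of a long-range correlated series
#'
#' Partitions the input walk(s) by moving-average crossings for each
#' window n, estimates the cluster length distribution P(l, n) and the
#' entropy curve S(l, n) = -log P(l, n), fits the decomposition
#' S0 + D log l + l/n per window, regresses the fitted linear slopes on
#' 1/n (the source entropy rate law), and estimates the Hurst exponent H
#' by DMA variance scaling (D = 2 - H).
#'
#' @param x a numeric series, a [dna_walk], a [seq_record], or a list of
#'   any of these; list elements are treated as replicate series (e.g.
#'   independent realizations or disjoint segments) whose cluster sets
#'   are pooled per window.
#' @param windows moving-average windows n (default `c(500, 1000, 2000)`).
#' @param bins_per_octave log-bin resolution of the length histograms.
#' @param min_count minimum clusters per bin entering entropy curves.
#' @param regime_factor ordered-regime bound l <= n/regime_factor.
#' @param ell_min smallest length entering ordered-regime fits.
#' @param hurst_windows windows for the DMA Hurst estimate; default
#'   dyadic 8..min(4096, L/10).
#' @param convention moving-average convention (see [moving_average()]).
#' @return object of class `"centropy"` with components `clusters`
#'   (per-window lists of cluster sets), `distributions`, `curves`
#'   (fitted), `rate` (if >= 3 windows), `powerlaw` (scaling estimate
#'   from the largest window's distribution) and `hurst` (per-series DMA
#'   estimates plus their mean).  Supports `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `plot` and `simulate`.
#' @examples
#' y <- rfbm(2^16, 0.6, seed = 1)
#' fit <- cluster_entropy(y, windows = c(100, 200, 400))
#' summary(fit)
#' @export
cluster_entropy <- function(x, windows = c(500, 1000, 2000),
                            bins_per_octave = 8, min_count = 5,
                            regime_factor = 2, ell_min = 5,
                            hurst_windows = NULL,
                            convention = "backward") {
  cl <- match.call()
  series <- if (is.list(x) && !inherits(x, c("dna_walk", "seq_record")))
    lapply(x, as_series) else list(as_series(x))
  L <- unique(lengths(series))
  windows <- sort(unique(as.integer(windows)))
  if (any(windows >= min(L)))
    stop("every window must be smaller than the shortest series")

  per_window <- lapply(windows, function(n) {
    lapply(series, function(y) {
      ma <- moving_average(y, n, convention)
      extract_clusters(y, ma)
    })
  })
  names(per_window) <- as.character(windows)
  dists <- lapply(per_window, length_histogram,
                  bins_per_octave = bins_per_octave)
  curves <- lapply(dists, function(d)
    fit_entropy_decomposition(cluster_entropy_curve(d, min_count = min_count),
                              regime_factor = regime_factor,
                              ell_min = ell_min))
  rate <- if (length(windows) >= 3L) source_entropy_rate(curves) else NULL
  powerlaw <- tryCatch(
    fit_powerlaw_exponent(dists[[length(dists)]], omega = regime_factor,
                          ell_min = ell_min, min_count = min_count),
    error = function(e) NULL)
  hw <- if (is.null(hurst_windows))
    2^(3:floor(log2(min(4096, min(L) / 10)))) else hurst_windows
  hurst <- lapply(series, function(y)
    tryCatch(estimate_hurst(y, hw, convention), error = function(e) NULL))
  hurst <- hurst[!vapply(hurst, is.null, logical(1))]
  Hs <- vapply(hurst, `[[`, numeric(1), "H")
  structure(list(call = cl, windows = windows, n_series = length(series),
                 series_length = L, clusters = per_window,
                 distributions = dists, curves = curves, rate = rate,
                 powerlaw = powerlaw,
                 hurst = list(H = mean(Hs), sd = if (length(Hs) > 1) sd(Hs)
                              else NA_real_, fits = hurst)),
            class = "centropy")
}

#' @export
print.centropy <- function(x, ...) {
  cat("Cluster-entropy fit\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  %d series of length %s; windows n = %s\n", x$n_series,
              paste(x$series_length, collapse = "/"),
              paste(x$windows, collapse = ", ")))
  cat(sprintf("  Hurst (DMA): H = %.4f%s;  D = 2 - H = %.4f\n",
              x$hurst$H,
              if (!is.na(x$hurst$sd)) sprintf(" (sd %.4f over %d series)",
                                              x$hurst$sd, x$n_series) else "",
              2 - x$hurst$H))
  invisible(x)
}

#' @export
summary.centropy <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$curves, function(cv)
    data.frame(n = cv$n, clusters = object$distributions[[as.character(cv$n)]]$total,
               S0 = cv$model$S0, D = cv$model$D,
               slope = cv$model$linear_slope, inv_n = 1 / cv$n)))
  rownames(tab) <- NULL
  structure(list(call = object$call, table = tab, hurst = object$hurst,
                 powerlaw = object$powerlaw,
                 rate_r2 = if (!is.null(object$rate)) attr(object$rate, "r.squared")
                           else NA_real_),
            class = "summary.centropy")
}

#' @export
print.summary.centropy <- function(x, ...) {
  cat("Cluster-entropy fit: S(l, n) = S0 + D log l + s(n) l\n\n")
  tab <- x$table
  tab$S0 <- round(tab$S0, 3); tab$D <- round(tab$D, 3)
  tab$slope <- signif(tab$slope, 3); tab$inv_n <- signif(tab$inv_n, 3)
  names(tab)[names(tab) == "inv_n"] <- "1/n"
  print(tab, row.names = FALSE)
  cat(sprintf("\nHurst (DMA variance scaling): H = %.4f, D = 2 - H = %.4f\n",
              x$hurst$H, 2 - x$hurst$H))
  if (!is.null(x$powerlaw))
    cat(sprintf("Power-law regime of P(l, n): D = %.4f (H = %.4f)\n",
                x$powerlaw$D, x$powerlaw$H))
  if (!is.na(x$rate_r2))
    cat(sprintf("Source entropy rate: regression of s(n) on 1/n, R^2 = %.4f\n",
                x$rate_r2))
  invisible(x)
}

#' @export
coef.centropy <- function(object, ...) {
  m <- do.call(rbind, lapply(object$curves, function(cv)
    c(S0 = cv$model$S0, D = cv$model$D, slope = cv$model$linear_slope)))
  rownames(m) <- paste0("n=", object$windows)
  attr(m, "hurst") <- c(H = object$hurst$H, D = 2 - object$hurst$H)
  m
}

#' Predicted entropy from the fitted decomposition
#'
#' Evaluates S0 + D log l + s(n) l for the requested lengths, using each
#' window's fitted parameters.
#'
#' @param object a [cluster_entropy()] fit.
#' @param newdata `data.frame` with columns `ell` and `n` (each `n` must
#'   be one of the fitted windows); default: the fitted bin centers.
#' @param ... unused.
#' @return numeric vector of entropies (nats).
#' @export
predict.centropy <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    newdata <- do.call(rbind, lapply(object$curves, function(cv)
      data.frame(ell = cv$ell, n = cv$n)))
  stopifnot(all(c("ell", "n") %in% names(newdata)))
  vapply(seq_len(nrow(newdata)), function(i) {
    n <- as.character(newdata$n[i])
    cv <- object$curves[[n]]
    if (is.null(cv)) stop("window n = ", n, " was not fitted")
    m <- cv$model
    m$S0 + m$D * log(newdata$ell[i]) +
      (if (is.na(m$linear_slope)) 0 else m$linear_slope) * newdata$ell[i]
  }, numeric(1))
}

#' @export
residuals.centropy <- function(object, ...) {
  do.call(rbind, lapply(object$curves, function(cv) {
    pred <- predict(object, data.frame(ell = cv$ell, n = cv$n))
    data.frame(n = cv$n, ell = cv$ell, S = cv$S, fitted = pred,
               residual = cv$S - pred)
  }))
}

#' Diagnostic plots for a cluster-entropy fit
#'
#' `which = 1`: log-log cluster length densities P(l, n).
#' `which = 2`: entropy curves S(l, n) with the fitted decompositions.
#' `which = 3`: DMA variance scaling of the first series.
#'
#' @param x a [cluster_entropy()] fit.
#' @param which subset of 1:3.
#' @param ... further graphical parameters.
#' @export
plot.centropy <- function(x, which = 1:2, ...) {
  ns <- x$windows
  cols <- seq_along(ns)
  if (1 %in% which) {
    xs <- lapply(x$distributions, function(d) d$center[d$counts > 0])
    ys <- lapply(x$distributions, function(d) d$density[d$counts > 0])
    plot(NA, log = "xy", xlim = range(unlist(xs)), ylim = range(unlist(ys)),
         xlab = "cluster length l", ylab = "P(l, n)",
         main = "Cluster length distribution", ...)
    for (i in seq_along(ns)) points(xs[[i]], ys[[i]], col = cols[i], pch = 20)
    legend("bottomleft", legend = paste0("n = ", ns), col = cols, pch = 20,
           bty = "n")
  }
  if (2 %in% which) {
    plot(NA, log = "x",
         xlim = range(unlist(lapply(x$curves, `[[`, "ell"))),
         ylim = range(unlist(lapply(x$curves, `[[`, "S"))),
         xlab = "cluster length l", ylab = "S(l, n) [nats]",
         main = "Cluster entropy", ...)
    for (i in seq_along(ns)) {
      cv <- x$curves[[i]]
      points(cv$ell, cv$S, col = cols[i], pch = 20)
      lines(cv$ell, predict(x, data.frame(ell = cv$ell, n = cv$n)),
            col = cols[i])
    }
    legend("topleft", legend = paste0("n = ", ns), col = cols, pch = 20,
           bty = "n")
  }
  if (3 %in% which && length(x$hurst$fits)) plot(x$hurst$fits[[1]])
  invisible(x)
}

#' Simulate surrogate walks from a fitted model
#'
#' Draws fractional Brownian walks with the fitted Hurst exponent and
#' the length of the fitted series -- surrogates sharing the model's
#' correlation structure.
#'
#' @param object a [cluster_entropy()] fit.
#' @param nsim number of surrogate series.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of `nsim` numeric series.
#' @export
simulate.centropy <- function(object, nsim = 1, seed = NULL, ...) {
  H <- min(max(object$hurst$H, 0.01), 0.99)
  L <- min(object$series_length)
  with_seed(seed, lapply(seq_len(nsim), function(i) rfbm(L, H)))
}
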