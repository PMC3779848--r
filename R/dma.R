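# Moving average, crossing detection, cluster extraction and the
# detrending-moving-average (DMA) Hurst estimator.

as_series <- function(x) {
  if (inherits(x, "dna_walk")) x$y
  else if (inherits(x, "seq_record")) dna_walk(x)$y
  else if (is.numeric(x)) as.numeric(x)
  else stop("expected a numeric series, dna_walk or seq_record")
}

#' Moving average of a series
#'
#' Backward (causal) moving average
#' \eqn{\tilde y_n(x) = \frac1n \sum_{k=0}^{n-1} y(x-k)}, the detrending
#' reference curve of the DMA cluster partition.  Positions in the warm-up
#' region (the first `window - 1` samples) are `NA` and excluded from
#' crossing detection.  A centered variant is available but the backward
#' convention is the default used throughout.
#'
#' @param y numeric series, [dna_walk] or [seq_record].
#' @param window window size n (1 <= n < length of the series).
#' @param convention `"backward"` (default) or `"centered"`.
#' @return numeric vector aligned with `y`; warm-up positions are `NA`.
#'   Attributes `window` and `convention` record the parameters; for
#'   integer-valued series with the backward convention the exact window
#'   sums are attached as attribute `wsum` so downstream crossing
#'   detection is free of floating-point ties.
#' @examples
#' moving_average(c(1, 2, 3, 4, 5), 2)   # x - 1/2 on its valid range
#' @export
moving_average <- function(y, window, convention = c("backward", "centered")) {
  convention <- match.arg(convention)
  y <- as_series(y)
  L <- length(y)
  window <- as.integer(window)
  if (window < 1L) stop("'window' must be >= 1")
  if (window >= L) stop("'window' (", window, ") must be smaller than the series length (", L, ")")
  S <- c(0, cumsum(y))
  wsum <- S[(window + 1):(L + 1)] - S[1:(L - window + 1)]
  ma <- wsum / window
  if (convention == "backward") {
    out <- c(rep(NA_real_, window - 1L), ma)
    if (all(y == round(y)))
      attr(out, "wsum") <- c(rep(NA_real_, window - 1L), wsum)
  } else {
    # center of an n-window at x covers x - floor((n-1)/2) .. x + floor(n/2)
    lead <- window %/% 2L
    out <- c(rep(NA_real_, window - 1L - lead), ma, rep(NA_real_, lead))
  }
  attr(out, "window") <- window
  attr(out, "convention") <- convention
  out
}

#' Crossings of a series with its moving average
#'
#' With d = y - moving average on the valid range, a crossing is recorded
#' at x + 1 whenever d changes sign strictly between x and x + 1, and at x
#' whenever d(x) is exactly zero (runs of consecutive zeros collapse to a
#' single crossing at the first zero).  For integer walks the comparison
#' is done on n*y minus the window sum, so crossing positions are
#' bit-exact.
#'
#' @param y numeric series, [dna_walk] or [seq_record].
#' @param ma its moving average, as returned by [moving_average()].
#' @return increasing integer vector of crossing positions (indices into
#'   `y`).  Fewer than 2 crossings means no clusters can be formed.
#' @export
find_crossings <- function(y, ma) {
  y <- as_series(y)
  window <- attr(ma, "window")
  valid <- which(!is.na(ma))
  wsum <- attr(ma, "wsum")
  d <- if (!is.null(wsum)) window * y[valid] - wsum[valid]
       else y[valid] - ma[valid]
  s <- sign(d)
  zi <- which(s == 0)
  if (length(zi)) zi <- zi[c(TRUE, diff(zi) > 1L)]
  sc <- which(s[-1] * s[-length(s)] < 0) + 1L
  valid[sort(unique(c(zi, sc)))]
}

#' Extract clusters between consecutive crossings
#'
#' One cluster per consecutive pair of crossings: the region of the walk
#' bounded by its moving average between two crossing points,
#' characterized by its length l (= duration for base-indexed
#' sequences), sign (above/below the moving average) and area
#' (sum of y - moving average over the cluster).  Regions before the
#' first and after the last crossing are discarded.
#'
#' @inheritParams find_crossings
#' @param crossings crossing positions, by default [find_crossings()].
#' @return a `data.frame` of class `"cluster_set"` with columns `start`
#'   (inclusive), `end` (exclusive), `length`, `duration`, `sign`
#'   (`"above"`/`"below"`), `area`; attributes `window`, `crossings` and
#'   `span` (first and last valid position analyzed).  Fewer than 2
#'   crossings yield an empty set (not an error).
#' @export
extract_clusters <- function(y, ma, crossings = find_crossings(y, ma)) {
  y <- as_series(y)
  window <- attr(ma, "window")
  valid <- which(!is.na(ma))
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), duration = integer(0),
                      sign = character(0), area = numeric(0))
  if (length(crossings) < 2L) {
    message("fewer than 2 crossings: empty cluster set")
    cs <- empty
  } else {
    start <- crossings[-length(crossings)]
    end <- crossings[-1]
    wsum <- attr(ma, "wsum")
    d <- numeric(length(y))
    d[valid] <- if (!is.null(wsum)) (window * y[valid] - wsum[valid]) / window
                else y[valid] - ma[valid]
    Sd <- c(0, cumsum(d))
    area <- Sd[end] - Sd[start]
    # sign of a cluster = sign of its first non-zero deviation
    nz <- valid[d[valid] != 0]
    pos <- findInterval(start - 1L, nz) + 1L
    first_nz <- ifelse(pos <= length(nz), nz[pos], NA_integer_)
    sgn <- ifelse(!is.na(first_nz) & first_nz < end,
                  ifelse(d[first_nz] > 0, "above", "below"), "flat")
    cs <- data.frame(start = start, end = end, length = end - start,
                     duration = end - start, sign = sgn, area = area)
  }
  structure(cs, class = c("cluster_set", "data.frame"),
            window = window, crossings = crossings,
            span = range(valid))
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> n = %d: %d clusters spanning [%d, %d]\n",
              attr(x, "window"), nrow(x),
              attr(x, "span")[1], attr(x, "span")[2]))
  if (nrow(x)) {
    cat(sprintf("  lengths: min %d, median %d, max %d\n",
                min(x$length), as.integer(median(x$length)), max(x$length)))
  }
  invisible(x)
}

#' DMA variance over a set of windows
#'
#' The detrending-moving-average second moment
#' \eqn{\sigma^2_{DMA}(n) = \langle (y - \tilde y_n)^2 \rangle}, computed
#' over the valid range of each window.  For a series of Hurst exponent H
#' it scales as \eqn{n^{2H}}.
#'
#' @param y numeric series, [dna_walk] or [seq_record].
#' @param windows integer vector of window sizes; each must satisfy
#'   n <= length(y)/10 so the average is taken over many windows.
#' @param convention moving-average convention, see [moving_average()].
#' @return `data.frame` with columns `n` and `sigma2`.
#' @export
dma_variance <- function(y, windows, convention = "backward") {
  y <- as_series(y)
  windows <- sort(unique(as.integer(windows)))
  if (any(windows < 2L) || any(windows > length(y) / 10))
    stop("windows must lie in [2, length(y)/10]")
  sigma2 <- vapply(windows, function(n) {
    ma <- moving_average(y, n, convention)
    v <- which(!is.na(ma))
    mean((y[v] - ma[v])^2)
  }, numeric(1))
  data.frame(n = windows, sigma2 = sigma2)
}

default_hurst_windows <- function(L) {
  2^(3:floor(log2(L / 10)))
}

#' Hurst exponent by DMA variance scaling
#'
#' Least-squares fit of \eqn{\log \sigma^2_{DMA}(n)} against
#' \eqn{\log n}; the slope equals 2H.  At least 5 roughly log-spaced
#' windows are required.
#'
#' @inheritParams dma_variance
#' @param windows window sizes; default dyadic 8, 16, ... up to
#'   length(y)/10.
#' @return object of class `"dma_hurst"`: list with `H`, `D` (= 2 - H),
#'   `intercept`, `stderr` (standard error of H), `table` (per-window
#'   variance, fit and residual) and `windows`.
#' @examples
#' y <- rfbm(2^14, 0.7, seed = 1)
#' estimate_hurst(y)
#' @export
estimate_hurst <- function(y, windows = NULL, convention = "backward") {
  y <- as_series(y)
  if (is.null(windows)) windows <- default_hurst_windows(length(y))
  windows <- sort(unique(as.integer(windows)))
  if (length(windows) < 5L)
    stop("need at least 5 window sizes, got ", length(windows))
  tab <- dma_variance(y, windows, convention)
  if (any(tab$sigma2 <= 0))
    stop("degenerate fit: zero DMA variance at n = ",
         paste(tab$n[tab$sigma2 <= 0], collapse = ", "))
  fit <- lm(log(sigma2) ~ log(n), data = tab)
  H <- unname(coef(fit)[2]) / 2
  tab$fitted <- exp(fitted(fit))
  tab$residual <- residuals(fit)
  structure(list(H = H, D = 2 - H,
                 intercept = unname(coef(fit)[1]),
                 stderr = unname(summary(fit)$coefficients[2, 2]) / 2,
                 table = tab, windows = range(windows)),
            class = "dma_hurst")
}

#' @export
print.dma_hurst <- function(x, ...) {
  cat(sprintf("DMA Hurst estimate: H = %.4f (se %.4f), D = 2 - H = %.4f\n",
              x$H, x$stderr, x$D))
  cat(sprintf("  windows %d..%d, %d points, max |log residual| %.3f\n",
              x$windows[1], x$windows[2], nrow(x$table),
              max(abs(x$table$residual))))
  invisible(x)
}

#' @export
coef.dma_hurst <- function(object, ...) {
  c(H = object$H, D = object$D)
}

#' @export
plot.dma_hurst <- function(x, ...) {
  plot(x$table$n, x$table$sigma2, log = "xy",
       xlab = "window n", ylab = expression(sigma[DMA]^2),
       main = sprintf("DMA scaling, H = %.3f", x$H), ...)
  lines(x$table$n, x$table$fitted, col = 2)
  invisible(x)
}
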