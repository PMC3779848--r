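# Generators of long-range correlated test signals: fractional Gaussian
# noise (fGn), fractional Brownian walks (fBm) and synthetic DNA whose
# purine/pyrimidine walk carries a prescribed Hurst exponent.

check_hurst <- function(hurst) {
  if (!is.numeric(hurst) || length(hurst) != 1L || !is.finite(hurst) ||
      hurst <= 0 || hurst >= 1)
    stop("'hurst' must be a single number strictly between 0 and 1, got: ",
         deparse(substitute(hurst)), " = ", format(hurst))
  hurst
}

check_length <- function(length) {
  if (!is.numeric(length) || length(length) != 1L || !is.finite(length) ||
      length < 2 || length != round(length))
    stop("'length' must be a single integer >= 2, got ", format(length))
  as.integer(length)
}

# fGn autocovariance gamma(k) = 1/2 (|k+1|^2H - 2|k|^2H + |k-1|^2H),
# unit variance.
fgn_acov <- function(k, hurst) {
  h2 <- 2 * hurst
  0.5 * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
}

#' Fractional Gaussian noise by circulant embedding
#'
#' Generates a stationary Gaussian series with the exact fractional
#' Gaussian noise autocovariance
#' \eqn{\gamma(k) = \frac12(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})}
#' (unit variance, zero mean) using circulant embedding of the covariance
#' (Davies--Harte synthesis).  The embedding is computed at the next power
#' of two at least as large as `length` and truncated; if the embedding is
#' not positive semi-definite it is doubled until it is.
#'
#' @param length number of samples to return (integer, at least 2).
#' @param hurst Hurst exponent H, strictly between 0 and 1.  H = 0.5 is
#'   white noise; H > 0.5 gives persistent (power-law) correlation.
#' @param seed optional integer seed; the same `(length, hurst, seed)`
#'   yields bit-identical output and the caller's RNG state is preserved.
#' @return numeric vector of `length` zero-mean increments.
#' @examples
#' x <- rfgn(4096, hurst = 0.8, seed = 1)
#' cor(x[-1], x[-4096])      # close to 2^(2*0.8-1) - 1
#' @seealso [rfbm()] for the integrated walk, [simulate_dna()].
#' @export
rfgn <- function(length, hurst, seed = NULL) {
  length <- check_length(length)
  check_hurst(hurst)
  with_seed(seed, {
    m <- 2^ceiling(log2(length))
    repeat {
      g <- fgn_acov(0:m, hurst)
      lambda <- Re(fft(c(g, g[m:2])))
      if (min(lambda) > -1e-8 * max(lambda)) break
      m <- 2 * m
    }
    lambda[lambda < 0] <- 0
    M <- 2L * m
    z <- rnorm(M)
    w <- complex(length.out = M)
    w[1] <- sqrt(lambda[1] / M) * z[1]
    w[m + 1] <- sqrt(lambda[m + 1] / M) * z[2]
    j <- 2:m
    w[j] <- sqrt(lambda[j] / (2 * M)) * (z[2 * j - 1] + 1i * z[2 * j])
    w[M + 2 - j] <- Conj(w[j])
    Re(fft(w))[seq_len(length)]
  })
}

#' Fractional Brownian walk
#'
#' Cumulative sum of [rfgn()] increments: a discrete fractional Brownian
#' motion, the direct analogue of the DNA walk.  `var(y(t))` scales as
#' `t^(2H)`.
#'
#' @inheritParams rfgn
#' @return numeric vector `y` with `y[x] = sum(increments[1:x])`.
#' @export
rfbm <- function(length, hurst, seed = NULL) {
  cumsum(rfgn(length, hurst, seed))
}

check_composition <- function(composition) {
  if (length(composition) != 4L || !is.numeric(composition))
    stop("'composition' must be 4 probabilities (A, C, G, T)")
  if (is.null(names(composition))) names(composition) <- c("A", "C", "G", "T")
  composition <- composition[c("A", "C", "G", "T")]
  if (anyNA(composition) || any(composition < 0))
    stop("'composition' must be named A,C,G,T with non-negative entries")
  if (abs(sum(composition) - 1) > 1e-12)
    stop("'composition' must sum to 1 (got ", format(sum(composition)), ")")
  composition
}

#' Synthetic DNA with long-range correlated purine/pyrimidine structure
#'
#' Draws a nucleotide sequence whose purine/pyrimidine (R/Y) walk inherits
#' long-range correlation from a fractional Gaussian noise path: the path is
#' thresholded at its median (so the purine fraction is balanced to within
#' one base), positions above the median become purines and the rest
#' pyrimidines; within the purine track A is emitted with probability
#' pi_A/(pi_A + pi_G) (else G), within the pyrimidine track T with
#' probability pi_T/(pi_T + pi_C) (else C).
#'
#' Marginal base frequencies match `composition` exactly only when
#' `composition["A"] + composition["G"] == 0.5` (the genomic regime the
#' purine/pyrimidine coding targets); otherwise the purine share is forced
#' to 1/2 by the median threshold.
#'
#' @inheritParams rfgn
#' @param composition probability vector over (A, C, G, T), summing to 1.
#' @param id sequence identifier for the returned record.
#' @return a [seq_record] of `length` bases over \{A,C,G,T\}.
#' @examples
#' rec <- simulate_dna(1000, hurst = 0.6, seed = 1)
#' base_counts(rec)
#' @export
simulate_dna <- function(length, hurst,
                         composition = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                         seed = NULL, id = NULL) {
  length <- check_length(length)
  check_hurst(hurst)
  composition <- check_composition(composition)
  if (is.null(id))
    id <- sprintf("synthetic_H%s_L%d", format(hurst), length)
  with_seed(seed, {
    x <- rfgn(length, hurst)
    purine <- x > median(x)
    pA <- composition[["A"]]; pG <- composition[["G"]]
    pC <- composition[["C"]]; pT <- composition[["T"]]
    p_a <- if (pA + pG > 0) pA / (pA + pG) else 0.5
    p_t <- if (pT + pC > 0) pT / (pT + pC) else 0.5
    u <- runif(length)
    bases <- character(length)
    bases[purine] <- ifelse(u[purine] < p_a, "A", "G")
    bases[!purine] <- ifelse(u[!purine] < p_t, "T", "C")
    seq_record(paste(bases, collapse = ""), id = id)
  })
}
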