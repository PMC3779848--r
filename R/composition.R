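# Per-cluster nucleotide composition, its fluctuation statistic sigma_C
# and correlation with user-supplied genomic features.

BASES <- c("A", "C", "G", "T")

# population standard deviation: sigma_C must be invariant under
# duplicating every cluster, which the n-1 sample form is not
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Nucleotide composition of each cluster
#'
#' Counts A, C, G, T over the bases covered by each cluster (a cluster
#' spans positions `start .. end - 1` of the sequence the walk was built
#' from) and expresses them as percentages of the unambiguous bases in
#' the cluster.  Fully ambiguous clusters get `NA` percentages and are
#' flagged.
#'
#' @param record the [seq_record] the cluster set was derived from.
#' @param cs a [cluster_set][extract_clusters] whose coordinates lie
#'   within the record.
#' @return `data.frame` of class `"composition_records"` with columns
#'   `start`, `end`, `length`, `A`, `C`, `G`, `T` (percent), `ambiguous`
#'   (count of N bases) and `flagged`; attribute `window`.
#' @export
cluster_composition <- function(record, cs) {
  stopifnot(inherits(record, "seq_record"), inherits(cs, "cluster_set"))
  if (nrow(cs) == 0L) stop("empty cluster set")
  if (max(cs$end) - 1L > record$length)
    stop("cluster coordinates exceed the sequence length")
  r <- utf8ToInt(record$bases)
  cum <- lapply(c(BASES, "N"), function(b) c(0, cumsum(r == utf8ToInt(b))))
  names(cum) <- c(BASES, "N")
  counts <- vapply(BASES, function(b) cum[[b]][cs$end] - cum[[b]][cs$start],
                   numeric(nrow(cs)))
  counts <- matrix(counts, nrow = nrow(cs),
                   dimnames = list(NULL, BASES))
  amb <- cum[["N"]][cs$end] - cum[["N"]][cs$start]
  denom <- cs$length - amb
  pct <- 100 * counts / ifelse(denom > 0, denom, NA_real_)
  out <- data.frame(start = cs$start, end = cs$end, length = cs$length,
                    pct, ambiguous = as.integer(amb),
                    flagged = denom == 0L)
  structure(out, class = c("composition_records", "data.frame"),
            window = attr(cs, "window"))
}

#' Composition as a function of cluster length
#'
#' Log-binned mean and spread of the per-cluster base percentages,
#' flagged by regime: ordered (power-law correlated, l <= n) against
#' disordered (exponentially correlated, l > n).  In the ordered regime
#' the mean composition matches the whole analyzed span.
#'
#' @param records a [composition_records][cluster_composition] table.
#' @param bins_per_octave log-bin resolution (default 8, the grid of
#'   [length_histogram()]).
#' @return `data.frame` with one row per occupied length bin: `ell`
#'   (bin center), `count`, `regime`, and `mean_*` / `sd_*` columns per
#'   base (percent).
#' @export
composition_vs_length <- function(records, bins_per_octave = 8) {
  stopifnot(inherits(records, "composition_records"))
  n <- attr(records, "window")
  rec <- records[!records$flagged, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no unflagged clusters")
  edges <- log_bin_edges(max(rec$length), bins_per_octave)
  idx <- findInterval(rec$length, edges)
  lo <- edges[-length(edges)]; hi <- edges[-1]
  center <- sqrt(lo * pmax(hi - 1, lo))
  occ <- sort(unique(idx))
  stat <- lapply(occ, function(i) {
    sub <- rec[idx == i, BASES, drop = FALSE]
    spread <- if (nrow(sub) == 1L) setNames(rep(0, 4), BASES)
              else apply(sub, 2, pop_sd)
    c(count = nrow(sub),
      setNames(colMeans(sub), paste0("mean_", BASES)),
      setNames(spread, paste0("sd_", BASES)))
  })
  out <- data.frame(ell = center[occ], do.call(rbind, stat))
  out$regime <- ifelse(out$ell <= n, "ordered", "disordered")
  structure(out, window = n)
}

#' Fluctuation of cluster composition (sigma_C)
#'
#' Mean and standard deviation (population form, so the statistic is
#' invariant under duplicating clusters), across clusters, of each
#' base's percentage.  By default every cluster counts as one
#' observation regardless of its length; `weighted = TRUE` weights
#' clusters by their unambiguous base count (the weighted mean then
#' reproduces the span composition exactly).
#'
#' @param records a [composition_records][cluster_composition] table.
#' @param id identifier for the summarized segment.
#' @param weighted length-weight the mean and SD (default `FALSE`).
#' @param regime `"all"` (default), `"ordered"` (l <= n) or
#'   `"disordered"` (l > n).
#' @return object of class `"composition_summary"`: list with `id`, `n`,
#'   `mean` and `sigma` (named percent vectors) and `clusters`.
#' @export
composition_sigma <- function(records, id = "segment", weighted = FALSE,
                              regime = c("all", "ordered", "disordered")) {
  stopifnot(inherits(records, "composition_records"))
  regime <- match.arg(regime)
  n <- attr(records, "window")
  rec <- records[!records$flagged, , drop = FALSE]
  rec <- switch(regime, all = rec,
                ordered = rec[rec$length <= n, , drop = FALSE],
                disordered = rec[rec$length > n, , drop = FALSE])
  if (nrow(rec) < 2L) stop("need at least 2 clusters, got ", nrow(rec))
  p <- as.matrix(rec[, BASES])
  if (weighted) {
    w <- rec$length - rec$ambiguous
    mu <- colSums(p * w) / sum(w)
    sig <- sqrt(colSums(w * sweep(p, 2, mu)^2) / sum(w))
  } else {
    mu <- colMeans(p)
    sig <- apply(p, 2, pop_sd)
  }
  structure(list(id = id, n = n, mean = mu, sigma = sig,
                 clusters = nrow(rec), regime = regime, weighted = weighted),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf("<composition_summary> %s (n = %d, %d clusters, %s):\n",
              x$id, x$n, x$clusters, x$regime))
  print(round(rbind(`mean %` = x$mean, sigma_C = x$sigma), 2))
  invisible(x)
}

#' Correlate composition fluctuations with genomic features
#'
#' Product-moment correlation of the sigma_C fluctuation statistic with
#' user-supplied per-chromosome features (length, gene density,
#' duplication rates, local composition, ...).  The per-base sigma_C are
#' averaged into one pooled value per chromosome; per-base correlations
#' are also reported.  Missing values are excluded pairwise; constant
#' vectors give `NA` with a note.
#'
#' @param summaries either a list of
#'   [composition_summary][composition_sigma] objects or a `data.frame`
#'   with a `chromosome` column and `sigma_A`, `sigma_C`, `sigma_G`,
#'   `sigma_T` columns.
#' @param features `data.frame` (or TSV path) whose first column names
#'   the chromosome, remaining columns numeric features.
#' @return `data.frame` of class `"correlation_report"`: one row per
#'   (feature, base) pair with the correlation `rho` and the number of
#'   paired observations.
#' @export
correlate_features <- function(summaries, features) {
  if (is.list(summaries) && !is.data.frame(summaries) &&
      all(vapply(summaries, inherits, logical(1), "composition_summary"))) {
    summaries <- data.frame(
      chromosome = vapply(summaries, `[[`, character(1), "id"),
      do.call(rbind, lapply(summaries, function(s)
        setNames(s$sigma, paste0("sigma_", BASES)))))
  }
  stopifnot(is.data.frame(summaries))
  if (is.character(features)) features <- read_features(features)
  names(features)[1] <- "chromosome"
  sig_cols <- paste0("sigma_", BASES)
  stopifnot(all(sig_cols %in% names(summaries)))
  summaries$sigma_pooled <- rowMeans(summaries[, sig_cols])
  merged <- merge(summaries, features, by = "chromosome")
  feat_cols <- setdiff(names(features), "chromosome")
  rows <- lapply(feat_cols, function(f) {
    do.call(rbind, lapply(c("pooled", BASES), function(b) {
      s <- merged[[if (b == "pooled") "sigma_pooled" else paste0("sigma_", b)]]
      x <- merged[[f]]
      ok <- complete.cases(s, x)
      rho <- if (sum(ok) < 3L || sd(s[ok]) == 0 || sd(x[ok]) == 0) NA_real_
             else cor(s[ok], x[ok])
      data.frame(feature = f, base = b, rho = rho, pairs = sum(ok))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyNA(out$rho))
    message("correlate_features: NA rho for constant or under-populated pairs")
  structure(out, class = c("correlation_report", "data.frame"))
}

#' Read a per-chromosome feature table
#'
#' TSV with a header; first column the chromosome name, remaining
#' columns numeric features.
#'
#' @param path file path.
#' @return `data.frame`.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  read.delim(path, check.names = FALSE)
}
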