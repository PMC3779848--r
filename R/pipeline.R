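# End-to-end orchestration: one call running walk -> clusters -> entropy
# -> composition on a sequence or series input, writing plain-text TSVs
# and a reproducibility manifest.

#' Configuration for a full analysis run
#'
#' @param input path to a FASTA(.gz) file, a one-value-per-line numeric
#'   series file, or `NULL` to simulate.
#' @param kind `"fasta"`, `"series"`, `"simulate_dna"` or
#'   `"simulate_fgn"` (inferred from `input` when `NULL`:
#'   simulation requires `length` and `hurst`).
#' @param windows moving-average windows n.
#' @param segment_length bases analyzed per sequence (`NULL` = whole
#'   sequence); sequences are truncated to their first `segment_length`
#'   bases.
#' @param bins_per_octave,min_count,regime_factor,ell_min see
#'   [cluster_entropy()].
#' @param seed integer seed for simulation inputs.
#' @param length,hurst,composition simulation parameters (see
#'   [simulate_dna()], [rfgn()]).
#' @param features optional path to a per-chromosome feature TSV for the
#'   correlation report.
#' @param out_dir output directory.
#' @param convention moving-average convention.
#' @param entropy_form `"surprisal"` or `"summand"`.
#' @param sigma_weighted length-weight sigma_C (default `FALSE`).
#' @param drop_n drop ambiguous bases instead of stepping 0.
#' @return a validated `"run_config"` list.
#' @export
run_config <- function(input = NULL,
                       kind = c("fasta", "series", "simulate_dna", "simulate_fgn"),
                       windows = c(2, 4, 10), segment_length = NULL,
                       bins_per_octave = 8, min_count = 5,
                       regime_factor = 2, ell_min = 5, seed = NULL,
                       length = NULL, hurst = NULL,
                       composition = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                       features = NULL, out_dir = "centropy_out",
                       convention = "backward",
                       entropy_form = "surprisal",
                       sigma_weighted = FALSE, drop_n = FALSE) {
  kind <- match.arg(kind)
  if (!is.null(input) && !file.exists(input))
    stop("input path does not exist: ", input)
  if (is.null(input) && !startsWith(kind, "simulate"))
    stop("'input' is required for kind = ", kind)
  if (startsWith(kind, "simulate") && (is.null(length) || is.null(hurst)))
    stop("simulation requires 'length' and 'hurst'")
  if (!is.null(features) && !file.exists(features))
    stop("feature table does not exist: ", features)
  windows <- sort(unique(as.integer(windows)))
  structure(list(input = input, kind = kind, windows = windows,
                 segment_length = segment_length,
                 bins_per_octave = bins_per_octave, min_count = min_count,
                 regime_factor = regime_factor, ell_min = ell_min,
                 seed = seed, length = length, hurst = hurst,
                 composition = composition, features = features,
                 out_dir = out_dir, convention = convention,
                 entropy_form = entropy_form,
                 sigma_weighted = sigma_weighted, drop_n = drop_n),
            class = "run_config")
}

write_tsv <- function(df, path, header_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 12, format = "g"))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

load_run_inputs <- function(config) {
  switch(config$kind,
    fasta = read_fasta(config$input),
    series = list(scan(config$input, what = numeric(), quiet = TRUE)),
    simulate_dna = list(simulate_dna(config$length, config$hurst,
                                     config$composition, seed = config$seed)),
    simulate_fgn = list(rfbm(config$length, config$hurst, seed = config$seed)))
}

#' Run the full cluster-entropy analysis
#'
#' Loads or simulates the input, builds walks, extracts clusters for
#' every window, estimates length distributions, entropy curves and
#' their decompositions, the Hurst exponent, and (for sequence inputs)
#' the per-cluster composition and its fluctuation sigma_C; writes
#' clusters, distribution, entropy, fits, hurst, composition and summary
#' TSVs plus a manifest recording the configuration.  All cluster
#' coordinates in emitted files are 1-based inclusive.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with the [cluster_entropy()] fits (one per
#'   record), composition summaries, the correlation report (if features
#'   were supplied) and the output paths.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  inputs <- load_run_inputs(config)
  is_seq <- inherits(inputs[[1]], "seq_record")
  if (is_seq && !is.null(config$segment_length))
    inputs <- lapply(inputs, function(r)
      seq_record(substr(r$bases, 1, config$segment_length), id = r$id))
  paths <- character(0)

  fits <- list(); summaries <- list(); comp_rows <- list()
  for (rec in inputs) {
    id <- if (is_seq) rec$id else "series"
    x <- if (is_seq) dna_walk(rec, drop_n = config$drop_n) else rec
    fit <- cluster_entropy(x, windows = config$windows,
                           bins_per_octave = config$bins_per_octave,
                           min_count = config$min_count,
                           regime_factor = config$regime_factor,
                           ell_min = config$ell_min,
                           convention = config$convention)
    fits[[id]] <- fit
    for (n in as.character(config$windows)) {
      cs <- fit$clusters[[n]][[1]]
      p <- out(sprintf("clusters_%s_n%s.tsv", id, n))
      paths <- c(paths, write_tsv(
        data.frame(name = id, start = cs$start, end = cs$end - 1L,
                   length = cs$length, sign = cs$sign,
                   area = cs$area, n = as.integer(n)),
        p, sprintf("clusters of %s, window n = %s, 1-based inclusive", id, n)))
      if (is_seq && nrow(cs) >= 2) {
        records <- cluster_composition(rec, cs)
        key <- paste(id, n, sep = "_n")
        summaries[[key]] <- composition_sigma(records, id = id,
                                              weighted = config$sigma_weighted)
        comp_rows[[key]] <- data.frame(name = id, n = as.integer(n),
                                       records)
      }
    }
  }

  dist_tab <- do.call(rbind, lapply(fits, function(fit)
    do.call(rbind, lapply(fit$distributions, function(d)
      data.frame(n = d$n, bin_lo = d$lo, bin_hi = d$hi - 1L,
                 count = d$counts, density = d$density)))))
  paths <- c(paths, write_tsv(dist_tab, out("distribution.tsv"),
                              "cluster length distributions P(l, n)"))
  ent_tab <- do.call(rbind, lapply(fits, function(fit)
    do.call(rbind, lapply(fit$curves, function(cv)
      data.frame(n = cv$n, ell = cv$ell, S = cv$S)))))
  paths <- c(paths, write_tsv(ent_tab, out("entropy.tsv"),
                              "cluster entropy S(l, n) in nats"))
  fit_tab <- do.call(rbind, lapply(names(fits), function(id)
    do.call(rbind, lapply(fits[[id]]$curves, function(cv)
      data.frame(name = id, n = cv$n, S0 = cv$model$S0, D = cv$model$D,
                 slope = cv$model$linear_slope,
                 flags = paste(cv$model$flags, collapse = "; "))))))
  paths <- c(paths, write_tsv(fit_tab, out("fits.tsv"),
                              "entropy decomposition S = S0 + D log l + slope l"))
  hurst_tab <- do.call(rbind, lapply(names(fits), function(id)
    data.frame(name = id, H = fits[[id]]$hurst$H,
               D = 2 - fits[[id]]$hurst$H)))
  paths <- c(paths, write_tsv(hurst_tab, out("hurst.tsv"),
                              "DMA Hurst exponents"))

  report <- NULL
  if (length(comp_rows)) {
    paths <- c(paths, write_tsv(do.call(rbind, comp_rows),
                                out("composition.tsv"),
                                "per-cluster base composition (percent), 1-based inclusive"))
    sum_tab <- do.call(rbind, lapply(summaries, function(s)
      data.frame(name = s$id, n = s$n, clusters = s$clusters,
                 t(setNames(s$mean, paste0("mean_", names(s$mean)))),
                 t(setNames(s$sigma, paste0("sigma_", names(s$sigma)))))))
    paths <- c(paths, write_tsv(sum_tab, out("summary.tsv"),
                                "composition fluctuation sigma_C per segment and window"))
    if (!is.null(config$features)) {
      report <- correlate_features(
        data.frame(chromosome = sum_tab$name,
                   sum_tab[, paste0("sigma_", c("A", "C", "G", "T"))]),
        config$features)
      paths <- c(paths, write_tsv(report, out("correlations.tsv"),
                                  "correlation of sigma_C with supplied features"))
    }
  }

  cfg_lines <- vapply(names(unclass(config)), function(k)
    paste0(k, " = ", paste(deparse(config[[k]]), collapse = "")), character(1))
  cfg_file <- tempfile(); writeLines(cfg_lines, cfg_file)
  manifest <- c(sprintf("package centropy %s", packageVersion("centropy")),
                sprintf("R %s", getRversion()),
                sprintf("config md5 %s", unname(tools::md5sum(cfg_file))),
                cfg_lines)
  unlink(cfg_file)
  writeLines(manifest, out("manifest.txt"))
  paths <- c(paths, out("manifest.txt"))
  invisible(list(fits = fits, summaries = summaries, correlations = report,
                 paths = paths))
}
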