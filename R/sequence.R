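# Nucleotide sequence records, FASTA input, the purine/pyrimidine +-1
# coding rule and the cumulative DNA walk.

#' Nucleotide sequence record
#'
#' A named sequence over the alphabet \{A, C, G, T, N\}.  Bases are
#' uppercased and every IUPAC ambiguity code other than A/C/G/T is
#' collapsed to N; the counts of collapsed codes are kept in the
#' `ambiguity` field.
#'
#' @param bases a single character string of bases.
#' @param id sequence identifier.
#' @param offset 0-based position of the first base in the source
#'   sequence (non-zero for segments cut from a larger sequence).
#' @return an object of class `"seq_record"` with fields `id`, `bases`,
#'   `length`, `offset` and `ambiguity` (named counts of normalized
#'   non-ACGT codes, possibly empty).
#' @export
seq_record <- function(bases, id = "seq", offset = 0L) {
  stopifnot(is.character(bases), length(bases) == 1L)
  bases <- toupper(bases)
  odd <- gsub("[ACGTN]", "", bases)
  tally <- integer(0)
  if (nzchar(odd)) {
    tally <- table(strsplit(odd, "")[[1]])
    tally <- setNames(as.integer(tally), names(tally))
    bases <- gsub("[^ACGT]", "N", bases)
  }
  structure(list(id = as.character(id), bases = bases,
                 length = nchar(bases), offset = as.integer(offset),
                 ambiguity = tally),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s: %d bases", x$id, x$length))
  if (x$offset > 0) cat(sprintf(" (offset %d)", x$offset))
  cat("\n")
  show <- substr(x$bases, 1, 60)
  cat("  ", show, if (x$length > 60) "..." else "", "\n", sep = "")
  if (length(x$ambiguity))
    cat("  collapsed to N:",
        paste(names(x$ambiguity), x$ambiguity, sep = "=", collapse = " "),
        "\n")
  invisible(x)
}

#' Base counts of a sequence record
#'
#' @param record a [seq_record].
#' @return named integer vector of A, C, G, T, N counts.
#' @export
base_counts <- function(record) {
  stopifnot(inherits(record, "seq_record"))
  r <- utf8ToInt(record$bases)
  vapply(c(A = "A", C = "C", G = "G", T = "T", N = "N"),
         function(b) sum(r == utf8ToInt(b)), integer(1))
}

#' Read FASTA sequences
#'
#' Reads a (optionally gzip-compressed) FASTA file into a list of
#' [seq_record]s.  Bases are uppercased; IUPAC ambiguity codes other than
#' A/C/G/T are collapsed to N and tallied per record.  Record order is
#' preserved.
#'
#' @param path path to a FASTA or FASTA.gz file.
#' @return list of [seq_record] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e)
                    stop("cannot parse FASTA file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("no sequences found in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  out <- lapply(seq_along(set), function(i)
    seq_record(as.character(set[[i]]), id = ids[i]))
  tot <- sum(vapply(out, function(r) sum(r$ambiguity), numeric(1)))
  if (tot > 0)
    message(sprintf("read_fasta: collapsed %d ambiguous bases to N", tot))
  out
}

#' Map bases to +1/-1 steps
#'
#' The purine/pyrimidine coding rule of the DNA walk: purines (A, G) map
#' to +1, pyrimidines (C, T) to -1.  Ambiguous bases (N) map to 0 with the
#' ambiguity mask set, so the walk stays flat there and genome coordinates
#' are preserved.
#'
#' @param record a [seq_record].
#' @param drop_n if `TRUE`, ambiguous bases are removed instead of mapped
#'   to 0 (coordinates are then no longer those of the source sequence).
#' @return list with integer vector `steps` (+1, -1 or 0) and logical
#'   `mask` (`TRUE` where the base was ambiguous).
#' @export
map_bases <- function(record, drop_n = FALSE) {
  stopifnot(inherits(record, "seq_record"))
  r <- utf8ToInt(record$bases)
  lut <- integer(256)
  lut[utf8ToInt("A") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 1L
  lut[utf8ToInt("C") + 1L] <- -1L
  lut[utf8ToInt("T") + 1L] <- -1L
  steps <- lut[r + 1L]
  mask <- r == utf8ToInt("N")
  if (drop_n) {
    steps <- steps[!mask]
    mask <- mask[!mask]
  }
  list(steps = steps, mask = mask)
}

#' Build the DNA walk from a step series
#'
#' Cumulative sum of the +1/-1 step series: `y[x] = sum(steps[1:x])`.
#'
#' @param steps integer step series (from [map_bases()] or any +-1 coding).
#' @param mask optional logical ambiguity mask aligned with `steps`.
#' @param offset 0-based source coordinate of the first step.
#' @param id identifier carried over to the walk.
#' @return object of class `"dna_walk"` with fields `y`, `steps`, `mask`,
#'   `offset`, `id`.
#' @export
build_walk <- function(steps, mask = NULL, offset = 0L, id = "walk") {
  if (length(steps) == 0L) stop("'steps' is empty")
  if (is.null(mask)) mask <- rep(FALSE, length(steps))
  stopifnot(length(mask) == length(steps))
  structure(list(y = cumsum(as.numeric(steps)), steps = as.integer(steps),
                 mask = mask, offset = as.integer(offset),
                 id = as.character(id)),
            class = "dna_walk")
}

#' DNA walk of a sequence record
#'
#' Convenience composition of [map_bases()] and [build_walk()].
#'
#' @inheritParams map_bases
#' @return a `"dna_walk"` object.
#' @examples
#' w <- dna_walk(seq_record("ACGTACGT"))
#' w$y
#' @export
dna_walk <- function(record, drop_n = FALSE) {
  m <- map_bases(record, drop_n = drop_n)
  build_walk(m$steps, m$mask, offset = record$offset, id = record$id)
}

#' @export
print.dna_walk <- function(x, ...) {
  cat(sprintf("<dna_walk> %s: %d steps, final displacement %d, %d ambiguous\n",
              x$id, length(x$y), as.integer(x$y[length(x$y)]), sum(x$mask)))
  invisible(x)
}

#' Split a sequence into disjoint consecutive segments
#'
#' Cuts `k` non-overlapping segments of `segment_length` bases from the
#' start of the sequence (the disjoint-subset design used for
#' cross-validating composition statistics).  If the sequence is too
#' short, as many full segments as fit are returned with a warning.
#'
#' @param record a [seq_record].
#' @param segment_length bases per segment.
#' @param k number of segments.
#' @return list of [seq_record]s with `offset` fields 0, `segment_length`,
#'   `2*segment_length`, ...
#' @export
split_disjoint_segments <- function(record, segment_length, k) {
  stopifnot(inherits(record, "seq_record"),
            segment_length >= 1, k >= 1)
  segment_length <- as.integer(segment_length)
  fit <- record$length %/% segment_length
  if (fit < k) {
    warning(sprintf("sequence %s holds only %d full segments of %d bases (%d requested)",
                    record$id, fit, segment_length, k))
    k <- fit
  }
  lapply(seq_len(k), function(i) {
    off <- (i - 1L) * segment_length
    seq_record(substr(record$bases, off + 1L, off + segment_length),
               id = sprintf("%s_M%d", record$id, i), offset = off)
  })
}
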