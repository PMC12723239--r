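#' Genome proxy sampling configuration
#'
#' A composite genome proxy is built from `n` randomly placed,
#' non-overlapping sub-fragments of equal length whose total is
#' `total_length` bp. Defaults are the established operating point for
#' k-mer signature work at this scale: 10 sub-fragments totalling 100 kbp.
#'
#' @param n Number of sub-fragments (default 10).
#' @param total_length Total proxy length in bp (default 1e5); must be
#'   divisible by `n`.
#' @return An object of class `proxy_config`.
#' @export
proxy_config <- function(n = 10L, total_length = 100000L) {
  n <- as.integer(n); total_length <- as.integer(total_length)
  stopifnot(n >= 1L, total_length >= 1L)
  if (total_length %% n != 0L) {
    stop("total_length (", total_length, ") must be divisible by n (", n, ")")
  }
  structure(list(n = n, total_length = total_length,
                 fragment_length = total_length %/% n),
            class = "proxy_config")
}

# Uniformly sample n non-overlapping fragment start positions (0-based) for
# windows of length f in a source of length L. Bijection with combinations:
# choosing n distinct values y_(1)<...<y_(n) from {0..L-nf+n-1} and setting
# start_i = y_(i) + (i-1)(f-1) enumerates every valid placement exactly once,
# so placements (zero gaps allowed) are equiprobable and marginal coverage of
# every raw position is flat.
.sample_starts <- function(L, n, f) {
  m <- L - n * f + n          # number of selectable values
  if (m < n) stop("source too short for ", n, " fragments of ", f, " bp")
  y <- sort.int(sample.int(m, n) - 1L)
  y + (seq_len(n) - 1L) * (f - 1L)
}

#' Select a composite genome proxy
#'
#' Builds the genome proxy of a record: (1) contigs are pseudo-concatenated
#' into one source string; (2) `n` non-overlapping windows of
#' `total_length/n` raw characters are sampled uniformly over all valid
#' non-overlapping placements (every raw position has equal inclusion
#' probability); (3) windows are pseudo-concatenated in ascending genomic
#' order. Windows may straddle contig separators; the `N`s they contain are
#' simply never counted in k-mers. If the source is shorter than
#' `total_length` the whole source is used and `truncated` is set.
#'
#' Sampling uses R's RNG: seed with [set.seed()] (or pass `seed`) for
#' reproducibility.
#'
#' @param record A [genome_record()].
#' @param config A [proxy_config()].
#' @param seed Optional integer seed applied via [set.seed()] before
#'   sampling.
#' @return An object of class `genome_proxy` with fields `genome_id`,
#'   `fragment_starts` (0-based, into the concatenated source),
#'   `fragment_length`, `sequence` (a `pseudo_concatenated`), `truncated`.
#' @export
select_proxy <- function(record, config = proxy_config(), seed = NULL) {
  stopifnot(inherits(record, "genome_record"), inherits(config, "proxy_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  source <- pseudo_concatenate(record$contigs)$sequence
  L <- nchar(source)
  if (L < config$total_length) {
    warning("genome '", record$id, "' (", L, " bp raw) shorter than proxy ",
            "length ", config$total_length, " bp; using whole genome")
    out <- select_whole_genome(record)
    out$truncated <- TRUE
    return(out)
  }
  f <- config$fragment_length
  starts <- .sample_starts(L, config$n, f)
  frags <- substring(source, starts + 1L, starts + f)
  structure(list(genome_id = record$id, fragment_starts = starts,
                 fragment_length = f, sequence = pseudo_concatenate(frags),
                 truncated = FALSE),
            class = "genome_proxy")
}

#' Use the whole genome as its own proxy
#'
#' The pseudo-concatenation of all contigs, i.e. the degenerate proxy with a
#' single fragment spanning the source.
#'
#' @param record A [genome_record()].
#' @return A `genome_proxy`.
#' @export
select_whole_genome <- function(record) {
  stopifnot(inherits(record, "genome_record"))
  pc <- pseudo_concatenate(record$contigs)
  structure(list(genome_id = record$id, fragment_starts = 0L,
                 fragment_length = pc$raw_length, sequence = pc,
                 truncated = FALSE),
            class = "genome_proxy")
}

#' @export
print.genome_proxy <- function(x, ...) {
  cat("<genome_proxy> ", x$genome_id, ": ", length(x$fragment_starts),
      " fragment(s) x ", x$fragment_length, " bp, effective length ",
      x$sequence$effective_length, " bp",
      if (x$truncated) " (truncated)" else "", "\n", sep = "")
  invisible(x)
}

#' Write a genome proxy as single-record FASTA
#'
#' The header encodes the genome id and the 0-based half-open fragment
#' coordinates relative to the concatenated source, so a proxy is fully
#' reproducible from its FASTA alone.
#'
#' @param proxy A `genome_proxy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proxy_fasta <- function(proxy, path) {
  stopifnot(inherits(proxy, "genome_proxy"))
  coords <- paste(sprintf("%d-%d", proxy$fragment_starts,
                          proxy$fragment_starts + proxy$fragment_length),
                  collapse = ",")
  header <- paste0(proxy$genome_id, " fragments=", coords)
  write_fasta(stats::setNames(proxy$sequence$sequence, header), path)
}
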