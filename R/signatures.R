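#' All k-mers in lexicographic order
#'
#' @param k k-mer size (1..9).
#' @return Character vector of length `4^k`, lexicographic over A<C<G<T.
#' @export
kmer_names <- function(k) {
  stopifnot(k >= 1L, k <= 9L)
  Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
}

# digit j (1 = leftmost letter, most significant lexicographically) of
# 0-based k-mer indices; A=0, C=1, G=2, T=3
.kmer_digit <- function(idx, j, k) (idx %/% 4L^(k - j)) %% 4L

# permutation p such that counts[p] gives, for each k-mer w (lexicographic),
# the count of reverse_complement(w)
.rc_permutation <- function(k) {
  idx <- 0:(4L^k - 1L)
  rc <- integer(length(idx))
  for (j in seq_len(k)) {
    d <- .kmer_digit(idx, j, k)
    rc <- rc + (3L - d) * 4L^(j - 1L)  # complement, and reverse position
  }
  rc + 1L
}

#' Count k-mer occurrences in a DNA sequence
#'
#' Sliding window of stride 1; windows containing any non-ACGT symbol
#' (including the pseudo-concatenation separator `N`) are not counted.
#'
#' @param seq A DNA string over `{A,C,G,T,N}`.
#' @param k k-mer size, 1..9.
#' @return Named integer vector of length `4^k` in lexicographic order, with
#'   attribute `total_counted` = number of counted windows.
#' @export
count_kmers <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1L, k >= 1L, k <= 9L)
  if (k > nchar(seq)) {
    warning("k (", k, ") exceeds sequence length (", nchar(seq),
            "); returning all-zero counts")
    counts <- stats::setNames(integer(4L^k), kmer_names(k))
  } else {
    counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                                   width = k)
  }
  attr(counts, "total_counted") <- sum(counts)
  counts
}

#' Canonical k-mer frequency vector
#'
#' The genomic signature feature vector: per k-mer, the average of its count
#' in the sequence and in the sequence's Watson-Crick reverse complement.
#' By construction `value(w) == value(reverse_complement(w))` for every w;
#' the vector keeps the full `4^k` length with mirrored values (4096 entries
#' at k = 6).
#'
#' @param seq A DNA string.
#' @param k k-mer size.
#' @param normalize Divide by the total so values sum to 1 (default `TRUE`;
#'   frequencies are the classifier features since proxies can differ in
#'   effective length).
#' @return Named numeric vector of length `4^k` with attributes
#'   `total_counted`, `k`, `normalized`.
#' @export
canonical_kmer_vector <- function(seq, k, normalize = TRUE) {
  counts <- count_kmers(seq, k)
  total <- attr(counts, "total_counted")
  vals <- (as.numeric(counts) + as.numeric(counts)[.rc_permutation(k)]) / 2
  if (normalize) {
    s <- sum(vals)
    if (s > 0) vals <- vals / s
  }
  names(vals) <- names(counts)
  attr(vals, "total_counted") <- total
  attr(vals, "k") <- as.integer(k)
  attr(vals, "normalized") <- normalize
  vals
}

# 1-based (row, col) grid address of every k-mer, lexicographic order.
# Corner convention (x, y): A=(0,1), C=(0,0), G=(1,0), T=(1,1).
# Reading a k-mer left to right, each letter halves the square toward its
# corner, so the letter read LAST contributes the most significant address
# bit. Row 1 is the top of the grid (y = 2^k - 1).
.fcgr_address <- function(k) {
  idx <- 0:(4L^k - 1L)
  x <- integer(length(idx)); y <- integer(length(idx))
  for (j in seq_len(k)) {
    d <- .kmer_digit(idx, j, k)
    x <- x + ifelse(d >= 2L, 1L, 0L) * 2L^(j - 1L)        # G,T right half
    y <- y + ifelse(d == 0L | d == 3L, 1L, 0L) * 2L^(j - 1L)  # A,T top half
  }
  side <- 2L^k
  cbind(row = side - y, col = x + 1L)
}

#' Frequency Chaos Game Representation matrix
#'
#' The FCGR is a 2-D re-indexing of the k-mer count vector: a
#' `2^k x 2^k` grid whose cell for k-mer w holds `count_kmers(seq, k)[w]`,
#' with the cell address obtained by k successive binary subdivisions of the
#' unit square under the corner convention A = top-left, C = bottom-left,
#' G = bottom-right, T = top-right.
#'
#' @param seq A DNA string (ignored when `counts` is given).
#' @param k k-mer size.
#' @param counts Optional precomputed lexicographic count/frequency vector
#'   of length `4^k`.
#' @return A `2^k x 2^k` matrix of class `fcgr` with attributes `k` and
#'   `corner_convention`.
#' @export
fcgr <- function(seq = NULL, k, counts = NULL) {
  if (is.null(counts)) counts <- count_kmers(seq, k)
  stopifnot(length(counts) == 4L^k)
  addr <- .fcgr_address(k)
  side <- 2L^k
  grid <- matrix(0, side, side)
  grid[cbind(addr[, "row"], addr[, "col"])] <- as.numeric(counts)
  structure(grid, class = c("fcgr", "matrix", "array"), k = as.integer(k),
            corner_convention = c(A = "top-left", C = "bottom-left",
                                  G = "bottom-right", T = "top-right"))
}

#' Flatten an FCGR grid back to lexicographic k-mer order
#'
#' Inverse of the [fcgr()] re-indexing; useful for checking conservation.
#'
#' @param grid An `fcgr` matrix.
#' @return Named numeric vector of length `4^k` in lexicographic order.
#' @export
fcgr_to_vector <- function(grid) {
  k <- attr(grid, "k")
  stopifnot(!is.null(k))
  addr <- .fcgr_address(k)
  stats::setNames(grid[cbind(addr[, "row"], addr[, "col"])], kmer_names(k))
}

#' Chaos Game Representation point trajectory
#'
#' Iteratively plots the midpoint between the current point and the corner
#' labelled by the nucleotide being read, starting from the square's center;
#' one point per nucleotide read.
#'
#' @param seq A DNA string over ACGT.
#' @return A `nchar(seq) x 2` matrix of (x, y) coordinates in the unit
#'   square.
#' @export
cgr_points <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  if (grepl("[^ACGT]", seq)) stop("cgr_points: sequence must be over {A,C,G,T}")
  corners <- matrix(c(0, 1, 0, 0, 1, 0, 1, 1), ncol = 2, byrow = TRUE,
                    dimnames = list(c("A", "C", "G", "T"), c("x", "y")))
  letters <- strsplit(seq, "")[[1L]]
  pts <- matrix(NA_real_, nchar(seq), 2, dimnames = list(NULL, c("x", "y")))
  cur <- c(0.5, 0.5)
  for (i in seq_along(letters)) {
    cur <- (cur + corners[letters[i], ]) / 2
    pts[i, ] <- cur
  }
  pts
}

#' Render an FCGR grid as a grayscale image
#'
#' Pixel intensity is `255 * (1 - value/max(value))`, rounded, so darker
#' pixels mean more frequent k-mers; an all-zero grid renders all white.
#' Output format follows the file extension: `.png` (via the png package)
#' or `.pgm` (plain-text P2).
#'
#' @param image An `fcgr` matrix (or any non-negative matrix).
#' @param path Output path ending in `.png` or `.pgm`.
#' @return `path`, invisibly.
#' @export
render_fcgr <- function(image, path) {
  stopifnot(is.matrix(image), length(image) > 0L)
  mx <- max(image)
  intensity <- if (mx > 0) round(255 * (1 - image / mx)) else
    matrix(255, nrow(image), ncol(image))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(intensity / 255, target = path)
  } else if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(intensity), nrow(intensity)), "255"), con)
    utils::write.table(intensity, con, row.names = FALSE, col.names = FALSE)
  } else {
    stop("unsupported image extension (use .png or .pgm): ", path)
  }
  invisible(path)
}

#' Signature matrix of a set of genome proxies
#'
#' @param proxies List of `genome_proxy` objects (or named character vector
#'   of sequences).
#' @param k k-mer size (default 6, the standard operating point).
#' @param normalize Passed to [canonical_kmer_vector()].
#' @return Numeric matrix, rows = genomes (named), columns = lexicographic
#'   k-mers.
#' @export
signature_matrix <- function(proxies, k = 6L, normalize = TRUE) {
  seqs <- if (is.character(proxies)) {
    proxies
  } else {
    stats::setNames(vapply(proxies, function(p) p$sequence$sequence,
                           character(1)),
                    vapply(proxies, function(p) p$genome_id, character(1)))
  }
  t(vapply(seqs, function(s) canonical_kmer_vector(s, k, normalize),
           numeric(4L^k)))
}

#' Write / read a signature matrix as TSV
#'
#' Rows are genomes, columns lexicographic k-mers; a JSON sidecar
#' (`<path>.json`) records k and normalization.
#'
#' @param mat Signature matrix from [signature_matrix()].
#' @param path Output TSV path.
#' @param k,normalized Metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_signature_tsv <- function(mat, path, k = as.integer(round(log(ncol(mat), 4))),
                                normalized = TRUE) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(k = k, normalized = normalized,
                            n_genomes = nrow(mat)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_signature_tsv
#' @export
read_signature_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  mat
}
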