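#' Read a FASTA file of genome contigs
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file, uppercases the
#' sequences, and validates the alphabet. IUPAC ambiguity codes other than
#' `N` are accepted on input but converted to `N`, so that all downstream
#' code sees a two-symbol non-ACGT policy: `N` means "position of unknown
#' or ambiguous base, never counted in a k-mer".
#'
#' @param path Path to a FASTA file.
#' @param collapse_iupac Convert non-N IUPAC ambiguity codes to `N`
#'   (default `TRUE`).
#' @return A named character vector: names are the FASTA headers (text after
#'   `>`, whitespace-trimmed), values are uppercase DNA strings.
#' @export
read_fasta <- function(path, collapse_iupac = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0L || hdr_idx[1L] != 1L) {
    bad <- if (length(hdr_idx) == 0L) 1L else 1L
    stop("malformed FASTA (no '>' header at line ", bad, "): ", path)
  }
  headers <- trimws(sub("^>", "", lines[hdr_idx]))
  starts <- hdr_idx + 1L
  ends <- c(hdr_idx[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr_idx), function(i) {
    if (starts[i] > ends[i]) return("")
    paste0(lines[starts[i]:ends[i]], collapse = "")
  }, character(1))
  seqs <- toupper(gsub("[ \t]", "", seqs))
  empty <- which(nchar(seqs) == 0L)
  if (length(empty) > 0L) {
    stop("FASTA record '", headers[empty[1L]], "' has an empty sequence")
  }
  bad <- regexpr("[^ACGTNRYSWKMBDHV]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    ch <- substr(seqs[i], bad[i], bad[i])
    stop("invalid character '", ch, "' in FASTA record '", headers[i], "'")
  }
  if (collapse_iupac) seqs <- gsub("[RYSWKMBDHV]", "N", seqs)
  names(seqs) <- headers
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of DNA strings.
#' @param path Output path.
#' @param width Line-wrap width; `Inf` writes each sequence on one line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (is.finite(width) && nchar(s) > width) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    } else {
      writeLines(s, con)
    }
  }
  invisible(path)
}

.temp_levels <- c("psychrophile", "mesophile", "thermophile", "hyperthermophile")
.ph_levels <- c("acidophile", "alkaliphile")
.domain_levels <- c("bacteria", "archaea")

#' Construct a genome record
#'
#' A `genome_record` bundles a genome's contigs with its taxonomy
#' (domain/genus/species) and optional environment labels. Temperature
#' categories follow optimal growth temperature: psychrophile (<20 C),
#' mesophile (20-45 C), thermophile (45-80 C), hyperthermophile (>80 C);
#' pH categories: acidophile (optimal growth pH < 5), alkaliphile (> 9).
#'
#' @param id Assembly accession / identifier.
#' @param contigs Character vector of uppercase DNA contig strings.
#' @param domain `"bacteria"` or `"archaea"`.
#' @param genus,species Taxonomy strings.
#' @param temp_label Optional temperature category (see above) or `NA`.
#' @param ph_label Optional pH category or `NA`.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(id, contigs, domain = NA_character_,
                          genus = NA_character_, species = NA_character_,
                          temp_label = NA_character_, ph_label = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  contigs <- toupper(as.character(contigs))
  if (length(contigs) < 1L) stop("genome record needs at least one contig")
  if (any(!nzchar(contigs))) stop("empty contig in genome record '", id, "'")
  bad <- regexpr("[^ACGTN]", contigs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("invalid character '", substr(contigs[i], bad[i], bad[i]),
         "' in contig ", i, " of '", id, "'")
  }
  if (!is.na(domain)) domain <- match.arg(tolower(domain), .domain_levels)
  if (!is.na(temp_label)) temp_label <- match.arg(tolower(temp_label), .temp_levels)
  if (!is.na(ph_label)) ph_label <- match.arg(tolower(ph_label), .ph_levels)
  structure(list(id = id, contigs = contigs, domain = domain, genus = genus,
                 species = species, temp_label = temp_label,
                 ph_label = ph_label),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$id, ": ", length(x$contigs), " contig(s), ",
      sum(nchar(x$contigs)), " bp; ", x$domain, " / ", x$genus, " / ",
      x$species, "\n", sep = "")
  if (!is.na(x$temp_label) || !is.na(x$ph_label)) {
    cat("  environment:", x$temp_label, "/", x$ph_label, "\n")
  }
  invisible(x)
}

#' Read a genome metadata table
#'
#' Reads a TSV or CSV (delimiter sniffed from the header line) with
#' case-insensitive columns `id`, `domain`, `genus`, `species`,
#' `temp_label`, `ph_label`. Empty environment cells become `NA`; unknown
#' category strings are an error listing the allowed values.
#'
#' @param path Path to the metadata file.
#' @return A data.frame with validated, lower-cased label columns.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = FALSE)
  names(df) <- tolower(names(df))
  required <- c("id", "domain", "genus", "species", "temp_label", "ph_label")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  }
  norm <- function(x) {
    x <- trimws(tolower(as.character(x)))
    x[!nzchar(x) | is.na(x)] <- NA_character_
    x
  }
  df$domain <- norm(df$domain)
  df$temp_label <- norm(df$temp_label)
  df$ph_label <- norm(df$ph_label)
  check_levels <- function(x, levels, what) {
    bad <- setdiff(unique(x[!is.na(x)]), levels)
    if (length(bad) > 0L) {
      stop("unknown ", what, " value(s) ", paste0("'", bad, "'", collapse = ", "),
           "; allowed: ", paste(levels, collapse = ", "))
    }
  }
  check_levels(df$domain, .domain_levels, "domain")
  check_levels(df$temp_label, .temp_levels, "temp_label")
  check_levels(df$ph_label, .ph_levels, "ph_label")
  if (anyDuplicated(df$id)) stop("duplicate genome id(s) in metadata")
  df
}

#' Pseudo-concatenate DNA sequences
#'
#' Joins sequences with a single `N` separator between every two consecutive
#' sequences, so that no spurious junction k-mers can form (k-mers containing
#' `N` are never counted). Separator `N`s do not count towards the effective
#' length.
#'
#' @param seqs Character vector of non-empty DNA strings.
#' @return A list of class `pseudo_concatenated` with elements `sequence`,
#'   `raw_length` (all characters) and `effective_length` (non-`N`
#'   characters).
#' @examples
#' pseudo_concatenate(c("AC", "GT"))$sequence # "ACNGT"
#' @export
pseudo_concatenate <- function(seqs) {
  seqs <- as.character(seqs)
  if (length(seqs) == 0L) stop("cannot pseudo-concatenate an empty list")
  if (any(!nzchar(seqs))) stop("cannot pseudo-concatenate empty sequences")
  sequence <- paste0(seqs, collapse = "N")
  raw_length <- nchar(sequence)
  n_sep <- lengths(regmatches(sequence, gregexpr("N", sequence, fixed = TRUE)))
  structure(list(sequence = sequence, raw_length = raw_length,
                 effective_length = raw_length - n_sep),
            class = "pseudo_concatenated")
}

#' Watson-Crick reverse complement
#'
#' `N` is its own complement; any character outside `{A,C,G,T,N}` is an
#' error.
#'
#' @param seq A DNA string.
#' @return The reverse complement string.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (grepl("[^ACGTN]", seq)) {
    stop("reverse_complement: sequence contains characters outside {A,C,G,T,N}")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
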