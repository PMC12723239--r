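# Geographic habitat co-occurrence: tabular cross-referencing of species
# occurrence records (e.g. 16S rRNA read surveys exported per species) by
# shared project id.

#' Read a species occurrence table
#'
#' TSV/CSV (delimiter sniffed) with case-insensitive columns `species`,
#' `project_id`, `sample_id` and optional `latitude`, `longitude`,
#' `env_descriptor`. Species names are matched exactly after case and
#' whitespace normalization; fuzzy matching is deliberately not attempted
#' (silent false joins are worse than missed ones). Records are
#' deduplicated by (species, project, sample).
#'
#' @param path Path to the occurrence table.
#' @return A data.frame of occurrence records.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  names(df) <- tolower(names(df))
  required <- c("species", "project_id", "sample_id")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("occurrence table missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df$species <- .norm_species(df$species)
  df$project_id <- trimws(as.character(df$project_id))
  if (any(!nzchar(df$species)) || any(!nzchar(df$project_id))) {
    stop("species and project_id must be non-empty")
  }
  for (col in c("latitude", "longitude")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  if (!"env_descriptor" %in% names(df)) df$env_descriptor <- NA_character_
  bad <- which(abs(df$latitude) > 90 | abs(df$longitude) > 180)
  if (length(bad) > 0L) {
    stop("out-of-range coordinates at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  df[!duplicated(df[c("species", "project_id", "sample_id")]), , drop = FALSE]
}

.norm_species <- function(x) gsub("[ \t]+", " ", trimws(tolower(x)))

#' Projects shared by all species in a set
#'
#' A project qualifies when every species in `species_set` has at least one
#' occurrence record with that project id — i.e. the species were sampled
#' from the same geographic location or microbiome.
#'
#' @param records Occurrence data.frame from [read_occurrences()].
#' @param species_set Character vector of species names.
#' @return A data.frame ordered by `project_id` with per-species sample
#'   counts and the project's environment descriptors; zero rows when the
#'   intersection is empty. Species entirely absent from `records` are
#'   reported in the `absent_species` attribute (not an error).
#' @export
shared_projects <- function(records, species_set) {
  stopifnot(is.data.frame(records), length(species_set) >= 1L)
  species_set <- unique(.norm_species(species_set))
  absent <- setdiff(species_set, unique(records$species))
  proj_species <- split(records$species, records$project_id)
  shared <- names(proj_species)[vapply(proj_species, function(sp) {
    all(species_set %in% sp)
  }, logical(1))]
  shared <- sort(shared)
  rows <- lapply(shared, function(p) {
    sub <- records[records$project_id == p & records$species %in% species_set, ]
    counts <- table(factor(sub$species, species_set))
    desc <- unique(stats::na.omit(sub$env_descriptor))
    cbind(data.frame(project_id = p),
          as.data.frame.matrix(t(as.matrix(counts))),
          data.frame(env_descriptors = paste(desc, collapse = "; ")))
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else {
    empty <- data.frame(project_id = character(0))
    for (s in species_set) empty[[s]] <- integer(0)
    empty$env_descriptors <- character(0)
    empty
  }
  attr(out, "absent_species") <- absent
  out
}

#' Per-group co-occurrence report
#'
#' For each bacterium-keyed pair group, lists the projects where the
#' bacterium co-occurs with each of its paired archaea (pairwise
#' cross-reference per bacterium-archaeon pair), plus map-ready
#' coordinates of the supporting records.
#'
#' @param groups List of pair groups from [group_by_bacterium()]; group
#'   members must be species names as used in the occurrence table.
#' @param records Occurrence data.frame from [read_occurrences()].
#' @return List of per-group lists with `group_id`, `bacterium`,
#'   `cooccurrence` (data.frame: archaeon, project_id, counts, descriptors
#'   — zero rows means no co-occurrence found) and `coordinates`
#'   (data.frame: species, project_id, latitude, longitude).
#' @export
cooccurrence_report <- function(groups, records) {
  lapply(groups, function(grp) {
    rows <- lapply(grp$archaea, function(a) {
      sp <- shared_projects(records, c(grp$bacterium, a))
      if (nrow(sp) == 0L) return(NULL)
      data.frame(archaeon = a, project_id = sp$project_id,
                 env_descriptors = sp$env_descriptors)
    })
    cooc <- do.call(rbind, rows)
    if (is.null(cooc)) {
      cooc <- data.frame(archaeon = character(0), project_id = character(0),
                         env_descriptors = character(0))
    }
    members <- .norm_species(c(grp$bacterium, grp$archaea))
    sub <- records[records$species %in% members &
                     records$project_id %in% cooc$project_id &
                     !is.na(records$latitude), , drop = FALSE]
    list(group_id = grp$group_id, bacterium = grp$bacterium,
         cooccurrence = cooc,
         coordinates = sub[, c("species", "project_id", "latitude",
                               "longitude")])
  })
}
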