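# Hypothesis-testing layer: do confirmed pairs share their extreme
# environment?

#' Environment matching rule
#'
#' Defines which labels count as identical-or-adjacent ("near") matches on
#' each environment axis, and which axes a pair must satisfy. By default
#' only thermophile and hyperthermophile are adjacent (both are
#' high-temperature environments); pH has no adjacency. `require = "either"`
#' encodes "temperature and/or pH": one matching axis suffices.
#'
#' @param temp_adjacency List of 2-element character vectors of temperature
#'   labels treated as near matches.
#' @param ph_adjacency Same for pH labels (default none).
#' @param require `"temp"`, `"ph"`, `"either"` or `"both"`.
#' @return An object of class `env_match_rule`.
#' @export
env_match_rule <- function(temp_adjacency =
                             list(c("thermophile", "hyperthermophile")),
                           ph_adjacency = list(),
                           require = c("either", "temp", "ph", "both")) {
  require <- match.arg(require)
  chk <- function(adj, levels, what) {
    for (p in adj) {
      if (length(p) != 2L || !all(p %in% levels)) {
        stop("invalid ", what, " adjacency pair: ", paste(p, collapse = "/"))
      }
    }
  }
  chk(temp_adjacency, .temp_levels, "temperature")
  chk(ph_adjacency, .ph_levels, "pH")
  structure(list(temp_adjacency = temp_adjacency,
                 ph_adjacency = ph_adjacency, require = require),
            class = "env_match_rule")
}

.axis_match <- function(a, b, adjacency) {
  if (is.na(a) || is.na(b)) return(NA_character_)
  if (a == b) return("match")
  for (p in adjacency) {
    if (setequal(c(a, b), p)) return("near_match")
  }
  "no_match"
}

#' Match the environment labels of two genomes
#'
#' @param recA,recB [genome_record()]s (or lists with `temp_label` /
#'   `ph_label` fields).
#' @param rule An [env_match_rule()].
#' @return `"match"`, `"near_match"` or `"no_match"`, with attributes
#'   `temp_axis` and `ph_axis` giving the per-axis outcome (`NA` when a
#'   label is missing).
#' @export
match_environment <- function(recA, recB, rule = env_match_rule()) {
  stopifnot(inherits(rule, "env_match_rule"))
  for (r in list(recA, recB)) {
    if (is.na(r$temp_label) && is.na(r$ph_label)) {
      stop("unlabeled sample: '", r$id,
           "' has neither a temperature nor a pH label")
    }
  }
  temp <- .axis_match(recA$temp_label, recB$temp_label, rule$temp_adjacency)
  ph <- .axis_match(recA$ph_label, recB$ph_label, rule$ph_adjacency)
  pick <- function(axes) {
    axes <- axes[!is.na(axes)]
    if (length(axes) == 0L) return("no_match")
    if (any(axes == "match")) return("match")
    if (any(axes == "near_match")) return("near_match")
    "no_match"
  }
  res <- switch(rule$require,
    temp = if (is.na(temp)) "no_match" else temp,
    ph = if (is.na(ph)) "no_match" else ph,
    either = pick(c(temp, ph)),
    both = {
      axes <- c(temp, ph)
      if (anyNA(axes) || any(axes == "no_match")) "no_match"
      else if (all(axes == "match")) "match" else "near_match"
    })
  attr(res, "temp_axis") <- temp
  attr(res, "ph_axis") <- ph
  res
}

#' Keep environment-related pairs
#'
#' Applies [match_environment()] to each confirmed pair and keeps those
#' with a match or near match. An optional manual exclusion list (genome
#' ids) removes pairs whose members are known to be unusable (e.g.
#' suppressed assemblies) — the package never decides this itself.
#'
#' @param pairs Data.frame with `bacterium` and `archaeon` columns.
#' @param records Named list of [genome_record()]s.
#' @param rule An [env_match_rule()].
#' @param exclude Character vector of genome ids to drop.
#' @return The pairs data.frame with `env_result`, `temp_axis`, `ph_axis`
#'   columns, filtered to matching/near-matching pairs.
#' @export
environment_related_pairs <- function(pairs, records,
                                      rule = env_match_rule(),
                                      exclude = character(0)) {
  if (nrow(pairs) == 0L) {
    pairs$env_result <- character(0)
    pairs$temp_axis <- character(0)
    pairs$ph_axis <- character(0)
    return(pairs)
  }
  keep <- !(pairs$bacterium %in% exclude | pairs$archaeon %in% exclude)
  pairs <- pairs[keep, , drop = FALSE]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    match_environment(records[[pairs$bacterium[i]]],
                      records[[pairs$archaeon[i]]], rule)
  })
  pairs$env_result <- vapply(res, as.character, character(1))
  pairs$temp_axis <- vapply(res, attr, character(1), "temp_axis")
  pairs$ph_axis <- vapply(res, attr, character(1), "ph_axis")
  out <- pairs[pairs$env_result %in% c("match", "near_match"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group pairs by their bacterium
#'
#' Multiple archaea often pair with a single bacterium; groups collect the
#' (deduplicated) archaea per distinct bacterium, ordered by bacterium id.
#'
#' @param pairs Data.frame with `bacterium` and `archaeon` columns.
#' @return List of `pair_group`s: each a list with `group_id`, `bacterium`,
#'   `archaea`.
#' @export
group_by_bacterium <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("bacterium", "archaeon") %in% names(pairs)))
  if (nrow(pairs) == 0L) return(list())
  bacts <- sort(unique(pairs$bacterium))
  lapply(seq_along(bacts), function(i) {
    structure(list(group_id = i, bacterium = bacts[i],
                   archaea = sort(unique(
                     pairs$archaeon[pairs$bacterium == bacts[i]]))),
              class = "pair_group")
  })
}
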