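#' Remove singleton polymorphisms from a clone alignment
#'
#' PCR polymerase misincorporation shows up as base changes carried by a
#' single clone. For each alignment column, any state carried by exactly
#' one clone is replaced by the column's majority state; states carried by
#' two or more clones are left untouched. The gap character is treated as
#' a state like any base. Alignment length and clone count are never
#' changed, so the operation is idempotent.
#'
#' @param cs a [clone_set] with at least 2 clones.
#' @return a [clone_set] with singleton states replaced; the number of
#'   modified cells is attached as attribute `modified_position_count`.
#' @export
filter_singleton_polymorphisms <- function(cs) {
  stopifnot(inherits(cs, "clone_set"))
  n <- length(cs$sequences)
  if (n < 2) {
    stop(sprintf("cannot filter %s|%s: singleton filtering is undefined for < 2 clones",
                 cs$species_id, cs$individual_id), call. = FALSE)
  }
  m <- seq_char_matrix(cs$sequences)
  modified <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (all(col == col[1])) next
    counts <- table(col)
    singles <- names(counts)[counts == 1L]
    if (!length(singles)) next
    # majority state; ties broken alphabetically (table() sorts names)
    majority <- names(counts)[which.max(counts)]
    hit <- col %in% singles
    m[hit, j] <- majority
    modified <- modified + sum(hit)
  }
  out <- clone_set(cs$species_id, cs$individual_id, cs$clone_ids,
                   apply(m, 1, paste, collapse = ""))
  attr(out, "modified_position_count") <- modified
  out
}

#' A validated intra-individual ITS sequence class
#'
#' @param version_id version label ("1", "2", ...).
#' @param aligned_form gapped sequence in the clone alignment frame.
#' @param clone_support number of clones carrying exactly this sequence
#'   (must be at least 2).
#' @param annotation optional [region_annotation] of the ungapped consensus.
#' @return an object of class `its_version` with the consensus (ungapped
#'   form) derived from `aligned_form`.
#' @export
its_version <- function(version_id, aligned_form, clone_support,
                        annotation = NULL) {
  if (clone_support < 2) stop("an ITS version requires clone_support >= 2")
  aligned_form <- clean_sequence(aligned_form, context = "version")
  structure(list(version_id = as.character(version_id),
                 aligned_form = aligned_form,
                 consensus = gsub("-", "", aligned_form, fixed = TRUE),
                 clone_support = as.integer(clone_support),
                 annotation = annotation),
            class = "its_version")
}

#' Identify ITS versions from a filtered clone set
#'
#' Clones are grouped by exact aligned-sequence identity. Each group
#' supported by at least `min_support` clones becomes an [its_version];
#' smaller groups are counted as discarded. Versions are ordered by
#' descending support (ties by first occurrence) and labelled "1", "2", ...
#'
#' @param cs a [clone_set], normally the output of
#'   [filter_singleton_polymorphisms].
#' @param min_support minimum clone support per version (default 2).
#' @return an object of class `version_table`: a list with `species_id`,
#'   `individual_id`, `versions` (list of [its_version]),
#'   `discarded_clone_count`, `total_clones` and
#'   `modified_position_count` (0 if the input carries no filter
#'   attribute). If no group reaches `min_support` the version list is
#'   empty and a warning is issued.
#' @export
identify_versions <- function(cs, min_support = 2L) {
  stopifnot(inherits(cs, "clone_set"))
  groups <- split(seq_along(cs$sequences),
                  factor(cs$sequences, levels = unique(cs$sequences)))
  support <- lengths(groups)
  keep <- support >= min_support
  ord <- order(-support[keep], match(names(groups)[keep], cs$sequences))
  kept <- groups[keep][ord]
  versions <- vector("list", length(kept))
  for (i in seq_along(kept)) {
    versions[[i]] <- its_version(as.character(i),
                                 cs$sequences[kept[[i]][1]],
                                 length(kept[[i]]))
  }
  if (!length(versions)) {
    warning(sprintf("no haplotype in %s|%s reaches clone support %d",
                    cs$species_id, cs$individual_id, min_support))
  }
  mod <- attr(cs, "modified_position_count")
  structure(list(species_id = cs$species_id,
                 individual_id = cs$individual_id,
                 versions = versions,
                 discarded_clone_count = as.integer(sum(support[!keep])),
                 total_clones = length(cs$sequences),
                 modified_position_count = if (is.null(mod)) 0L else mod),
            class = "version_table")
}

#' @export
print.version_table <- function(x, ...) {
  cat(sprintf("version_table %s|%s: %d version(s) [support %s], %d clone(s) discarded\n",
              x$species_id, x$individual_id, length(x$versions),
              paste(vapply(x$versions, function(v) v$clone_support, 1L),
                    collapse = "/"),
              x$discarded_clone_count))
  invisible(x)
}

#' Classify a pair of ITS versions as barely or highly divergent
#'
#' Two intra-individual versions are called highly divergent when their
#' aligned difference count (gap and N columns excluded, see
#' [count_min_differences]) reaches `divergence_threshold`; the boundary
#' is inclusive. Empirically, co-occurring versions either differ at a
#' handful of sites (intraspecific variation) or by tens of substitutions
#' (divergent paralogues); the default threshold of 10 sits in the gap
#' between the two regimes.
#'
#' @param v1,v2 [its_version] objects in the same alignment frame.
#' @param divergence_threshold integer count (default 10).
#' @return `"highly_divergent"` or `"barely_divergent"`.
#' @export
classify_version_pair <- function(v1, v2, divergence_threshold = 10L) {
  d <- count_min_differences(v1$aligned_form, v2$aligned_form)
  if (d >= divergence_threshold) "highly_divergent" else "barely_divergent"
}

#' Run filtering and version identification over clone sets
#'
#' @param clone_sets list of [clone_set] objects.
#' @param min_support minimum clone support per version.
#' @return list of `version_table` objects (one per clone set).
#' @export
identify_all_versions <- function(clone_sets, min_support = 2L) {
  lapply(clone_sets, function(cs) {
    identify_versions(filter_singleton_polymorphisms(cs),
                      min_support = min_support)
  })
}

#' Flatten version tables to a data frame
#'
#' @param tables list of `version_table` objects.
#' @return data frame with one row per version (plus one row per table
#'   with zero versions), columns `species_id`, `individual_id`,
#'   `version_id`, `clone_support`, `total_clones`,
#'   `discarded_clone_count`, `modified_position_count`, `consensus`.
#' @export
version_table_report <- function(tables) {
  rows <- lapply(tables, function(vt) {
    if (!length(vt$versions)) {
      return(data.frame(species_id = vt$species_id,
                        individual_id = vt$individual_id,
                        version_id = NA_character_,
                        clone_support = NA_integer_,
                        total_clones = vt$total_clones,
                        discarded_clone_count = vt$discarded_clone_count,
                        modified_position_count = vt$modified_position_count,
                        consensus = NA_character_,
                        stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(vt$versions, function(v) {
      data.frame(species_id = vt$species_id,
                 individual_id = vt$individual_id,
                 version_id = v$version_id,
                 clone_support = v$clone_support,
                 total_clones = vt$total_clones,
                 discarded_clone_count = vt$discarded_clone_count,
                 modified_position_count = vt$modified_position_count,
                 consensus = v$consensus,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
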