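# Minimum-difference distances between sequence sets and the
# hybrid-signature classification: an individual carrying two ITS copies
# that are less similar to one another than each is to a sequence in
# another species is inferred to have hybrid ancestry.

min_diff_detail <- function(set_a, set_b, mode = "pairwise_deletion") {
  set_a <- as.character(set_a)
  set_b <- as.character(set_b)
  lens <- unique(nchar(c(set_a, set_b)))
  if (length(lens) != 1) {
    stop(sprintf("alignment frame mismatch: gapped lengths %s",
                 paste(sort(lens), collapse = ", ")), call. = FALSE)
  }
  ma <- seq_char_matrix(set_a)
  mb <- seq_char_matrix(set_b)
  if (mode == "complete") {
    ok_all <- apply(rbind(ma, mb), 2, function(col) all(col %in% BASES))
    ma <- ma[, ok_all, drop = FALSE]
    mb <- mb[, ok_all, drop = FALSE]
  }
  best <- list(d = Inf, sites = 0L, i = NA_integer_, j = NA_integer_)
  for (i in seq_len(nrow(ma))) {
    for (j in seq_len(nrow(mb))) {
      a <- ma[i, ]
      b <- mb[j, ]
      ok <- a %in% BASES & b %in% BASES
      d <- sum(a[ok] != b[ok])
      if (d < best$d) best <- list(d = d, sites = sum(ok), i = i, j = j)
    }
  }
  best$d <- as.integer(best$d)
  best$sites <- as.integer(best$sites)
  best
}

#' Minimum difference count between two sets of aligned sequences
#'
#' For every cross pair the number of differing columns is counted and
#' the minimum over pairs is returned. In `pairwise_deletion` mode (the
#' default, matching how divergent-copy distances are usually tabulated)
#' a column contributes only when both members of the pair carry an
#' unambiguous base (`A,C,G,T`); gap and `N` columns are excluded per
#' pair. In `complete` mode columns carrying a gap or `N` in *any*
#' sequence of either set are removed before counting.
#'
#' @param set_a,set_b character vectors of sequences in one alignment
#'   frame (equal gapped lengths).
#' @param mode `"pairwise_deletion"` or `"complete"`.
#' @return integer minimum difference count. The number of compared sites
#'   for the minimising pair is attached as attribute `sites`.
#' @export
count_min_differences <- function(set_a, set_b,
                                  mode = c("pairwise_deletion", "complete")) {
  mode <- match.arg(mode)
  det <- min_diff_detail(set_a, set_b, mode = mode)
  structure(det$d, sites = det$sites)
}

#' Hybrid-signature classification of per-species ITS versions
#'
#' For each species carrying two divergent ITS versions, computes the
#' within-individual distance `d_v1_v2` and, for each version, the
#' minimum distance to any version found in any other species. A hybrid
#' signature is called when the two co-occurring versions are further
#' from each other than each is from its nearest foreign sequence
#' (`d_v1_v2 > d_v1_nearest` and `d_v1_v2 > d_v2_nearest`). Species with
#' a single version are reported as `single_version` (nearest-species
#' distances still computed); species with more than two versions are
#' evaluated on their two most divergent versions and flagged in `note`.
#' Ties for the nearest species are reported comma-joined.
#'
#' @param tables list of `version_table` objects (one or more species;
#'   all versions must share one alignment frame).
#' @param divergence_threshold count separating barely from highly
#'   divergent version pairs (default 10; see [classify_version_pair]).
#' @param mode distance mode passed to [count_min_differences].
#' @return data frame with columns `species_id`, `n_versions`,
#'   `d_v1_v2`, `p_v1_v2` (proportional form, count / compared sites),
#'   `nearest_sp_v1`, `d_v1_nearest`, `nearest_sp_v2`, `d_v2_nearest`,
#'   `divergence_class`, `verdict`, `note`.
#' @export
classify_hybrid_signature <- function(tables, divergence_threshold = 10L,
                                      mode = "pairwise_deletion") {
  tables <- tables[vapply(tables, function(vt) length(vt$versions) > 0,
                          logical(1))]
  sp_ids <- vapply(tables, function(vt) vt$species_id, "")
  if (length(unique(sp_ids)) < 2) {
    stop("hybrid classification needs versions from at least 2 species")
  }
  # pool versions per species (multiple individuals contribute jointly)
  by_sp <- lapply(split(tables, factor(sp_ids, levels = unique(sp_ids))),
                  function(tabs) {
                    do.call(c, lapply(tabs, function(vt) vt$versions))
                  })
  lens <- unique(unlist(lapply(by_sp, function(vs)
    nchar(vapply(vs, function(v) v$aligned_form, "")))))
  if (length(lens) != 1) {
    stop("versions are in different alignment frames; re-align before classification")
  }

  nearest_foreign <- function(v, focal_sp) {
    ds <- vapply(setdiff(names(by_sp), focal_sp), function(other) {
      seqs <- vapply(by_sp[[other]], function(x) x$aligned_form, "")
      min_diff_detail(v$aligned_form, seqs, mode = mode)$d
    }, 1L)
    dmin <- min(ds)
    list(d = dmin, sp = paste(names(ds)[ds == dmin], collapse = ","))
  }

  rows <- lapply(names(by_sp), function(sp) {
    vs <- by_sp[[sp]]
    note <- ""
    if (length(vs) > 2) {
      # evaluate the two most divergent versions
      best <- c(1L, 2L, -1L)
      for (i in seq_len(length(vs) - 1)) {
        for (j in seq(i + 1, length(vs))) {
          d <- min_diff_detail(vs[[i]]$aligned_form,
                               vs[[j]]$aligned_form, mode = mode)$d
          if (d > best[3]) best <- c(i, j, d)
        }
      }
      note <- sprintf("%d versions present; evaluated most divergent pair (%s,%s)",
                      length(vs), vs[[best[1]]]$version_id,
                      vs[[best[2]]]$version_id)
      vs <- vs[best[1:2]]
    }
    if (length(vs) == 1) {
      n1 <- nearest_foreign(vs[[1]], sp)
      return(data.frame(species_id = sp, n_versions = 1L,
                        d_v1_v2 = NA_integer_, p_v1_v2 = NA_real_,
                        nearest_sp_v1 = n1$sp, d_v1_nearest = n1$d,
                        nearest_sp_v2 = NA_character_,
                        d_v2_nearest = NA_integer_,
                        divergence_class = NA_character_,
                        verdict = "single_version", note = note,
                        stringsAsFactors = FALSE))
    }
    det <- min_diff_detail(vs[[1]]$aligned_form, vs[[2]]$aligned_form,
                           mode = mode)
    n1 <- nearest_foreign(vs[[1]], sp)
    n2 <- nearest_foreign(vs[[2]], sp)
    verdict <- if (det$d > n1$d && det$d > n2$d) "hybrid_signature" else "no_signature"
    data.frame(species_id = sp, n_versions = length(by_sp[[sp]]),
               d_v1_v2 = det$d,
               p_v1_v2 = if (det$sites > 0) det$d / det$sites else NA_real_,
               nearest_sp_v1 = n1$sp, d_v1_nearest = n1$d,
               nearest_sp_v2 = n2$sp, d_v2_nearest = n2$d,
               divergence_class = if (det$d >= divergence_threshold)
                 "highly_divergent" else "barely_divergent",
               verdict = verdict, note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summary of within- and between-species distances
#'
#' Restricted to species evaluable for the hybrid criterion (two highly
#' divergent versions): the range of within-individual distances and the
#' largest version-to-nearest-foreign-species distance.
#'
#' @param records data frame from [classify_hybrid_signature].
#' @return named numeric vector `c(min_within, max_within, max_between)`.
#' @export
distance_summary <- function(records) {
  ev <- records[!is.na(records$d_v1_v2) &
                  records$divergence_class == "highly_divergent", , drop = FALSE]
  if (!nrow(ev)) stop("no species with two highly divergent versions to summarise")
  c(min_within = min(ev$d_v1_v2),
    max_within = max(ev$d_v1_v2),
    max_between = max(c(ev$d_v1_nearest, ev$d_v2_nearest), na.rm = TRUE))
}
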