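# Reference-based annotation of the ITS1 / 5.8S / ITS2 regions, GC
# content, the three conserved 5.8S motifs required for ITS2
# proximal-stem formation, and the pseudogene screen built on them.

#' Conserved 5.8S motifs
#'
#' Motif 2 is shared by all seed plants; motifs 1 and 3 by all
#' angiosperms. Their loss disrupts the ITS2 proximal stem and marks a
#' ribosomal DNA copy as a putative pseudogene.
#' @format named character vector of length 3.
#' @export
R58S_MOTIFS <- c(motif1 = "CGATGAAGAACGTAGC",
                 motif2 = "GAATTGCAGAATCC",
                 motif3 = "TTTGAACGCA")

#' Region annotation of an ungapped ITS sequence
#'
#' Intervals are 0-based half-open over ungapped coordinates and must be
#' ordered, non-overlapping and non-empty: ITS1, then 5.8S, then ITS2.
#'
#' @param its1,r58s,its2 length-2 integer vectors `c(start, end)`.
#' @return an object of class `region_annotation`.
#' @export
region_annotation <- function(its1, r58s, its2) {
  iv <- list(its1 = as.integer(its1), r58s = as.integer(r58s),
             its2 = as.integer(its2))
  for (nm in names(iv)) {
    if (length(iv[[nm]]) != 2 || iv[[nm]][1] < 0 || iv[[nm]][2] <= iv[[nm]][1]) {
      stop(sprintf("invalid or empty interval for %s", nm), call. = FALSE)
    }
  }
  if (iv$its1[2] > iv$r58s[1] || iv$r58s[2] > iv$its2[1]) {
    stop("regions must be ordered and non-overlapping: ITS1 < 5.8S < ITS2",
         call. = FALSE)
  }
  structure(iv, class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat(sprintf("region_annotation: ITS1 [%d,%d) 5.8S [%d,%d) ITS2 [%d,%d)\n",
              x$its1[1], x$its1[2], x$r58s[1], x$r58s[2],
              x$its2[1], x$its2[2]))
  invisible(x)
}

region_lengths <- function(ann) {
  vapply(ann[c("its1", "r58s", "its2")], function(iv) iv[2] - iv[1], 1L)
}

#' Transfer region boundaries from an annotated reference
#'
#' The query is aligned end-to-end to the reference (default scores:
#' match +1, mismatch -1, gap -2 per gapped position; terminal gaps are
#' free, so flanking bases outside the reference do not distort the
#' mapping) and each reference boundary is mapped to the query
#' coordinate aligned with it; a boundary falling on a query gap maps
#' to the nearest query position rightward. An alignment scoring below
#' `score_floor * min(sequence lengths)` aborts with an
#' annotation-failure error (the query is then unlikely to be an ITS
#' sequence at all).
#'
#' @param seq ungapped query sequence (length >= 100).
#' @param reference ungapped reference sequence.
#' @param reference_annotation [region_annotation] of the reference.
#' @param match,mismatch,gap alignment scores (gap is the per-position
#'   penalty, given as a negative number).
#' @param score_floor minimum acceptable score per reference base
#'   (default 0.3).
#' @return [region_annotation] of the query.
#' @export
annotate_regions <- function(seq, reference, reference_annotation,
                             match = 1, mismatch = -1, gap = -2,
                             score_floor = 0.3) {
  seq <- clean_sequence(seq, "query")
  reference <- clean_sequence(reference, "reference")
  if (nchar(seq) < 100) stop("query shorter than 100 bases")
  stopifnot(inherits(reference_annotation, "region_annotation"))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                     mismatch = mismatch,
                                                     baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(pattern = seq, subject = reference,
                                      type = "overlap",
                                      substitutionMatrix = submat,
                                      gapOpening = 0, gapExtension = -gap)
  if (Biostrings::score(pa) < score_floor * min(nchar(seq), nchar(reference))) {
    stop(sprintf("annotation failure: alignment score %.1f below floor %.1f; query is likely not an ITS sequence",
                 Biostrings::score(pa),
                 score_floor * min(nchar(seq), nchar(reference))),
         call. = FALSE)
  }
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  # qmap[b + 1] = query position (0-based) aligned with reference
  # position b, pushed rightward over query gaps; reference positions
  # outside the aligned overlap clamp to its ends
  rlen <- nchar(reference)
  qmap <- rep(NA_integer_, rlen + 1)
  qpos <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  rpos <- Biostrings::start(Biostrings::subject(pa)) - 1L
  qmap[seq_len(rpos + 1L)] <- qpos    # ref prefix before the overlap
  for (k in seq_along(ra)) {
    if (ra[k] != "-") {
      qmap[rpos + 1L] <- qpos
      rpos <- rpos + 1L
    }
    if (qa[k] != "-") qpos <- qpos + 1L
  }
  qmap[(rpos + 1L):(rlen + 1L)] <- qpos    # ref suffix after the overlap
  mapb <- function(b) qmap[b + 1L]
  region_annotation(
    its1 = c(mapb(reference_annotation$its1[1]), mapb(reference_annotation$its1[2])),
    r58s = c(mapb(reference_annotation$r58s[1]), mapb(reference_annotation$r58s[2])),
    its2 = c(mapb(reference_annotation$its2[1]), mapb(reference_annotation$its2[2])))
}

#' GC content of a sequence interval
#'
#' Fraction (G + C) / (interval length excluding N). An all-N interval
#' returns `NA`.
#'
#' @param seq ungapped sequence.
#' @param interval optional `c(start, end)` 0-based half-open; default
#'   whole sequence.
#' @return fraction in `[0, 1]`, or `NA` for an all-N interval.
#' @export
gc_content <- function(seq, interval = NULL) {
  seq <- clean_sequence(seq, "sequence")
  n <- nchar(seq)
  if (is.null(interval)) interval <- c(0L, n)
  if (interval[2] <= interval[1]) stop("empty interval")
  if (interval[1] < 0 || interval[2] > n) stop("interval outside sequence")
  ch <- strsplit(substr(seq, interval[1] + 1L, interval[2]), "")[[1]]
  ch <- ch[ch != "N"]
  if (!length(ch)) return(NA_real_)
  sum(ch %in% c("G", "C")) / length(ch)
}

#' Screen the three conserved 5.8S motifs
#'
#' Each motif is flagged present when it occurs as an exact substring of
#' the annotated 5.8S region, extended by `edge_slack` bases on either
#' side to absorb boundary-transfer error. With `max_mismatch = 1` a
#' single edit (substitution or indel) is tolerated.
#'
#' @param seq ungapped sequence.
#' @param annotation [region_annotation] of `seq`.
#' @param edge_slack bases of tolerance at the region edges (default 5).
#' @param max_mismatch 0 (exact, default) or 1.
#' @return named logical vector `c(motif1, motif2, motif3)`.
#' @export
screen_motifs <- function(seq, annotation, edge_slack = 5L, max_mismatch = 0L) {
  seq <- clean_sequence(seq, "sequence")
  stopifnot(inherits(annotation, "region_annotation"))
  s <- max(0L, annotation$r58s[1] - edge_slack)
  e <- min(nchar(seq), annotation$r58s[2] + edge_slack)
  region <- substr(seq, s + 1L, e)
  vapply(R58S_MOTIFS, function(m) {
    if (nchar(region) < 1) return(FALSE)
    if (max_mismatch == 0) {
      grepl(m, region, fixed = TRUE)
    } else {
      length(Biostrings::matchPattern(m, region,
                                      max.mismatch = max_mismatch,
                                      with.indels = TRUE)) > 0
    }
  }, logical(1))
}

#' Pseudogene screen for an annotated ITS sequence
#'
#' A copy is reported as a putative pseudogene when any conserved 5.8S
#' motif is absent or when its full-length GC content falls more than
#' `gc_drop_threshold` below the functional reference's GC content.
#'
#' @param seq ungapped sequence.
#' @param annotation [region_annotation] of `seq`.
#' @param reference_gc GC fraction of the functional reference ITS.
#' @param gc_drop_threshold GC drop (fraction) that triggers the low-GC
#'   reason (default 0.10).
#' @param edge_slack,max_mismatch passed to [screen_motifs].
#' @return list of class `pseudogene_report`: per-region GC fractions,
#'   the motif screen, `reasons` (subset of `missing_motif_1/2/3`,
#'   `low_gc`) and `verdict` (`functional` or `putative_pseudogene`,
#'   pseudogene iff `reasons` is non-empty).
#' @export
classify_pseudogene <- function(seq, annotation, reference_gc,
                                gc_drop_threshold = 0.10,
                                edge_slack = 5L, max_mismatch = 0L) {
  seq <- clean_sequence(seq, "sequence")
  motifs <- screen_motifs(seq, annotation, edge_slack = edge_slack,
                          max_mismatch = max_mismatch)
  gc_full <- gc_content(seq, c(annotation$its1[1], annotation$its2[2]))
  reasons <- if (all(motifs)) character(0) else
    paste0("missing_motif_", which(!motifs))
  if (!is.na(gc_full) && gc_full < reference_gc - gc_drop_threshold) {
    reasons <- c(reasons, "low_gc")
  }
  structure(list(gc_its1 = gc_content(seq, annotation$its1),
                 gc_58s = gc_content(seq, annotation$r58s),
                 gc_its2 = gc_content(seq, annotation$its2),
                 gc_full = gc_full,
                 reference_gc_full = reference_gc,
                 motifs = motifs,
                 reasons = reasons,
                 verdict = if (length(reasons)) "putative_pseudogene" else "functional"),
            class = "pseudogene_report")
}

#' @export
print.pseudogene_report <- function(x, ...) {
  cat(sprintf("pseudogene_report: %s (GC %.3f vs reference %.3f; motifs %s)\n",
              x$verdict, x$gc_full, x$reference_gc_full,
              paste(ifelse(x$motifs, "+", "-"), collapse = "")))
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Read a reference region sidecar file
#'
#' Three whitespace-separated lines `name start end` (0-based half-open),
#' naming `its1`, `r58s`/`5.8S`, `its2` in any order.
#'
#' @param path sidecar file.
#' @return [region_annotation].
#' @export
read_region_sidecar <- function(path) {
  tab <- utils::read.table(path, col.names = c("name", "start", "end"),
                           stringsAsFactors = FALSE)
  nm <- tolower(tab$name)
  nm[nm %in% c("5.8s", "58s", "5_8s")] <- "r58s"
  rownames(tab) <- nm
  need <- c("its1", "r58s", "its2")
  if (!all(need %in% nm)) {
    stop("region sidecar must name its1, r58s (5.8S) and its2")
  }
  region_annotation(its1 = unlist(tab["its1", 2:3]),
                    r58s = unlist(tab["r58s", 2:3]),
                    its2 = unlist(tab["its2", 2:3]))
}

#' Write a reference region sidecar file
#'
#' @param annotation [region_annotation].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_region_sidecar <- function(annotation, path) {
  stopifnot(inherits(annotation, "region_annotation"))
  writeLines(sprintf("%s\t%d\t%d", c("its1", "r58s", "its2"),
                     vapply(annotation[c("its1", "r58s", "its2")], `[`, 1L, 1),
                     vapply(annotation[c("its1", "r58s", "its2")], `[`, 1L, 2)),
             path)
  invisible(path)
}
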