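# Validation workflow for a published clone-survey dataset: given the
# study's deposited ITS version sequences (aligned, headers
# "Species|version") and an annotated functional reference, recompute
# the headline statistics of such a survey — per-region lengths, the
# within/between distance table, the hybrid-signature count, tandem
# repeats and reference GC content.

#' Recompute survey statistics from deposited version sequences
#'
#' Intended for validating the pipeline against a published dataset:
#' the deposited per-species ITS versions (one aligned FASTA, headers
#' `Species<delim>version`) are re-analysed end to end. Sequence data
#' must be supplied by the user (e.g. downloaded from GenBank); nothing
#' is fetched.
#'
#' @param aligned_fasta aligned FASTA of deposited version sequences.
#' @param reference_fasta single-record FASTA of the annotated
#'   functional reference ITS.
#' @param reference_regions region sidecar for the reference (see
#'   [read_region_sidecar]).
#' @param delim header delimiter (default `"|"`).
#' @param divergence_threshold passed to [classify_hybrid_signature].
#' @return list with `r58s_lengths` (named per sequence), `its_lengths`
#'   (ungapped, named), `max_its_length`, `records` (distance/verdict
#'   table), `summary` (`min_within`, `max_within`, `max_between`),
#'   `n_hybrid_flagged`, `repeats` (per-sequence tandem-repeat hits
#'   with region labels) and `reference_gc`.
#' @export
validate_published_dataset <- function(aligned_fasta, reference_fasta,
                                       reference_regions, delim = "|",
                                       divergence_threshold = 10L) {
  for (p in c(aligned_fasta, reference_fasta, reference_regions)) {
    if (!file.exists(p)) {
      stop(sprintf("input file not available: %s (deposited sequences must be supplied by the user; nothing is downloaded)",
                   p), call. = FALSE)
    }
  }
  seqs <- as.character(Biostrings::readBStringSet(aligned_fasta))
  names(seqs) <- trimws(names(seqs))
  parts <- strsplit(names(seqs), delim, fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop(sprintf("headers must follow 'Species%sversion'", delim))
  }
  sp <- vapply(parts, `[`, "", 1)
  ver <- vapply(parts, `[`, "", 2)
  seqs <- clean_sequence(seqs, "deposited sequences")

  ref_seq <- clean_sequence(
    as.character(Biostrings::readBStringSet(reference_fasta))[[1]], "reference")
  ref_ann <- read_region_sidecar(reference_regions)
  ref_gc <- gc_content(ref_seq, c(ref_ann$its1[1], ref_ann$its2[2]))

  ungapped <- gsub("-", "", seqs, fixed = TRUE)
  anns <- lapply(ungapped, annotate_regions, reference = ref_seq,
                 reference_annotation = ref_ann)
  r58s_lengths <- vapply(anns, function(a) a$r58s[2] - a$r58s[1], 1L)
  its_lengths <- vapply(anns, function(a) a$its2[2] - a$its1[1], 1L)

  # one version table per species; deposited versions carry no clone
  # counts, so support is taken at the reporting minimum of 2
  tables <- lapply(split(seq_along(seqs), factor(sp, levels = unique(sp))),
                   function(idx) {
    structure(list(species_id = sp[idx[1]], individual_id = "deposited",
                   versions = lapply(idx, function(i) {
                     its_version(ver[i], seqs[[i]], 2L)
                   }),
                   discarded_clone_count = 0L,
                   total_clones = NA_integer_,
                   modified_position_count = 0L),
              class = "version_table")
  })
  records <- classify_hybrid_signature(tables,
                                       divergence_threshold = divergence_threshold)

  repeats <- do.call(rbind, lapply(names(ungapped), function(nm) {
    h <- find_tandem_repeats(ungapped[[nm]])
    if (!nrow(h)) return(NULL)
    cbind(data.frame(seq_id = nm, stringsAsFactors = FALSE),
          assign_repeat_region(h, anns[[nm]]))
  }))

  list(r58s_lengths = r58s_lengths,
       its_lengths = its_lengths,
       max_its_length = max(its_lengths),
       records = records,
       summary = distance_summary(records),
       n_hybrid_flagged = sum(records$verdict == "hybrid_signature"),
       repeats = repeats,
       reference_gc = ref_gc)
}
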