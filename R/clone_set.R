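#' @importFrom stats setNames
NULL

# Alphabet accepted for aligned nucleotide data. All coordinates in the
# package API are 0-based half-open; gap columns are excluded from ungapped
# coordinates.
SEQ_ALPHABET <- c("A", "C", "G", "T", "N", "-")
BASES <- c("A", "C", "G", "T")

#' Normalise a nucleotide string
#'
#' Uppercases, maps U to T, and rejects characters outside `A,C,G,T,N,-`.
#'
#' @param x character vector of sequences.
#' @param context label used in error messages.
#' @return character vector of cleaned sequences.
#' @keywords internal
clean_sequence <- function(x, context = "sequence") {
  x <- chartr("u", "t", x)
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- vapply(strsplit(x, "", fixed = TRUE),
                function(ch) any(!ch %in% SEQ_ALPHABET), logical(1))
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N,-}: entry %d",
                 context, which(bad)[1]), call. = FALSE)
  }
  x
}

seq_char_matrix <- function(seqs) {
  do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}

#' One individual's set of aligned ITS clones
#'
#' A `clone_set` groups the cloned, aligned ITS sequences obtained from a
#' single individual of a species. All clone strings must have identical
#' (gapped) length; clone identifiers must be unique within the set.
#'
#' @param species_id species label.
#' @param individual_id individual (accession) label.
#' @param clone_ids character vector of clone identifiers.
#' @param sequences character vector of aligned sequences over
#'   `A,C,G,T,N,-`, one per clone.
#' @return an object of class `clone_set` with fields `species_id`,
#'   `individual_id`, `clone_ids`, `sequences` and `alignment_length`.
#' @export
clone_set <- function(species_id, individual_id, clone_ids, sequences) {
  stopifnot(length(clone_ids) == length(sequences))
  if (length(sequences) < 1) stop("a clone_set needs at least one clone")
  if (anyDuplicated(clone_ids)) {
    stop(sprintf("duplicate clone ids in %s|%s: %s", species_id, individual_id,
                 paste(unique(clone_ids[duplicated(clone_ids)]), collapse = ", ")),
         call. = FALSE)
  }
  sequences <- clean_sequence(sequences,
                              context = paste0(species_id, "|", individual_id))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1) {
    stop(sprintf("ragged alignment in group %s|%s: lengths %s",
                 species_id, individual_id,
                 paste(sort(unique(lens)), collapse = ", ")), call. = FALSE)
  }
  structure(list(species_id = species_id,
                 individual_id = individual_id,
                 clone_ids = as.character(clone_ids),
                 sequences = unname(sequences),
                 alignment_length = unname(lens[1])),
            class = "clone_set")
}

#' @export
print.clone_set <- function(x, ...) {
  cat(sprintf("clone_set %s|%s: %d clones, alignment length %d\n",
              x$species_id, x$individual_id, length(x$clone_ids),
              x$alignment_length))
  invisible(x)
}

#' Read aligned clone FASTA grouped by species and individual
#'
#' Headers must follow the schema `species<delim>individual<delim>clone`.
#' Records are grouped by (species, individual) into [clone_set] objects;
#' the equal-length invariant is enforced per group.
#'
#' @param path FASTA file of aligned clones.
#' @param delim header field delimiter (default `"|"`).
#' @return named list of [clone_set] objects, names `species|individual`.
#' @export
read_clone_fasta <- function(path, delim = "|") {
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  seqs <- as.character(ss)
  parts <- strsplit(headers, delim, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3)) {
    i <- which(nf != 3)[1]
    stop(sprintf("header does not match schema 'species%sindividual%sclone' at record %d: '%s'",
                 delim, delim, i, headers[i]), call. = FALSE)
  }
  sp <- vapply(parts, `[`, "", 1)
  ind <- vapply(parts, `[`, "", 2)
  cl <- vapply(parts, `[`, "", 3)
  key <- paste(sp, ind, sep = "|")
  out <- lapply(split(seq_along(key), factor(key, levels = unique(key))),
                function(idx) {
                  clone_set(sp[idx[1]], ind[idx[1]], cl[idx], seqs[idx])
                })
  out
}

#' Write clone sets (or any named sequences) to FASTA
#'
#' @param x a [clone_set], a list of them, or a named character vector of
#'   sequences.
#' @param path output file.
#' @param delim header delimiter used for clone sets.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, delim = "|") {
  if (inherits(x, "clone_set")) x <- list(x)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "clone_set"))) {
    seqs <- unlist(unname(lapply(x, function(cs) {
      setNames(cs$sequences,
               paste(cs$species_id, cs$individual_id, cs$clone_ids, sep = delim))
    })))
  } else {
    seqs <- x
    if (is.null(names(seqs))) stop("sequences must be named")
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a Newick tree
#'
#' Wraps [ape::read.tree] with validation: at least two leaves and unique
#' leaf labels.
#'
#' @param path Newick file.
#' @return an [ape::read.tree] `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop(sprintf("could not parse Newick file '%s'", path))
  validate_tree(tr)
  tr
}

validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylogenetic tree")
  if (length(tr$tip.label) < 2) stop("tree must have at least 2 leaves")
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup)) {
    stop(sprintf("duplicate leaf label(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  invisible(tr)
}

#' Write a tree to Newick
#'
#' @param tree a `phylo` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  validate_tree(tree)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a tabular report as tab-separated text
#'
#' Fixed column order is taken from the data frame itself; no quoting, no
#' row names, `NA` written as empty string.
#'
#' @param records a data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Enumerate the non-trivial leaf bipartitions of a tree
#'
#' Each internal edge splits the leaves into two sets; the bipartition is
#' represented canonically as the sorted side containing the
#' alphabetically first leaf. Used for topology comparison.
#'
#' @param tree a `phylo` object.
#' @return character vector of canonical bipartition encodings.
#' @export
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- character(0)
  for (part in pp) {
    side <- sort(labs[part])
    other <- setdiff(tips, side)
    if (length(side) <= 1 || length(other) <= 1) next
    canon <- if (tips[1] %in% side) side else other
    out <- c(out, paste(canon, collapse = ","))
  }
  sort(unique(out))
}
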