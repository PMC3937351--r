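# Clade assignment on rooted trees via seed taxa + MRCA, detection of
# clade-membership incongruence between two phylogenies (the classic
# signal of chloroplast capture), cherry checks for intra-individual
# ITS versions, and a neighbor-joining convenience wrapper.

tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1]]]
}

#' Assign tree leaves to clades defined by seed taxa
#'
#' Each clade is operationalised as the full leaf set of the most
#' recent common ancestor of its seed taxa. Every leaf is assigned to
#' the smallest clade containing it (nested clades resolve to the more
#' nested one); leaves inside no clade are `unassigned`.
#'
#' @param tree rooted `phylo` tree.
#' @param defs named list: clade label -> character vector of at least
#'   2 seed leaf labels. Seed sets must be disjoint across clades.
#' @return named character vector mapping every leaf label to a clade
#'   label or `"unassigned"`.
#' @export
assign_clades <- function(tree, defs) {
  validate_tree(tree)
  stopifnot(is.list(defs), length(defs) >= 1, !is.null(names(defs)))
  seeds_all <- unlist(defs)
  if (anyDuplicated(seeds_all)) {
    stop(sprintf("seed taxa appear in more than one clade: %s",
                 paste(unique(seeds_all[duplicated(seeds_all)]), collapse = ", ")))
  }
  missing <- setdiff(seeds_all, tree$tip.label)
  if (length(missing)) {
    stop(sprintf("seed taxon/taxa missing from tree: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  clade_sets <- lapply(defs, function(seeds) {
    if (length(seeds) < 2) stop("each clade needs at least 2 seed taxa")
    mrca <- ape::getMRCA(tree, seeds)
    tips_under(tree, mrca)
  })
  out <- setNames(rep("unassigned", length(tree$tip.label)), tree$tip.label)
  sizes <- lengths(clade_sets)
  for (lab in names(clade_sets)[order(-sizes)]) {
    out[clade_sets[[lab]]] <- lab     # smaller (nested) clades overwrite
  }
  out
}

#' Detect clade-membership incongruence between two phylogenies
#'
#' Compares per-taxon clade assignments from two trees (for example ITS
#' versus cpDNA). A taxon is discordant when it is assigned to
#' different clades in the two maps; taxa unassigned in either map are
#' reported with `discordant = FALSE` and a note, and taxa missing from
#' either map are skipped with a note.
#'
#' @param map1,map2 named character vectors from [assign_clades].
#' @param label_translation optional named character vector translating
#'   `map1` leaf labels (e.g. `"spX#1"`) to `map2` taxon labels
#'   (`"spX"`); labels absent from it are used as-is.
#' @return data frame with columns `leaf_label`, `taxon`,
#'   `clade_tree1`, `clade_tree2`, `discordant`, `note` — one row per
#'   `map1` leaf whose translated taxon occurs in `map2`.
#' @export
detect_incongruence <- function(map1, map2, label_translation = NULL) {
  taxa1 <- names(map1)
  translated <- if (is.null(label_translation)) taxa1 else {
    ifelse(taxa1 %in% names(label_translation),
           label_translation[taxa1], taxa1)
  }
  shared <- translated %in% names(map2)
  if (!any(shared)) stop("no shared taxa between the two clade maps")
  rows <- lapply(which(shared), function(i) {
    c1 <- unname(map1[[taxa1[i]]])
    c2 <- unname(map2[[translated[i]]])
    una <- c1 == "unassigned" || c2 == "unassigned"
    data.frame(leaf_label = taxa1[i], taxon = translated[i],
               clade_tree1 = c1, clade_tree2 = c2,
               discordant = !una && c1 != c2,
               note = if (una) "unassigned in at least one tree" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  skipped <- taxa1[!shared]
  if (length(skipped)) {
    attr(out, "skipped") <- skipped
  }
  rownames(out) <- NULL
  out
}

#' Do two leaves form a cherry?
#'
#' `TRUE` iff the two leaves are siblings under their most recent
#' common ancestor with no other leaf below it — the topology expected
#' for two barely divergent intra-individual ITS versions, and the
#' opposite of the pattern left by hybridization.
#'
#' @param tree `phylo` tree.
#' @param v1_label,v2_label leaf labels.
#' @return logical.
#' @export
versions_cluster_together <- function(tree, v1_label, v2_label) {
  validate_tree(tree)
  missing <- setdiff(c(v1_label, v2_label), tree$tip.label)
  if (length(missing)) {
    stop(sprintf("leaf label(s) missing from tree: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  mrca <- ape::getMRCA(tree, c(v1_label, v2_label))
  setequal(tips_under(tree, mrca), c(v1_label, v2_label))
}

#' Build a rooted neighbor-joining tree from a distance matrix
#'
#' Convenience wrapper around [ape::nj] for turning the package's
#' difference-count matrices into trees that the clade logic can
#' consume. The unrooted NJ tree is rooted on `outgroup` when given,
#' otherwise midpoint-rooted.
#'
#' @param labels taxon labels (row order of `distance_matrix`).
#' @param distance_matrix symmetric matrix with zero diagonal.
#' @param outgroup optional leaf label to root on.
#' @return rooted `phylo` tree.
#' @export
build_nj_tree <- function(labels, distance_matrix, outgroup = NULL) {
  distance_matrix <- as.matrix(distance_matrix)
  if (!isSymmetric(unname(distance_matrix), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  if (any(abs(diag(distance_matrix)) > 1e-12)) {
    stop("distance matrix must have a zero diagonal")
  }
  dimnames(distance_matrix) <- list(labels, labels)
  tr <- ape::nj(distance_matrix)
  tr <- if (!is.null(outgroup)) {
    ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  } else {
    phangorn::midpoint(tr)
  }
  validate_tree(tr)
  tr
}

#' Pairwise minimum-difference distance matrix
#'
#' Applies [count_min_differences] to every pair of sequence sets; used
#' to feed [build_nj_tree].
#'
#' @param seq_sets named list; each element a character vector of
#'   aligned sequences (one frame across all sets).
#' @param mode distance mode passed to [count_min_differences].
#' @return symmetric integer matrix.
#' @export
min_difference_matrix <- function(seq_sets, mode = "pairwise_deletion") {
  n <- length(seq_sets)
  out <- matrix(0, n, n, dimnames = list(names(seq_sets), names(seq_sets)))
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- count_min_differences(seq_sets[[i]], seq_sets[[j]], mode = mode)
      out[i, j] <- out[j, i] <- as.integer(d)
    }
  }
  out
}
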