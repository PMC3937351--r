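# End-to-end orchestration: clones -> versions -> annotation and
# pseudogene screen -> hybrid calls -> repeats -> indel codes ->
# optional tree incongruence, with a combined report bundle. All
# analysis stages are deterministic; randomness lives only in the
# simulator.

#' Pipeline configuration
#'
#' @param clones path to the aligned clone FASTA.
#' @param reference path to the reference ITS FASTA (single record).
#' @param reference_regions path to the 3-line region sidecar (see
#'   [read_region_sidecar]).
#' @param out_dir output directory.
#' @param its_tree,cp_tree optional Newick paths for the incongruence
#'   stage.
#' @param clade_seeds optional named list (clade label -> seed taxa)
#'   for [assign_clades]; needed when trees are given.
#' @param min_support,divergence_threshold,gc_drop thresholds (defaults
#'   2, 10, 0.10).
#' @param repeat_opts [repeat_params] for the repeat stage.
#' @param exclude_pseudogenes drop pseudogene-flagged versions from the
#'   hybrid classification (default TRUE; they stay listed in
#'   `pseudogenes.tsv` and are marked in `table3.tsv`).
#' @param delim clone-header delimiter.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(clones, reference, reference_regions, out_dir,
                            its_tree = NULL, cp_tree = NULL,
                            clade_seeds = NULL,
                            min_support = 2L, divergence_threshold = 10L,
                            gc_drop = 0.10, repeat_opts = repeat_params(),
                            exclude_pseudogenes = TRUE, delim = "|") {
  stopifnot(min_support >= 2, divergence_threshold >= 1,
            gc_drop > 0, gc_drop < 1)
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  for (f in c("clones", "reference", "reference_regions", "its_tree", "cp_tree")) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p)) {
      stop(sprintf("input file for '%s' does not exist: %s", f, p),
           call. = FALSE)
    }
  }
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config];
#' `clade_seeds` is a mapping from clade label to a list of seed taxa,
#' `repeat_opts` a mapping of [repeat_params] arguments.
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$repeat_opts)) y$repeat_opts <- do.call(repeat_params, y$repeat_opts)
  do.call(pipeline_config, y)
}

stage <- function(name, input, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed on %s: %s",
                 name, input, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Stages: read and group clones; filter singleton polymorphisms and
#' identify versions; annotate each version against the reference and
#' screen for pseudogenes; classify hybrid signatures (pseudogene-
#' flagged versions excluded when configured, and marked); find tandem
#' repeats per version; code indels over the version alignment; and,
#' when both trees are supplied, detect clade-membership incongruence.
#' Writes `versions.tsv`, `pseudogenes.tsv`, `table3.tsv`,
#' `repeats.tsv`, `indels.tsv` (+ `.key`), `incongruence.tsv` (trees
#' only) and `run_log.txt` to the output directory.
#'
#' @param config a [pipeline_config] or the path to its YAML form.
#' @return invisible list of the report data frames.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("reticulITS pipeline run: %s", format(Sys.time())),
                 sprintf("thresholds: min_support=%d divergence_threshold=%d gc_drop=%.2f",
                         config$min_support, config$divergence_threshold,
                         config$gc_drop),
                 sprintf("repeat params: match=%d mismatch=%d indel=%d min_score=%d",
                         config$repeat_opts$match, config$repeat_opts$mismatch,
                         config$repeat_opts$indel, config$repeat_opts$min_score),
                 sprintf("exclude_pseudogenes=%s", config$exclude_pseudogenes))

  clone_sets <- stage("read_clones", config$clones,
                      read_clone_fasta(config$clones, delim = config$delim))
  tables <- stage("identify_versions", config$clones,
                  identify_all_versions(clone_sets,
                                        min_support = config$min_support))
  versions_df <- version_table_report(tables)
  write_report(versions_df, file.path(config$out_dir, "versions.tsv"))

  ref_seq <- as.character(Biostrings::readBStringSet(config$reference))[[1]]
  ref_ann <- read_region_sidecar(config$reference_regions)
  ref_gc <- gc_content(ref_seq, c(ref_ann$its1[1], ref_ann$its2[2]))

  pseudo_rows <- list()
  flagged <- character(0)   # "species|individual|version" keys
  for (vt in tables) {
    for (v in vt$versions) {
      key <- paste(vt$species_id, vt$individual_id, v$version_id, sep = "|")
      rep <- stage("pseudogene_screen", key, {
        ann <- annotate_regions(v$consensus, ref_seq, ref_ann)
        classify_pseudogene(v$consensus, ann, reference_gc = ref_gc,
                            gc_drop_threshold = config$gc_drop)
      })
      pseudo_rows[[key]] <- data.frame(
        species_id = vt$species_id, individual_id = vt$individual_id,
        version_id = v$version_id,
        gc_its1 = rep$gc_its1, gc_58s = rep$gc_58s, gc_its2 = rep$gc_its2,
        gc_full = rep$gc_full, reference_gc = rep$reference_gc_full,
        motif1 = rep$motifs[["motif1"]], motif2 = rep$motifs[["motif2"]],
        motif3 = rep$motifs[["motif3"]],
        verdict = rep$verdict,
        reasons = paste(rep$reasons, collapse = ","),
        stringsAsFactors = FALSE)
      if (rep$verdict == "putative_pseudogene") flagged <- c(flagged, key)
    }
  }
  pseudo_df <- do.call(rbind, c(pseudo_rows, list(make.row.names = FALSE)))
  write_report(pseudo_df, file.path(config$out_dir, "pseudogenes.tsv"))

  hybrid_tables <- tables
  if (config$exclude_pseudogenes && length(flagged)) {
    hybrid_tables <- lapply(tables, function(vt) {
      keep <- vapply(vt$versions, function(v) {
        !(paste(vt$species_id, vt$individual_id, v$version_id, sep = "|") %in% flagged)
      }, logical(1))
      vt$versions <- vt$versions[keep]
      vt
    })
    log_lines <- c(log_lines,
                   sprintf("excluded pseudogene-flagged version(s): %s",
                           paste(flagged, collapse = ", ")))
  }
  table3 <- stage("hybrid_classification", config$clones,
                  classify_hybrid_signature(
                    hybrid_tables,
                    divergence_threshold = config$divergence_threshold))
  if (length(flagged)) {
    fl_sp <- unique(vapply(strsplit(flagged, "|", fixed = TRUE), `[`, "", 1))
    hit <- table3$species_id %in% fl_sp
    table3$note[hit] <- trimws(paste(table3$note[hit],
                                     "pseudogene-flagged version(s) excluded"))
  }
  write_report(table3, file.path(config$out_dir, "table3.tsv"))

  repeat_rows <- list()
  for (vt in tables) {
    for (v in vt$versions) {
      key <- paste(vt$species_id, vt$individual_id, v$version_id, sep = "|")
      hits <- stage("repeat_search", key, {
        h <- find_tandem_repeats(v$consensus, config$repeat_opts)
        if (nrow(h)) {
          ann <- annotate_regions(v$consensus, ref_seq, ref_ann)
          h <- assign_repeat_region(h, ann)
        }
        h
      })
      if (nrow(hits)) {
        repeat_rows[[key]] <- cbind(data.frame(species_id = vt$species_id,
                                               individual_id = vt$individual_id,
                                               version_id = v$version_id,
                                               stringsAsFactors = FALSE),
                                    hits)
      }
    }
  }
  repeats_df <- if (length(repeat_rows)) {
    do.call(rbind, c(repeat_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(species_id = character(0), individual_id = character(0),
               version_id = character(0), start = integer(0), end = integer(0),
               consensus_pattern = character(0), consensus_size = integer(0),
               copy_number = numeric(0), percent_matches = integer(0),
               score = integer(0), region_label = character(0))
  }
  write_report(repeats_df, file.path(config$out_dir, "repeats.tsv"))

  aln <- unlist(lapply(tables, function(vt) {
    setNames(vapply(vt$versions, function(v) v$aligned_form, ""),
             vapply(vt$versions, function(v)
               paste0(vt$species_id, "#", v$version_id), ""))
  }))
  indels_df <- NULL
  if (length(aln) >= 2) {
    im <- stage("indel_coding", config$clones, code_indels(aln))
    write_indel_matrix(im, file.path(config$out_dir, "indels.tsv"))
    indels_df <- im
  }

  incong <- NULL
  if (!is.null(config$its_tree) && !is.null(config$cp_tree)) {
    incong <- stage("incongruence", config$its_tree, {
      t1 <- read_newick(config$its_tree)
      t2 <- read_newick(config$cp_tree)
      if (is.null(config$clade_seeds)) {
        stop("clade_seeds must be provided when trees are supplied")
      }
      # version leaves "species#k" translate to the species label
      trans <- setNames(sub("#\\d+$", "", t1$tip.label), t1$tip.label)
      detect_incongruence(assign_clades(t1, config$clade_seeds),
                          assign_clades(t2, config$clade_seeds),
                          label_translation = trans)
    })
    write_report(incong, file.path(config$out_dir, "incongruence.tsv"))
  } else {
    log_lines <- c(log_lines, "no trees supplied; incongruence stage skipped")
  }

  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(versions = versions_df, pseudogenes = pseudo_df,
                 table3 = table3, repeats = repeats_df, indels = indels_df,
                 incongruence = incong))
}
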