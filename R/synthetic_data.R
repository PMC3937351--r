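# Radiation simulator: a pure-birth species tree with clades, ITS and
# cpDNA sequence evolution under a single-parameter substitution model,
# hybridization events that graft a second ITS version from a donor
# clade, chloroplast capture, concerted-evolution homogenization, and
# per-clone PCR error. Every stage of the analysis pipeline can be
# exercised against the emitted truth table.

#' Simulation configuration
#'
#' Defaults emulate a radiating clade of 24 species sampled with 15
#' clones per species, ITS of 560 bp (200 + 164 + 196) and 2 kb of
#' cpDNA. Substitution is a single-parameter per-site model scaled by
#' branch length (tree depth is normalised to 1); the 5.8S segment is
#' held invariant by default, mirroring its strong conservation.
#'
#' @param n_species number of species (default 24).
#' @param its1_length,its2_length spacer lengths; the 5.8S segment is a
#'   fixed 164-bp synthetic sequence carrying the conserved motifs.
#' @param cp_length cpDNA length (default 2000).
#' @param subst_rate per-site substitution rate for the ITS spacers per
#'   unit tree depth (default 0.03).
#' @param r58s_rate_scale multiplier on `subst_rate` inside 5.8S
#'   (default 0 = invariant).
#' @param cp_subst_rate per-site cpDNA rate (default 0.008).
#' @param n_clades number of major clades cut from the species tree
#'   (default 4, labelled A, B, C, ...).
#' @param clade_crown_start optional depth in (0,1) to which the
#'   between-clade divergence period is stretched: the tree is
#'   time-warped so clades begin diversifying only after this depth,
#'   giving deep between-clade and shallow within-clade divergence.
#'   `NULL` (default) leaves the pure-birth depths untouched.
#' @param hybrid_events explicit list of events, each
#'   `list(recipient=, donor_clade=, time_fraction=)`; or use
#'   `n_hybrid_events` to have recipients and donor clades drawn at
#'   random (seeded).
#' @param n_hybrid_events number of auto-drawn hybrid events (default 0).
#' @param hybrid_time_fraction event time for auto-drawn events
#'   (default 0.8; 0 = root, 1 = present).
#' @param capture_events,n_capture_events,capture_time_fraction same
#'   for chloroplast capture (defaults: none, 0.9).
#' @param homogenization_prob probability that concerted evolution has
#'   collapsed a hybrid back to a single ITS version (default 0).
#' @param clones_per_species clones sequenced per species (default 15).
#' @param clone_split clone support for (version 1, version 2) in
#'   two-version species; must sum to `clones_per_species`, each part
#'   at least 2 (default c(10, 5)).
#' @param pcr_error_rate per-base per-clone error probability
#'   (default 5e-4).
#' @param seed integer seed; same seed, same outputs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_species = 24L, its1_length = 200L,
                       its2_length = 196L, cp_length = 2000L,
                       subst_rate = 0.03, r58s_rate_scale = 0,
                       cp_subst_rate = 0.008, n_clades = 4L,
                       clade_crown_start = NULL,
                       hybrid_events = list(), n_hybrid_events = 0L,
                       hybrid_time_fraction = 0.8,
                       capture_events = list(), n_capture_events = 0L,
                       capture_time_fraction = 0.9,
                       homogenization_prob = 0,
                       clones_per_species = 15L, clone_split = c(10L, 5L),
                       pcr_error_rate = 5e-4, seed = 1L) {
  stopifnot(n_species >= 4, n_clades >= 2, n_clades < n_species,
            subst_rate >= 0, subst_rate <= 1,
            r58s_rate_scale >= 0, r58s_rate_scale <= 1,
            cp_subst_rate >= 0, cp_subst_rate <= 1,
            homogenization_prob >= 0, homogenization_prob <= 1,
            pcr_error_rate >= 0, pcr_error_rate <= 1,
            clones_per_species >= 2,
            sum(clone_split) == clones_per_species, all(clone_split >= 2))
  if (!is.null(clade_crown_start)) {
    stopifnot(clade_crown_start > 0, clade_crown_start < 1)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Deep-divergence study regime
#'
#' Preset emulating the empirical situation the pipeline targets: a
#' 24-species radiation whose clades are separated by deep stems
#' (between-clade ITS divergence of roughly 20-40 substitutions, nearest
#' within-clade neighbours typically under 10), with seven hybridization events
#' donating a second ITS version across clades and no concerted-evolution
#' homogenization.
#'
#' @param seed integer seed.
#' @param n_hybrid_events number of injected hybrid events (default 7).
#' @param homogenization_prob see [sim_config] (default 0).
#' @return `sim_config`.
#' @export
deep_divergence_config <- function(seed = 1L, n_hybrid_events = 7L,
                                   homogenization_prob = 0) {
  sim_config(subst_rate = 0.035,
             n_hybrid_events = n_hybrid_events,
             hybrid_time_fraction = 0.8,
             clade_crown_start = 0.75,
             homogenization_prob = homogenization_prob,
             seed = seed)
}

#' Chloroplast-capture-only study regime
#'
#' No hybrid ITS events; a single chloroplast capture. The nuclear
#' pipeline should stay silent and the incongruence module should flag
#' exactly the captured species.
#'
#' @param seed integer seed.
#' @param n_capture_events number of capture events (default 1).
#' @return `sim_config`.
#' @export
capture_only_config <- function(seed = 1L, n_capture_events = 1L) {
  sim_config(n_hybrid_events = 0L, n_capture_events = n_capture_events,
             capture_time_fraction = 0.9, clade_crown_start = 0.75,
             seed = seed)
}

INT2BASE <- c("A", "C", "G", "T")

int_to_seq <- function(x) paste(INT2BASE[x], collapse = "")
seq_to_int <- function(s) match(strsplit(s, "", fixed = TRUE)[[1]], INT2BASE)

random_spacer_int <- function(n, gc = 0.67) {
  sample(1:4, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Mutate an integer-coded sequence along a branch: per-site substitution
# probability 1 - exp(-rate * len), new state uniform over the other 3.
mutate_seq <- function(x, rates, len) {
  p <- 1 - exp(-rates * len)
  hit <- which(stats::runif(length(x)) < p)
  if (length(hit)) {
    x[hit] <- (x[hit] - 1L + sample(1:3, length(hit), replace = TRUE)) %% 4L + 1L
  }
  x
}

node_path_to_root <- function(tree, node) {
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  path <- node
  while (TRUE) {
    e <- match(node, child)
    if (is.na(e)) break
    node <- parent[e]
    path <- c(path, node)
  }
  path  # tip first, root last
}

# Edge crossing depth t on the path from the root to a given tip;
# returns the child node and the distance from the child up to t.
edge_crossing_on_path <- function(tree, tip_label, t) {
  depths <- ape::node.depth.edgelength(tree)
  tipn <- match(tip_label, tree$tip.label)
  if (is.na(tipn)) stop(sprintf("tip '%s' not in tree", tip_label))
  path <- node_path_to_root(tree, tipn)
  for (k in seq(length(path), 2)) {
    p <- path[k]
    ch <- path[k - 1]
    if (depths[p] <= t && t < depths[ch]) {
      return(list(child = ch, position = depths[ch] - t))
    }
  }
  stop(sprintf("no edge crossing depth %.3f on path to '%s'", t, tip_label))
}

# Attach a single new tip to the edge above `where`, `position` above it.
bind_tip <- function(tree, label, where, position, pendant) {
  tip <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                        tip.label = label,
                        edge.length = pendant, Nnode = 1L),
                   class = "phylo")
  ape::bind.tree(tree, tip, where = where, position = position)
}

#' Simulate a radiating clade with hybridization and chloroplast capture
#'
#' Grows a pure-birth species tree (depth normalised to 1), cuts it into
#' major clades at the point where `n_clades` lineages coexist
#' (optionally time-warping the depths so clades diversify only after
#' `clade_crown_start`), evolves ITS and cpDNA along it, then applies
#' hybrid events (version 2 sampled from a donor-clade lineage at the
#' event time and evolved to the present), concerted-evolution
#' homogenization, and chloroplast capture. Deterministic given the
#' config seed.
#'
#' @param config a [sim_config].
#' @return list of class `radiation_sim`: `species_tree`, `clade_map`
#'   (species -> clade label), `its_versions` (species -> named vector
#'   of 1-2 ungapped sequences, all in one frame), `cp_seqs`,
#'   `annotation` ([region_annotation] shared by all ITS sequences),
#'   `truth` (data frame: `species_id`, `clade`, `is_hybrid`,
#'   `donor_clade`, `n_true_versions`, `cp_captured`,
#'   `cp_donor_clade`), `its_tree_true`, `cp_tree_true` (version-level /
#'   capture-adjusted trees), and the `config` echo.
#' @export
simulate_radiation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_species
  sp <- sprintf("sp%02d", seq_len(n))

  # --- species tree, depth normalised to 1 ---------------------------
  tree <- ape::rphylo(n, birth = 1, death = 0)
  tree$tip.label <- sp[as.integer(sub("^t", "", tree$tip.label))]
  depths <- ape::node.depth.edgelength(tree)
  tree$edge.length <- tree$edge.length / max(depths)
  depths <- ape::node.depth.edgelength(tree)

  # --- clades: lineages present when n_clades lineages coexist -------
  int_depths <- sort(depths[(n + 1):(n + tree$Nnode)])
  tcut <- if (length(int_depths) >= config$n_clades) {
    (int_depths[config$n_clades - 1] + int_depths[config$n_clades]) / 2
  } else {
    (int_depths[config$n_clades - 1] + 1) / 2
  }

  # optional time warp: the between-clade splitting period [0, tcut] is
  # compressed toward the root ([0, 0.1]) and the within-clade period
  # [tcut, 1] onto [crown, 1], giving deep stems between clades and
  # late crown diversification within them
  if (!is.null(config$clade_crown_start)) {
    crown <- config$clade_crown_start
    stem_top <- min(0.1, crown / 2)
    warp <- function(d) ifelse(d <= tcut, d * stem_top / tcut,
                               crown + (d - tcut) * (1 - crown) / (1 - tcut))
    parent <- tree$edge[, 1]
    child <- tree$edge[, 2]
    tree$edge.length <- warp(depths[child]) - warp(depths[parent])
    depths <- ape::node.depth.edgelength(tree)
    tcut <- crown
  }

  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  crossing <- which(depths[parent] <= tcut & depths[child] > tcut)
  clade_tips <- lapply(crossing, function(e) sort(tips_under(tree, child[e])))
  ord <- order(-lengths(clade_tips),
               vapply(clade_tips, `[`, "", 1))
  clade_tips <- clade_tips[ord]
  clade_stem_child <- child[crossing][ord]
  clade_labels <- LETTERS[seq_along(clade_tips)]
  clade_map <- setNames(rep(NA_character_, n), sp)
  for (i in seq_along(clade_tips)) clade_map[clade_tips[[i]]] <- clade_labels[i]

  # --- sequence evolution --------------------------------------------
  # the radiation descends from a reference-like functional ancestor:
  # with default spacer lengths the root ITS is the synthetic reference
  # itself, so boundary transfer against it mirrors the real analysis;
  # non-default lengths fall back to random spacers at functional GC
  ref <- synthetic_reference()
  its1_root <- if (config$its1_length == 200L) seq_to_int(SYNTHETIC_ITS1)
               else random_spacer_int(config$its1_length, gc = 0.67)
  its2_root <- if (config$its2_length == 196L) seq_to_int(SYNTHETIC_ITS2)
               else random_spacer_int(config$its2_length, gc = 0.67)
  its_root <- c(its1_root, seq_to_int(SYNTHETIC_R58S), its2_root)
  L <- length(its_root)
  b1 <- config$its1_length
  b2 <- b1 + 164L
  its_rates <- rep(config$subst_rate, L)
  its_rates[(b1 + 1):b2] <- config$subst_rate * config$r58s_rate_scale
  annotation <- region_annotation(c(0L, b1), c(b1, b2), c(b2, L))

  cp_root <- random_spacer_int(config$cp_length, gc = 0.38)
  cp_rates <- rep(config$cp_subst_rate, config$cp_length)

  nnode <- n + tree$Nnode
  its_nodes <- vector("list", nnode)
  cp_nodes <- vector("list", nnode)
  root <- n + 1L
  its_nodes[[root]] <- its_root
  cp_nodes[[root]] <- cp_root
  eord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(eord$edge))) {
    p <- eord$edge[e, 1]
    ch <- eord$edge[e, 2]
    len <- eord$edge.length[e]
    its_nodes[[ch]] <- mutate_seq(its_nodes[[p]], its_rates, len)
    cp_nodes[[ch]] <- mutate_seq(cp_nodes[[p]], cp_rates, len)
  }

  # --- resolve events ------------------------------------------------
  # auto-picked recipients come from clades with at least 3 members
  # (so they have within-clade neighbours and leave clade seeds free)
  # and donors from clades with at least 2
  clade_sizes <- table(clade_map)
  eligible_recip <- sp[clade_sizes[clade_map[sp]] >= 3]
  donor_pool <- function(own) {
    setdiff(clade_labels[clade_sizes[clade_labels] >= 2], own)
  }
  events <- config$hybrid_events
  if (!length(events) && config$n_hybrid_events > 0) {
    recips <- sample(eligible_recip, config$n_hybrid_events)
    events <- lapply(recips, function(r) {
      list(recipient = r,
           donor_clade = sample(donor_pool(clade_map[[r]]), 1),
           time_fraction = config$hybrid_time_fraction)
    })
  }
  captures <- config$capture_events
  if (!length(captures) && config$n_capture_events > 0) {
    # a captured species must sit inside the crown group spanned by the
    # other members of its clade, or its own-tree clade membership is
    # topologically undefined and the incongruence signal ill-posed
    nested <- vapply(eligible_recip, function(r) {
      others <- setdiff(clade_tips[[match(clade_map[[r]], clade_labels)]], r)
      if (length(others) < 2) return(FALSE)
      r %in% tips_under(tree, ape::getMRCA(tree, others))
    }, logical(1))
    recips <- sample(setdiff(eligible_recip[nested],
                             vapply(events, `[[`, "", "recipient")),
                     config$n_capture_events)
    captures <- lapply(recips, function(r) {
      list(recipient = r,
           donor_clade = sample(donor_pool(clade_map[[r]]), 1),
           time_fraction = config$capture_time_fraction)
    })
  }

  # sample a donor-clade lineage at time t and evolve it to the
  # present; if the donor crown postdates t the event is deferred to
  # just after the crown split, so the transferred lineage always
  # nests inside the donor crown group rather than attaching to its stem
  sample_donor_lineage <- function(donor_clade, t, nodes, rates) {
    ci <- match(donor_clade, clade_labels)
    if (is.na(ci)) stop(sprintf("unknown donor clade '%s'", donor_clade))
    stem <- clade_stem_child[ci]
    crown <- if (stem > n) depths[stem] else depths[parent[match(stem, child)]]
    t <- min(max(t, crown + 0.02), 0.995)
    in_clade <- c(stem,
                  if (stem > n) phangorn::Descendants(tree, stem, "all") else integer(0))
    cand <- which(child %in% in_clade &
                    depths[parent] <= t & depths[child] > t)
    if (!length(cand)) {
      stop(sprintf("donor clade %s has no lineage at time %.2f", donor_clade, t))
    }
    e <- if (length(cand) == 1) cand else sample(cand, 1)
    # the transferred lineage diverges from the donor edge at time t:
    # under the symmetric model the sequence there is the child endpoint
    # mutated back for (depth[child] - t), then evolved to the present
    x <- mutate_seq(nodes[[child[e]]], rates, depths[child[e]] - t)
    list(seq = int_to_seq(mutate_seq(x, rates, 1 - t)),
         rep_tip = sort(tips_under(tree, child[e]))[1],
         time = t)
  }

  truth <- data.frame(species_id = sp, clade = unname(clade_map[sp]),
                      is_hybrid = FALSE, donor_clade = NA_character_,
                      n_true_versions = 1L, cp_captured = FALSE,
                      cp_donor_clade = NA_character_,
                      stringsAsFactors = FALSE)
  its_versions <- setNames(lapply(sp, function(s) {
    setNames(int_to_seq(its_nodes[[match(s, tree$tip.label)]]), "1")
  }), sp)
  graft_info <- list()

  for (ev in events) {
    r <- ev$recipient
    if (!r %in% sp) stop(sprintf("unknown recipient '%s'", r))
    if (identical(ev$donor_clade, clade_map[[r]])) {
      stop(sprintf("recipient %s cannot receive from its own clade", r))
    }
    don <- sample_donor_lineage(ev$donor_clade, ev$time_fraction,
                                its_nodes, its_rates)
    i <- match(r, truth$species_id)
    truth$is_hybrid[i] <- TRUE
    truth$donor_clade[i] <- ev$donor_clade
    if (stats::runif(1) < config$homogenization_prob) {
      truth$n_true_versions[i] <- 1L      # concerted evolution won
    } else {
      truth$n_true_versions[i] <- 2L
      its_versions[[r]] <- c(its_versions[[r]], "2" = don$seq)
      graft_info[[length(graft_info) + 1]] <-
        list(species = r, rep_tip = don$rep_tip, time = don$time)
    }
  }

  cp_seqs <- setNames(vapply(sp, function(s) {
    int_to_seq(cp_nodes[[match(s, tree$tip.label)]])
  }, ""), sp)
  capture_info <- list()
  for (ev in captures) {
    r <- ev$recipient
    if (identical(ev$donor_clade, clade_map[[r]])) {
      stop(sprintf("capture recipient %s cannot receive from its own clade", r))
    }
    don <- sample_donor_lineage(ev$donor_clade, ev$time_fraction,
                                cp_nodes, cp_rates)
    i <- match(r, truth$species_id)
    truth$cp_captured[i] <- TRUE
    truth$cp_donor_clade[i] <- ev$donor_clade
    cp_seqs[[r]] <- don$seq
    capture_info[[length(capture_info) + 1]] <-
      list(species = r, rep_tip = don$rep_tip, time = don$time)
  }

  # --- truth trees ---------------------------------------------------
  its_tree <- tree
  renamed <- setNames(sp, sp)
  for (g in graft_info) {
    new <- paste0(g$species, "#1")
    its_tree$tip.label[its_tree$tip.label == g$species] <- new
    renamed[g$species] <- new
  }
  for (g in graft_info) {
    at <- edge_crossing_on_path(its_tree, renamed[[g$rep_tip]], g$time)
    its_tree <- bind_tip(its_tree, paste0(g$species, "#2"),
                         where = at$child, position = at$position,
                         pendant = 1 - g$time)
  }
  cp_tree <- tree
  for (g in capture_info) {
    cp_tree <- ape::drop.tip(cp_tree, g$species)
    at <- edge_crossing_on_path(cp_tree, g$rep_tip, g$time)
    cp_tree <- bind_tip(cp_tree, g$species, where = at$child,
                        position = at$position, pendant = 1 - g$time)
  }

  structure(list(species_tree = tree, clade_map = clade_map,
                 its_versions = its_versions, cp_seqs = cp_seqs,
                 annotation = annotation, truth = truth,
                 its_tree_true = its_tree, cp_tree_true = cp_tree,
                 reference = ref, config = config),
            class = "radiation_sim")
}

#' @export
print.radiation_sim <- function(x, ...) {
  cat(sprintf("radiation_sim: %d species, %d clade(s), %d hybrid event(s), %d capture(s) [seed %d]\n",
              nrow(x$truth), length(unique(x$truth$clade)),
              sum(x$truth$is_hybrid), sum(x$truth$cp_captured),
              x$config$seed))
  invisible(x)
}

#' Generate cloned reads for one species' ITS versions
#'
#' Each clone is its version's sequence with independent per-base PCR
#' errors at `pcr_error_rate`. With two versions the support split must
#' give each version at least 2 clones, otherwise the version would be
#' undetectable by design.
#'
#' @param versions named character vector of 1 or 2 version sequences.
#' @param species_id,individual_id labels for the emitted [clone_set].
#' @param clones_per_species total clones.
#' @param split integer vector of per-version clone counts (default:
#'   all clones for a single version, `c(10, 5)`-style two-thirds/
#'   one-third for two).
#' @param pcr_error_rate per-base error probability.
#' @param seed optional seed (set only if non-NULL).
#' @return a [clone_set].
#' @export
generate_clone_reads <- function(versions, species_id,
                                 individual_id = "i1",
                                 clones_per_species = 15L, split = NULL,
                                 pcr_error_rate = 5e-4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nv <- length(versions)
  stopifnot(nv %in% 1:2)
  if (is.null(split)) {
    split <- if (nv == 1) clones_per_species else {
      c(clones_per_species - max(2L, floor(clones_per_species / 3)),
        max(2L, floor(clones_per_species / 3)))
    }
  }
  stopifnot(length(split) == nv, sum(split) == clones_per_species)
  if (nv == 2 && any(split < 2)) {
    stop("with two versions each part of the clone split must be >= 2")
  }
  assign <- rep(seq_len(nv), times = split)
  seqs <- vapply(assign, function(v) {
    x <- seq_to_int(versions[[v]])
    hit <- which(stats::runif(length(x)) < pcr_error_rate)
    if (length(hit)) {
      x[hit] <- (x[hit] - 1L + sample(1:3, length(hit), TRUE)) %% 4L + 1L
    }
    int_to_seq(x)
  }, "")
  clone_set(species_id, individual_id,
            sprintf("c%02d", seq_along(assign)), seqs)
}

#' Generate clone sets for every species of a simulation
#'
#' @param sim `radiation_sim`.
#' @param seed seed for the clone-level randomness (default: config
#'   seed + 500000).
#' @return named list of [clone_set] objects.
#' @export
simulate_clone_sets <- function(sim, seed = NULL) {
  stopifnot(inherits(sim, "radiation_sim"))
  if (is.null(seed)) seed <- sim$config$seed + 500000L
  set.seed(seed)
  cfg <- sim$config
  setNames(lapply(names(sim$its_versions), function(s) {
    v <- sim$its_versions[[s]]
    generate_clone_reads(v, species_id = s,
                         clones_per_species = cfg$clones_per_species,
                         split = if (length(v) == 2) cfg$clone_split else NULL,
                         pcr_error_rate = cfg$pcr_error_rate)
  }), names(sim$its_versions))
}

#' Knock one conserved 5.8S motif out of a sequence
#'
#' Substitutes a single base (drawn at random within the motif) so the
#' exact-match screen no longer finds it; used to inject pseudogene
#' signal into simulated data.
#'
#' @param seq ungapped sequence containing the motif in its 5.8S region.
#' @param motif_index 1, 2 or 3.
#' @return the modified sequence.
#' @export
inject_motif_knockout <- function(seq, motif_index) {
  m <- R58S_MOTIFS[[motif_index]]
  at <- regexpr(m, seq, fixed = TRUE)
  if (at < 0) stop(sprintf("motif %d not present; cannot knock out", motif_index))
  pos <- at + sample(nchar(m), 1) - 1L
  old <- substr(seq, pos, pos)
  new <- sample(setdiff(BASES, old), 1)
  paste0(substr(seq, 1, pos - 1L), new,
         substr(seq, pos + 1L, nchar(seq)))
}

#' Depress the GC content of a sequence
#'
#' Converts randomly chosen G/C positions outside the 5.8S region to A
#' or T until the full-region GC content has dropped by at least
#' `drop`; emulates the GC erosion of a ribosomal pseudogene without
#' touching the conserved motifs.
#'
#' @param seq ungapped sequence.
#' @param annotation [region_annotation] of `seq`.
#' @param drop target GC drop as a fraction (default 0.15).
#' @return the modified sequence.
#' @export
inject_gc_drop <- function(seq, annotation, drop = 0.15) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  full <- (annotation$its1[1] + 1L):annotation$its2[2]
  spacer <- setdiff(full, (annotation$r58s[1] + 1L):annotation$r58s[2])
  gc_pos <- spacer[ch[spacer] %in% c("G", "C")]
  k <- ceiling(drop * length(full))
  if (k > length(gc_pos)) {
    stop("not enough G/C positions outside 5.8S to reach the requested drop")
  }
  flip <- sample(gc_pos, k)
  ch[flip] <- sample(c("A", "T"), k, replace = TRUE)
  paste(ch, collapse = "")
}

#' Run the full pipeline on a simulation and score it against truth
#'
#' Generates clone sets, filters and identifies versions, classifies
#' hybrid signatures, and (when the simulation contains capture events
#' or `check_capture = TRUE`) assigns clades seeded by event-free
#' species on the ITS and cpDNA trees and detects incongruence.
#' Results are compared per species with the simulation's truth table.
#' By default the incongruence stage consumes the simulation's true
#' trees — mirroring the analysis design, where phylogenies are inputs
#' — with `trees = "nj"` it instead estimates both trees by
#' neighbor-joining from minimum-difference distances.
#'
#' @param config a [sim_config].
#' @param check_capture also run the incongruence stage (default: only
#'   when the config contains capture events).
#' @param trees `"true"` (default) or `"nj"`; see above.
#' @return list with `truth`, `records` (hybrid-call table),
#'   `confusion` (`n_true_hybrids`, `true_positives`,
#'   `false_negatives`, `false_positives`), `incongruence` (or NULL)
#'   and `capture_flagged` (character vector of discordant species).
#' @export
end_to_end_recovery <- function(config, check_capture = NULL,
                                trees = c("true", "nj")) {
  trees <- match.arg(trees)
  sim <- simulate_radiation(config)
  if (is.null(check_capture)) {
    check_capture <- any(sim$truth$cp_captured)
  }
  clone_sets <- simulate_clone_sets(sim)
  tables <- identify_all_versions(clone_sets)
  records <- classify_hybrid_signature(tables)

  truth <- sim$truth
  flagged <- records$species_id[records$verdict == "hybrid_signature"]
  true_hyb <- truth$species_id[truth$is_hybrid & truth$n_true_versions == 2L]
  confusion <- c(n_true_hybrids = length(true_hyb),
                 true_positives = length(intersect(flagged, true_hyb)),
                 false_negatives = length(setdiff(true_hyb, flagged)),
                 false_positives = length(setdiff(flagged, true_hyb)))

  incong <- NULL
  capture_flagged <- character(0)
  if (check_capture) {
    if (trees == "nj") {
      # version-1 consensus per species from the recovered tables
      its_seqs <- lapply(tables, function(vt) {
        if (length(vt$versions)) vt$versions[[1]]$aligned_form
        else sim$its_versions[[vt$species_id]][[1]]
      })
      names(its_seqs) <- vapply(tables, function(vt) vt$species_id, "")
      cp_sets <- lapply(sim$cp_seqs, identity)
      t_its <- build_nj_tree(names(its_seqs), min_difference_matrix(its_seqs))
      t_cp <- build_nj_tree(names(cp_sets), min_difference_matrix(cp_sets))
    } else {
      t_its <- sim$its_tree_true
      t_cp <- sim$cp_tree_true
    }
    # clades are seeded by every event-free species they contain, so
    # each clade definition spans its full crown group
    clean <- truth$species_id[!truth$is_hybrid & !truth$cp_captured]
    defs <- split(clean, truth$clade[match(clean, truth$species_id)])
    defs <- defs[lengths(defs) >= 2]
    trans <- setNames(sub("#\\d+$", "", t_its$tip.label), t_its$tip.label)
    incong <- detect_incongruence(assign_clades(t_its, defs),
                                  assign_clades(t_cp, defs),
                                  label_translation = trans)
    capture_flagged <- unique(incong$taxon[incong$discordant])
  }
  list(truth = truth, records = records, confusion = confusion,
       incongruence = incong, capture_flagged = capture_flagged)
}

#' Write simulation outputs to a directory
#'
#' Emits `clones.fasta`, `cp.fasta`, `versions_truth.tsv`,
#' `its_true.nwk`, `cp_true.nwk` and a `config.yaml` echo.
#'
#' @param sim `radiation_sim`.
#' @param dir output directory (created if needed).
#' @param clone_sets optional pre-generated clone sets (default:
#'   [simulate_clone_sets] of `sim`).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, clone_sets = NULL) {
  stopifnot(inherits(sim, "radiation_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(clone_sets)) clone_sets <- simulate_clone_sets(sim)
  write_fasta(clone_sets, file.path(dir, "clones.fasta"))
  write_fasta(sim$cp_seqs, file.path(dir, "cp.fasta"))
  write_report(sim$truth, file.path(dir, "versions_truth.tsv"))
  write_newick(sim$its_tree_true, file.path(dir, "its_true.nwk"))
  write_newick(sim$cp_tree_true, file.path(dir, "cp_true.nwk"))
  cfg <- sim$config
  cfg$hybrid_events <- NULL
  cfg$capture_events <- NULL
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))],
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
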