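test_that("simulations are byte-identical under one seed", {
  a <- simulate_radiation(deep_divergence_config(seed = 4))
  b <- simulate_radiation(deep_divergence_config(seed = 4))
  expect_identical(a$its_versions, b$its_versions)
  expect_identical(a$cp_seqs, b$cp_seqs)
  expect_identical(a$truth, b$truth)
  expect_identical(ape::write.tree(a$its_tree_true),
                   ape::write.tree(b$its_tree_true))
  d <- simulate_radiation(deep_divergence_config(seed = 5))
  expect_false(identical(a$its_versions, d$its_versions))
})

test_that("the no-event regime yields one version everywhere", {
  sim <- simulate_radiation(sim_config(seed = 2))
  expect_true(all(sim$truth$n_true_versions == 1L))
  expect_false(any(sim$truth$is_hybrid))
  expect_false(any(sim$truth$cp_captured))
  expect_equal(lengths(sim$its_versions), setNames(rep(1L, 24),
                                                   sim$truth$species_id))
})

test_that("zero substitution rate collapses all species to one sequence", {
  sim <- simulate_radiation(sim_config(subst_rate = 0, cp_subst_rate = 0,
                                       seed = 3))
  its <- vapply(sim$its_versions, `[[`, "", 1)
  expect_equal(length(unique(its)), 1L)
  expect_equal(length(unique(sim$cp_seqs)), 1L)
})

test_that("event bookkeeping matches the truth table", {
  sim <- simulate_radiation(deep_divergence_config(seed = 6))
  expect_equal(sum(sim$truth$is_hybrid), 7L)
  expect_equal(sum(sim$truth$n_true_versions == 2L), 7L)
  expect_true(all(lengths(sim$its_versions)[
    sim$truth$species_id[sim$truth$n_true_versions == 2L]] == 2L))
  # homogenization removes second versions but not hybrid ancestry
  simh <- simulate_radiation(deep_divergence_config(seed = 6,
                                                    homogenization_prob = 1))
  expect_equal(sum(simh$truth$is_hybrid), 7L)
  expect_equal(sum(simh$truth$n_true_versions == 2L), 0L)
  expect_true(all(lengths(simh$its_versions) == 1L))
  # a single capture event marks exactly one species
  simc <- simulate_radiation(capture_only_config(seed = 2))
  expect_equal(sum(simc$truth$cp_captured), 1L)
  expect_false(any(simc$truth$is_hybrid))
})

test_that("donor clades differ from recipient clades", {
  for (seed in 1:5) {
    sim <- simulate_radiation(deep_divergence_config(seed = seed))
    hy <- sim$truth[sim$truth$is_hybrid, ]
    expect_true(all(hy$donor_clade != hy$clade))
  }
})

test_that("grafted version-2 leaves sit inside their donor clade in the true tree", {
  sim <- simulate_radiation(deep_divergence_config(seed = 8))
  truth <- sim$truth
  # seed every clade with all of its members, version-1 leaves renamed
  tips <- ifelse(truth$n_true_versions == 2L,
                 paste0(truth$species_id, "#1"), truth$species_id)
  defs <- split(tips, truth$clade)
  defs <- defs[lengths(defs) >= 2]
  m <- assign_clades(sim$its_tree_true, defs)
  hy <- truth[truth$n_true_versions == 2L, ]
  for (i in seq_len(nrow(hy))) {
    if (hy$donor_clade[i] %in% names(defs)) {
      expect_equal(unname(m[paste0(hy$species_id[i], "#2")]),
                   hy$donor_clade[i])
    }
    if (hy$clade[i] %in% names(defs)) {
      expect_equal(unname(m[paste0(hy$species_id[i], "#1")]), hy$clade[i])
    }
  }
})

test_that("clone reads reproduce their versions at zero error", {
  v <- c("1" = strrep("ACGT", 30))
  cs <- generate_clone_reads(v, "spZ", clones_per_species = 15L,
                             pcr_error_rate = 0, seed = 1)
  expect_equal(length(cs$clone_ids), 15L)
  expect_true(all(cs$sequences == v[[1]]))
  expect_error(generate_clone_reads(c("1" = "ACGT", "2" = "ACGA"), "spZ",
                                    clones_per_species = 15L,
                                    split = c(14L, 1L)),
               ">= 2")
})

test_that("clone generation is deterministic and split-respecting", {
  v <- c("1" = strrep("ACGT", 30), "2" = strrep("TGCA", 30))
  a <- generate_clone_reads(v, "spZ", split = c(13L, 2L),
                            pcr_error_rate = 5e-4, seed = 10)
  b <- generate_clone_reads(v, "spZ", split = c(13L, 2L),
                            pcr_error_rate = 5e-4, seed = 10)
  expect_identical(a$sequences, b$sequences)
  vt <- identify_versions(filter_singleton_polymorphisms(a))
  expect_equal(vapply(vt$versions, function(x) x$clone_support, 1L),
               c(13L, 2L))
  expect_setequal(vapply(vt$versions, function(x) x$aligned_form, ""),
                  unname(v))
})

test_that("pseudogene injections change exactly the targeted signal", {
  ref <- synthetic_reference()
  set.seed(21)
  ko <- inject_motif_knockout(ref$sequence, 2)
  m <- screen_motifs(ko, ref$annotation)
  expect_false(m[["motif2"]])
  expect_true(m[["motif1"]] && m[["motif3"]])

  low <- inject_gc_drop(ref$sequence, ref$annotation, drop = 0.12)
  expect_lte(gc_content(low), ref$gc_full - 0.12)
  expect_true(all(screen_motifs(low, ref$annotation)))
})

test_that("simulation output bundles round-trip through files", {
  sim <- simulate_radiation(capture_only_config(seed = 7))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(dir,
    c("clones.fasta", "cp.fasta", "versions_truth.tsv",
      "its_true.nwk", "cp_true.nwk", "config.yaml")))))
  sets <- read_clone_fasta(file.path(dir, "clones.fasta"))
  expect_length(sets, 24)
  tr <- read_newick(file.path(dir, "its_true.nwk"))
  expect_equal(sort(tr$tip.label), sort(sim$its_tree_true$tip.label))
})
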