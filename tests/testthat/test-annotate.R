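ref <- synthetic_reference()

test_that("the reference annotates itself with identical boundaries", {
  ann <- annotate_regions(ref$sequence, ref$sequence, ref$annotation)
  expect_equal(unclass(ann)[c("its1", "r58s", "its2")],
               unclass(ref$annotation)[c("its1", "r58s", "its2")])
})

test_that("an insertion inside ITS1 lengthens only ITS1", {
  ins <- "TTTTTTTTTT"
  query <- paste0(substr(ref$sequence, 1, 100), ins,
                  substr(ref$sequence, 101, nchar(ref$sequence)))
  ann <- annotate_regions(query, ref$sequence, ref$annotation)
  expect_equal(ann$its1, c(0L, 210L))
  expect_equal(ann$r58s - ref$annotation$r58s, c(10L, 10L))
  expect_equal(diff(ann$r58s), 164L)
  expect_equal(diff(ann$its2), diff(ref$annotation$its2))
})

test_that("flanking bases leave the transferred region lengths unchanged", {
  query <- paste0("GGATCC", ref$sequence, "TCTAGAGG")
  ann <- annotate_regions(query, ref$sequence, ref$annotation)
  expect_equal(diff(ann$its1), diff(ref$annotation$its1))
  expect_equal(diff(ann$r58s), 164L)
  expect_equal(diff(ann$its2), diff(ref$annotation$its2))
})

test_that("a non-ITS query fails annotation with a score-floor error", {
  set.seed(42)
  junk <- paste(sample(c("A", "T"), 400, replace = TRUE), collapse = "")
  expect_error(annotate_regions(junk, ref$sequence, ref$annotation),
               "annotation failure")
  expect_error(annotate_regions("ACGT", ref$sequence, ref$annotation),
               "100")
})

test_that("GC content counts G+C over non-N sites", {
  expect_equal(gc_content("GCGC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("GCATNN"), 0.5)
  expect_true(is.na(gc_content("NNNN")))
  expect_error(gc_content("ACGT", c(2, 2)), "empty")
  # invariance under complementation
  for (seed in 1:5) {
    set.seed(seed)
    s <- rand_seq(60)
    comp <- chartr("ACGT", "TGCA", s)
    expect_equal(gc_content(s), gc_content(comp))
  }
})

test_that("motif screening is exact within the 5.8S region", {
  m <- screen_motifs(ref$sequence, ref$annotation)
  expect_true(all(m))

  # single substitution in motif2 knocks out only motif2
  ko <- sub("GAATTGCAGAATCC", "GAATTGCACAATCC", ref$sequence, fixed = TRUE)
  m2 <- screen_motifs(ko, ref$annotation)
  expect_equal(unname(m2), c(TRUE, FALSE, TRUE))
  # tolerant mode recovers the single-substitution motif
  m2tol <- screen_motifs(ko, ref$annotation, max_mismatch = 1L)
  expect_true(all(m2tol))

  # a 5.8S region with no motifs at all
  bare <- paste0(substr(ref$sequence, 1, 200), strrep("AT", 82),
                 substr(ref$sequence, 365, 560))
  expect_false(any(screen_motifs(bare, ref$annotation)))
})

test_that("motifs are found despite small boundary-transfer error", {
  # shift the annotation 4 bases left; slack absorbs it
  ann_off <- region_annotation(c(0, 196), c(196, 360), c(360, 556))
  expect_true(all(screen_motifs(substr(ref$sequence, 1, 556), ann_off)))
})

test_that("pseudogene classification combines motif and GC reasons", {
  rep_ok <- classify_pseudogene(ref$sequence, ref$annotation,
                                reference_gc = ref$gc_full)
  expect_equal(rep_ok$verdict, "functional")
  expect_length(rep_ok$reasons, 0)
  expect_equal(rep_ok$gc_full, ref$gc_full)
  expect_equal(diff(ref$annotation$r58s), 164L)

  ko3 <- sub("TTTGAACGCA", "TTTGAACGCC", ref$sequence, fixed = TRUE)
  rep3 <- classify_pseudogene(ko3, ref$annotation, reference_gc = ref$gc_full)
  expect_equal(rep3$verdict, "putative_pseudogene")
  expect_equal(rep3$reasons, "missing_motif_3")

  low <- inject_gc_drop(ref$sequence, ref$annotation, drop = 0.15)
  repl <- classify_pseudogene(low, ref$annotation, reference_gc = ref$gc_full)
  expect_equal(repl$verdict, "putative_pseudogene")
  expect_equal(repl$reasons, "low_gc")

  # verdict is monotone: knocking a motif out of the low-GC copy can
  # only add reasons
  both <- classify_pseudogene(sub("TTTGAACGCA", "TTTGAACGCC", low, fixed = TRUE),
                              ref$annotation, reference_gc = ref$gc_full)
  expect_equal(both$verdict, "putative_pseudogene")
  expect_true(all(c("missing_motif_3", "low_gc") %in% both$reasons))
})

test_that("region sidecar files round-trip", {
  f <- withr::local_tempfile(fileext = ".regions")
  write_region_sidecar(ref$annotation, f)
  back <- read_region_sidecar(f)
  expect_equal(unclass(back)[c("its1", "r58s", "its2")],
               unclass(ref$annotation)[c("its1", "r58s", "its2")])
})
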