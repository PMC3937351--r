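make_set <- function(seqs) {
  clone_set("sp", "i1", sprintf("c%02d", seq_along(seqs)), seqs)
}

test_that("identical clones pass through the singleton filter untouched", {
  cs <- make_set(rep("ACGTACGT", 10))
  out <- filter_singleton_polymorphisms(cs)
  expect_equal(out$sequences, cs$sequences)
  expect_equal(attr(out, "modified_position_count"), 0L)
})

test_that("a base carried by a single clone is rewritten to the column majority", {
  seqs <- rep(strrep("C", 20), 5)
  substr(seqs[3], 12, 12) <- "T"
  out <- filter_singleton_polymorphisms(make_set(seqs))
  expect_equal(out$sequences[3], strrep("C", 20))
  expect_equal(attr(out, "modified_position_count"), 1L)
})

test_that("columns whose minority states all have two carriers are untouched", {
  seqs <- rep(strrep("A", 10), 4)
  substr(seqs[1], 7, 7) <- "G"
  substr(seqs[2], 7, 7) <- "G"
  out <- filter_singleton_polymorphisms(make_set(seqs))
  expect_equal(out$sequences, seqs)
})

test_that("the filter treats gaps as states and preserves shape", {
  seqs <- c("AC-TA", "AC-TA", "ACGTA")
  out <- filter_singleton_polymorphisms(make_set(seqs))
  # the G is the singleton at column 3; the gap pair is the majority
  expect_equal(out$sequences, rep("AC-TA", 3))
  expect_equal(out$alignment_length, 5L)
  expect_length(out$sequences, 3)
  expect_error(filter_singleton_polymorphisms(make_set("ACGT")), "< 2 clones")
})

test_that("the filter is idempotent and matches the brute-force oracle", {
  for (seed in 1:20) {
    cs <- random_clone_set(seed)
    once <- filter_singleton_polymorphisms(cs)
    twice <- filter_singleton_polymorphisms(once)
    expect_equal(twice$sequences, once$sequences)
    expect_equal(once$sequences, unname(oracle_filter_singletons(cs$sequences)))
  }
})

test_that("version identification applies the two-clone support rule", {
  hapA <- strrep("ACGT", 5)
  hapB <- paste0("T", substr(hapA, 2, 20))
  vt <- identify_versions(make_set(c(rep(hapA, 13), rep(hapB, 2))))
  expect_length(vt$versions, 2)
  expect_equal(vapply(vt$versions, function(v) v$clone_support, 1L), c(13L, 2L))
  expect_equal(vt$versions[[1]]$version_id, "1")
  expect_equal(vt$versions[[1]]$aligned_form, hapA)

  vt1 <- identify_versions(make_set(rep(hapA, 15)))
  expect_length(vt1$versions, 1)
  expect_equal(vt1$versions[[1]]$clone_support, 15L)
  expect_equal(vt1$discarded_clone_count, 0L)
})

test_that("unsupported haplotypes are discarded, not promoted", {
  hapA <- strrep("AC", 10)
  hapB <- paste0("G", substr(hapA, 2, 20))
  hapC <- paste0("T", substr(hapA, 2, 20))
  vt <- identify_versions(make_set(c(hapA, hapA, hapB, hapB, hapC)))
  expect_length(vt$versions, 2)
  expect_equal(vt$discarded_clone_count, 1L)
  orc <- oracle_group_versions(c(hapA, hapA, hapB, hapB, hapC))
  expect_equal(vapply(vt$versions, function(v) v$aligned_form, ""),
               unname(orc$haplotypes))

  expect_warning(vt0 <- identify_versions(make_set(c(hapA, hapB, hapC))),
                 "support")
  expect_length(vt0$versions, 0)
  expect_equal(vt0$discarded_clone_count, 3L)
})

test_that("version-pair divergence classification is boundary inclusive", {
  base <- strrep("ACGTT", 20)
  mk <- function(ndiff) {
    s <- base
    for (p in seq_len(ndiff)) {
      substr(s, p * 3, p * 3) <-
        setdiff(c("A", "C", "G", "T"), substr(base, p * 3, p * 3))[1]
    }
    s
  }
  v1 <- its_version("1", base, 10)
  expect_equal(classify_version_pair(v1, its_version("2", mk(33), 2)),
               "highly_divergent")
  expect_equal(classify_version_pair(v1, its_version("2", mk(2), 2)),
               "barely_divergent")
  expect_equal(classify_version_pair(v1, its_version("2", mk(10), 2)),
               "highly_divergent")
  expect_equal(classify_version_pair(v1, its_version("2", mk(9), 2)),
               "barely_divergent")
})

test_that("simulated clone sets with rare PCR error recover the true haplotypes", {
  base <- strrep("ACGGT", 30)
  hap2 <- base
  for (p in c(10, 50, 90)) substr(hap2, p, p) <- "A"
  for (seed in 1:10) {
    cs <- generate_clone_reads(c("1" = base, "2" = hap2), "spY",
                               clones_per_species = 15L, split = c(12L, 3L),
                               pcr_error_rate = 0.001, seed = seed)
    vt <- identify_versions(filter_singleton_polymorphisms(cs))
    haps <- vapply(vt$versions, function(v) v$aligned_form, "")
    expect_setequal(haps, c(base, hap2))
  }
})
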