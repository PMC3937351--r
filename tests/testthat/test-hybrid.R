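test_that("minimum differences are counted with pairwise gap/N deletion", {
  expect_equal(as.integer(count_min_differences("ACGTA", "ACGTA")), 0L)
  d <- count_min_differences("ACGT-", "ACTTG")
  expect_equal(as.integer(d), 1L)
  expect_equal(attr(d, "sites"), 4L)
  # N columns excluded in the same way as gaps
  expect_equal(as.integer(count_min_differences("ACNTA", "AGTTA")), 1L)
  # minimum over cross pairs
  expect_equal(as.integer(count_min_differences(c("AAAA", "ACGT"),
                                                c("TTTT", "ACGA"))), 1L)
  expect_error(count_min_differences("ACGT", "ACGTA"), "frame")
})

test_that("complete deletion removes columns gapped in any sequence", {
  # column 2 is gapped in one sequence of set_a only; complete mode
  # drops it for every pair
  d_pw <- count_min_differences(c("A-GT", "ACGT"), "ATGT")
  d_cm <- count_min_differences(c("A-GT", "ACGT"), "ATGT", mode = "complete")
  expect_equal(as.integer(d_pw), 0L)
  expect_equal(as.integer(d_cm), 0L)
  expect_equal(attr(d_cm, "sites"), 3L)
})

test_that("minimum difference is symmetric and monotone under union", {
  for (seed in 1:10) {
    set.seed(seed)
    a <- vapply(1:2, function(i) rand_seq(30), "")
    b <- vapply(1:3, function(i) rand_seq(30), "")
    extra <- rand_seq(30)
    d_ab <- as.integer(count_min_differences(a, b))
    expect_equal(as.integer(count_min_differences(b, a)), d_ab)
    expect_lte(as.integer(count_min_differences(a, c(b, extra))), d_ab)
  }
})

# construct a three-species scenario with controlled distances:
# spH carries two versions 23 apart; version 1 is 5 from spP, version 2
# is 15 from spG
make_tables <- function() {
  L <- 200
  base <- strrep("ACGGT", L / 5)
  mut <- function(s, positions, to = "T") {
    for (p in positions) {
      cur <- substr(s, p, p)
      substr(s, p, p) <- if (cur == to) "A" else to
    }
    s
  }
  v1 <- base
  v2 <- mut(base, seq(1, by = 2, length.out = 23))          # 23 from v1
  spP <- mut(base, seq(101, by = 2, length.out = 5))        # 5 from v1
  spG <- mut(v2, seq(102, by = 2, length.out = 15))         # 15 from v2
  vt <- function(sp, seqs) {
    structure(list(species_id = sp, individual_id = "i1",
                   versions = lapply(seq_along(seqs), function(i) {
                     its_version(as.character(i), seqs[[i]], 3L)
                   }),
                   discarded_clone_count = 0L, total_clones = 15L,
                   modified_position_count = 0L),
              class = "version_table")
  }
  list(vt("spH", c(v1, v2)), vt("spP", spP), vt("spG", spG))
}

test_that("the hybrid criterion flags versions closer to other species than to each other", {
  rec <- classify_hybrid_signature(make_tables())
  h <- rec[rec$species_id == "spH", ]
  expect_equal(h$d_v1_v2, 23L)
  expect_equal(h$d_v1_nearest, 5L)
  expect_equal(h$nearest_sp_v1, "spP")
  expect_equal(h$d_v2_nearest, 15L)
  expect_equal(h$nearest_sp_v2, "spG")
  expect_equal(h$verdict, "hybrid_signature")
  expect_equal(h$divergence_class, "highly_divergent")
  expect_equal(h$p_v1_v2, 23 / 200)
  # single-version species still get nearest distances
  s <- rec[rec$species_id == "spP", ]
  expect_equal(s$verdict, "single_version")
  expect_false(is.na(s$d_v1_nearest))
})

test_that("barely divergent co-occurring versions give no hybrid signature", {
  tabs <- make_tables()
  # replace spH's second version with one 2 bases from version 1
  v1 <- tabs[[1]]$versions[[1]]$aligned_form
  near <- v1
  substr(near, 1, 1) <- "T"
  substr(near, 3, 3) <- "A"
  tabs[[1]]$versions[[2]] <- its_version("2", near, 3L)
  rec <- classify_hybrid_signature(tabs)
  h <- rec[rec$species_id == "spH", ]
  expect_equal(h$d_v1_v2, 2L)
  expect_equal(h$verdict, "no_signature")
  expect_equal(h$divergence_class, "barely_divergent")
})

test_that("species with more than two versions are evaluated on the most divergent pair", {
  tabs <- make_tables()
  v1 <- tabs[[1]]$versions[[1]]$aligned_form
  mid <- v1
  substr(mid, 2, 2) <- "G"
  tabs[[1]]$versions <- c(tabs[[1]]$versions, list(its_version("3", mid, 2L)))
  rec <- classify_hybrid_signature(tabs)
  h <- rec[rec$species_id == "spH", ]
  expect_equal(h$n_versions, 3L)
  # version 3 differs from version 1 at one site only, so the most
  # divergent pair is (2,3) at 24 differences
  expect_equal(h$d_v1_v2, 24L)
  expect_match(h$note, "most divergent pair \\(2,3\\)|most divergent pair \\(3,2\\)")
})

test_that("nearest-species ties are reported comma-joined", {
  L <- 100
  base <- strrep("AC", L / 2)
  m <- function(s, p) { substr(s, p, p) <- "T"; s }
  tabs <- list(
    structure(list(species_id = "spA", individual_id = "i1",
                   versions = list(its_version("1", base, 2L)),
                   discarded_clone_count = 0L, total_clones = 2L,
                   modified_position_count = 0L), class = "version_table"),
    structure(list(species_id = "spB", individual_id = "i1",
                   versions = list(its_version("1", m(base, 1), 2L)),
                   discarded_clone_count = 0L, total_clones = 2L,
                   modified_position_count = 0L), class = "version_table"),
    structure(list(species_id = "spC", individual_id = "i1",
                   versions = list(its_version("1", m(base, 3), 2L)),
                   discarded_clone_count = 0L, total_clones = 2L,
                   modified_position_count = 0L), class = "version_table"))
  rec <- classify_hybrid_signature(tabs)
  expect_equal(rec$nearest_sp_v1[rec$species_id == "spA"], "spB,spC")
})

test_that("distance summary reports within range and highest between distance", {
  rec <- classify_hybrid_signature(make_tables())
  expect_equal(unname(distance_summary(rec)), c(23, 23, 15))
  expect_error(distance_summary(rec[rec$verdict == "single_version", ]),
               "no species")
})

test_that("summary arithmetic on a published-style distance table", {
  # seven species with two divergent versions: (within, n1, n2) rows
  rows <- list(c(23, 5, 15), c(20, 6, 14), c(23, 4, 11), c(19, 15, 11),
               c(35, 7, 11), c(24, 14, 11), c(26, 16, 11))
  rec <- do.call(rbind, lapply(seq_along(rows), function(i) {
    data.frame(species_id = paste0("sp", i), n_versions = 2L,
               d_v1_v2 = rows[[i]][1], p_v1_v2 = NA_real_,
               nearest_sp_v1 = "x", d_v1_nearest = rows[[i]][2],
               nearest_sp_v2 = "y", d_v2_nearest = rows[[i]][3],
               divergence_class = "highly_divergent",
               verdict = "hybrid_signature", note = "")
  }))
  expect_equal(unname(distance_summary(rec)), c(19, 35, 16))
  expect_equal(sum(rec$d_v1_v2 > rec$d_v1_nearest &
                     rec$d_v1_v2 > rec$d_v2_nearest), 7L)
})
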