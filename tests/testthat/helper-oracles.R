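# Independent brute-force oracles and fixture builders. These stay
# deliberately naive and separate from the package implementations
# they check.

BASES4 <- c("A", "C", "G", "T")

rand_seq <- function(n, alphabet = BASES4) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# brute-force singleton filter: per column, tally states by explicit
# looping and rewrite every state seen exactly once to the most common
# state (alphabetical on ties)
oracle_filter_singletons <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  for (j in seq_len(ncol(m))) {
    tally <- list()
    for (i in seq_len(nrow(m))) {
      st <- m[i, j]
      tally[[st]] <- c(tally[[st]], i)
    }
    if (length(tally) < 2) next
    sizes <- vapply(tally, length, 1L)
    states <- sort(names(tally))
    maj <- states[which.max(sizes[states])]
    for (st in names(tally)) {
      if (length(tally[[st]]) == 1L) m[tally[[st]], j] <- maj
    }
  }
  apply(m, 1, paste, collapse = "")
}

# exhaustive haplotype grouping: support counts per distinct sequence,
# ordered by descending support then first appearance
oracle_group_versions <- function(seqs, min_support = 2) {
  uniq <- unique(seqs)
  support <- vapply(uniq, function(u) sum(seqs == u), 1L)
  keep <- support >= min_support
  list(haplotypes = uniq[keep][order(-support[keep])],
       supports = sort(support[keep], decreasing = TRUE),
       discarded = sum(support[!keep]))
}

# plain Needleman-Wunsch global alignment score (no wraparound)
oracle_nw_score <- function(a, b, match = 2, mismatch = 7, indel = 7) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- -(0:n) * indel
  D[1, ] <- -(0:m) * indel
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else -mismatch
      D[i + 1, j + 1] <- max(D[i, j] + s, D[i, j + 1] - indel,
                             D[i + 1, j] - indel)
    }
  }
  D[n + 1, m + 1]
}

# brute-force wraparound alignment score: enumerate every start phase
# of the consensus and every total pattern length, align globally, and
# take the best. Pattern lengths far from the region length are cut by
# the exact bound score <= 2*min(m,L) - indel*|m-L| (every alignment of
# unequal lengths pays at least |m-L| indels), so the enumeration stays
# exact.
oracle_wraparound_score <- function(region, cons, match = 2, mismatch = 7,
                                    indel = 7) {
  m <- nchar(region)
  p <- nchar(cons)
  cyc <- strrep(cons, ceiling((m + p + p) / p) + 2)
  best <- -Inf
  for (s in 0:(p - 1)) {
    for (L in 1:(m + p)) {
      bound <- match * min(m, L) - indel * abs(m - L)
      if (bound <= best) next
      text <- substr(cyc, s + 1, s + L)
      sc <- oracle_nw_score(region, text, match, mismatch, indel)
      if (sc > best) best <- sc
    }
  }
  best
}

# distinct internal maximal gap intervals of an alignment (terminal
# runs excluded), counted directly from the gap mask
oracle_gap_intervals <- function(seqs) {
  ivs <- list()
  for (sq in seqs) {
    mask <- strsplit(sq, "")[[1]] == "-"
    L <- length(mask)
    i <- 1
    while (i <= L) {
      if (mask[i]) {
        j <- i
        while (j < L && mask[j + 1]) j <- j + 1
        if (i > 1 && j < L) ivs[[length(ivs) + 1]] <- c(i - 1, j)
        i <- j + 1
      } else i <- i + 1
    }
  }
  unique(ivs)
}

random_clone_set <- function(seed, n_clones = 8, len = 60) {
  set.seed(seed)
  base <- rand_seq(len)
  hap2 <- base
  for (pos in sample(len, 5)) {
    substr(hap2, pos, pos) <- sample(setdiff(BASES4, substr(base, pos, pos)), 1)
  }
  haps <- c(base, hap2)
  assign <- sample(1:2, n_clones, replace = TRUE, prob = c(0.7, 0.3))
  seqs <- vapply(assign, function(h) {
    s <- haps[h]
    if (runif(1) < 0.5) {   # sprinkle singleton-style noise
      pos <- sample(len, 1)
      substr(s, pos, pos) <- sample(BASES4, 1)
    }
    s
  }, "")
  clone_set("spX", "i1", sprintf("c%02d", seq_len(n_clones)), seqs)
}

random_gapped_alignment <- function(seed, n_taxa = 6, len = 50) {
  set.seed(seed)
  base <- rand_seq(len)
  out <- vapply(seq_len(n_taxa), function(i) {
    s <- strsplit(base, "")[[1]]
    n_gaps <- sample(0:3, 1)
    for (g in seq_len(n_gaps)) {
      gl <- sample(1:6, 1)
      st <- sample(len - gl, 1)
      s[st:(st + gl - 1)] <- "-"
    }
    paste(s, collapse = "")
  }, "")
  names(out) <- paste0("t", seq_len(n_taxa))
  out
}

# random non-periodic pattern: reject patterns equal to a rotation of
# themselves under any proper period
random_nonperiodic_pattern <- function(len) {
  repeat {
    p <- rand_seq(len)
    periodic <- any(vapply(seq_len(len - 1), function(d) {
      len %% d == 0 && p == strrep(substr(p, 1, d), len / d)
    }, logical(1)))
    if (!periodic) return(p)
  }
}
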