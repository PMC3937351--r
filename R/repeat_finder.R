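# Tandem-repeat detection: candidate periods from matching k-mer
# spacings, consensus by majority over copies, and scoring by wraparound
# alignment of the locus against tandem copies of the consensus with
# match/mismatch/indel weights and a minimum reportable score.

#' Tandem-repeat search parameters
#'
#' Defaults follow the conventional repeat-search weighting: match +2,
#' mismatch and indel penalties 7 (applied as negative scores), minimum
#' alignment score 50.
#'
#' @param match match weight (positive).
#' @param mismatch mismatch penalty (positive magnitude).
#' @param indel indel penalty (positive magnitude).
#' @param min_score minimum reportable alignment score.
#' @param max_period largest repeat period considered (default 500).
#' @param k k-mer size used for candidate-period discovery (default 5).
#' @return list of class `repeat_params`.
#' @export
repeat_params <- function(match = 2L, mismatch = 7L, indel = 7L,
                          min_score = 50L, max_period = 500L, k = 5L) {
  stopifnot(match > 0, mismatch > 0, indel > 0, min_score > 0,
            max_period > 0, k >= 2)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 indel = as.integer(indel), min_score = as.integer(min_score),
                 max_period = as.integer(max_period), k = as.integer(k)),
            class = "repeat_params")
}

round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

# Wraparound global alignment of a region against cyclic repetitions of
# a consensus pattern: free choice of start and end phase in the
# pattern; pattern-character skips and region-character skips both cost
# the indel penalty. Returns the optimal score plus match/aligned-column
# counts from the traceback.
wraparound_align <- function(region, cons, match = 2L, mismatch = 7L,
                             indel = 7L) {
  r <- strsplit(region, "", fixed = TRUE)[[1]]
  cch <- strsplit(cons, "", fixed = TRUE)[[1]]
  m <- length(r)
  p <- length(cch)
  D <- matrix(-Inf, m + 1, p)
  P <- matrix(0L, m + 1, p)
  D[1, ] <- 0
  for (i in seq_len(m)) {
    row <- i + 1L
    # two passes so that the wrap dependency (column 1 on column p
    # within the same row) is resolved; a second full wrap can never
    # help because every within-row move costs -indel
    for (pass in 1:2) {
      for (j in seq_len(p)) {
        jm1 <- if (j == 1L) p else j - 1L
        sub <- if (r[i] == cch[j]) match else -mismatch
        best <- D[row - 1L, jm1] + sub
        mv <- 1L
        alt <- D[row - 1L, j] - indel
        if (alt > best) { best <- alt; mv <- 2L }
        alt <- D[row, jm1] - indel
        if (alt > best) { best <- alt; mv <- 3L }
        if (best > D[row, j]) { D[row, j] <- best; P[row, j] <- mv }
      }
    }
  }
  j <- which.max(D[m + 1L, ])
  score <- D[m + 1L, j]
  # traceback for match / aligned-column counts
  i <- m + 1L
  matches <- 0L
  aligned <- 0L
  while (i > 1L) {
    mv <- P[i, j]
    if (mv == 1L) {
      aligned <- aligned + 1L
      if (r[i - 1L] == cch[j]) matches <- matches + 1L
      i <- i - 1L
      j <- if (j == 1L) p else j - 1L
    } else if (mv == 2L) {
      aligned <- aligned + 1L
      i <- i - 1L
    } else if (mv == 3L) {
      aligned <- aligned + 1L
      j <- if (j == 1L) p else j - 1L
    } else break
  }
  list(score = score, matches = matches, aligned = aligned)
}

# Majority consensus over the tandem copies of a candidate region
# (partial last copy included; ties broken alphabetically).
copies_consensus <- function(chars, period) {
  vapply(seq_len(period), function(t) {
    states <- chars[seq(t, length(chars), by = period)]
    counts <- table(states)
    names(counts)[which.max(counts)]
  }, "")
}

#' Find tandem repeats in an ungapped sequence
#'
#' Candidate periods are discovered from the spacings between repeated
#' k-mers; each candidate locus is extended by an X-drop scan of the
#' lag-d self-match, a consensus is built by per-position majority over
#' the copies, and the locus is scored by wraparound alignment against
#' cyclic repetitions of that consensus. Hits scoring at least
#' `min_score` are reported, reduced to the best-scoring hit per locus
#' (ties: smaller period, then leftmost).
#'
#' @param seq ungapped nucleotide sequence.
#' @param params [repeat_params].
#' @return data frame with columns `start`, `end` (0-based half-open),
#'   `consensus_pattern`, `consensus_size`, `copy_number` (one decimal,
#'   half-up), `percent_matches` (integer), `score`, `region_label`
#'   (always `"unassigned"`; see [assign_repeat_region]). Zero rows when
#'   nothing reaches `min_score`.
#' @export
find_tandem_repeats <- function(seq, params = repeat_params()) {
  seq <- clean_sequence(seq, "sequence")
  if (grepl("-", seq, fixed = TRUE)) {
    stop("tandem-repeat search requires an ungapped sequence")
  }
  n <- nchar(seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      consensus_pattern = character(0),
                      consensus_size = integer(0), copy_number = numeric(0),
                      percent_matches = integer(0), score = integer(0),
                      region_label = character(0), stringsAsFactors = FALSE)
  k <- params$k
  if (n < 2L * k) return(empty)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  occ <- split(starts, kmers)
  occ <- occ[lengths(occ) >= 2L]
  cands <- unique(do.call(rbind, lapply(occ, function(pos) {
    d <- diff(pos)
    ok <- d >= 1L & d <= params$max_period
    if (!any(ok)) return(NULL)
    cbind(pos = pos[-length(pos)][ok], period = d[ok])
  })))
  if (is.null(cands) || !nrow(cands)) return(empty)

  xdrop <- 3L * params$mismatch
  seen <- character(0)
  hits <- list()
  for (ci in seq_len(nrow(cands))) {
    i <- cands[ci, "pos"]
    d <- cands[ci, "period"]
    j0 <- i + d
    if (j0 > n) next
    # X-drop extension of the lag-d self-match, rightward then leftward
    cur <- 0L; best <- -1L; hi <- j0 - 1L
    for (j in j0:n) {
      cur <- cur + (if (s[j] == s[j - d]) params$match else -params$mismatch)
      if (cur > best) { best <- cur; hi <- j }
      if (cur < best - xdrop) break
    }
    cur <- 0L; bestL <- 0L; lo <- j0
    if (j0 - 1L >= d + 1L) {
      for (j in (j0 - 1L):(d + 1L)) {
        cur <- cur + (if (s[j] == s[j - d]) params$match else -params$mismatch)
        if (cur > bestL) { bestL <- cur; lo <- j }
        if (cur < bestL - xdrop) break
      }
    }
    if (hi < j0) next
    rs <- lo - d              # first position of the repeat region
    re <- hi                  # last position (1-based inclusive)
    m <- re - rs + 1L
    if (m < ceiling(1.8 * d)) next
    key <- paste(rs, re, d, sep = ":")
    if (key %in% seen) next
    seen <- c(seen, key)
    chars <- s[rs:re]
    cons <- copies_consensus(chars, d)
    wa <- wraparound_align(paste(chars, collapse = ""),
                           paste(cons, collapse = ""),
                           match = params$match, mismatch = params$mismatch,
                           indel = params$indel)
    if (wa$score < params$min_score) next
    hits[[length(hits) + 1L]] <- data.frame(
      start = rs - 1L, end = re,
      consensus_pattern = paste(cons, collapse = ""),
      consensus_size = d,
      copy_number = round_half_up(m / d, 1),
      percent_matches = as.integer(round_half_up(100 * wa$matches / wa$aligned)),
      score = as.integer(wa$score),
      region_label = "unassigned", stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  # best-scoring hit per locus: greedy selection of non-overlapping hits
  out <- out[order(-out$score, out$consensus_size, out$start), , drop = FALSE]
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    ov <- keep & out$start < out$end[i] & out$end > out$start[i]
    keep[i] <- !any(ov)
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign a repeat hit to an annotated ITS region
#'
#' The hit is labelled with the region containing its midpoint
#' (ITS1, 5.8S, ITS2, or `unassigned` if the midpoint falls outside all
#' three).
#'
#' @param hits data frame from [find_tandem_repeats].
#' @param annotation [region_annotation] of the searched sequence.
#' @return the hit data frame with `region_label` filled in.
#' @export
assign_repeat_region <- function(hits, annotation) {
  stopifnot(inherits(annotation, "region_annotation"))
  if (!nrow(hits)) return(hits)
  mid <- (hits$start + hits$end) %/% 2L
  lab <- rep("unassigned", nrow(hits))
  lab[mid >= annotation$its1[1] & mid < annotation$its1[2]] <- "ITS1"
  lab[mid >= annotation$r58s[1] & mid < annotation$r58s[2]] <- "5.8S"
  lab[mid >= annotation$its2[1] & mid < annotation$its2[2]] <- "ITS2"
  hits$region_label <- lab
  hits
}
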