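# Simple indel coding: every distinct maximal internal gap run in the
# alignment becomes one binary presence/absence character; a taxon whose
# own gap strictly contains a character's interval is scored as
# inapplicable ("?"), and terminal (leading/trailing) gaps are treated
# as missing data rather than coded.

#' Code alignment gaps as binary indel characters
#'
#' Implements simple indel coding (Simmons & Ochoterena). Each maximal
#' gap run observed in at least one taxon — excluding leading and
#' trailing gap runs, which are treated as missing data — becomes one
#' character with interval `(start, end)` in 0-based half-open alignment
#' columns. A taxon scores `1` when it carries a gap run with exactly
#' that interval, `?` when one of its gap runs strictly contains the
#' interval or the interval lies inside its terminal gap, and `0`
#' otherwise.
#'
#' @param alignment named character vector of equal-length gapped
#'   sequences (at least 2 taxa).
#' @return list of class `indel_matrix` with `characters` (data frame
#'   `index`, `start`, `end`) and `matrix` (taxa x characters, entries
#'   `"0"`, `"1"`, `"?"`).
#' @export
code_indels <- function(alignment) {
  if (is.list(alignment)) alignment <- unlist(alignment)
  if (is.null(names(alignment)) || any(names(alignment) == "")) {
    stop("alignment sequences must be named by taxon")
  }
  if (length(alignment) < 2) stop("indel coding needs at least 2 taxa")
  alignment <- clean_sequence(alignment, "alignment")
  lens <- unique(nchar(alignment))
  if (length(lens) != 1) {
    stop(sprintf("ragged alignment: lengths %s",
                 paste(sort(lens), collapse = ", ")))
  }
  L <- lens
  taxa <- names(alignment)
  runs <- lapply(alignment, function(sq) {
    r <- rle(strsplit(sq, "", fixed = TRUE)[[1]] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths    # 0-based
    gap <- r$values
    data.frame(start = starts[gap], end = ends[gap])
  })
  internal <- lapply(runs, function(rn) {
    rn[rn$start > 0 & rn$end < L, , drop = FALSE]
  })
  terminal <- lapply(runs, function(rn) {
    rn[rn$start == 0 | rn$end == L, , drop = FALSE]
  })
  chars <- unique(do.call(rbind, internal))
  if (is.null(chars) || !nrow(chars)) {
    return(structure(list(characters = data.frame(index = integer(0),
                                                  start = integer(0),
                                                  end = integer(0)),
                          matrix = matrix(character(0), nrow = length(taxa),
                                          ncol = 0,
                                          dimnames = list(taxa, NULL))),
                     class = "indel_matrix"))
  }
  chars <- chars[order(chars$start, chars$end), , drop = FALSE]
  mat <- matrix("0", nrow = length(taxa), ncol = nrow(chars),
                dimnames = list(taxa, paste0("indel", seq_len(nrow(chars)))))
  for (ti in seq_along(taxa)) {
    own <- internal[[ti]]
    term <- terminal[[ti]]
    for (ci in seq_len(nrow(chars))) {
      cs <- chars$start[ci]
      ce <- chars$end[ci]
      if (any(own$start == cs & own$end == ce)) {
        mat[ti, ci] <- "1"
      } else if (any(own$start <= cs & own$end >= ce &
                       (own$start < cs | own$end > ce))) {
        mat[ti, ci] <- "?"
      } else if (nrow(term) && any(term$start <= cs & term$end >= ce)) {
        mat[ti, ci] <- "?"
      }
    }
  }
  structure(list(characters = data.frame(index = seq_len(nrow(chars)),
                                         start = chars$start,
                                         end = chars$end,
                                         row.names = NULL),
                 matrix = mat),
            class = "indel_matrix")
}

#' @export
print.indel_matrix <- function(x, ...) {
  cat(sprintf("indel_matrix: %d taxa, %d character(s)\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Write an indel character matrix and its character key
#'
#' The matrix is written as TSV (taxon plus one 0/1/? column per
#' character); the key file maps each character index to its alignment
#' interval.
#'
#' @param im `indel_matrix` from [code_indels].
#' @param path matrix output file.
#' @param key_path optional key output file (default `paste0(path, ".key")`).
#' @return `path`, invisibly.
#' @export
write_indel_matrix <- function(im, path, key_path = paste0(path, ".key")) {
  df <- data.frame(taxon = rownames(im$matrix), im$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_report(df, path)
  write_report(im$characters, key_path)
  invisible(path)
}

#' Append indel characters to a nucleotide alignment
#'
#' @param alignment named character vector of gapped sequences.
#' @param im `indel_matrix` coded from the same alignment.
#' @return named character vector: each sequence with its 0/1/? indel
#'   scores appended.
#' @export
concat_indel_characters <- function(alignment, im) {
  stopifnot(all(names(alignment) %in% rownames(im$matrix)))
  vapply(names(alignment), function(tx) {
    paste0(alignment[[tx]], paste(im$matrix[tx, ], collapse = ""))
  }, "")
}
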