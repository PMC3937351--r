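# A synthetic annotated reference ITS record. Boundary transfer needs a
# reference whose ITS1 / 5.8S / ITS2 boundaries are known; this record
# is constructed, not downloaded: GC-rich spacers typical of functional
# plant ITS (~0.65 overall) around a 164-bp 5.8S segment carrying the
# three conserved motifs. It is synthetic and is labelled as such
# everywhere it is shipped.

# 164-bp synthetic 5.8S carrying motif1/motif2/motif3 verbatim.
SYNTHETIC_R58S <- paste0(
  "CTTGCCTCACGTGGATGTAAGACTCCTAACCGATGAAGAACGTAGCTACTGCCGTGGGAC",
  "CCCTTTCGGAGAAAACTTTGGGCAGGGAATTGCAGAATCCGTTTGCGCCTGTTCATAGCG",
  "CTAGTTTGAACGCAGGGGGGCAGGCTGTTTCTAATCGAAGGGGT")

SYNTHETIC_ITS1 <- paste0(
  "GGCAATTAATTCGCGATGCTCGCGGCCTTCCGGGGACCAGCTCCCGCGGAGGGCCACGAT",
  "CCGCCGAACGGGCGGCTAGGGCAGGCTGCGGAGCCCTTCCCCCTTCCAGGGCCGGGTGGC",
  "TGCCGGGAGTTACAAACGCTGAGGGAGTAGCCTGCCGACTATGGGCGCGCTTCTCTCGCC",
  "GACGCACGGCAGCTCGAGGC")

SYNTHETIC_ITS2 <- paste0(
  "CTGAGTGATCCCGCCAGCCGGAACAGACGTTCAGACGCGTTGCGCTCGGGCGCCCTCCGC",
  "GCGGTCACTCGCGGACAGAGCGTAAGGGGAGGGTGGACGCCCCCCAGCCGCCGGGGCGTA",
  "CTACAGTATCGGTGCGTCAACGGCAGCCGGCAGCGCGGTGGGACTGTGGCCCCCCATAGC",
  "CGTACATTCGGTCCGA")

#' Synthetic annotated reference ITS record
#'
#' A constructed 560-bp ITS1–5.8S–ITS2 record with known boundaries,
#' used as the annotation reference in examples, simulations and
#' pipelines. The 5.8S segment (164 bp) carries the three conserved
#' motifs verbatim; the spacers have the high GC content characteristic
#' of functional plant ITS. This record is synthetic — it stands in for
#' an annotated GenBank reference where one is not supplied.
#'
#' @return list with `sequence` (560-base string), `annotation`
#'   ([region_annotation]: ITS1 `[0,200)`, 5.8S `[200,364)`, ITS2
#'   `[364,560)`) and `gc_full` (GC fraction over the full record).
#' @export
synthetic_reference <- function() {
  seqn <- paste0(SYNTHETIC_ITS1, SYNTHETIC_R58S, SYNTHETIC_ITS2)
  ann <- region_annotation(its1 = c(0L, 200L), r58s = c(200L, 364L),
                           its2 = c(364L, 560L))
  list(sequence = seqn, annotation = ann, gc_full = gc_content(seqn))
}
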