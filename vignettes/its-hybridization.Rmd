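---
title: "Detecting hybridization from cloned ITS sequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hybridization from cloned ITS sequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

The nuclear ribosomal internal transcribed spacer region
(ITS1–5.8S–ITS2) exists in hundreds of tandem copies per plant genome.
Concerted evolution normally homogenises these copies, so one
individual yields one ITS sequence. After hybridization, however, an
individual can carry two divergent ITS lineages — one from each
parental lineage — until concerted evolution catches up, which can take
thousands to millions of generations. In groups that radiated recently,
divergent intra-individual ITS copies and conflicts between nuclear and
chloroplast phylogenies are therefore two complementary signatures of
reticulate evolution.

`reticulITS` implements the full inference chain from cloned ITS
sequences to hybridization calls:

1. **Clone-error filtering** — PCR polymerase misincorporation produces
   base changes seen in a single clone; any state carried by exactly
   one clone in an alignment column is replaced by the column majority.
2. **Version identification** — clones are grouped by exact post-filter
   sequence identity; a haplotype class supported by at least two
   clones is accepted as an ITS *version*.
3. **Pseudogene screen** — each version is checked for the three
   conserved 5.8S motifs required for correct ITS2 proximal-stem
   formation and for depressed GC content relative to a functional
   reference; failing copies are putative pseudogenes and are excluded
   from hybrid inference.
4. **Hybrid-signature classification** — an individual whose two ITS
   versions are *less similar to one another than each is to a sequence
   found in another species* is inferred to have hybrid ancestry. All
   distances are minimum difference counts over aligned positions with
   pairwise gap/`N` deletion.
5. **Cytonuclear incongruence** — species assigned to different major
   clades by the ITS and chloroplast trees indicate hybridization (for
   example chloroplast capture) even where concerted evolution has
   already collapsed the nuclear signal.

Supporting stages — reference-based ITS1/5.8S/ITS2 boundary transfer,
tandem-repeat detection, and simple indel coding — reproduce the
descriptive statistics such a survey reports.

# Distance model and the hybrid criterion

For two sets of aligned sequences the package counts, for every cross
pair, the positions at which both members carry an unambiguous base and
the bases differ, and takes the minimum over pairs
(`count_min_differences()`). Using minimum counts makes the criterion
conservative: a species is only called hybrid when even the *closest*
foreign sequence is nearer to each of its versions than the versions
are to each other. The proportional form (count divided by compared
sites) is reported alongside. A `complete` deletion mode — excluding
every column that is gapped or ambiguous in *any* sequence under
comparison — is available; counts including indel columns and counts
with pairwise deletion can differ noticeably for gappy alignments,
which is worth keeping in mind when comparing published figures
computed under different conventions.

Within one individual, version pairs are classed as *barely divergent*
(intraspecific variation, typically 1–3 sites) or *highly divergent*
(divergent paralogues, typically tens of sites). The boundary,
`divergence_threshold = 10`, is configurable and sits in the empirically
empty zone between the two regimes; the classification is
boundary-inclusive. Only highly divergent pairs enter the
distance-summary statistics.

# Clone filtering choices

The filtering rule replaces a singleton state with the column majority
(ties broken alphabetically) rather than dropping the clone or the
column, keeping the alignment rectangular and the clone count constant;
the filter is idempotent. Gap characters are treated as states like any
base. What counts as "singleton" is evaluated per column, so a clone
may be corrected at one column and untouched elsewhere. Version
equivalence after filtering is exact sequence identity — no fuzzy
clustering — so residual within-version variation across individuals is
preserved rather than averaged away.

# Boundary annotation and the pseudogene screen

Region boundaries are transferred from an annotated reference through a
pairwise alignment (match +1, mismatch −1, gap −2 per position;
terminal gaps free, so primer-derived flanks do not distort the
mapping). Each reference boundary maps to the query position aligned
with it, pushed rightward across query gaps. An alignment scoring below
`0.3 × min(length)` raises an annotation-failure error rather than
returning nonsense coordinates. The package ships a *synthetic*
annotated reference (`synthetic_reference()`: ITS1 200 bp, 5.8S 164 bp,
ITS2 196 bp, overall GC 0.65, all three conserved motifs verbatim) for
simulations and examples; for real data the user supplies their own
annotated reference record.

Motif search is exact substring matching within the annotated 5.8S
region ±5 bp of slack (an edit-distance-1 mode exists but is off by
default, since functional copies are expected to carry the motifs
unaltered). The low-GC reason fires when full-region GC falls more than
`gc_drop` (default 0.10) below the reference GC. A copy is a putative
pseudogene exactly when at least one reason fires. In the pipeline,
flagged versions are excluded from hybrid classification and the
affected species is marked — the screen's role is to prevent pseudogene
copies from masquerading as hybridization signal, and exclusion is the
conservative operationalisation (it is toggleable).

# Tandem repeats

`find_tandem_repeats()` is a self-contained reimplementation of
weighted tandem-repeat search, not a clone of any particular tool:
candidate periods come from the spacings of repeated 5-mers, each
candidate locus is extended by an X-drop scan of the lag-*d*
self-match, a consensus is built by per-position majority over the
copies, and the locus is scored by *wraparound* dynamic programming
against cyclic repetitions of the consensus with weights match +2,
mismatch −7, indel −7 and minimum reportable score 50 (all
configurable). Free choice of entry and exit phase in the pattern makes
the score independent of where the array starts within its period.
Overlapping candidates are reduced to the best-scoring hit per locus
(ties: smaller period, then leftmost). Copy number is reported to one
decimal, rounded half-up; percent matches is the matched fraction of
aligned columns from the traceback. Note that for a nearly-perfect
array the maximiser may legitimately be a truncated, phase-rotated
locus that excludes a defect near the array edge — scores, not copy
counts, are optimised. The full statistical significance model of
probabilistic repeat finders is out of scope; the scoring itself is
verified in the test suite against a brute-force enumeration over all
phases and pattern lengths.

# Indel coding

`code_indels()` implements simple indel coding: every distinct maximal
internal gap run becomes one binary character; a taxon scores 1 with an
identical run, `?` when its own longer gap strictly contains the
interval, 0 otherwise. Leading and trailing gap runs are treated as
missing data — they usually reflect incomplete sequences rather than
evolutionary deletions — so they generate no characters, and characters
falling inside a taxon's terminal gap are scored `?` for that taxon.

# Trees, clades and incongruence

Phylogenies are *inputs* to this package: tree inference (model
selection, ML, Bayesian analysis) is deliberately out of scope. A
neighbor-joining utility (`build_nj_tree()`, wrapping the standard NJ
implementation with outgroup or midpoint rooting) is provided as
plumbing so the synthetic pipeline can build trees from its own
distance matrices.

Major clades are operationalised by *seed taxa*: a clade is the full
leaf set of the most recent common ancestor of its seeds, and every
leaf belongs to the smallest clade containing it. This mirrors how
clades are marked on published trees, but makes the definition
explicit, user-editable configuration rather than ground truth. Two
practical consequences: seeds should span the clade (seeding with all
known members is safer than with two arbitrary ones), and a species
attached to a clade's stem — above its crown — is *unassigned*, not a
member. Incongruence records compare per-taxon clade assignments
between two trees; intra-individual version leaves (`species#1`,
`species#2`) are translated to their species label when matched against
a one-leaf-per-species chloroplast tree. Discordance calls are purely
topological; support values are carried through but not used.

# The simulator: what it emulates, and what it does not

`simulate_radiation()` grows a pure-birth species tree (depth
normalised to 1), cuts it into major clades at the point where
`n_clades` lineages coexist, evolves ITS and cpDNA along it under a
single-parameter per-site substitution model, and then applies the
processes the pipeline is supposed to detect:

* **Hybridization** grafts a second ITS version sampled from a donor
  clade lineage at the event time and evolves it to the present. Under
  the symmetric substitution model the sequence at time *t* on an edge
  is obtained by mutating back from the edge's child endpoint, so the
  transferred version coalesces with the donor lineage exactly at the
  event time.
* **Concerted evolution** removes the second version with probability
  `homogenization_prob`, erasing the nuclear signal while leaving the
  truth table aware of the event.
* **Chloroplast capture** replaces a recipient's cpDNA with a
  donor-clade lineage's.
* **PCR error** perturbs each clone independently at
  `pcr_error_rate` per base (default 5 × 10⁻⁴).

The deep-divergence preset (`deep_divergence_config()`) encodes the
study regime the pipeline targets: the between-clade splitting period
is compressed toward the root and clade crowns open only at depth 0.75,
so clades are separated by long stems (between-clade divergence roughly
20–40 substitutions over a 560-bp ITS at rate 0.035 per site per unit
depth, with the 164-bp 5.8S held invariant) while within-clade
neighbours sit at roughly 3–12 substitutions. Seven hybridization
events with no homogenization reproduce the situation where seven
species carry two divergent versions whose within-individual distances
(about 19–35) exceed every version-to-nearest-foreign-species distance
(≤ 16). These defaults are the preset's definition of the regime and
live in configuration, not in the analysis code.

Three regime conventions are worth stating explicitly. Auto-picked
event recipients are drawn from clades with at least three members, so
a recipient always has within-clade neighbours — the regime the
distance criterion presumes. Donor lineages always nest inside the
donor clade's crown group: if the requested event time predates the
donor crown, the event is deferred to just after the crown split
(attaching a transfer to a bare clade stem would make its clade
membership topologically undefined). And captured species are required
to sit inside the crown group spanned by the rest of their clade, which
is precisely the geometry in which cytonuclear discordance is
well-posed.

What the simulator does **not** emulate: indel evolution (simulated
alignments are gapless, so the indel coder is exercised on constructed
and randomised alignments instead), rate heterogeneity among lineages
or sites beyond the conserved 5.8S, coalescent gene-tree discordance,
gene conversion, and within-species population structure. Passing the
recovery tests therefore shows that the inference chain is correct
under its stated model, not that it is robust to every failure mode of
real data — alignment error in particular is assumed solved upstream,
since inputs are pre-aligned.

`end_to_end_recovery()` runs the incongruence stage on the simulation's
true trees by default, mirroring the analysis design in which
phylogenies are inputs. With `trees = "nj"` both trees are instead
estimated by neighbor joining from minimum-difference distances; this
route is subject to estimation noise at the shallow within-clade nodes
(in our checks it resolves the captured species exactly in 9 of 10
seeds, versus 25 of 25 with input trees).

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; gaps are excluded from
  ungapped coordinates.
* Sequences are uppercased on read, `U` maps to `T`, and anything
  outside `{A,C,G,T,N,-}` is rejected up front.
* Majority ties (clone filter, repeat consensus) break alphabetically;
  nearest-species ties are reported comma-joined rather than broken.
* `copy_number` and `percent_matches` round half-up, so 2.05 reports
  as 2.1 and 99.5 as 100.
* An all-`N` interval has undefined GC content (`NA`), and a zero-width
  interval is an error.
* A clone set with fewer than two clones cannot be singleton-filtered
  (error); a clone set in which no haplotype reaches support 2 yields
  an empty version list with a warning, not an error.
* A species with more than two versions is classified on its two most
  divergent versions and flagged in the record's `note`.

# Problem sizes

The shipped tests and the acceptance script run entirely on simulated
and constructed data: 24 species × 15 clones × 560 bp per simulation,
20 seeds for hybrid-recovery sweeps, 100 seeded clone sets and 100
random gapped alignments for the oracle comparisons, 50 pseudogene
injections, and brute-force repeat-score verification on arrays up to
200 bp. These sizes were chosen to match the scale of a single-genus
clone survey while keeping every oracle exhaustive.

# Limitations

The hybrid criterion cannot distinguish allopolyploidy, ancient
introgression and recent introgression — all three produce the same
two-version signature; resolving them needs population-level sampling
and more markers. Concerted evolution toward the maternal copy erases
the signal entirely, so sensitivity estimates from the simulator's
no-homogenization regime are upper bounds. Distances are raw counts
without multiple-hit correction, appropriate at the divergence scale of
a recent radiation but not beyond it. The clade formalism depends on
user-chosen seed taxa and rooted input trees; unrooted or poorly
sampled trees will leave taxa unassigned rather than guess.
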