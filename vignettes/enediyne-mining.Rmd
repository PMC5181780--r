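---
title: "Mining genome collections for enediyne biosynthetic gene clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining genome collections for enediyne biosynthetic gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edmine)
```

## The problem

Enediynes are bacterial natural products built around a 9- or 10-membered
carbocycle carrying two acetylenic groups conjugated to a double bond; their
DNA-cleaving diradical chemistry makes them among the most cytotoxic
molecules known, and several serve as antibody–drug-conjugate payloads. All
known enediyne biosynthetic gene clusters (BGCs) share a conserved five-gene
polyketide synthase cassette — here labelled E3, E4, E5, E (the iterative
PKS itself) and E10. That conservation makes the cassette a screening handle:
a large strain collection can be surveyed by PCR for the cassette, positive
strains can be dereplicated so only genuinely distinct clusters are pursued,
and the sequenced clusters can be compared and classified before any
fermentation work is invested.

`edmine` implements that computational workflow end to end:

1. **In-silico PCR screen** (`screen_cohort()`): two primer pairs target the
   E5/E and E/E10 junctions. A strain amplifying with both pairs carries the
   E5/E/E10 genes in one block ("clustered"); amplification with exactly one
   pair indicates a cassette with E5 or E10 located elsewhere ("split");
   no product is a negative. Products are summarised by a predicted melting
   temperature, the in-silico surrogate of the melting-curve peak read out in
   the high-throughput assay.
2. **Dereplication** (`identity_matrix()`, `collapse_clades()`): hits are
   compared through the translated 1-kb internal fragment of E; strains with
   at least 90% amino-acid identity are collapsed into one clade, and a
   medoid representative per clade is chosen (`pick_representatives()`).
   A neighbor-joining tree (`nj_tree()`) summarises the relationships.
3. **Genome neighborhood network** (`all_vs_all()`, `build_gnn()`,
   `detect_families()`): proteins of the representative clusters and of
   labelled reference clusters are aligned all-versus-all (Smith–Waterman);
   pairs significant at an E-value threshold of 1e-6 become edges, connected
   components become protein families, and family labels transfer from the
   reference members by majority vote.
4. **Classification** (`predict_ring_size()`, `predict_moieties()`,
   `novelty_report()`): ring size follows the exclusive-presence rule — an
   E2 family hit without R3 predicts a 9-membered product, R3 without E2 a
   10-membered one. Peripheral moieties (chromoprotein/apoprotein, β-amino
   acid, amino sugar, benzoxazolinate) are predicted from curated gene sets,
   and unknown families and singletons are counted as a novelty measure.

## Alignment and significance conventions

Percent identity is defined over **all** alignment columns, including gap
columns. Some convention must be fixed for a 90% cutoff to be reproducible;
this is the most conservative choice (gaps can only lower identity), and for
the generator's substitution-only evolution model it coincides with ungapped
identity.

Global (Needleman–Wunsch) alignments use BLOSUM62 with affine gap penalties
`gap_open = 10`, `gap_extend = 0.5`, where a gap of length $L$ costs
`gap_open + L * gap_extend` — the familiar needle-style parameterisation
under which published cassette identity ranges were most plausibly computed.
The package's substitution matrices carry the 20 amino acids plus `X`, which
scores 0 against everything.

Local (Smith–Waterman) alignments feeding the network use `gap_open = 11`,
`gap_extend = 1` and convert scores to expected chance-hit counts with the
Karlin–Altschul formula

$$E = K \, m \, n \, e^{-\lambda S},$$

with $\lambda = 0.267$, $K = 0.041$ — the published statistics for *gapped*
BLOSUM62 alignment at exactly those penalties — and $m \times n$ the product
of the two sequence lengths (a pairwise, self-contained search-space
convention; any database-wide convention would rescale all E-values by a
constant and leave thresholding order intact). The two stages deliberately
use different gap penalties: with the weaker `10/0.5` extension penalty,
local alignments of unrelated 200–400-residue sequences drift out of the
logarithmic score regime the Karlin–Altschul theory assumes, and E-values
computed with the `11/1` constants overstate their significance enough to
create spurious network edges. Matching penalties to their published
statistics removes that artifact.

Two E-value thresholds matter: `1e-6`, the working threshold at which the
network is built, and `1e-75`, a strict threshold used to re-partition the
one family in which the homologous marker proteins E2, E3 and R3 merge.
The ring-size rule needs the subfamilies separated; `detect_families()`
therefore re-runs component detection inside marker-containing families
using only strict edges. Family detection is deterministic (components, not
stochastic community detection), invariant to input file order, and family
sets at a stricter threshold are always nested within the looser ones.

## The synthetic cohort generator

Deposited genomes and the original screening amplicons are not required for
any of the package's tests: `generate_cohort()` produces mock genome
collections in which every relevant property is planted and recorded in a
truth table.

* **Reference proteins** — a fixed synthetic set (package constant):
  the five cassette proteins (E 400 aa; E3/E4/E5/E10 220–260 aa), the
  markers E2 and R3 (210 aa, both distant homologs of E3 at 40% and 35%
  identity, so the three merge at 1e-6 and separate at 1e-75, as their real
  counterparts do), an apoprotein, and three moiety gene sets (3–4 genes
  each, 140–180 aa).
* **Between-clade structure** — the configured band (default 0.33–0.69,
  the band reported for pairwise comparisons of known cassettes) is the band
  of *pairwise* fragment identities. Each clade founder is evolved from the
  common reference at an identity drawn uniformly from the square root of
  the band: two founders at $\sqrt{p}$ and $\sqrt{q}$ to the reference sit
  near $\sqrt{pq}$ to each other, so pairwise identities land in the band
  itself (up to a small back-substitution term and binomial placement noise
  of roughly ±2–3 points on a 333-residue fragment).
* **Within-clade structure** — each clade has a pool of $2s$ variable
  positions with one fixed alternate residue each, where
  $s = \mathrm{round}((1-w)L)$ for within-clade identity $w$ (default 0.93);
  each strain substitutes a random $s$-subset. Identity to the founder is
  exactly $w$ and expected pairwise identity between clade mates is $w$ too.
  (Evolving strains independently from the founder would square the
  identity — $0.93^2 \approx 0.86$, *below* the 90% cutoff — and make clade
  recovery ill-posed.)
* **Conserved genes** — E3 and the markers evolve in a higher band (default
  0.80–0.90): the strict 1e-75 subfamily linkage that ring prediction relies
  on is arithmetically impossible for a 210-residue marker below roughly 70%
  identity, and the real marker genes are indeed the well-conserved
  components of these clusters. Other cassette and moiety genes use the
  clade's band identity; genes other than E carry no within-clade variation
  (dereplication only measures E).
* **Primer sites** — the default primers are 21-mers copied from the
  reference coding sequences at fixed anchor codons. Those codons are never
  substituted during evolution and are always reverse-translated with the
  reference codons, so every planted cassette contains exact binding sites
  (the screen's sensitivity statement is about the method, not about primer
  degeneracy). The two diagnostic anchors sit ~70 codons before the end of
  E5 (or E) and ~8 codons into E (or E10), giving products of ~350–750 bp
  for the default 100–500 bp intergenic spacers, inside the default
  300–3000 bp product window; the internal-fragment primers bound exactly
  the 999-bp codon-aligned window that `extract_internal_fragment()`
  computes for a 1200-bp E gene.
* **Architectures** — `clustered` places E5/E/E10 contiguously; `split_E5`
  and `split_E10` move the respective gene ≥ 10 kb downstream across pure
  intergenic spacer, so the corresponding primer pair cannot yield a product
  within the length window. The marker gene is planted on the minus strand,
  exercising strand handling end to end.
* **Decoys** — composition-preserving shuffles of the reference proteins:
  realistic residue composition with no residual homology (a chance
  Smith–Waterman hit at E ≤ 1e-6 would need a raw score above ~100 for
  these lengths; observed random maxima are near 60).
* **Determinism** — the whole cohort, including FASTA/GenBank output, is a
  pure function of the configuration and seed.

What the generator does **not** emulate: indels in the default evolution
model (an exact substitution count makes identity targets sharp; real
fragments would align with gaps), rearrangement or HGT, nucleotide-level
substitution models, primer mismatches in producers, and assembly artifacts.
Passing tests therefore demonstrate the correctness of the pipeline's logic
and statistics under the stated model, not robustness to degraded real-world
inputs — mismatch tolerance and product windows exist precisely for those
and are exercised separately with constructed cases.

## Numerical and degenerate-input choices

* Alignment traceback ties are resolved deterministically by the alignment
  engine; scores, identity percentages and all downstream decisions are
  traceback-independent under the substitution-only model.
* A local alignment with no positive-scoring residue pair is reported as an
  empty alignment with score 0 and identity 0.
* Neighbor joining can estimate negative branch lengths; these are clamped
  to zero with the deficit moved to the sibling edge, preserving path
  lengths through the parent.
* Clade collapsing treats identity exactly at the cutoff as linked
  (`>= cutoff`); single linkage (components) is the default because it is
  the order-independent analogue of collapsing a tree at a threshold, with
  complete linkage available via `linkage = "complete"`.
* `extract_internal_fragment()` rounds the centring offset down to a codon
  boundary and rounds non-multiple-of-3 windows down with a warning; CDS
  shorter than the window plus two codons is an error.
* Representative choice is the clade medoid (maximum summed identity to
  clade mates), ties lexicographic — the canonical order-free choice when no
  external ranking (titer, culturability) is available.
* With both markers present the ring call is `ambiguous` rather than an
  error: the exclusive-presence rule is simply inapplicable, and the case is
  reported as such.
* Moiety thresholds default to the majority of each gene set (1 for the
  single apoprotein gene); the real moiety gene tables live in supplementary
  material, so the shipped definitions are editable placeholders keyed to
  the four moiety names (`read_moiety_config()`).

## Problem sizes and runtime

The shipped tests and the acceptance script use cohorts of 14–38 genomes
(about 13–30 kb each), clade counts up to 28, protein counts up to ~320 in
the network stage, 1,000 random pairs for the brute-force alignment oracle
and 200 random additive matrices for the neighbor-joining oracle. These
sizes keep a full run in a few minutes on one CPU while leaving every
statistical margin wide (the strict-threshold linkage margin, the
clade-separation margin and the decoy significance margin are all factors
of several, not percent).

## Known limitations

* E-values use pairwise search spaces; absolute values are not comparable
  to database BLAST E-values (thresholds were chosen for this convention).
* The Tm model is the salt-adjusted GC/length formula — appropriate for
  0.5–2 kb products, not for oligo thermodynamics; it is a pluggable
  surrogate for melting-curve readout, not a PCR efficiency model.
* Families are connected components; a single promiscuous protein can
  bridge families at loose thresholds (the strict re-partition exists for
  exactly the one family where this matters).
* The identity-band construction is exact in expectation, not per pair;
  bands narrower than ~4 points between within- and between-clade settings
  are not guaranteed to separate.
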