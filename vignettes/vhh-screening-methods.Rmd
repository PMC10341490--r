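---
title: "Screening tumor-specific VHH binders from panning sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening tumor-specific VHH binders from panning sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VHHscreen)
```

## The problem

Whole-cell phage-display panning enriches a VHH (nanobody) library for
clones that bind a target tumor cell line. Sequencing the library before
selection (round 0) and after the final round turns binder discovery into
a counting problem: clones whose frequency rises steeply through panning
are binder candidates, and comparing several independently panned
libraries (one per cell line) separates mono-specific binders from
cross-reactive ones. `VHHscreen` implements this screening strategy as a
reusable pipeline:

1. **Read processing** — merge 2x300 bp paired-end amplicon reads,
   filter by expected errors, locate the amplicon primers, classify the
   hinge isotype (short IgG2-type vs long IgG3-type by which reverse
   primer matches), and translate in the primer-anchored frame.
2. **Clonotyping and ranking** — dereplicate amino-acid sequences into
   clonotypes, compute each clone's amplification fold (final-round
   frequency over round-0 frequency), and keep the top K = 50 per
   library.
3. **Phylogenetic grouping** — build neighbor-joining trees of the
   top-ranked clones from pairwise alignment p-distances and cut them
   into high-homology clusters; a cluster drawn from one library is a
   mono-specific candidate family, a mixed cluster is not.
4. **Cross-reactivity calling** — group clones across libraries by
   identical CDR3; a CDR3 present in two or more libraries' top lists
   flags a cross-reactive (multi-specific) family.

A ground-truthed panning simulator generates the paired-end FASTQ inputs
with known binder identities, so every stage is testable end to end
without the original sequencing archive.

## The ranking statistic

For a clone with final-round count $c_f$ in a library with $M_f$ merged
reads, and round-0 count $c_0$ out of $M_0$:

$$\mathrm{fold} = \frac{c_f / M_f}{\max(c_0, 1) / M_0}$$

The frequency denominator is the library's merged-read total — that
convention is forced by the summary-table arithmetic, where all
percentages are relative to the "number of merged sequences (100%)"
row. Clones unobserved at round 0 receive an effective floor count of 1
(configurable to a 0.5 pseudocount) so folds stay finite; such clones are
flagged `r0_floored`.

**Ranking eligibility.** Whether the original analysis applied an
abundance floor before ranking is not stated, so the package makes its
own choice: by default only clones observed in round 0 compete for top-K
slots. A fold with a floored denominator is not a measurement — it is an
upper bound scaled by an arbitrary floor — and at realistic error rates
the floored population is dominated by the sequencing-error shoulder of
abundant clones (see *Known limitations*). Round-0-unobserved clones are
still reported (`unranked_novel_clones.tsv`) and are re-admitted to
ranking when their final frequency reaches `novelMinFreq` (default
0.005): a clone at frequency $f$ spawns any specific single-substitution
read variant at frequency of order $f \times
\mathrm{error\ rate} / 3$, so a threshold at or above the per-base error
rate cannot be reached by the error shoulder of even a fully dominant
clone, while a genuinely abundant novel clone passes it easily.

## CDR3 extraction and identity

CDR3 is cut with an IMGT-like anchor convention: the conserved FR3
cysteine is the C of the last `[YFW][YFAVLI]C` motif within the first
110 residues (fallback: last C in that window), the conserved FR4
tryptophan is the W of the first `WG.G` at or after four residues past
the cysteine (fallback: first W after it); the loop between the anchors,
anchors excluded, is CDR3, accepted at 3-40 residues. Extraction
failures are statuses, not errors, so attrition stays countable.

CDR3 identity is matches over alignment length under global alignment
with gaps counted as mismatches. Cross-library grouping defaults to
exact CDR3 matching, with a single-linkage mode at >= 0.98 identity
mirroring the reported "98% sequence homology" phrasing; whether that
phrase was meant for the CDR3 or the whole VHH is ambiguous in the
source, so both modes exist and neither is asserted as the original
intent.

## Trees and clusters

Pairwise distances are p-distances on global pairwise alignments
(match-counting, terminal gaps excluded from the column count). The
original analysis used a commercial workbench with unstated settings; a
pairwise p-distance is reproducible, dependency-light, and adequate for
sets of at most a few hundred highly similar sequences — no multiple
alignment is attempted.

Neighbor joining is the Saitou-Nei algorithm with the Studier-Keppler
Q criterion. Numerical choices, all made for bit-reproducibility:

* ties in Q are broken by the smallest (i, j) label-index pair;
* a negative limb length is clamped to 0 with the deficit moved onto the
  sister limb, keeping their sum equal to the joined distance, which
  preserves exact recovery of additive matrices;
* the final three nodes join at a trifurcation (unrooted tree).

Clusters are the leaf sets on either side of every tree edge (all
maximal clades under every rooting) whose minimum pairwise homology
(1 − p-distance) reaches the threshold — default 0.988, the reported
cluster-calling homology — with at least 2 members; overlapping
candidates resolve toward larger clades. A cluster is `mono_specific`
when all members originate from one library.

## Candidate calling and the evidence hierarchy

The candidate report has one row per tree cluster and per cross-reactive
CDR3 group; each row's representative is its highest-fold member (ties:
earliest library name). CDR3 sharing outranks cluster purity: clones of
a "mono-specific" cluster that share a CDR3 across libraries are
reported through the CDR3 group, and because cluster members are
near-identical by construction, a cluster containing such clones is
itself reported multi-specific. Predictions are exactly that —
computational predictions from composition and CDR3 sharing; binding
validation is out of scope.

## The simulator: what it emulates and what it does not

`generateRepertoire()` draws clones on fixed framework scaffolds
carrying the canonical `...YYC` / `WGQG...` anchors, with random
CDR1/2/3 loops and a short-IgG2 or long-IgG3 hinge tail; nucleotide
sequences are random synonymous encodings flanked by the amplicon primer
regions. CDR loops exclude Cys and Trp so the anchors stay unambiguous —
a simplification relative to real repertoires, where CDR3 cysteines
occur. A `binderFraction` (default 0.02) of clones binds exactly one
cell line and a `crossReactiveFraction` (default 0.005) binds two or
three, with per-round selection advantages drawn log-normally
(meanlog 3, sdlog 0.5, i.e. median ~20-fold advantage); everything else
is neutral. Defaults were chosen once as the simulated study conditions:
1,000 clones, 2 selection rounds, 100,000 reads per round, 0.5% per-base
substitution error, four cell lines sharing one round-0 library.

Round-0 abundances follow Dirichlet(0.1), reproducing the skewed
clone-size spectrum of real libraries (a few dominant clones, a long
singleton tail). Selection is multinomial resampling with probability
proportional to frequency x binding weight — subtractive (absorbent-cell)
panning is modeled implicitly through the weights, since the analysis
pipeline only ever sees post-selection counts. The error model is
substitution-only, keeping reading frames intact; indels, chimeras, PCR
bias, and quality degradation along the read are not modeled. Per-base
qualities follow a four-level MiSeq-like profile rescaled so the mean
error equals the configured rate, and errors are injected at each base's
quality-implied probability — so expected-error filtering behaves as it
would on real data. Passing tests therefore demonstrate correct
arithmetic and faithful recovery under this idealized error process, not
performance on real sequencing runs.

## Numerical and degenerate-input choices

* Merging takes the best ungapped overlap maximizing matched bases
  (minimum 20 nt, mismatch fraction <= 0.1), consensus by higher base
  quality, summed quality (capped Q60) on agreement; merged reads whose
  expected error exceeds 1.0 are dropped. These are community-standard
  amplicon settings; the original merge parameters are unstated.
  A pair merging onto the reverse strand (mates swapped) is re-oriented
  by locating the forward primer on either strand.
* Primer matching is IUPAC-aware with at most 2 mismatches within 5 nt
  of the read ends; an exact tie between the two reverse primers is an
  ambiguity rejection, counted separately.
* Translation is frame 0 anchored at the forward primer's 3' end
  (offset configurable); any stop codon rejects the read; minimum
  accepted length 90 aa.
* Percentages in the summary report round half-up to 2 decimals; full
  precision is kept internally.
* Ranking ties break by higher final frequency, then lexicographic
  sequence (C locale), making the top-K input-order independent.

Problem sizes in the test suite were chosen for fast, deterministic
runs: most unit tests simulate 30-150 clones at a few thousand reads;
the end-to-end benchmark runs the full default scale (1,000 clones,
5 x 100,000 read pairs) once.

## Known limitations

The dominant limitation is the **sequencing-error shoulder** at the
clonotype level. A clone at frequency $f$ produces each specific
single-substitution amino-acid variant at frequency of order
$f \times \varepsilon$ for per-base error rate $\varepsilon$ in the
singly-covered part of the amplicon. After strong takeover (a top clone
at 50-90% of the library), these variants have final counts up to the
low hundreds and round-0 counts of 0-2 — the same count signature as a
genuinely rare binder — and their folds ride their parent's. Fold
ranking therefore cannot guarantee that every >= 10x-enriched binder
outranks the shoulder of a dominant clone, and the pipeline deliberately
performs no denoising at the dereplication stage (the tree-cluster stage
is where near-identical variants regroup, which is also why candidate
reporting works at the family level). The benchmark
(`recoveryBenchmark()`) measures this honestly: with default settings
binder recovery in the top-50 is high but not guaranteed to be complete,
while family-level specificity calls and cross-reactive flags remain
accurate. Real datasets with post-filter error rates well below the
simulator's default 0.5% per base sit in a friendlier regime.

Other limitations: no demultiplexing (one FASTQ pair per library/round
is expected), no chimera or indel handling, no CDR1/CDR2 annotation or
germline assignment, no bootstrap support or tree visualization, and no
modeling of phage biology or cell sorting.
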