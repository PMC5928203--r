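---
title: "Methods: comparative-genomics regulon reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative-genomics regulon reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`regulonscan` reconstructs regulons — the sets of genes and operons
controlled by one transcription factor — across a clade of annotated
bacterial genomes. The method chain mirrors the classic comparative-genomics
workflow for carbohydrate-utilization regulators in high-GC Gram-positives:
palindromic operator discovery in upstream regions, PWM scanning with a
strong/weak two-threshold scheme, cross-genome filtering along ortholog
groups, promoter-geometry classification of repression versus activation,
and gene-content phenotype assignment for arabinose and
arabino-oligosaccharide (AOS) utilization.

## The motif model

Operators bound by homodimeric LacI/TetR/ROK-family regulators are
dyad-symmetric, so the count matrix of an aligned site set is symmetrized:

$$N'(b, j) = \tfrac12\left(N(b, j) + N(\bar b,\; L+1-j)\right)$$

which is idempotent and makes the matrix equal to its own
reverse-complement mirror. Weights are zero-sum log counts,

$$w(b, j) = \ln\left(N'(b, j) + c\right) - \tfrac14 \sum_{b'} \ln\left(N'(b', j) + c\right)$$

with pseudocount $c = 0.5$. This form was chosen because (i) a sequence
and its reverse complement score identically under a symmetrized matrix —
a property the tests verify exhaustively at $L = 6$ — and (ii) consensus
scores are easy to verify by hand (a fully conserved column of four sites
contributes $0.75\ln 9$ for the consensus base). Information content is
the standard $\sum_j \sum_b f(b,j)\log_2(f(b,j)/0.25)$ on pseudocounted
frequencies, bounded by 2 bits per column.

## Motif discovery

Discovery is a seeded greedy iteration with one site (zero or one) per
region: score every window of every region, keep each region's best
window, rebuild the symmetrized counts and weights, repeat until the site
set is stable (at most 50 iterations). Restarts are not random windows:
seed windows are ranked by *self-complementarity* — the number of
positions at which a window matches its own reverse complement — because
a palindromic operator scores at or near the maximum while ~60% GC
background rarely does. The top `n_restarts` (default 20) non-overlapping
windows are used, with ties shuffled under the mandatory seed. A purely
random-seed variant converges to local optima in the large majority of
restarts (the chance of seeding inside the single implanted site of a
400-bp window is below 1%); the palindromicity ranking is what makes
recovery reliable at realistic noise.

The winning restart maximizes (IC per column) × (fraction of regions
whose best site reaches `coverage_frac` — default 0.6 — of the consensus
score); the same objective selects among candidate lengths (default
{14, 16, 18, 20, 22}, even only). Significance is judged against a
composition-preserving null: discovery re-run on letter-shuffled copies
of the same regions, with the observed IC compared to the 95th percentile
of the null ICs. By construction ~5% of background-only inputs will be
called significant; consumers needing a harder guarantee should raise the
quantile or the number of shuffles.

## Thresholds

Absolute PWM score scales are internal to each model, so thresholds are
anchored to the training sites: strong = minimum training-site score,
weak = 0.95 × strong, preserving the conventional strong:weak ratio of
such tools (5 versus 4.75 on their internal scale). A laxer preset for
global-regulator searches lowers the strong threshold itself by the same
0.95 factor and sets weak = (4.5/4.75) × strong, reproducing the
4.75/4.5 convention. Both thresholds accept absolute overrides.

## Upstream windows and operons

Windows span −350..+50 bp around the annotated start codon (0-based
half-open coordinates internally; GFF3 output is 1-based inclusive per
the standard). The window is deliberately *not* truncated at the boundary
of the preceding gene — the fixed-window rule is what a fixed −350..+50
scan implies — but overlap with an upstream gene is flagged
(`overlaps_upstream_gene`). Operons are consecutive same-strand genes
with intergenic gaps ≤ 150 bp (configurable; a conventional prokaryotic
threshold), and regulation is attributed to the operon leader's upstream
region. A site in the shared region of a divergently transcribed pair
falls inside both leaders' windows and is attributed to both (flagged
`shared`), the arrangement by which one palindromic operator co-regulates
a regulator/transporter pair.

## Orthology

Ortholog groups come from reciprocal best hits under global pairwise
alignment (BLOSUM62, affine gaps 11/1), thresholds 30% identity and 70%
bidirectional coverage — conventional orthology cutoffs, exposed in the
configuration — followed by single-linkage clustering. When one genome
contributes several genes to a cluster, the copy sharing an orthologous
neighbor within 5 genes (synteny) is kept, else the best-scoring one;
displaced copies become singletons. Ties break by longer alignment then
lexicographic gene id, so results are independent of input order. A
precomputed ortholog table can be supplied to bypass alignment entirely.

## Consistency check and footprinting

A candidate member (keyed by the ortholog groups of its target-operon
genes) is accepted when strong sites recur in at least
$\min(\texttt{min\_genomes},\ \lceil n_\text{carriers}/2\rceil)$ genomes,
where $n_\text{carriers}$ counts genomes carrying the gene. The literal
two-branch rule — `min_genomes` for widely distributed genes, 50% of
carriers only when fewer than `min_genomes` carry the gene — is not
monotone in `min_genomes` (a gene carried by exactly `min_genomes`
genomes can flip from rejected to accepted as the requirement rises into
the fallback branch); the capped form above is the minimal relaxation
that restores monotonicity, which the package treats as non-negotiable
because downstream comparisons across settings depend on it. Weak sites
count toward conservation only when the same group has a strong site in
at least one *other* genome — the footprinting operationalized as
orthologous-site support rather than promoter alignment. Genome-specific
genes need a strong site and are flagged. Core members are those
conserved in ≥ 20 genomes by default, matching the conventional
core-regulon definition at clade scale.

## Promoter elements and mode of regulation

−35/−10 elements are located with fixed consensus matrices (TTGACA,
TATAAT, built from four pseudo-observations with the standard
pseudocount so they share the motif score scale), spacer 15–19 bp with
no penalty inside the range and exclusion outside. Only the coding
strand is searched. The best joint arrangement is compared against the
95th percentile of best joint scores over letter-shuffles of the same
region (50 shuffles, fixed internal seed, so repeated calls agree);
below the cutoff the annotation is `none` and mode calls become ND.
Equal-scoring arrangements resolve toward the start codon,
deterministically.

Mode classification is purely geometric and collapses to one exhaustive,
exclusive rule: a site ending strictly before the −35 hexamer is an
**activator**; everything else — overlapping either hexamer, inside the
spacer, or downstream of the −10 element — is a **repressor** when a
confident promoter exists. The spacer case is not covered by the verbal
convention (it can only arise for a 14-bp site inside a 15–19 bp spacer);
it is classified repressor because a spacer-bound protein occludes open
complex formation, and because this choice preserves the invariant that
sliding a site downstream through a fixed promoter switches
activator → repressor exactly once and never back.

## Phenotype rules

The subsystem is a controlled vocabulary of arabinose/AOS roles
(catabolic araB/araD/araA, transporters araE and araFGH, AOS uptake
systems, α- and β-L-arabinofuranosidases, arabinanases, and the
regulators). Labels are conjunctions over a genome's role row:

* **U1**: araBDA and an arabinose transporter (araE, or complete araFGH);
* **U2**: araBDA, an α-AOS uptake system (complete araNt/Pt/Qt, complete
  aauABC, abfT1, abfT2 or xsaT) and ≥ 1 intracellular
  α-L-arabinofuranosidase;
* **U3**: araBDA, a β-AOS transporter (complete bauABC or bauT) and
  hypBA1;
* **"0"** when nothing applies; the transporter-less pattern
  (araBDA present, no known arabinose/AOS transporter at all) is reported
  as `"unique"`.

Multi-subunit transporters are strict by default (every subunit present;
`completeness_frac` relaxes this). The xylo-oligosaccharide system
xosABC is deliberately *not* counted as an arabinose/AOS transporter: it
only supports the advisory `axos_route_possible` flag (AXOS imported and
deararabinosylated intracellularly), since that route is a hypothesis,
not an established uptake pathway. The rule set is monotone — adding
roles never removes a label — and `assign_truth_phenotypes()` inverts it
with minimal witnesses, which the tests round-trip.

# The synthetic clade generator

The generator emulates exactly the statistical structure the analysis
assumes: a clade of genomes sharing ortholog families (random ancestor
proteins mutated along a star topology, no indels), ~60% GC i.i.d.
intergenic background, a 16-bp palindromic operator implanted at a
configurable per-position mismatch probability (default 0.1) upstream of
designated target families per a design matrix, σ70 promoter layouts,
and per-genome role complements realizing requested phenotype labels.
Implant noise mutates the first half of the site and mirrors it, so
every emitted site remains self-complementary (an optional cap bounds
mismatches per half-site for fixed-strength benchmarks). Targets
alternate strands, and the first target carries a co-transcribed
follower 50 bp downstream so operon attribution is exercised.

Two truth-label guarantees are enforced at generation time rather than
assumed: the `"repressor"` layout places its site at −50 (downstream of
a promoter at −98/−75) since a site at the default −120 would sit
upstream of that promoter's −35 element and be geometrically an
activator; and for the `"none"` layout the background flank is
re-sampled (seeded, deterministic) until the assembled upstream window
contains no confident promoter arrangement. The latter defines
"promoterless" relative to the package's own σ70 model — without it,
roughly 5% of promoterless layouts would carry a spurious confident
promoter purely by construction of the 95th-percentile cutoff, and the
ND truth label would be wrong for them.

What the generator does *not* emulate: realistic codon usage, indels,
horizontal transfer, overlapping genes, multi-copy paralog families, or
correlated background (e.g. low-complexity repeats). Passing tests
therefore demonstrate correctness of the algorithms under the stated
statistical assumptions, not performance on real genome annotation
noise, and threshold calibration on real training sites will be looser
than on implants.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which every property is meaningfully exercised:
clades of 2–8 genomes with 120-residue proteins, 100 seeded discovery
runs for consensus recovery, exhaustive enumeration at $L \in \{4, 6\}$
for score properties, and a 22-strain fermentation panel for
concordance. Other fixed numerical choices: pseudocount 0.5 everywhere;
natural-log weights (scores are unitless); discovery convergence by
site-set stability with a 50-iteration cap; shuffle nulls of size 20
(motif significance) and 50 (promoters) at the 95th percentile;
consensus ties broken alphabetically; RBH ties by alignment length then
gene id; all randomness behind explicit seeds with the caller's RNG
state restored.

# Known limitations

* Promoter models are canonical σ70 hexamers; alternative sigma factors
  and extended −10 elements are not modeled (swappable matrices are the
  extension point).
* The consistency filter's carrier count uses ortholog-group size, so
  annotation gaps deflate carriers and can soften the acceptance
  requirement for rare genes.
* Discovery assumes one operator per upstream region; tandem sites are
  only found at scan time.
* GenBank parsing is minimal (simple and `complement()` CDS locations;
  `join()` features are skipped with a warning) — FASTA+GFF3 is the
  first-class input path.
* Phenotype calls are gene-content predictions; they say nothing about
  expression or enzyme kinetics, and the U2/U3 conjunctions are the
  minimal reading of the pathway models.
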