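---
title: "Methods: TraN typing, similarity, trees and synthetic corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TraN typing, similarity, trees and synthetic corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records how `trantyper` computes what it computes: the
procedures, the tunable parameters and their defaults, the numerical
conventions, and the design choices made where more than one reasonable
option existed. It states no empirical result beyond what the package's
tests and `scripts/acceptance.R` themselves compute.

## The typing problem

MPF~F~ conjugation systems stabilize mating pairs through TraN, a donor
outer-membrane protein built from a conserved base and a variable distal
tip; the tip binds a recipient outer-membrane protein and thereby sets
conjugation efficiency and species range. Across plasmid corpora TraN
falls into length-separated families — short (IncF), medium (IncA/C),
long (IncH) and the two-tipped V form of *Acinetobacter baumannii*
plasmids — which subdivide further into subclades with distinct host
associations. `trantyper` types proteins against one representative
reference per subclade and reports everything downstream of that
assignment.

## Extraction rules

A CDS is a TraN candidate when its `gene` or `product` qualifier,
compared as a whole token after stripping flanking whitespace, equals one
of `traN`, `TraN`, `trhN`, `TrhN` (case-sensitive). The comparison is
deliberately exact: annotation survey rules are lists of exact strings,
and widening them silently would change denominators. Because deposited
annotations are inconsistent, `substring = TRUE` relaxes the rule
explicitly, and the name set itself is an argument. `product` is
consulted before `gene` purely for reporting (`matched_qualifier`); a
feature matching on either is extracted once. Features lacking a
`/translation` are translated from their span with NCBI genetic code 11
(reverse-complemented first on the minus strand), the trailing stop
stripped and fuzzy codons rendered `X`; matched features with no
obtainable sequence are skipped with a warning rather than failing the
corpus.

## Pairwise similarity

Every similarity in the package comes from one operation: exact global
Needleman–Wunsch alignment with affine gap costs, end gaps penalized.
Defaults: BLOSUM62, gap open 10, gap extend 1 (a gap of length *L* costs
`open + L * extend`). The traceback is deterministic — at equal score a
diagonal step beats a gap in the second sequence, which beats a gap in
the first — so alignments, similarity matrices, trees and tip projections
are all reproducible bit for bit.

Percent similarity is `100 × identities / alignment columns`. Gap columns
count in the denominator on purpose: the typology leans on large length
differences, and a 605 aa protein embedded perfectly inside an 1,800 aa
one should *not* score high. The alternative convention
(`identities / shorter input length`) is available as
`metric = "shorter"`. `X` scores whatever the substitution matrix assigns
it but never counts as an identity, so masked or ambiguous residues can
only dilute similarity. Production surveys computed similarities with a
progressive multiple aligner; this package substitutes the exact pairwise
DP so that results are self-contained, deterministic and testable against
a brute-force oracle. Consequently the 30% family threshold is an
operating point of *this* metric and is exposed as an argument, not a
hard-coded constant.

## Typing

* **Size class** — S: 550–660 aa, M: 880–950 aa, L: 1,050–1,070 aa (all
  inclusive), `other` outside the bins. 891 aa is flagged `"possible V"`:
  the V class collides with the M bin and is only ever *confirmed* by
  similarity to the V reference.
* **Family and subclade** — percent similarity to each of the six
  reference profiles; the best reference at or above the threshold
  (default 30) assigns family and subclade. Exact ties resolve by
  reference order as listed in the packaged profile table. Below
  threshold, short-bin proteins fall back to family `S` (isotype
  subtyping requires user-supplied TraN_S profiles, accepted via
  `reference_profiles()`); everything else is `unassigned`. Subclades in
  published trees are clades, not numeric rules; nearest-reference
  assignment is the reproducible proxy, and the tree from the phylo
  module is exported alongside for inspection.
* **Tip projection** — the query is aligned to its matched reference and
  the reference tip boundaries are pushed through the alignment. A
  boundary landing on a gap moves to the nearest query residue inside the
  tip span; a tip with no aligned residue at all is reported absent with
  a note. Projection refuses queries below the family threshold, where
  coordinates would be meaningless. Tip coordinates are interpreted on
  the full deposited protein; `verify_reference()` checks each profile's
  length and anchor residues so a signal-peptide-trimmed or mis-paired
  sequence is caught before it contaminates projections.

The packaged profile table records, per subclade, the representative
protein accession, deposited length and tip span with anchor residues
(e.g. the M-alpha tip 230C–360D). Deposited sequences are not
redistributed; `synthetic_references()` instantiates the same lengths,
spans and anchors as seeded synthetic sequences so every test runs
offline, and real sequences can be attached from FASTA when available.

## Trees

Similarity converts to distance as `d = (100 − s)/100`. Neighbor joining
follows the standard Q-criterion agglomeration with two numerical
conventions: negative intermediate branch lengths are clamped to zero
with a warning, and ties on Q break deterministically toward the
lexicographically smallest pair of representative leaf labels. NJ is
exact on additive matrices, which is the oracle the tests use (random
trees with up to 8 leaves, cophenetic matrices, exact topology and edge
length recovery). Midpoint rooting bisects the longest leaf-to-leaf path
(ties again lexicographic), inserting a degree-2 root on the containing
edge; degree-2 relics of previous rootings are spliced out first, making
the operation idempotent. Newick output carries 6-significant-digit
branch lengths and single-quotes labels containing metacharacters.
Maximum-likelihood inference and bootstrap support are deliberately out
of scope — they need a multiple alignment this pipeline does not build —
but the exported Newick and PHYLIP files feed external tools directly.

## Survey statistics

Copy-number categories are literal: `0`, `1`, `2-3`, `>3`. The `2-3`
bucket mirrors the multi-copy pattern actually observed in MPF~F~
corpora; higher counts get their own bucket rather than a silent merge.
All percentages are `100·k/n` rounded **half-up** to one decimal — base
R's round-half-even produces different final digits at the `.x5`
boundary than surveyed tables print. Each table labels its denominator
(plasmids vs extracted proteins) because the two differ whenever
plasmids carry zero or multiple copies. Conjugation frequency is
`log10(transconjugant CFU/mL ÷ recipient CFU/mL)`; a zero transconjugant
count returns a below-detection sentinel (`NA` plus attribute), never
`−Inf`, and fold differences are `10^(a−b)` on the log scale.
Replicate-level significance testing is out of scope.

## Host-range prediction

The curated table (`inst/extdata/hostrange_evidence.tsv`) maps each
subclade to its receptor and to qualitative per-recipient tiers —
`high`, `reduced`, `very_low`, `untested` — with a citation string on
every row. Tiers are qualitative because per-pair frequencies are
reported graphically in the underlying assays; printed magnitudes
(~80-fold, ~350-fold) are kept inside evidence strings rather than
promoted to thresholds. Receptor `unknown` is explicit (the M and V
partners are undetermined), the L-beta subclade carries the family-level
OmpA inference with `untested` tiers, and the V entry records that tip
T2 functions only toward *A. baumannii*. Lookups fall back from subclade
to family level; unassigned queries return an empty prediction with a
note. The table is closed over the typology and editable without code
changes.

## Synthetic corpora

The generator exists so every stage has known ground truth. Its defaults
*are* the surveyed corpus structure: 1,517 plasmids — 121 with no TraN
annotation, 1,358 single-copy, 38 with 2–3 copies (36 + 2, giving 1,436
proteins) — size classes 898 S / 216 M / 160 L / 162 outside the bins,
carbapenemase carriage 72/184 (medium) and 24/155 (long), and host
mixes with 122/184 of medium-class plasmids from Enterobacteriaceae and
154/155 of long-class plasmids enteric. Choices the surveyed tables do
not pin down were fixed once: the M-beta:M-alpha split 138:46 (the beta
clade dominates), the L subclade split 62/46/47, a default substitution
rate of 0.1 (within-subclade divergence well above the 30% threshold),
no indels by default, and the two extra seed references for the short
(605 aa) and outside-bin (1,882 aa) groups. Host-taxon structure is
emulated through the single `host_family` metadata field — order-level
versus family-level taxonomy is not modelled.

Quota mode hits category counts exactly via largest-remainder allocation
(floors first, remainders by largest fractional part, ties by category
order); survey percentages are exact ratios, so this mode
regression-locks them. Random mode draws categories independently for
distributional tests. Class quotas apply to proteins, with all copies on
one plasmid sharing a class; multi-copy plasmids are placed first so the
protein-level quota is met exactly. Every draw flows from one master
seed through hashed, labelled substreams, so sub-generators are
independent of call order and corpora are byte-stable.

Mutation applies per-site substitutions (uniform over the 19 other
residues) and optional geometric-length indels in a single left-to-right
pass, logging each event in parent coordinates; replaying the log
reproduces the child exactly, and planted tip coordinates project
through the log. Back-translation takes the lexicographically first
codon per residue under code 11 and appends a stop, so CDS re-translate
to the exact protein; codon-usage realism, plasmid backbones and
replication modules are non-goals. Decoy CDS (`traM`, `repA`, a
`"putative TraN"` product) exercise the exact-match extraction rule.

What passing tests on these corpora show — and what they do not: they
validate the pipeline's bookkeeping, determinism, threshold behaviour
and recovery of planted structure, under divergence that is uniform
across sites. Real TraN proteins diverge non-uniformly (conserved base,
variable tip), carry annotation noise, and include recombinants;
perfect recovery on synthetic corpora therefore bounds software
correctness, not expected performance on deposited records.

## Problem sizes and tolerances

The test suite runs in roughly a minute on one CPU: alignment oracles on
peptides of length ≤ 8 (exhaustive enumeration) and random pairs up to
40 aa; NJ oracles on trees of 4–8 leaves; typing corpora of 10–60
plasmids; one full 1,517-plasmid quota corpus and one 339-plasmid
association corpus for the survey regression locks.
`scripts/acceptance.R` rebuilds both large corpora from its `--seed` and
re-measures every headline quantity in about a minute. Statistical
checks use 3-sigma binomial bands around planted rates; numerical tree
comparisons use an absolute tolerance of 1e-8; floating-point score ties
in the aligner are exact because BLOSUM62 and the default penalties are
integers.

## Known limitations

* Subclade assignment is nearest-reference, not clade membership; a
  protein equidistant between references resolves by table order.
* The M-alpha/M-beta boundary has no published numeric criterion; the
  packaged references operationalize it.
* TraN_S isotyping (α/β/γ/δ) needs user-supplied reference sequences;
  by default short proteins are typed `S` from length alone.
* The similarity metric is not the one production surveys used, so
  absolute percentages near the 30% threshold can differ; the threshold
  is an argument for exactly this reason.
* Host-range tiers summarize laboratory conjugation panels; they are
  predictions about plasmid compatibility, not clinical risk scores.
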