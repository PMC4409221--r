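---
title: "Guide design by off-target quality: model, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide design by off-target quality: model, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidecraft)
```

## The problem

An SpCas9/sgRNA complex cuts a genomic site defined by a ~20-nt
protospacer followed by a PAM (NGG, more permissively NRG). Because a
20-mer recurs in real genomes and the complex tolerates some mismatches,
choosing a guide is an exercise in *specificity*: enumerate every genomic
site the guide could plausibly cut, weigh how dangerous each one is, and
rank the candidate guides accordingly. guidecraft implements that
workflow: candidate discovery in a query sequence, genome-wide off-target
enumeration, nearest-exon annotation, scoring/ranking, and cloning-oligo
design.

## The off-target model

A genomic window (protospacer plus PAM, either strand) is a retained
off-target of a candidate when all three hold:

* at most `max_core_mismatches` (default 2) mismatches fall inside the
  PAM-proximal **core** (default 12 bp) — mismatches near the PAM
  largely abolish cleavage;
* at most `max_total_mismatches` (default 4) mismatches over the whole
  protospacer — more than four and the site is not cut;
* the PAM matches the off-target motif (`NGG` or `NRG`, selectable
  independently of the discovery motif).

Mismatches are counted over the protospacer only; PAM bases are matched
by motif and never scored. Ambiguous genome characters (N and friends)
never match anything, including pattern N — masked or unsequenced regions
therefore cannot contribute hits. Windows never span sequence-record
boundaries.

Two engines implement this contract. The production engine builds an
exact k-mer index: the core is split into `max_core_mismatches + 1`
near-equal segments, so by pigeonhole every admissible site matches at
least one segment exactly; candidate loci from segment lookups are then
verified in full. The oracle engine (`brute_force_search()`) scans every
window with no index. The test-suite drives both across random genomes
and asserts set identity; this dual-route check is the backbone of the
package's correctness argument.

The presumed on-target hit — the one overlapping a user-supplied query
locus, or else the single best alignment (fewest total, then fewest core
mismatches, then lowest coordinate) — is flagged and excluded from the
off-target list. A *second* perfect match elsewhere is deliberately kept:
it is the most dangerous off-target there is. If the genome does not
contain the query at all, the best-alignment presumption will still eat
one hit; supply `on_target_locus`/`query_locus` when that matters.

## Scores

Per off-target, each mismatch at 1-based position $p$ (counted from the
protospacer 5' end; position 20 abuts the PAM) contributes $1.2^p$:

$$\mathrm{score}_{\mathrm{off}} = \sum_{\mathrm{mismatch}} 1.2^{p}.$$

The base 1.2 is an empirical constant; anything $>1$ preserves the
ordering "PAM-proximal mismatches are safer for specificity". Higher
per-off-target scores mean less stable heteroduplexes, i.e. *less*
dangerous off-targets.

Per candidate, with $n$ retained off-targets of which those with an
assigned exon form set $E$ and $d_i$ is the distance to that exon:

$$\mathrm{score} = \sum_{i \in E}\left[\log_{10} d_i +
\frac{\mathrm{score}_{\mathrm{off},i}}{n}\right] - n.$$

Candidates are ranked by descending score (ties: fewer off-targets, then
query position, then + strand). Numerical choices:

* $d_i$ is clamped to $\ge 1$ before the logarithm; an off-target
  overlapping an exon has distance 0 by definition and would otherwise
  produce $-\infty$. The clamp keeps "closer is worse" with a finite
  floor.
* The sum runs over exon-associated off-targets only, but $n$ in both the
  denominator and the subtracted term counts *all* retained off-targets:
  exon-less sites still matter for specificity and the count term is the
  only place they can act.
* A candidate with no off-targets scores exactly 0. A consequence of the
  literal formula, documented rather than patched: one benign off-target
  far from any exon contributes $\log_{10} d - 1 + \mathrm{score}/1 > 0$
  and can outrank a zero-off-target candidate. Adding an *exon-less*
  off-target, by contrast, always lowers the score by exactly 1.

## Exon annotation

Exons arrive as BED (0-based half-open; the name field carries
`gene_name|gene_id`). For each off-target the closest exon on the same
chromosome is assigned using interval-gap distance
$\max(0,\ s_h - e_x,\ s_x - e_h)$, so overlap *and* direct abutment give
0 (the published rule defines only overlap; the gap extends it
continuously). "Closer than 100 kb" is strict: a gap of exactly 100000
yields NA. Ties break by lower exon start, then gene id — deterministic
output. Location is `exonic` on exon overlap, `intronic` when the hit
lies inside the assigned gene's span (reconstructed as the range of exons
sharing the gene id — exon BEDs carry no transcript structure), else
`intergenic`. Distance is measured edge-to-edge, not from the window
midpoint; with 23-bp windows the difference is at most 11 bp and no
downstream decision is that sharp.

## Oligo design

For the DR274 vector (BsaI golden gate), annealed pairs must leave a
`TAGG` 5' overhang on the forward and `AAAC` on the reverse strand, and
T7 transcription wants the guide to start GG. Protospacers starting `GG`
are used as-is; `Gx` gains one lowercase `g` (extension) or has base 2
replaced (substitution); anything else gets `gg`. The published designs
show only the single-`g` case; the double-`g` rule is the natural
generalisation and is validated structurally by an annealing oracle
(explicit base-pairing of the two strands) rather than against printed
sequences. Lowercase marks the modified bases in the forward oligo only,
matching how such oligos are conventionally printed; the reverse oligo is
uppercase.

## The synthetic world

`make_synthetic_genome()` states the world the tests live in: uniform
ACGT background (default 50 kb per chromosome — large enough for seed
index structure to matter, small enough for the brute-force oracle),
plus planted sites with exactly specified mismatch positions, PAMs,
strands and exon gaps. Substituted bases are guaranteed to differ from
the original; backgrounds accidentally containing extra admissible hits
are redrawn (rejection sampling against the oracle engine), so the truth
table is exhaustive by construction. Generation is bit-reproducible per
seed and leaves the caller's RNG untouched.

What the generator does *not* emulate: repeat families, GC skew, soft
masking, assembly gaps — the features that make real genomes produce
many near-duplicate hits. A green recovery test therefore establishes
the correctness of the constraint logic and coordinate arithmetic, not
the tool's hit yield on a vertebrate genome; the published genome-scale
counts need the real medaka reference and are out of desk-scale reach.

## Degenerate inputs and edge policies

* Query shorter than one window: empty candidate list, not an error; a
  non-IUPAC character is an error.
* Protospacers containing non-ACGT are never candidates and never
  searched (the engines refuse them).
* Soft-masked (lowercase) genome bases are uppercased and treated as
  normal sequence.
* Zero candidates still produce a valid (empty) report; zero-score runs
  write a BED score of 1000 for a single site (degenerate min-max).

## Known limitations

* Substitution-only model: RNA/DNA bulges (indel off-targets) are out of
  scope.
* No on-target activity prediction; ranking reflects specificity only,
  and the top-ranked site is not always the best experimental choice.
* The seed index is exact-match and in-memory; it is a desk-scale tool,
  not an aligner replacement for many-gigabase genomes.
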