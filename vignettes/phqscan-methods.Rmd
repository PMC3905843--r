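---
title: "Scanning for hybrid G-quadruplex motifs around transcription start sites"
author: "phqscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning for hybrid G-quadruplex motifs around transcription start sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phqscan)
library(dplyr)
```

## The biological question

During transcription, a guanine-rich non-template DNA strand can pair with
the nascent RNA to form a DNA:RNA hybrid G-quadruplex (HQ). Because the RNA
supplies part of the quartet stack, only two G-tracts on the DNA are needed
— half the four tracts required for an intramolecular quadruplex. A genome
scan for *putative HQ-forming sequences* (PHQS) therefore uses the relaxed
pattern

```
G{3,}(.{1,7}?G{3,}){1,}      # PHQS: >= 2 tracts of >= 3 G, loops 1-7 nt
G{3,}(.{1,7}?G{3,}){3,}      # PQS:  >= 4 tracts (classic quadruplex motif)
G{2,}(.{1,7}?G{2,}){0,}      # pre-scan for the isolated-G3 control
```

with a *lazy* loop quantifier and greedy tract/outer quantifiers, so that
G-tracts are never swallowed as loop characters. Matching is global
(leftmost, non-overlapping) over the whole sequence, so a cluster of many
tracts is one long hit rather than several overlapping ones. Hits are
grouped by the number of G-tracts in the matched span — 1G, 2G, 3G, 4G+ —
and located by the position of their first guanine relative to the
transcription start site (TSS). Three derived statistics carry the
biology:

* **TSS-centred distributions** — hit counts in 100-nt bins over ±4 kb,
  normalised per 100 sequences;
* **strand bias** — the contrast between non-template ($N_N$) and template
  ($N_T$) counts in the 1 kb downstream of the TSS, where only
  non-template tracts can join the transcript in an HQ;
* **gene-level prevalence/abundance** — the share of genes with at least
  one motif, and motifs per gene, near the TSS or in the transcribed
  region.

## The chain scanner and its oracle

Backtracking regex semantics are awkward to reason about, so the scanner
uses an equivalent closed form. All maximal runs of `G` with length
$L \ge t$ (tract minimum $t$; 3 for PHQS/PQS, 2 for the pre-scan) are
chained whenever the gap between consecutive runs is between 1 and 7 nt. A
chain yields exactly one hit, spanning the whole chain, iff its total
*tract capacity*

$$\sum_{\text{runs}} \left\lfloor \frac{L + 1}{t + 1} \right\rfloor$$

reaches the required tract count (2 for PHQS, 4 for PQS, 1 for the
pre-scan). The capacity term counts how many tracts of exactly $t$ G,
separated by single-guanine loops, fit into one run — this is what lets a
single G$_{15}$ run satisfy the four-tract PQS pattern
(G$_3$-G-G$_3$-G-G$_3$-G-G$_3$, $\lfloor 16/4 \rfloor = 4$).

The package also ships `regex_oracle()`, which matches the literal
pattern with a PCRE backtracking engine. The test suite asserts
span-identical output of scanner and oracle on 1,000 seeded random
kilobase sequences at guanine fractions 0.1-0.4 for all three
configurations; the two implementations share no code.

```{r oracle}
s <- "GGGTTGGGATTTTGGGGGGGGGGGGGGG"
scan_strand(s, scan_config("phqs"))
regex_oracle(s, scan_config("phqs"))
```

### Tract counting and the 1G category

The number of tracts reported for a hit is the number of *maximal* G-runs
in its span, not the tract count of any particular regex parse. A G$_{15}$
run is therefore one tract (category 1G) even though it can be parsed as
two G$_7$ or four G$_3$ tracts — the parse is ambiguous, the maximal-run
count is not. Because of this ambiguity, 1G hits are excluded from the
binned frequency distributions by default (they can be re-included with
`categories = c("1G", ...)`).

### Template strand and coordinates

All sequences are stored as the sense (non-template) strand, 5'→3', with a
TSS anchor; the template strand is scanned as the reverse complement and
spans are mapped back to sense coordinates. Every internal position is
0-based and every interval half-open; the TSS-relative coordinate of a hit
is the position of its **first guanine in motif orientation**, which for a
template-strand hit is the *rightmost* sense base of the span. Either end
of a template span is a defensible anchor; with 100-nt bins the choice
moves a hit by at most one bin, and `template_coord = "span_start"`
selects the alternative. A bin is labelled
by its start coordinate, so the TSS sits at the start of bin `[0, 100)`.

## Masking

Two masking modes cover the usual regulatory-element masks, both by conversion
to `N` followed by a re-scan (`N` never extends a G-run but is a legal
loop character, mirroring `.` in the patterns):

* **interval masks** (CpG islands, G-rich transcription-factor binding
  sites) — BED intervals projected into gene-relative coordinates, or
  gene-relative intervals directly, with union semantics;
* **ordered literal masks** (hnRNP A/H recognition motifs) — the default
  list `TAGGGT`, `TAGGGA`, `GGGA` is masked in that order, each pass
  replacing left-to-right non-overlapping occurrences in the
  already-masked sequence. The motif list is fully configurable (the
  hnRNP literature counts a fourth G-rich motif that is not pinned down
  to a literal, so nothing beyond the three defaults is guessed).
  Restricting masking to the non-template strand restricts where
  occurrences are *searched*; the masked sequence is necessarily shared by
  both strand scans, since a single stored sequence cannot carry
  strand-specific bases.

The per-bin difference between the unmasked and masked distributions is
the masked motif's contribution. One subtlety, verified constructively in
the tests: masking an *interior* tract of a long chain can split one
multi-tract hit into two shorter hits, so per-bin counts are not
universally monotone under masking. Monotonicity holds exactly when masks
remove whole motif spans; for arbitrary masks the guaranteed contract is
conservation (contribution + masked = unmasked, bin by bin), and total
G-tract mass never increases.

Curves can be divided by their own background level — the mean frequency
over bins starting in `[3000, 4000)` nt downstream, where TSS-proximal
enrichment has decayed — which rescales each (strand, category) curve to
average 1 over that window by construction. The background window is taken
on the downstream flank by default; both bounds are adjustable, so the
upstream flank or a pooled window can be used instead.

## Strand bias

Two definitions of the strand-bias statistic are in common use — a
normalised difference and a relative excess. Both are implemented and
every output records which was used:

$$\mathrm{bias}_{nd} = \frac{N_N - N_T}{N_N + N_T}, \qquad
  \mathrm{bias}_{re} = \frac{N_N - N_T}{N_T}.$$

The normalised difference is the default: it is bounded in $[-1, 1]$,
symmetric under strand swap, and stable at small counts. Undefined cases
(empty denominator) propagate as missing values with a warning, never as
errors, so batch runs over sparse categories complete.

Gene positivity counts hits on either strand by default;
`nontemplate_only = TRUE` restricts to the sense strand.

## The synthetic gene generator

`simulate_gene_set()` emulates the statistical structure the analysis
measures — TSS-proximal enrichment plus strand bias — with exact ground
truth. Defaults: 4,000 nt upstream flank, 6,000 nt transcribed region
(the ±4 kb scan window fits entirely), i.i.d. background with guanine
fraction 0.15 (close to gene-body guanine content), planted motifs
uniform over the first 1 kb downstream of the TSS, and a configurable
probability `p_nontemplate` of placing each plant on the non-template
strand, so the expected normalised-difference bias is
$2\,p_{nt} - 1$.

Three deliberate construction rules make the truth table exact rather
than approximate, at the cost of realism:

* the background is strand-symmetric (C fraction = G fraction = 0.15), so
  background motifs arise at the same rate on both strands and cannot
  masquerade as planted strand bias;
* every plant carries 8 nt of `{A, T}` padding on both sides, so a plant
  can never chain with a background run on either strand — a scan always
  recovers the planted span exactly;
* plant loops are drawn from `{A, C, T}` and rejection-sampled to exclude
  `CC`, so the reverse complement of a plant contains no G-run of length
  ≥ 2 and plants are invisible to the opposite-strand scan.

Real promoters violate all three rules (CpG islands, isochores, nested
and overlapping motifs), so passing recovery tests demonstrates the
correctness of the machinery, not genomic realism. With a G/C-free
background the recovered hit set equals the truth table identically; with
the default background every plant is still recovered at its exact span,
while background hits add realistic clutter around it.

Randomness is driven by one integer seed with per-gene substreams derived
from the gene index, so the same seed yields byte-identical FASTA and
truth files and individual genes are reproducible in isolation.

```{r sim}
sim <- simulate_gene_set(n_genes = 3, flank_len = 300, gene_len = 900,
                         planting = list("2G" = 1, "3G" = 1),
                         p_nontemplate = 0.75, seed = 42)
sim$truth
```

## Numerical and interface choices

* Windows must be divisible by the bin width; violations are hard errors
  rather than silent truncation.
* Genes shorter than the scan window contribute only the coordinates they
  have, but the normalisation denominator stays the full gene count
  ("per 100 sequences"), accepting edge attenuation.
* Input sequences are uppercased; non-ACGT letters become `N`. Soft-masked
  (lowercase) bases are kept by default, so repeat regions are scanned
  like any other sequence; `lowercase = "mask"` hard-masks them instead.
* The upstream flank length is data-driven via the TSS offset in the
  sidecar table, not hard-coded; the ±4 kb analyses simply require flanks
  of at least 4 kb.
* TSV outputs have fixed column sets and round-trip losslessly through the
  package's readers; the CLI writes them atomically (temp file + rename).
  Option values starting with a dash use `--flag=value` syntax, e.g.
  `--window=-4000,4000`.

## Problem sizes used in the checks

The test suite exercises the scanner-oracle equivalence on 1,000 random
kilobase sequences per configuration, planted-motif identity on 500 genes
with 2,000 plants, strand-bias recovery on ≥ 2,000 plants at
`p_nontemplate = 0.75` (binomial standard error ≈ 0.02, checked within
three standard errors), and byte-level determinism of the full
simulate-scan-bias pipeline. The acceptance script
(`scripts/acceptance.R`) recomputes the same quantities from scratch at
300 sequences per oracle comparison and 500 genes per simulation.

## Known limitations

* No generalised G4 propensity scoring (G4Hunter-style), RNA-pattern
  scanning, or two-quartet patterns beyond the isolated-G3 pre-scan.
* No retrieval from genome databases and no splice-aware projection of
  motifs onto mature mRNA; inputs are FASTA plus a TSS sidecar.
* Masks are consumed as given intervals or literals; there is no motif
  discovery or PWM scanning for binding sites.
* The generator does not imitate promoter base composition; it validates
  the pipeline, not genome biology.
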