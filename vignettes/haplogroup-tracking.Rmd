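---
title: "Classifying and tracking mitochondrial haplogroups from fragmented sequence data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and tracking mitochondrial haplogroups from fragmented sequence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplogrouper)
```

## The problem

Human mtDNA lineages are organised into haplogroups, each defined by the set
of variants its carriers share relative to the rCRS coordinate frame, and
arranged in a rooted phylogeny (Phylotree-style). Fresh samples yield
full-length mitochondrial genomes and classify almost unambiguously. Ancient
or otherwise degraded samples do not: DNA survives in short fragments, so
typing starts from a handful of control-region (CR) amplicons, and the CR
alone rarely separates closely related haplogroups. The question this
package answers is therefore not just *"which haplogroup?"* but *"which
haplogroups are still compatible with the fragments in hand, and which
coding-region amplicon should be sequenced next to decide between them?"*

## The ranking model

For a sample with variant set $S$ (size $V_s$) covering reference ranges
$R$, and a haplogroup $g$ with cumulative variant profile $P_g$, let

$$V_p = |P_g \cap S|, \qquad
  V_m = |\{v \in P_g : \mathrm{pos}(v) \in R\} \setminus S|,$$

and rank haplogroups by the variant identity

$$\mathrm{identity}(g) = \frac{V_p - V_m}{V_s}.$$

Restricting $V_m$ to covered ranges is the load-bearing choice for
fragmented data: a haplogroup is penalised only for profile variants the
fragments could have seen but did not. Haplogroups attaining the four
highest distinct identity values form Rank Groups 1–4; lower values are
dropped (their count is reported, not the members).

Within a rank group, candidates are ordered by the private-variant
frequency score

$$\mathrm{score}(g) = \sum_{v \in \mathrm{extras}} \frac{H_e(g,v)}{H(g)}
  + \sum_{v \in \mathrm{missing}} \frac{H_m(g,v)}{H(g)},$$

where *extras* are sample variants beyond $P_g$ and *missing* are the
in-range profile variants the sample lacks. $H(g)$ counts database samples
classified to $g$; $H_e(g,v)$ counts those carrying extra $v$; $H_m(g,v)$
counts those lacking profile variant $v$. A high score means the sample's
private variants are *familiar* for that haplogroup, so the score acts as
support, ordered descending. Identity always outranks score: scores only
re-order candidates that tie on identity.

Two readings of $H_m$ are defensible — "samples of $g$ recorded as lacking
$v$" versus "carrying $v$". We count *lacking*, the reading symmetric with
$H_e$'s role (both measure how often this exact private-variant pattern has
been seen for $g$). This is a documented interpretation, not an asserted
fact about any other implementation.

### Degenerate input

A sample with $V_s = 0$ (an rCRS-identical read) leaves the identity
undefined. Such samples are ranked by ascending $V_m$ — the haplogroups
requiring the fewest unobserved variants come first — and the identity is
reported as `NaN`. Rank-group formation otherwise compares identities
exactly: for a fixed sample all identities share the denominator $V_s$, so
groups are formed on the integer numerator $V_p - V_m$ and no
floating-point tie-breaking is involved.

## Alignment and variant calling

Fragments are aligned with the Gotoh affine-gap algorithm, global in the
query and free at the reference ends, since a fragment is a subsequence of
the genome. The implementation delegates the dynamic programming to
`Biostrings::pairwiseAlignment(type = "global-local")`; the test suite
checks its scores against an independently written brute-force three-state
recurrence. Defaults (match +1, mismatch −1, gap open −4, gap extend −1,
where a gap of length $L$ costs $\mathrm{open} + (L-1)\,\mathrm{extend}$)
are conventional weights for high-identity mtDNA fragments and are fully
configurable; no claim is made that they replicate any particular server
bit-for-bit.

Calls follow Phylotree notation: transitions as bare positions,
transversions with the derived base, insertions as `pos.NX`, deletions as
`posd`. Indels are right-shifted to their 3′-most equivalent placement
before naming, which makes calls invariant to where a tie-broken traceback
happened to put the gap (the poly-C tract insertions all surface as
`315.1C`-style tokens). Ambiguous IUPAC bases yield no call, never a
variant. Position 3107 — the historical placeholder in the rCRS frame — is
never called.

The genome is treated as circular: fragments are aligned against a doubled
reference and coordinates re-mapped, so CR fragments spanning the 16569/1
origin align in one piece and report an origin-split range pair.

Overlapping fragments that disagree at a position (one calls a variant, the
other covers the site and calls reference) are an **error**, not a vote:
with amplicon data such a conflict means contamination, damage or a sample
mix-up, and silently unioning the calls would manufacture chimeric
profiles. This is also why the damage simulator (below) routinely trips
this check when overlapping fragments are damaged independently — that is
the intended behaviour, not a bug.

The default hotspot mask excludes position 16519, insertions anchored at
309/315, the 523–524 AC indel region and 3107 — the standard
length-heteroplasmy and phylogenetically uninformative sites of
mitochondrial haplotyping. The mask is configurable because published
ignore-lists differ.

## The haplotype database

`build_db()` classifies a corpus, credits every Rank-Group-1 haplogroup of
each sample ($H$, $H_e$, $H_m$ counts, each tie receiving full weight 1),
and repeats — three passes by default — so that from the second pass
onward the frequency scores produced by the previous pass can re-order tied
candidates. Records shorter than 400 bp are filtered out (boundary
inclusive at 400); identical sequences under different ids are deliberately
kept as distinct samples, since recurring haplotypes are exactly the signal
the frequency tables should accumulate. On a corpus whose classifications
are stable the counts reach a fixed point at the second pass, which the
tests verify. Crediting all of Rank Group 1 (rather than the top four
groups, or fractional 1/k weights) is a design choice exposed as
configuration knobs (`credit_groups`; weighting is all-or-nothing by
construction).

## Tracking

One tracking cycle is: classify → narrow Rank Group 1 (prefer candidates
with score > 0 when any exist, cap at the top five scored) → compute the
variants discriminating the remaining candidates → pick panel amplicons
covering them → sequence → merge → re-classify. Amplicon choice is a
greedy set cover maximising the number of candidate classes split per
amplicon, with ties broken by panel order; with at most five candidates
greedy choice is optimal or within one amplicon of it, and it is
deterministic. Tracking finishes when one haplogroup remains, or when the
remaining candidates carry identical cumulative profiles — then the deepest
candidate is reported, the MRCA-verification endpoint. If no panel amplicon
can split the candidates the state is marked *stalled*, never silently
finished.

The first track uses four tiled CR amplicons (16024–16365, 16268–16569,
1–285, 220–576). These are round coordinates tiling the CR with overlaps at
the hypervariable segments; published primer panels differ in their exact
ends and none is replicated here.

`simulate_tracking()` runs this loop on noise-free fragments cut from a
haplogroup's reconstructed reference sequence, which measures the *minimum*
amplicon requirement per haplogroup — a floor for what real, damaged
samples would need. The outcome counts tracks and amplicons and judges
agreement at the profile level: recovering a profile-identical relative of
the truth counts as agreement, since no data could ever separate the two.

## What the synthetic data does and does not emulate

No real Phylotree export, GenBank corpus or rCRS sequence ships with the
package; everything is generated:

* **Reference.** A deterministic synthetic 16,569 bp sequence carrying the
  structural anchors the conventions need (N at 3107, poly-C tract at
  303–315, AC at 523–524). Coordinate arithmetic, notation and alignment
  behave identically on the real NC_012920.1, which can be supplied by
  path.
* **Trees.** `generate_toy_tree()` draws random topologies whose branches
  carry substitution variants at positions unique across the tree, so
  cumulative profiles are unique by construction; requested CR-ambiguous
  sibling pairs share one CR variant and differ at one coding position
  each, reproducing the multi-candidate situation that motivates tracking.
  Branches are 60 % CR-weighted (`cr_frac`), reflecting the CR's elevated
  substitution density. Toy branches carry no indels or back-mutations;
  those paths are exercised by direct notation and reconstruction tests
  instead.
* **Samples and corpora.** Fragments are cut from reconstructed genomes,
  optionally with a terminal C→T / G→A damage model of exponentially
  decaying rate — a labelled stand-in for aDNA deamination, not a
  calibrated model of it.

Passing tests on this material demonstrates the *algorithmic* properties —
exact profile recovery, correct counting, deterministic ranking and
termination — under conditions where truth is knowable. They do not
demonstrate performance on real ancient DNA, where damage, contamination,
heteroplasmy and reference biases dominate; none of those are modelled.

Problem sizes used throughout the tests and the acceptance script — trees
of 10–51 nodes, corpora of ~30 control-region records, 200 alignment oracle
pairs, 1,000 notation round-trip tokens — were chosen as the smallest sizes
at which every code path (ties, ambiguity, multi-range coverage,
fixed-point iteration) is actually exercised.

## Known limitations

* Base qualities, aDNA damage rescaling and heteroplasmy are out of scope;
  calls are binary per site.
* The recombination QC implements a single fragment-concordance rule
  (fragments whose individual best haplogroups meet only near the root
  while the joint call is deep); it is not a full rule-based QC system.
* Sub-haplogroup levels can be counted with or without structural
  pass-through nodes (`collapse_empty`); curated trees differ on whether
  such nodes are named ranks, so both countings are exposed rather than
  asserting one.
* The frequency-score database interface accepts any count table; no
  population-scale database ships with the package.
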