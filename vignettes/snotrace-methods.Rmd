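---
title: "Tracing snoRNA ancestry and mobility: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing snoRNA ancestry and mobility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snotrace)
```

# The question

Small nucleolar RNAs (snoRNAs) guide chemical modification of ribosomal RNA:
C/D-box snoRNAs direct 2'-O-methylation through a contiguous antisense guide
element, H/ACA snoRNAs direct pseudouridylation through bipartite guides.
Many snoRNAs sit inside introns of protein-coding host genes. Two linked
comparative questions drive this package:

1. **Antiquity** — which snoRNA families can be traced to the Last Eukaryotic
   Common Ancestor (LECA), the root of the eukaryote species tree, and do
   their rRNA modification targets trace back as well?
2. **Positional stability** — when an intron position itself is ancestral,
   are the snoRNAs occupying that intron in different lineages homologous
   (stable genomic location), or unrelated (ongoing intragenomic mobility)?

`snotrace` implements the full inference chain — ancestral-state
reconstruction, guide-based target mapping, intron-locus projection,
occupancy and homology verdicts, expression-breadth comparison, and a
total-evidence intersection — together with a seeded synthetic-data
generator that plants every relevant signal with known ground truth, so each
stage is testable end to end without any external downloads.

# Dollo parsimony on presence/absence characters

Every character (a snoRNA family, a clan, an intron locus, a target-site
locus) is binary over the species of a rooted tree. Under Dollo parsimony a
character is gained exactly once and may be lost any number of times;
absence is the default state. Given that constraint, the most-parsimonious
scenario is fully determined:

* the **gain** sits at the most recent common ancestor (MRCA) of all
  presence leaves;
* **losses** are assigned to the highest branches whose subtrees contain
  only absence leaves (the maximal absent subtrees below the gain);
* a character is present at the **root** if and only if each child subtree
  of the root retains at least one carrier — the "root rule" used for every
  LECA verdict in the package.

`dollo_reconstruct()` implements this directly; `brute_force_min_losses()`
is a deliberately different formulation kept as an oracle: it enumerates all
`2^k` assignments of states to the `k` internal nodes, keeps those with
exactly one origin (a presence root, or a single 0→1 edge) and minimises the
number of 1→0 edges. The test suite sweeps every leaf pattern on batteries
of random trees and requires exact agreement in both the minimum loss count
and the root state.

Species missing from a matrix are scored absent — the conservative
convention under which presence must be demonstrated. A per-taxon `unscored`
mask is available for genomes that were never assessed: masked taxa
constrain neither gains nor losses. Clans are scored as the union of their
member families (a taxon carries the clan if it carries at least one
member); whether the original analyses merged clans this way or through
merged covariance-model hits is not documented anywhere we know of, so the
union — the weaker, more inclusive reading — is the package's choice.

# Mapping C/D guides onto rRNA

C/D guides are contiguous and antisense to their target, so target mapping
reduces to finding high-identity ungapped matches between the reverse
complement of a snoRNA and the SSU/LSU rRNA. `search_guides()` is a
deterministic seed-and-extend search:

| parameter | default | role |
|---|---|---|
| `word_size` | 5 nt | exact seed shared by revcomp(snoRNA) and rRNA |
| `match`, `mismatch` | +1, −2 | ungapped scoring |
| `dropoff` | 4 | X-dropoff bounding the extension span |
| `min_len` | 10 nt | shortest reportable hit |
| `min_identity` | 0.90 | fraction of matching bases |

Gaps are disallowed outright: with classic gap penalties of 50 no guide-scale
alignment could ever open one, so the search space is the set of diagonals.
Within the X-dropoff span around each seed the search enumerates every
window passing the length and identity thresholds; overlapping hits are
deduplicated to the best-scoring one (ties: shortest, then leftmost, then
lowest snoRNA offset — a fixed total order that makes output independent of
seed discovery order). There are no E-values; the length/identity thresholds
are calibrated so that a canonical 10–21-nt guide with at most one mismatch
passes while isolated random 5-mer seeds cannot be extended into a report.
The defaults admit exactly the windows with at most one mismatch per ten
bases, which always contain a 5-mer seed — so seeding loses nothing at these
thresholds.

The hit **center** is the floor midpoint of the rRNA interval (the rRNA
side, not the snoRNA side, is the coordinate that matters for modification
sites). Centers are projected into alignment columns of the curated rRNA
alignment (`ungapped_to_column()`), making per-species coordinates
comparable, and binned into **site loci** by single-linkage clustering with
a ±2-column tolerance. Single linkage, rather than fixed-width bins, avoids
bin-boundary artifacts; loci supported by a single species are discarded as
unreplicated. A site locus is called LECA-conserved when its carrier species
satisfy the Dollo root rule.

Binning by hit center (not by a box-offset rule) means the reported
modified-nucleotide identity is simply the rRNA base at the representative
column; no C/D/C'/D' box detection is attempted.

# Intron loci, occupancy and homology verdicts

Intron positions are compared across species in the amino-acid space of the
host protein: the position of an intron is the number of coding bases 5' of
it divided by 3 (floor). The phrase "first codon of the upstream exon" admits
two readings; the boundary reading used here (coding bases up to the
exon/intron junction) is the one that keeps adjacent introns of one exon
distinct, matching standard intron-phase mapping. Introns lying in UTRs have
no defined protein position and are excluded. Positions are projected onto
the group's protein alignment through each species' row and single-linkage
binned with a ±5-column tolerance.

A snoRNA **occupies** an intron locus when its genomic interval is fully
contained in that species' intron; copies straddling an exon boundary are
flagged and never assigned. Occupancy requires the host strand by default —
intronic snoRNAs are processed from the host pre-mRNA — with a switch for
annotations where orientation is unreliable.

For each occupied locus traceable to LECA, `cross_supergroup_homology()`
issues a verdict in decreasing order of evidence: `same_family` (one family
spans ≥ 2 supergroups), `same_clan`, `same_class_no_evidence`,
`unrelated_classes` (both C/D and H/ACA present — homology excluded), or
`single_supergroup`. `date_association()` separately dates each
(family, locus) association at the MRCA of the sharing species and calls a
**recent gain** when that node is strictly shallower than the Dollo
placement of the host gene itself — the signature of a snoRNA moving into an
old gene.

# Expression breadth

Expression breadth is the Shannon entropy of a gene's tissue proportion
vector, `S = -Σ p_i ln p_i` with `p_i = E_i / Σ E_j`, in nats, so `S` ranges
from 0 (single tissue) to `ln k` (uniform over `k` tissues); zero-signal
tissues contribute nothing (limit convention). `median_signal()` collapses
duplicate tissues (e.g. brain subsamples) by averaging within groups before
taking the median; the duplicate map is caller-supplied with an identity
default, since no canonical list of duplicates ships with any expression
matrix.

Host and non-host genes are compared with a Mann–Whitney/Wilcoxon rank-sum
test, one-sided (host > non-host) as the primary report because the
scientific claim is directional; two-sided is available. The U statistic
uses midranks. For `n1 · n2 ≤ 400` the p-value comes from the exact
permutation distribution, computed by a tie-aware subset-sum recursion over
doubled midranks — mathematically identical to enumerating all
`choose(n1+n2, n1)` labellings, which the tests verify literally for all
group sizes up to 6. Larger samples use the normal approximation with
tie-corrected variance and continuity correction.

# Total evidence

Three independent lines of evidence are intersected at the family level:
**A**, families (directly or through their clan) placed at LECA from
annotated presence; **B**, families supporting at least one LECA
guide-mapped site locus; **C**, families with an independently reported
modification site whose reporting species span the root (the
one-bikont-plus-one-unikont rule, configurable). Families that cannot take
part in guide mapping — H/ACA families and cleavage-only C/D families such
as the U3/snoU13 group — are listed as exclusions rather than silently
counted against the intersection. `clan_expansion_check()` asks, for clans
with two or more LECA member families, whether those families guide distinct
LECA site loci (consistent with duplication before the root) or share a
target (consistent with an artefactual split of one orthologous group during
family-model building).

# The synthetic-data generator

`simulate_bundle()` writes a complete input set (Newick tree + supergroup
map, family catalog, per-species GFF3 and snoRNA FASTA, aligned rRNA and
protein FASTA, ortholog table, known-site table, expression matrix) plus
JSON truth tables, all from one seed; regeneration is byte-identical.

What it emulates, and the reference conditions (the `sim_params()` defaults):

* a two-supergroup (unikont/bikont) tree, 2 × 6 taxa, root = LECA;
* 50 ancestral families born at the root plus 5 later births, each carried
  family lost per branch with probability 0.15 — enough loss that some
  ancestral families drop out of one root subtree, exercising the root rule
  in both directions;
* 14 host-gene ortholog groups with 5 ancestral introns each (positions ≥ 12
  amino acids apart so loci stay distinct under the ±5 tolerance; capacity
  comfortably exceeds the families plus reserved mobility destinations),
  per-branch intron loss 0.05 and a handful of derived intron gains;
* 30 target windows of 10–14 nt planted on 1.8-kb SSU/LSU rRNAs, each
  assigned to a C/D family whose carriers receive the exact reverse
  complement as a guide; windows are frozen during sequence evolution so the
  planted signal is unambiguous;
* 5 copy-and-relocate mobility events (source retained, the
  retrotransposition convention) plus 2 planted independent-gain pairs —
  two unrelated families, one per root subtree, homed at the same
  orthologous intron — the ground truth for `unrelated_classes` /
  `same_class_no_evidence` verdicts;
* 30 species-specific decoy snoRNAs and a 0.5-nat expression-entropy gap
  between host and non-host genes across 37 tissues (Dirichlet profiles,
  non-host concentration solved numerically from the digamma expression for
  the expected entropy).

Two construction guarantees matter for interpretation. First, **decoys are
certified inert**: at 1.8-kb rRNA scale every 5-mer occurs somewhere, so
seed-free decoys cannot exist; instead the generator scans each decoy (and
every non-guide snoRNA segment) against both rRNAs and mutates away any
antisense window that meets the hit thresholds, iterating across subunits to
a joint fixed point. Checking windows of length 10–19 suffices because any
longer qualifying window contains a qualifying sub-window in that range.
Second, **planted guides are unique**: window contents are made mutually
dissimilar, the root rRNAs are scrubbed of near-duplicates of every window
at a 0.8-identity margin, and a final per-species sweep removes any
hit-level similarity that substitutions re-created — so a planted guide maps
to exactly its window in every carrier.

What the generator does **not** emulate: covariance-model family discovery
(families are known labels), alignment inference (alignments are emitted
gap-consistently from the root sequence with point substitutions and short
deletions at known columns — no insertions, no rate heterogeneity, no codon
structure beyond phase-0 introns), H/ACA guide architecture, paralogy within
a family beyond the planted copies, and annotation noise. Passing tests
therefore demonstrate that the inference chain is correct when its inputs
mean what they claim — not that any particular real dataset satisfies those
assumptions.

# Numerical conventions and edge cases

* All internal coordinates are 0-based half-open; GFF3 (1-based closed) and
  the known-site table (1-based positions) are converted at the I/O
  boundary. Both `-` and `.` count as alignment gaps.
* "Full-length matches with fewer than 2 substitutions" in the snoRNA
  locator is read literally as ≤ 1 substitution and exposed as the
  `max_subst` parameter of `locate_full_length()`, which searches both
  strands and records strand and substitution count.
* Even-length guide hits take the floor midpoint as center; the binning
  tolerance (±2) absorbs the half-base ambiguity.
* The dedup total order (score desc, length asc, start asc, snoRNA offset
  asc) and sorted-column clustering make every stage permutation-invariant
  and byte-reproducible; reports embed the seed.
* One transcript per gene (longest CDS) is used when multiple isoforms
  exist.
* Degenerate inputs fail loudly: all-zero characters, empty queries,
  all-zero expression profiles, H/ACA records offered to the guide search,
  unknown taxa or families.

# Problem sizes

The shipped tests and the acceptance script run entirely on generated data:
exhaustive Dollo sweeps use 25 random 8-leaf trees × all 255 presence
patterns; guide-search oracle comparisons cover every snoRNA × rRNA pair of
a 6-species fixture with 30 planted guides and 30 decoys; binning is checked
against transitive-closure components over 1 000 random instances; the
end-to-end fixture is the 12-taxon reference study above. These sizes give
exact, enumerable ground truth for every claim while keeping a full run in
the minutes range on one CPU.

# Known limitations

* Parsimony only: no likelihood or Bayesian gain/loss model, no rate
  estimation — the root rule is a conservative lower bound on antiquity.
* Guide mapping covers C/D snoRNAs only; H/ACA target prediction (bipartite
  guides) is out of scope, and such families surface only through the
  presence/absence and occupancy stages.
* Cross-species coordinate unification assumes the curated alignments are
  trustworthy; a misaligned rRNA row displaces every site of that species.
* The homology verdicts reduce "manual inspection of sequence and structure"
  to family/clan/class identity; they can only be as good as the family
  assignments.
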