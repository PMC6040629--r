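---
title: "Reconstructing ancestral gene-family content with stemtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing ancestral gene-family content with stemtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemtrace)
```

## The problem

Comparative surveys of animals, choanoflagellates and their unicellular
relatives ask which gene families were already present in deep ancestors —
the last common ancestors of animals (the Urmetazoan), of animals plus
choanoflagellates (the Urchoanozoan), of holozoans, opisthokonts and
eukaryotes — and which were gained or lost on each stem lineage. The raw
material is an all-vs-all protein homology search clustered into orthologous
groups. Two failure modes dominate naive reconstructions from such data:

1. **Spurious cluster members.** Markov clustering of a BLAST graph admits
   proteins attached to a family by one or two marginal hits. Treated as
   binary presence, a single spurious choanoflagellate protein in an
   otherwise animal-specific family back-dates the family to the
   Urchoanozoan.
2. **Uneven data quality.** Transcriptome-derived gene catalogs miss lowly
   expressed genes, so absence of evidence in one species is weak evidence of
   absence.

`stemtrace` addresses both with a probabilistic membership score and
deliberately topology-light parsimony rules, and ships the surrounding
bookkeeping: transcriptome decontamination and error filters, Dollo
parsimony, retention and core-family summaries, a domain-architecture
evidence engine, and a synthetic-data generator that makes the whole pipeline
testable without sequencing data.

## Membership probabilities

For a protein $p$ in family $F$ with members $m_1, \dots, m_k$, the support
for membership is the arithmetic mean of its best hit E-values to the other
members,

$$\bar E(p) = \frac{1}{k-1}\sum_{m \ne p} E(p, m),$$

where a missing hit contributes the maximum possible (least probable) value
$e_{\max}$, the search threshold ($10^{-5}$ by default). The average is taken
on the raw E-value scale: that is what makes the missing-hit penalty bite,
since a single $e_{\max}$ term dominates a mean of otherwise tiny E-values. A
true ortholog hits nearly all co-members strongly and gets a small mean; a
spurious member hits one or two members weakly and its mean is pinned near
$e_{\max}$.

Means are mapped to probabilities through the empirical cumulative
distribution of *all* E-values from the all-vs-all search, ordered from
highest to lowest:

$$P(p) = \frac{\#\{e \in \mathrm{ref} : e > \bar E(p)\}}{|\mathrm{ref}|}.$$

The counting is strictly-greater, so the worst value in the reference maps to
0, ties share a probability, and the function is monotone non-increasing.
Reported E-values of exactly zero are floored at $10^{-200}$ before ranking.
When a species has several proteins in one family, the protein with the
lowest mean represents the species; a singleton family's sole species gets
probability 1, since the family is defined by that protein. Self-hits are
excluded from both the means and the reference. Whether hits between
proteins that belong to no family should enter the reference is not
decidable from first principles; `stemtrace` includes all non-self hits and
exposes the reference as an explicit `ecdf_reference` object so callers can
restrict it.

```{r membership}
bundle <- simulate_paperlike(seed = 1, gains_per_stem = c(Urmetazoan = 5L,
                                                          Urchoanozoan = 5L),
                             loss_prob = 0.1)
m <- presence_probabilities(bundle$catalog, bundle$hits,
                            species = bundle$tree$phy$tip.label)
round(m[1:3, c("cra01", "spo01", "lat01", "fun01")], 3)
```

## Group presence and origin rules

A family is *present in a group* of $n$ species when the sum of its
membership probabilities over the group is at least $0.1\,n$ — equivalently,
a mean probability of at least 10%. For a 21-species group this is met by,
for example, three species at probability 0.70 or six at 0.35. The rule is
deliberately independent of within-group topology, so unresolved
relationships (notably among early-branching animals) cannot change the
outcome. Comparisons are inclusive and evaluated at floating-point tolerance
(three times 0.70 must equal 2.1).

Origins then follow two parsimony rules over the annotated species tree:

* present in **two or more major groups** → present in their last common
  ancestor (the named node at or above the MRCA);
* present in **exactly one major group** → placed on that group's stem (its
  own named ancestor) only if at least two of the group's sub-groups pass
  the same 10% rule; otherwise the family originated *within* the group.
  Sub-groups are sponges / ctenophores / later-branching animals and
  craspedids / loricates for choanoflagellates; a single-species sub-group
  passes when that species reaches probability 0.10.

Groups that have no named stem ancestor of their own (single-species
outgroups, unannotated outgroup sets) fall through to `within-<group>`
directly; requiring sub-groups there would make every outgroup-only family a
configuration error. A group that *does* have a named ancestor but no
configured sub-groups raises an error, since the single-group rule is then
genuinely inapplicable.

Presence at a node is monotone along the path from a family's origin to its
extant groups: a family placed in the Uropisthokont by fungi and animals is
also counted as present at the intermediate Urholozoan and Urchoanozoan in
the gain/loss bookkeeping, and a family present at a node's named parent but
absent from every major group below the node is a loss on the branch to that
node.

```{r origins}
origins <- infer_origins(m, bundle$tree)
table(origins$origin)
node_gain_loss(origins, m, bundle$tree)
```

## Retention, cores, Dollo, heat maps

`retention_sums()` sums, per species, the probabilities of families
partitioned by origin. Because every family carries a small probability in
every species, species outside an origin's descendants accumulate a small
residual background — expected, and useful as a sanity check on the ECDF.
`core_families()` finds group-specific families passing the 10% per-species
criterion in *every* group member (inclusive, so exactly 0.10 passes);
`near_core_families()` relaxes that by a bounded number of species.

`dollo_reconstruct()` gives the classical single-gain reconstruction: a
family is gained at the MRCA of its possessing species and lost on the
maximal subtrees below the gain node that contain none of them. The package's
implementation is checked in the test suite against an exhaustive
minimal-loss search over all ancestral state assignments on small trees. The
default binarization threshold reuses the 10% species-level criterion.

`heatmap_order()` sorts families by their 2^5 pattern of major-group
presence (group order as configured, present before absent) and clusters
within each pattern with average-linkage hierarchical clustering on
uncentered Pearson similarity $s(x,y)=\sum x_i y_i / \sqrt{\sum x_i^2 \sum
y_i^2}$ — the Cluster 3.0 convention, so the exported CDT files open directly
in Java TreeView. All-zero rows (similarity 0 to everything) sort last
within their pattern; remaining ties break on family id.

## Transcriptome quality filters

Three bespoke filters precede family construction when starting from
de novo transcriptomes:

* **Cross-contamination** (`flag_contaminant_pairs()`,
  `resolve_sources()`): cross-species contig matches at ≥ 96% identity over
  ≥ 90 bases are treated as index-swap contaminants; within a flagged pair
  the contig with ≥ 10× the partner's mapped reads is kept, everything else
  discarded — except that a contig with ≥ 10,000 reads is never discarded,
  because highly expressed conserved genes (tubulins, EF-1α) legitimately
  match across species at read ratios near one. Both contigs of a pair can
  survive via the floor, and both can fall. A contig flagged against several
  partners is discarded if any pairing discards it (conservative).
* **Error-correction filter** (`neighbor_distribution()`,
  `select_max_neighbors()`, `apply_error_filter()`): corrections from
  iterated k-spectrum error correctors split into sporadic errors (no other
  error within the same k-mer window) and implausible clusters. Reads are
  grouped by total error count; within each group the distribution of
  per-error neighbor counts is bimodal, and the cutoff is the count just
  before the secondary increase (first index $i$ with
  $c_i > c_{i-1}$, minus one). If the distribution never rises there is no
  clustered regime and everything is accepted. The window defaults to 13,
  matching the corrector's k-mer length; correctors are sometimes tuned with
  a longer assembly k-mer (25), so the window is a parameter.
* **Redundancy and noise** (`dedupe_predicted_proteins()`,
  `fpkm_noise_filter()`): a contig whose predicted protein set is a subset
  of (or equal to) another retained contig's set is dropped, keeping the
  lexicographically smallest id among exact duplicates — the output is
  subset-free and the operation idempotent. Contigs below FPKM 0.01 are
  noise; the boundary value is retained ("below" discards strictly less).

## Domain-architecture evidence

BLAST-based families are unreliable for repeat-rich genes (EGF, LRR,
ankyrin), so receptor-type genes are scored directly from Pfam domain
architectures with declarative rules at three evidence levels. A rule is an
ordered token list; each token accepts a set of names or prefixes (any
`LRR*` variant, `TIR`/`TIR_2`), may be negated (kinase-TIR proteins must
*lack* a transmembrane segment), and matches as an ordered subsequence, so
interleaved irrelevant domains never break a match and adding domains never
demotes a negation-free rule. Transmembrane segments and signal peptides
join the architecture as `TM`/`SP` pseudo-domains from Phobius output.
The shipped library (`default_rule_library()`) covers Notch (EGF⁺, Notch,
TM, Ank in order), Delta (MNNL + DSL), TLR (LRR⁺, TM, TIR in order) and its
choanoflagellate kinase variants, interleukin-receptor-like architectures,
Flamingo at strong/moderate/weak levels, Protocadherin, integrin β,
Argonaute, Dicer, the TGF-β ligand/receptor/SMAD set and NLRs; YAML rule
files extend or override it.

## The synthetic-data generator

`simulate_family_evolution()` gains each family once at an assigned stem
node and loses it independently with probability 0.2 per descendant branch
(the default; loss is rampant at these evolutionary distances, and 0.2 per
branch on the demonstration tree yields per-species retention fractions in a
realistic range). The demonstration tree mirrors a realistic sampling
design: 20 choanoflagellates (10 craspedids, 10 loricates), 20 animals (3
sponges, 1 ctenophore, 16 later-branching), one filasterean, 5 fungi, 9
other eukaryotes, with within-group polytomies (the presence rules ignore
within-group topology, and early-animal branching is genuinely unresolved).

`simulate_hit_table()` gives each true member a hit to 95% of its
co-members, log10-uniform in $[10^{-200}, 10^{-20}]$; injected false
positives hit only 1–2 members at $[10^{-10}, 10^{-5}]$; and background
cross-family hits — nine per within-family hit — populate the weak tail of
the ECDF reference, as the bulk of hits at a $10^{-5}$ threshold do in any
real all-vs-all search. Without that tail the ECDF would assign mid-range
probabilities to strong orthologs; the 9:1 default places tight ortholog
families above probability 0.9 and near-threshold false positives near 0.03,
reproducing the bimodality the method relies on. What the generator does
*not* emulate: real sequence content (no alignments are computed), database-
size effects on E-values, correlated loss across families, paralogy and
family fission/fusion. Passing tests therefore demonstrate the statistical
machinery, not robustness to clustering artifacts in real data.

Two evaluation conventions matter when reading the simulation results:

* **Origin recovery** is measured against the *identifiable* origin — the
  node the parsimony rules assign given perfect knowledge of the true binary
  presence pattern. With per-branch loss 0.2, a family gained at the
  Urchoanozoan loses its entire animal stem about one run in five; no method
  can distinguish that outcome from a choanoflagellate innovation, so raw
  agreement with the generating gain node is bounded near 80% by the loss
  process itself, not by the scoring. Both numbers are reported by the
  acceptance script; the identifiable-origin recovery (≈ 99% at the default
  settings) is the one that evaluates the E-value → ECDF → threshold
  machinery.
* **Decontamination** scenarios use a contaminant read fraction of 0.01, an
  order of magnitude below the 10× ratio, so perfect recall with zero false
  discards is the designed outcome and any miss indicates a defect.

## Numerical choices and degenerate inputs

* E-value zero floors to $10^{-200}$ everywhere (means and reference).
* Pair E-values are the minimum over both search directions.
* All threshold comparisons are inclusive; sums are compared at a $10^{-9}$
  absolute tolerance to keep "3 × 0.70 ≥ 2.1" true in floating point.
* Post-hoc scoring of additional species (best-reciprocal hits only)
  averages best hits per original species in the family, assigns each new
  protein to its single lowest-mean family (ties to the lexicographically
  smallest id, with a message) and reuses the *original* ECDF.
* Empty families are rejected by the catalog; families absent everywhere are
  skipped with a warning by Dollo; zero-probability rows sort last in the
  heat map; an empty matrix writes a header-only file.

## Problem sizes

The bundled demonstration preset uses 260 families over 55 species
(~64,000 within-family hits, ~640,000 hits including background), which a
single core processes end to end in well under a minute; unit tests use
smaller presets of 12–60 families. All generators are bit-reproducible under
a fixed seed, and the pipeline writes byte-identical output bundles for
identical configurations.
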