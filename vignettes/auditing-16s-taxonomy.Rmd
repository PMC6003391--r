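---
title: "Auditing 16S taxonomy annotations and guide trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing 16S taxonomy annotations and guide trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxaudit)
```

# The problem

Reference databases for the 16S rRNA gene attach a taxonomic lineage
(phylum through genus, sometimes domain and species) to each sequence.
Most of those lineages are predictions — from a classifier, or from
curation guided by an inferred "guide tree" — rather than observations of
cultured, trait-characterized strains. `taxaudit` implements a family of
internal-consistency audits that quantify how error-prone such
annotations are without requiring any external truth:

1. **Cross-database conflicts.** If two databases contain an identical
   sequence and annotate it with different names from their *common
   nomenclature* (the names present in both), at least one is wrong. The
   conflict fraction is a lower bound on the *sum* of the two databases'
   error rates, because identical errors in both databases produce no
   disagreement and per-sequence double errors only add to the sum.
2. **Tree/taxonomy conflicts.** If taxonomy were consistent with a
   correct tree, the subtree under each taxon's LCA would contain no
   other taxon of the same rank ("purity"). Counting impure taxa and
   overlapped leaves measures the disagreement between a guide tree and
   its annotations.
3. **Tree/tree concurrence.** Two guide trees for the same sequences can
   be compared through taxonomy: the Taxonomy Concurrence Score (TCS) is
   the fraction of non-singleton taxa for which both trees place the same
   *set of taxon names* under the taxon's LCA. Name sets, not sequence
   sets, are compared, so a single misplaced sequence does not count as
   many disagreements. Generic topological distances (Robinson–Foulds,
   branch-score) are deliberately not used: they weight all branching
   differences equally, while only purity-changing differences matter
   here.
4. **Blinded classifier evaluation.** Sequences present in a newer
   training-set version but absent from an older one have annotations the
   old reference never saw; classifying them with the old reference and
   scoring against the new annotations is a blinded test.
5. **High-identity outliers.** A pair of nearly identical sequences whose
   lineages share only a high rank (their *lowest common rank*, LCR) is a
   probable annotation error.

# Definitions and conventions

**Ranks.** The fixed order is domain < phylum < class < order < family <
genus < species. All conflict, purity, concurrence and outlier tables run
over phylum..genus by default; domain and species are parsed and retained
but excluded, because reference databases annotate them too inconsistently
for cross-database counting to be meaningful.

**Blanks.** A lineage may be blank at any rank (no prefix-completeness is
assumed; real databases violate it). The tokens treated as blank —
empty payloads, bare rank prefixes such as `g__`, `unclassified`,
`unidentified`, `uncultured`, and `*_unclassified` names — are
configurable in `normalize_name()`; the defaults cover the three supported
dialects' conventions. A blank never equals any real name. In purity and
concurrence analyses, leaves blank at the queried rank are invisible to
that rank: they contribute neither names nor leaf counts. In the conflict
audit, blank-vs-name at a rank is itself a conflict (a false negative in
one database or a false positive in the other) when the named side is in
the common nomenclature.

**Name matching** is case-sensitive after stripping rank prefixes and
collapsing whitespace. Database names are consistently capitalized, and
case-folding would risk merging genuinely distinct names; punctuation is
preserved so combined genera like "Escherichia–Shigella" stay atomic.

**Identical sequences** means byte equality after normalization
(uppercase, U→T, gaps and whitespace removed, non-ACGT mapped to N). No
containment or substring matching is attempted: the counting unit of the
audit is the sequence, and containment would silently change denominators.

**Parent maps.** Real databases contain internally inconsistent lineages,
so "the" parent of a taxon name is taken as the majority parent over the
database's lineages, ties broken lexicographically. A hierarchy
disagreement is a common-nomenclature name whose majority parents differ
between databases with at least one of the two parents in the common
nomenclature. In the per-sequence conflict table, the hierarchy column
counts sequences where both databases agree on a common-nomenclature name
at a rank but place it under different common-nomenclature parents in
that sequence's own lineages — the conflict is then attributed to the
rank of the shared (child) name.

**Highest conflicted rank.** Ranks are scanned from phylum downward and a
conflicted sequence is tabulated once, at the first conflicted rank. When
a sequence occurs under several accessions, the verdict is
sequence-level: conflicted if any cross-database annotation pair
conflicts, with the highest conflicted rank over pairs.

**Purity bookkeeping.** Singletons (one annotated leaf) are pure in any
tree, so the pure/impure taxon split covers non-singleton taxa only and
singletons get their own row. Leaf counts cover all annotated leaves: a
leaf is overlapped (impure) when it lies under the LCAs of two or more
same-rank taxa, and a singleton's leaf can be overlapped by another
taxon's LCA subtree.

**Lowest pure taxon.** The LPT of a node is found by scanning ranks from
genus upward for a taxon containing every annotated leaf under the node.
A taxon with exactly one child taxon at the next-lower rank is ineligible
(its child would be pure whenever it is, at a lower rank). An edge is
pure when both endpoints have the same defined LPT.

**Trees** are used exactly as rooted in their Newick files; no re-rooting
is attempted because purity verdicts depend on the root and no principled
re-rooting rule exists without outgroup information. Multifurcations are
handled natively — resolving them arbitrarily would manufacture purity
verdicts. Branch lengths are carried through subset extraction (summed
along suppressed unary paths) but never influence any verdict; all audit
computations are topology- and label-driven.

**Subset trees.** To compare two guide trees through an independent
reference, the three databases are intersected by identical sequence, the
induced subtree extracted from each guide tree (prune, then suppress
unary nodes), and both trees' leaves relabeled with the reference
accessions so both carry the same annotations. Duplicate sequences within
one database are represented by their first accession.

# Pairwise identity

No published convention pins down "percent identity" exactly, so the
package defines it as: global (ends-free) alignment, identity = matches /
alignment columns with terminal gap columns excluded — the natural choice
for near-full-length marker genes where terminal overhangs reflect
trimming, not divergence. Scoring is match +1, mismatch −2, gap open −10,
gap extension −1 (configurable); the scoring only affects identity through
the column count of the optimal alignment. The kernel is a compiled Gotoh
dynamic program with a deterministic traceback preference
(substitution > gap in the second sequence > gap in the first). Because
co-optimal alignments can differ in identity, the two sequences are put in
a canonical order before aligning, making the reported identity exactly
symmetric. For unrelated sequences the ends-free optimum can be a short
perfect overlap with a misleading identity of 1.0; the outlier scanner's
k-mer prefilter (pairs must share ≥ 8 distinct 16-mers by default,
configurable down to 0 for an exhaustive scan) suppresses such pairs, and
identity values are only meaningful within collections of homologous
sequences, which 16S databases are.

The classifier's bootstrap subsamples ⌈W/8⌉ of the query's W distinct
k-words per replicate, drawn without replacement — a subsample, not a
resample, keeps replicate word sets distinct from the full set at small W.
Defaults are word length k = 8, B = 100 replicates, confidence cutoff
0.8 with add-half smoothing `(n_g(w) + 0.5) / (N_g + 1)`; these mirror the
widely used bootstrap word-classifier design closely enough to exercise
the blinded pipeline, which is their only job — parity with any external
classifier build is explicitly out of scope. Genus-score ties break to the
lexicographically smallest name so runs are reproducible under a seed. A
query is "known" at a rank when its true name occurs in the reference at
that rank, evaluated per rank — a query can be known at family and novel
at genus. Queries with blank truth at a rank are excluded from that rank's
totals, since no error type is defined for them.

# The synthetic-data generator

The generator exists so that every audit stage can be validated against a
planted ground truth. `sim_config()` defaults describe a small but
structurally realistic database pair:

| parameter | default | rationale |
|---|---|---|
| taxonomy shape | 3×2×2×2×3 (72 genera) | deep enough that every rank has non-trivial taxa, small enough for fast tests |
| sequences per genus | 2–6, 20% singletons | roughly half of real genera are sparse; singletons exercise the singleton rules |
| sequence length | 1,500 nt | near-full-length 16S |
| substitution probability | 0.01 per site per edge | keeps within-genus identity high and records distinct |
| annotation error rates | 0.17 per database | the scale of error the cross-database audit itself suggests for the large curated databases |
| perturbation moves | 10 | enough regrafts to degrade concurrence measurably |

Corruption is **exact-count** (`round(rate × n)` records, sampled without
replacement) rather than Bernoulli, so tests can assert equalities; the
realized rate differs from the nominal one by at most 0.5/n of rounding.
A corrupted record's lineage is replaced from a uniformly chosen rank
downward with the corresponding suffix of another record's lineage whose
name at that rank differs — corrupted annotations therefore stay inside
the shared nomenclature and are always detectable as name-vs-name
conflicts, and the replacement suffix is internally consistent. Tree
perturbation uses uniform leaf prune-and-regraft moves (uniform leaf,
uniform edge, uniform position), the simplest move that degrades
concurrence; the leaf set is preserved and all moves are logged.

What the generator does **not** emulate: rate heterogeneity, indels,
chimeras, primer/trimming artifacts, correlated (systematic) annotation
errors shared by both databases, and partial-length sequences. Passing
tests on synthetic data therefore demonstrate that the *computations* are
correct and that planted parameters are recovered under the generator's
assumptions — not that real databases satisfy those assumptions. In
particular, the conflict lower bound is only a lower bound on real data
precisely because correlated errors (which the generator omits) hide
conflicts.

# Numerical and degenerate-input choices

* `round(rate × n)` uses R's round-half-to-even; tests assert against the
  same convention.
* TCS with zero non-singleton taxa at a rank is reported as `NA` rather
  than an error inside the per-rank table; `tcs_from_counts()` with an
  all-zero vector errors, since a single undefined ratio is requested.
* Metric rates with `K = 0` (or `L = 0`) are reported as `NA` ("absent"),
  not 0 — dividing by zero opportunities is undefined, and printing 0
  would claim a measurement that was never made.
* Identity of an alignment is always over ≥ 1 column (empty overlaps are
  not produced); empty sequences are rejected at normalization.
* The Newick reader rejects unbalanced input with the character position
  and rejects duplicate leaf labels; trees are otherwise taken as-is.
* All stochastic functions take a `seed` argument that saves and restores
  the caller's RNG state; `build_audit_pair()` derives all stage
  randomness from the single master seed.

# Problem sizes used in the test suite

Oracle-equivalence tests run on ≥ 100 random instances per operation with
trees of 8–15 leaves and sequences of 15–60 nt, where brute-force
enumeration (path intersection, subtree enumeration, all triplets, full
dynamic programming) is exact and fast. Parameter-recovery tests use 20
independent seeds of ~50-record database pairs with 150 nt sequences —
sizes chosen so the whole suite completes in well under a minute while the
binomial error bars on recovered rates remain tight enough to be
informative. The blinded-classifier tests use references of a few dozen
records with reduced bootstrap counts (B = 25–50).

# Known limitations

* The audit detects disagreement; it never adjudicates which database is
  wrong.
* Purity verdicts inherit the file's rooting; a mis-rooted guide tree
  will inflate impurity counts.
* The conflict lower bound assumes a name means the same thing in both
  nomenclatures; names that genuinely changed definition between
  nomenclature revisions contribute spurious conflicts (a small minority
  in practice).
* The stand-in classifier is for pipeline validation, not for production
  taxonomy assignment.
* No fuzzy name matching or synonym resolution is attempted; nomenclature
  synonyms count as distinct names.
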