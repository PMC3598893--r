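---
title: "Methods: surveying overlaps between disease groups and protein interaction data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying overlaps between disease groups and protein interaction data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digoverlap)
```

## The scientific question

Many inherited diseases are multigenic: mutations in any of several genes
produce related phenotypes. A long-standing hypothesis is that such gene
groups often encode subunits of one protein complex, members of one
pathway, or partners in a web of direct interactions, so that disrupting
any member perturbs the same molecular machine. `digoverlap` implements a
survey methodology for testing this hypothesis at scale: it builds
"disease groups" (DiGs) from a Morbid-Map-style catalogue of disease-gene
associations, models consolidated protein-interaction data in its three
distinct forms (binary records, n-ary/bipartite complex records, and
spoke-encoded complexes hidden inside binary records), and scores every
DiG against every protein group with hypergeometric statistics under
multiple-testing control.

The package ships a synthetic-data generator with a ground-truth manifest,
so the entire pipeline is testable end to end without the licensed
disease catalogue or any particular interaction-database release.

## Disease-group construction

Each Morbid-Map entry has four pipe-delimited columns: a disease title
(with trailing catalogue identifier and a parenthesized evidence code),
the gene's official symbol and synonyms, the entry identifier, and the
gene's map location. Only evidence code 3 is retained — both the
disease-associated mutation and the phenotype were mapped to the gene —
since weaker codes do not establish the gene-disease link this survey
relies on.

Titles describing subtypes of one disease differ in systematic ways
("Alport syndrome, X-linked" vs "Alport syndrome, autosomal recessive").
`normalize_title()` reduces each title to a search key by truncating at
the first comma (or stripping the trailing tag and identifier when no
comma is present), truncating before the subtype keywords "due to" and
"with", removing stand-alone digits and roman numerals, recording and
stripping the leading `{`/`[` susceptibility markers, and case-folding.
`group_titles()` then clusters keys by anchored prefix matching: a
partial hit is accepted only when it ends at a word boundary or
punctuation, or continues with one of the allowed suffixes *s*, *tous*,
*tosis*.

Two design choices here were genuinely open:

* **Suffix handling.** A literal prefix test cannot co-group
  "adenomatous ..." with "adenomatosis ...", because neither full key is
  a prefix of the other. We therefore apply the suffix rule as a per-word
  stem (*tosis* → "", *tous* → "", trailing *s* → "") on both sides
  before the prefix comparison. This realizes the stated intent — the
  allowed suffixes make spelling variants equivalent — with a symmetric,
  deterministic rule.
* **Determinism.** Keys are processed in sorted order and a key joins the
  first matching cluster, so DiG identifiers are invariant under
  permutations of the input file. Case is folded before matching, since
  SQL-style text searches are conventionally case-insensitive.

Gene symbols resolve against a gene-info table in two passes: official
symbol at taxon 9606 with a matching map location first, then a broadened
search over synonyms and locus tags. Multiple surviving candidates yield
an explicit *ambiguous* result, never a guess. Resolved genes map to
canonical protein identifiers via the supplied gene-to-protein table;
genes without a protein stay in the DiG as non-mappable members — they
can never intersect a protein group, but they still enlarge the DiG's
sample size, making every test conservative rather than silently
shrinking the group.

## Interaction data types

Binary records assert a (direct or indirect) relationship between exactly
two proteins. N-ary records list three or more proteins observed together
and are represented bipartitely: an artificial complex node linked to
each member, recognizable in MITAB by a `complex:` interactor or a `C`
edge type. A third population hides in plain sight: databases that encode
n-ary results as bait-centred fans of binary rows (the spoke model).
`regenerate()` recovers these by grouping whitelisted-method binary
records on the full key (source database, publication, method, bait);
a group must contain at least two distinct preys, because a single
bait-prey row is indistinguishable from a genuine binary record. Records
lacking a bait annotation are skipped and counted rather than assigned an
arbitrary hub. The method whitelist defaults to the nineteen MI codes of
techniques that can produce n-ary data (affinity chromatography,
coimmunoprecipitation variants, pull down, and related).

The binary PIN is built from canonicalized binary records: one edge per
unordered canonical pair regardless of how many databases report it,
self-records excluded (the possible-pair population `n(n-1)/2` of the
enrichment test assumes no self-pairs), with per-edge provenance (source
databases, publications, minimum lpr) kept for attribution reports.

## Statistics

Four similarity indices are computed per (DiG, group) pair: Jaccard,
Meet/Min, Geometric, and a hypergeometric index (`-log p` normalized by
its full-overlap value). Decisions rest on two hypergeometric tests,
both exact upper tails computed on the log scale — printed p-values span
below 1e-12, far outside normal-approximation territory.

**Type 1 (DiG vs protein group).** Population: the distinct proteins
appearing in DiGs plus groups (joint union by default; a fixed population
is configurable, since the published description does not pin down
whether the union was taken jointly or per pair). Success population: the
group. Sample: the DiG, counting non-mappable genes. Successes: the
intersection. P-values are adjusted per DiG across all groups of one data
type (each group one test; a global family is available) with Bonferroni,
Benjamini-Hochberg and Benjamini-Yekutieli; the FDR-adjusted value at
0.05 drives significance calls and best-match selection, as the least
conservative of the three.

**Type 2 (binary enrichment).** Population: all `n(n-1)/2` possible
pairs in the PIN. Success population: the documented edges. Sample: the
possible pairs among the DiG's mapped proteins. Successes: the observed
edges among them. The sample counts pairs over *mapped proteins* rather
than genes: the two coincide for fully mapped DiGs, and pairs involving a
protein-less gene can never be observed, so counting them would only
deflate the test asymmetrically.

The hypergeometric model treats every pair as equally likely, but
high-degree proteins acquire interactions more easily.
`mc_degree_matched_null()` corrects for this: each DiG protein is
replaced, in each of 10,000 simulations, by a node of similar degree
(multiplicative band [d/2, 2d], widened stepwise with a message if
empty — "similar degree" is not otherwise quantified), sampled without
replacement within a simulation; the empirical p uses the standard +1
correction so it is never exactly zero. On degree-homogeneous networks
the MC null and the analytic tail agree closely; the package follows the
survey's operational rule of calling binary enrichment at raw
hypergeometric p < 0.0004, the cutoff whose decisions reproduce the MC
null, while keeping the simulation available for degree-heterogeneous
cases. All thresholds (0.05 for complexes and pathways, 0.0004 for
binary, 0.01 for DiG-DiG overlaps) are exposed in `survey_config()`.

Pathway overlap reuses the type-1 test verbatim on GMT gene sets mapped
to proteins; no pathway-specific statistic exists in this methodology.

## Reporting

`dig_verdicts()` combines the per-data-type results into one row per DiG;
`venn_partition()` counts the exclusive regions (the partition property —
disjoint regions summing to the DiGs significant anywhere — is enforced
by construction and asserted in tests); `database_attribution()` tallies
distinct best-match complexes by source-database set, counting
multi-source complexes once under a combined label;
`low_throughput_fraction()` counts best matches with lpr below 22;
`compare_runs()` produces the side-by-side metric table used to track
how conclusions drift as databases grow. `export_cytoscape()` writes
SIF plus attribute files (circle = DiG, hexagon = complex, edge weight =
Jaccard). Regenerated complexes supported by several databases are
reported as separate complexes (the database is part of the key),
cross-referenced by identical member sets; both tallies are available.

## The synthetic-data generator

`simulate_survey()` emulates the statistical structure of all four
inputs under a single seed that fixes every generated byte:

* disease groups with two to six genes whose Morbid rows cycle through
  realistic title variants (comma subtypes, "due to"/"with" clauses,
  trailing digits and roman numerals, susceptibility braces), plus
  single-gene groups, weaker-evidence noise rows, synonym-only gene
  fields, and a configurable fraction of protein-less genes;
* bipartite complexes (some containing a DiG's mapped proteins, the rest
  decoys), spoke fans sharing one (database, publication, method, bait)
  key, a heterogeneous-degree binary background drawn by weighted
  attachment (weight ∝ rank^-1.2, so the Monte-Carlo null faces
  non-trivial degree structure), planted edge cliques inside selected
  DiGs, and duplicated rows at a configurable rate;
* pathway sets containing whole DiGs plus decoy sets sharing no gene
  with any DiG.

Defaults (300 genes, 5% unmappable, 12 multigenic + 3 singleton DiGs, 12
bipartite + 8 spoke complexes of size 3-6, 150 background edges) keep a
full survey run under a few seconds while leaving every code path
exercised; they are study conditions, not tuning knobs. The generator
does not emulate curation errors, cross-database identifier conflicts, or
the consolidation procedure that produces canonical identifiers in real
distributions — canonicalization is consumed as an input mapping — so
passing tests demonstrate correctness of the survey machinery, not
robustness to dirty real-world inputs.

Test problem sizes were chosen to make the property checks sharp but
quick: exhaustive enumeration oracles run at populations of at most 12;
the MC-vs-analytic comparison uses a 2,000-node degree-10 circulant
graph with 10,000 simulations; calibration uses an Erdős–Rényi network
(2,000 nodes, pair probability 0.05) and 1,000 null DiGs of 40 proteins,
where the discrete test's achievable levels lie close enough to the
nominal α for a 3-standard-error check to be meaningful.

## Numerical and degenerate-input choices

* Hypergeometric tails come from `phyper` (log-scale exact); the
  enumeration oracle in the test suite is an independent combinatorial
  computation.
* Empty set pairs yield `NA` indices; zero overlap yields p = 1; DiGs
  with fewer than two mapped proteins are flagged untestable rather than
  scored.
* Malformed Morbid or MITAB lines are collected in reject reports with
  line numbers, never silently dropped; missing mandatory MITAB columns
  abort with the column name.
* Best-match ties break by larger overlap, then lexicographic group
  identifier — invented rules, stated here because the methodology never
  documents facing a tie.
* DiG identifiers, cluster representatives, regenerated-complex ordering
  and all generator output are deterministic given inputs and seed.

## Known limitations

The title-grouping rules reimplement a described procedure whose exact
regular expressions were never published; edge-case behaviour (e.g.
which cluster wins when a key prefix-matches two existing clusters) is
fixed here by the sorted-order rule and may differ from the original on
pathological inputs. Headline counts from any particular disease
catalogue or interaction-database release depend on those licensed,
versioned inputs and are out of scope; the package instead guarantees the
statistical machinery (exact tails, adjustment ordering, calibration,
planted-structure recovery) on data whose ground truth is known.
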