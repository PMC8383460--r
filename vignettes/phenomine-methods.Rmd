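---
title: "Methods: mining and harvesting disease-phenotype associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and harvesting disease-phenotype associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomine)
```

## The problem

Clinical data is recorded against disease terminologies such as ICD-10,
while computational phenotype analysis (patient matching, gene
prioritization, cross-species comparison) runs on phenotype ontologies such
as HPO and MP. Most ICD-10 classes have no curated phenotype profile.
`phenomine` builds such profiles by two complementary routes and evaluates
them against gold standards:

1. **Text mining**: detect disease and phenotype class mentions in an
   abstract corpus, propagate mentions over the subclass hierarchies, and
   score each disease-phenotype pair by normalized pointwise mutual
   information (NPMI).
2. **Semi-automatic harvesting**: merge curated association tables through
   cross-terminology mapping bridges (e.g. OMIM-keyed annotations bridged
   onto ICD-10 codes), filter generic phenotypes, and propagate annotations
   down the disease hierarchy and via lexical superclass matches.

## The NPMI model

For ontology classes $C$ (disease) and $D$ (phenotype), every class is
represented by its term set $\mathrm{Terms}(C)$: the normalized labels and
synonyms of $C$ and of every subclass of $C$. Mentioning any member of
$\mathrm{Terms}(C)$ in an abstract counts as mentioning $C$ — this is
equivalent to detecting direct mentions and closing the mention set under
superclass addition, and the package tests both routes against each other.

Counts are abstract-level and boolean (an abstract either mentions a class
or it does not). The restricted corpus is the set of abstracts containing
at least one disease *and* one phenotype mention; $n_{tot}$ is its size,
and $n_C$, $n_D$, $n_{C,D}$ are occurrence and co-occurrence counts over
that corpus. The association score is

$$\mathrm{npmi}(C,D) =
  \frac{\log\frac{n_{C,D}\, n_{tot}}{n_C\, n_D}}
       {-\log\frac{n_{C,D}}{n_{tot}}} \in [-1, 1],$$

0 at independence and 1 at perfect co-occurrence. Counting all four
quantities over the same restricted corpus keeps the score internally
consistent ($n_{C,D} \le \min(n_C, n_D) \le n_{tot}$ guarantees the upper
bound). Two degenerate cases are defined by convention so the codomain is
total: $n_{C,D} = 0 \mapsto -1$ and $n_{C,D} = n_{tot} \mapsto +1$. The
natural logarithm is used; NPMI is base-invariant. Association datasets
keep strictly positive scores (`score_all(positive_only = TRUE)`), and
per-disease profiles are built by ranking phenotypes by score and cutting
at rank $k$ (`threshold_profile`); ties are broken by phenotype identifier
so runs are reproducible.

### Matching and normalization

The matcher is deliberately simple and fully specified: lowercase,
collapse whitespace, strip leading/trailing punctuation per token, no
stemming. Matching is longest-match, non-overlapping, on token boundaries;
a term naming several classes yields all of them. Acronyms receive no
special casing — they pass through the same normalization as any label.
Disease mentions are propagated up the disease hierarchy exactly as
phenotype mentions are propagated up theirs; the disease side can be
switched off (`propagate_disease = FALSE`) since one could argue for
propagating only phenotypes, but the symmetric default follows from
$\mathrm{Terms}(\cdot)$ being defined identically for every class.

## The harvesting pipeline

`run_harvest` composes, in order: bridge curated associations through a
mapping table (`bridge_associations`; fan-out when one source id maps to
several codes, drops reported for unmapped ids), deduplicate keeping one
provenance per pair, filter generic phenotypes, propagate down the disease
hierarchy (`propagate_icd`), lexically annotate still-unannotated diseases
(`propagate_lexical`), optionally restrict to a common-disease list, and
apply expert overrides (`apply_curation`).

Decisions worth noting:

* **Provenance precedence** when the same pair arrives repeatedly:
  `umls_direct > hpo_via_umls > hpo_via_wikidata > wikidata > expert >
  prop_icd > prop_lexical`. Direct mappings have empirically far lower
  error rates than bridged ones, so the most direct source keeps the
  credit; propagated records never displace curated ones.
* **Hierarchy propagation** is parent-to-child only (a class's phenotypes
  are inherited by its subclasses; e.g. a G30-level annotation reaches
  G30.0-G30.9). Child-to-parent ascent is not performed — a subclass's
  specific phenotype need not hold for the broader class. For codes absent
  from the loaded hierarchy, dotted-code syntax (`G30.0` under `G30`)
  stands in; chapter/block levels are never synthesized.
* **The generic-phenotype filter** ships with five canonical ids
  (inheritance modes, clinical modifier, laterality). Curation teams
  typically block around twenty; the list is an input
  (`filter_generic(records, blocked = ...)`) precisely because it is a
  curation decision, and only ids with a defensible default are shipped.
* **Lexical matching** links an unannotated disease to a phenotype class
  whose normalized label occurs as a token-boundary substring of the
  disease label (longest label wins). Only diseases with no record from
  any other provenance are eligible, so the weakest evidence never
  overwrites stronger sources.
* Removals are never silent: filtered and curated-out records are returned
  through attributes (`n_removed`, `removed`) and the released set's
  provenance counts always partition its total.

## Embeddings and similarity

Phenotype profiles are compared in a vector space learned from the
annotation graph: nodes are phenotype classes plus entities (diseases or
genes), edges are subclass edges plus entity-phenotype annotation edges.
The graph is explored by uniform random walks (depth 3, 10 walks per node
by default) and the walk corpus is embedded by skip-gram with negative
sampling (dimension 100, window 5, minimum count 1). Walk depth, window
and dimension follow common practice for graph embeddings of this type;
walks per node is a throughput dial with no effect on the expected
neighborhood distribution. Similarity is cosine,
$\mathrm{sim}(v_1,v_2) = v_1 \cdot v_2 / (\lVert v_1\rVert\,\lVert
v_2\rVert)$, and ranking quality is summarized by ROC AUC in its
rank/Mann-Whitney form (ties count one half), which the tests verify
against a brute-force concordant-pair count.

Training is single-worker and fully seeded: walk generation uses R's RNG
under the caller's seed, and the trainer's negative sampling uses an
internal xorshift generator, so a (walks, seed) pair reproduces vectors
bit-for-bit. The per-pair SGD with linearly decaying learning rate is
implemented in C++; at fixture scale a training run takes well under a
second.

## Strict and soft evaluation

`compare_strict` is exact set algebra on (disease, phenotype) pairs.
`compare_soft` first closes both prediction and gold sets under
phenotype-ancestor addition per disease, then compares exactly; the
disease side is never closed. Soft evaluation therefore credits
predictions that differ from the gold standard only in granularity, and
its true-positive count can never fall below the strict one (a tested
invariant). P/R/F are kept at full precision internally and rounded to two
decimals only in reports; coverage percentages round to a whole percent.
The error-analysis report (`corrected_report`) re-labels a caller-supplied
number of false positives as true positives — the subset comes from manual
review and is an input, never inferred.

## What the synthetic fixtures emulate

The generators produce, from a single seed: two labeled DAG ontologies
with multi-token labels and synonyms (disease side with dotted ICD-style
leaf codes), a corpus with planted co-mention structure, a gold standard
with ancestor-lifted variants, mapping bridges with an adjustable
wrong-link fraction, and gene-phenotype tables as noisy copies of disease
profiles.

Default study conditions: 2,000 documents, 20 planted pairs co-mentioned
at rate 0.3 per document, matched background pairs at 0.02, and a solo
mention rate of 0.05 per leaf class so that marginal counts exceed joint
counts (in real abstracts most class mentions are not co-mentions; without
solo mentions every observed pair would degenerate to NPMI = 1). Planted
and background pairs use disjoint leaf classes so each pair's nominal
co-mention rate is exact, which the tests verify against binomial
standard errors. Hierarchies default to depth 3 with branching 4 (85
classes, 64 leaves per side).

What the fixtures do **not** emulate: natural language (documents are
label bags in filler text — no negation, no ambiguity, no acronym
collisions), realistic label distributions, corpus-scale class imbalance,
and the long-tailed annotation depth of real curated databases. Passing
the planted-recovery suite shows the statistical machinery is correct; it
does not certify extraction quality on real text.

## Numerical and degenerate-input choices

* NPMI conventions at the boundary, above; zero marginals with a nonzero
  joint raise `phenomine_inconsistent_counts` rather than returning NaN.
* Rank ties: lexicographic phenotype id, applied identically in scoring
  and in the tests' independent sort oracle.
* An empty restricted corpus (no co-mention abstract) is an error, not an
  empty result, since every downstream quantity would be undefined.
* Cosine of a zero vector and AUC of a single-class sample are errors with
  dedicated condition classes.
* Obsolete or unlabeled ontology classes load but never enter the term
  lexicon — they cannot be mentioned in text.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full pipeline on corpora
of 120-2,000 documents over 85-class ontologies, 5 seeded replicates for
planted recovery and 10 seeded replicates for embedding checks; metric
arithmetic (P/R/F, coverage, provenance totals) runs on the reference
count tables shipped under `inst/extdata/`. These sizes make every check
a pure function of a small seed set while keeping each property
statistically identifiable.

## Known limitations

* The matcher has no disambiguation: a string naming several classes
  counts for all of them.
* Mention propagation assumes the subclass hierarchy is the only semantic
  relation worth closing over; part-of or association axioms are ignored.
* The lexical superclass match is a single containment heuristic; it is
  isolated behind its own provenance tag so downstream users can drop it.
* The embedding graph uses subclass + annotation edges only; richer axiom
  patterns would need a different graph builder, which the walk-corpus
  file interface allows swapping in.
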