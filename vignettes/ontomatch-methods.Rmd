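---
title: "Matching large ontologies with ontomatch: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching large ontologies with ontomatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontomatch)
```

## The problem

Biomedical knowledge organisation systems — from flat terminologies to formal
OWL ontologies — describe overlapping domains with different vocabularies.
Interoperating between them requires an *alignment*: a set of equivalence
mappings $\langle e_1, e_2, s \rangle$ between entities (classes and
properties) of two ontologies, each with a confidence score $s \in [0, 1]$.
At the scale of resources like SNOMED-CT or the FMA (tens to hundreds of
thousands of concepts), pairwise comparison of all entities is infeasible;
`ontomatch` instead treats matching as an information-retrieval problem:
every entity becomes a small *virtual document*, each ontology becomes a
searchable inverted index, and candidate mappings are found by querying one
index with the other ontology's documents.

## The model

### Ontologies and virtual documents

An ontology is modelled as a 5-tuple: a concept set, relations split into an
is-a taxonomy, transversal (object-property) relations and datatype
attributes, a property hierarchy, and a label function mapping concepts to
their (multilingual) synonym terms. `load_ontology()` reduces OWL (RDF/XML
or Turtle), RDFS, SKOS and OBO 1.4 files to this model; SKOS
`prefLabel`/`altLabel` and OBO `name`/`synonym` all populate the label
table, `skos:broader` and OBO `is_a` both populate the taxonomy.

The *direct virtual document* dVD(e) of an entity collects its URI, local
name, labels per language, comments, and — for properties — domain/range
labels and constraint flags, in named fields (`directNameC`,
`directLabelCEN`, `dRange`, `propertyType`, ...). Fields are generated
dynamically: an entity only has the fields its description supports. The
*extended* document eVD(c) adds the labels and local names of the direct
parents (`supLabels`, `supLocalNames`); for properties, the super-property
local names.

### Normalization, permutation and exact indexing

Every label passes through a fixed filter chain: camelCase/underscore
splitting, lowercasing, removal of non-alphanumeric runs, tokenization,
stopword removal, spelling out of integer tokens 0–999 ("T9 Vertebra" and
"Ninth thoracic vertebra" then share a stemmable token), and Porter
stemming. The stemmer is implemented in the package and the stopword lists
ship as plain-text files, so results are reproducible across machines. A
stem can itself be a stopword ("NOS" → "no"), so stopwords are re-filtered
after stemming; this makes the chain idempotent on its own output.

UMLS-derived synonym lists often contain all word orders of a term
("myocardial infarction", "infarctions myocardial"). To be robust to this,
labels are enriched with all permutations of their first four words
(before stemming, after stopword removal). In *exact* indexing mode, each
permuted, stemmed variant is concatenated without spaces into a single
term ("thoracic vertebral foramen" → `thoracvertebrforamen`, ...), giving
high-precision whole-label matching that is word-order invariant by
construction. *Relaxed* mode indexes the token streams instead and is used
for the extended stage, where eVDs mix many labels.

### Retrieval and scoring

The index scores a query document against an indexed entity with a
Lucene-style tf-idf function:

$$\mathrm{score}(q, e) = \mathrm{coord}(q, e)\,\cdot\,\mathrm{queryNorm}(q)
  \sum_{t \in q} \sqrt{tf_{t,e}}\; \mathrm{idf}(t)^2\; \mathrm{boost}(t)\;
  \mathrm{norm}(t, e)$$

with $\mathrm{idf}(t) = 1 + \ln(N / (1 + \mathrm{entityFreq}(t)))$,
$\mathrm{norm}(t, e) = \mathrm{fieldBoost}/\sqrt{\mathrm{field\ length}}$,
$\mathrm{coord}$ the fraction of query terms matched and
$\mathrm{queryNorm} = 1/\sqrt{\sum_t \mathrm{idf}(t)^2}$. These constants
are frozen in the package and pinned by a dual-route test: the
postings-based search must produce exactly the scores of a dense
linear-algebra evaluation of the same function. The `uri` field is boosted
at 0.5 (URIs rarely carry independent evidence); all other fields default
to 1 and are configurable.

### The lexical stage (M_exact, M_prop)

Each concept of ontology 1 queries the index of ontology 2 and vice versa.
Per query the Best-k hits (default `best_k = 3`) with engine score at least
`max_score` (default 0.1 on this package's score scale) are kept, and only
pairs found from *both* directions survive. The engine score acts as a
pre-filter comparing labels as a whole; surviving pairs are then scored
with the weighted string-similarity ensemble

$$\mathrm{Sim}_{lex}(e_1, e_2) = \alpha\,\mathrm{ISub} + \beta\,\mathrm{QGram}
  + \gamma\,\mathrm{Levenshtein}, \qquad \alpha + \beta + \gamma = 1$$

and kept when $\mathrm{Sim}_{lex} \ge \theta$ (default 0.75). Defaults are
$\alpha = 0.4, \beta = 0.3, \gamma = 0.3$ — ISub weighted highest as the
measure designed for entity names — and all are configurable and echoed
into the run report. Each component is the maximum over the cross pairs of
the two entities' label sets, where a label set contains the normalized
pre-stem strings *including the permuted variants*. Evaluating
$\mathrm{Sim}_{lex}$ on permuted variants is deliberate: a pair like
"heart attack" / "attack heart" scores 1 exactly, keeping the exact stage's
word-order invariance through the threshold filter, whereas raw-string
evaluation would score such pairs around 0.55 and discard them. Properties
are matched with the same pipeline, restricted to object–object and
datatype–datatype pairs (M_prop).

Two string-metric conventions are pinned by tests rather than left to
chance: ISub's native $[-1, 1]$ range is rescaled to $[0, 1]$ by
$(x+1)/2$, its greedy common-substring removal is evaluated in canonical
(lexicographic) argument order so the measure is symmetric, and identical
strings score 1 regardless of length; Monge–Elkan is symmetrized as the
mean of its two directional values. Q-grams use $q = 3$ with boundary
padding and Dice normalization.

### The extended stage (M_extended)

Concepts unmatched by the lexical stage are re-indexed as eVDs in relaxed
mode and searched two-way again, so pairs supported partly by ancestor
vocabulary can surface; the same $\theta$ filter applies. Independently, a
synonym lexicon (TSV of normalized `term`/`synonym` pairs — the bundled
generator emits one; a WordNet-derived table can be attached the same way)
bridges residuals: each label is expanded by single-hop, whole-word or
whole-phrase substitution, and a pair is proposed when an expanded label of
one side equals a label of the other side as an exact permuted-stemmed
form. Substitution is deliberately single-hop — synonym chains degrade
precision quickly — and bridged pairs are floored at
$\theta_{syn} = \theta$ since the lexicon itself asserts the equivalence.

### The contextual stage (M_context)

Lexical matching cannot find concepts whose labels share nothing. The
contextual stage assumes M_exact is high-precision and uses it as a base
learner. Candidate pairs (*pcc*) are the unmapped cross pairs among the
ancestors × ancestors, descendants × descendants and siblings × siblings of
each anchor pair. Each candidate is gated by a structural score
$s = s_{sub} + s_{sup} + s_{sib} > \varphi$ (default 0.5), where matched
descendant/ancestor pairs within depth 2 contribute $1/\mathrm{depth}$
(evidence further away counts less — the depth kernel is the package's
choice; only the monotone principle is inherent to the method) and matched
sibling pairs contribute 1.

Gated pairs are classified by a decision tree over five string features
(q-gram, Levenshtein, block distance, word Jaccard, Monge–Elkan) computed
between *context texts*: the entity's normalized labels plus those of its
direct parents, properties excluded. Training data is auto-labelled: every
anchor is a "yes"; for each anchor $(c_1, c_2)$, `neg_per_pos = 2` "no"
rows pair $c_1$ with a sampled ancestor or descendant of $c_2$ — a concept
cannot map both to a concept and to its ancestor or descendant. The tree
is fitted with `rpart` (CART); a tied leaf predicts "no", keeping the
stage precision-first. With fewer than `min_positives = 10` anchors the
stage aborts and M_context is empty.

### Post-processing

Candidates are the disjoint union of the four stages (later stages never
re-propose earlier pairs). Two consistency filters then run, in order:
*disjointness* — if $c_1 \perp c_2$ in one ontology and $(c_1, c_3)$ is an
anchor, any candidate $(c_2, c_3)$ is discarded — and *criss-cross* — for
an anchor $(c_1, c_2)$, candidates pairing $c_1$ with a transitive
ancestor/descendant of $c_2$ (or vice versa) are discarded. Anchors
themselves are exempt from the criss-cross filter: they define the
constraint; the filters exist mainly to repair the less precise extended
and contextual candidates. Transitive (not just direct) hierarchy closure
is used, since a mapping conflicts with an anchor at any depth. After
filtering, *enrichment* adds unmapped direct-child pairs of mapped pairs
when their $\mathrm{Sim}_{lex}$ passes $\theta$ (gating enrichment by
$\theta$ rather than adding all sub-concept pairs unconditionally preserves
the precision-first character; the gate can be disabled in config).
Finally a greedy selector sorts by score (ties: provenance rank
exact > prop > extended > context, then IRI order) and emits a one-to-one
or one-to-many alignment.

External logical repair systems are a documented hook, not a dependency:
full coherence repair tends to be aggressive and is out of scope.

### The light profile

`profile = "lt"` reproduces a fast degenerate configuration: only the
larger ontology is indexed, the smaller one queries it, properties and the
contextual stage are skipped, candidates are selected by Levenshtein
similarity of local names, and the output is one-to-many. It is useful as
a high-throughput baseline and in the acceptance script doubles as a
second, independently configured measurement.

## Evaluation

With a reference alignment, `evaluate_alignment()` computes
$P = |RM \cap CM| / |RM|$, $R = |RM \cap CM| / |CM|$ and
$F = 2PR/(P+R)$ over unordered entity pairs, returning 0 (with a warning)
on zero denominators. Alignments and references are read and written in
the OAEI Alignment RDF format; cells are serialized in sorted order so the
same result always produces byte-identical files.

## The synthetic generator: what it emulates and what it does not

`generate_pair()` builds a random is-a tree with unique 2–3-word labels
drawn from a pool of pronounceable pseudo-words, object/datatype
properties with domains, ranges and functional flags, and optional sibling
disjointness. The second ontology is a namespace-shifted copy whose labels
are, per concept: word-permuted (`p_permute`), replaced through an emitted
synonym lexicon (`p_synonym`), replaced by an opaque 8–12-letter code-like
token (`p_opaque`), or kept; a `p_unmatched` fraction of concepts is
deleted, with children re-attached to the nearest surviving ancestor. The
surviving copy pairs are the reference alignment.

Defaults — 300 concepts, branching 3, 10 properties, `p_permute = 0.15`,
`p_synonym = 0.1`, `p_opaque = 0.1`, `p_unmatched = 0.1`,
`p_disjoint_siblings = 0.05` — are chosen once as a plausible profile of a
mid-sized biomedical vocabulary pair annotated from a shared metathesaurus:
most labels agree, a substantial minority differ by word order or synonymy,
and a tail is unrecognizable. Opaque labels are single code-like tokens,
mirroring identifier-style names in real vocabularies.

The generator emulates the *mechanisms* the matcher targets (word-order
variation, synonymy with a lexicon, lexically opaque concepts anchored by
structure, missing concepts, disjoint siblings). It does not emulate
several features of real biomedical ontologies: labels are not
morphologically related across concepts (no shared heads like "lobe of
lung"/"lobe of liver"), hierarchies are trees rather than DAGs with
multiple parents, there is no multilingual labelling, and synonym lists
per concept have size 1. Passing tests therefore demonstrate that each
pipeline stage does its job under controlled conditions, not that the
measured F-values transfer to any particular real ontology pair.

## Numerical and degenerate-input choices

* Thresholds are inclusive ($\mathrm{Sim}_{lex} \ge \theta$) except the
  structural gate ($s > \varphi$), matching each rule's natural reading.
* All randomness (negative sampling, generator perturbations) flows from
  explicit integer seeds; per-stage seeds are derived from the master seed
  by fixed offsets, and tree fitting is deterministic.
* Ties everywhere break deterministically (score, then provenance rank,
  then IRI lexicographic), so repeated runs are byte-identical.
* Entities with no label fall back to their local name; entities with
  neither are indexed with a URI-only document and logged.
* Input is-a cycles (a taxonomy should not have them) are broken by
  dropping the back-edge encountered last in load order, with a warning.
* Empty label sets give $\mathrm{Sim}_{lex} = 0$ with a warning; empty
  M_exact degrades the contextual stage to an empty M_context.
* Comments are indexed into a dedicated low-value `comments` field; domain
  and range fields of property documents use the referenced concepts'
  labels (falling back to local names), unstemmed.

## Problem sizes used by the test and acceptance suites

The bundled suites run the pipeline at 300–500 concepts per ontology —
identity recovery at 500, permutation robustness at 300, synonym bridging
at 300, contextual recovery at 400 (20% opaque), plus smaller fixtures for
unit-level properties. These sizes exercise every stage with comfortable
statistical margins while keeping the default check fast; the method
itself has no size-dependent switches except the documented small/large
task profile (500-concept rule), so behaviour at larger scale differs only
in runtime.

## Known limitations

* Only equivalence mappings are produced; subsumption/disjointness
  orientation and instance-level matching are out of scope.
* No OWL reasoning: disjointness is taken from explicit axioms only, and
  no coherence repair is attempted beyond the two structural filters.
* The Porter stemmer and bundled stopword list cover English; other
  languages currently fall back to unstemmed tokens without stopword
  removal.
* The contextual stage needs a reasonably large, high-precision M_exact;
  on nearly disjoint vocabularies it correctly degenerates to producing
  nothing rather than guessing.
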