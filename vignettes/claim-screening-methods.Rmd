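---
title: "Knowledge-graph claim screening: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-graph claim screening: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mkgfwa)
```

`mkgfwa` screens health-insurance claims for three clinically incoherent
patterns — a diagnosis no prescribed drug treats, therapeutically duplicated
drugs, and interacting drugs — by deterministic rule reasoning over a typed
medical knowledge graph. This vignette explains the underlying models, the
parameters that matter, what the synthetic fixtures do and do not emulate,
and the design decisions taken where more than one reading was defensible.

## The graph model

Nodes carry one of seven categories. Diseases follow an ICD-10-style
taxonomy (`is_a` between diseases encodes chapter/block/category nesting);
drugs are modelled at three levels — product, generic, and ATC class — with
`is_a` running product → generic → ATC and ATC → ATC up the classification;
examinations, symptoms, and operations complete the schema. Seven edge
types are allowed (`is_a`, `indication`, `contraindication`, `interaction`,
`check`, `treat`, `has_symptom`), each restricted to specific endpoint
categories; `interaction` edges carry a subtype (`promotion`,
`contraindication`, `none`) and sit preferentially at the ATC level, where
chemical-composition knowledge lives. Edges are directed; where a reasoning
rule needs a direction-less step, the matcher takes the union of both
directions.

Validation is strict about endpoint categories, required codes (ATC nodes
must carry one), interaction subtypes, and confidence bounds, but tolerant
of `is_a` cycles: real terminologies are near-acyclic, so a cycle produces
a warning while every traversal keeps a visited set and terminates
regardless. Manually curated edges default to confidence 1.0; extractor
provenance and confidence are stored per edge so a curation workflow can
prioritise review.

## Extraction from drug-label text

Tokenization is per unicode character — Chinese clinical text has no
whitespace tokens — and all spans are 0-based half-open character intervals.

**Entity tagging and repair.** `dictionary_tag()` performs greedy
leftmost-longest lexicon matching. `adjust_tags()` repairs an arbitrary
(possibly invalid) per-character tagging with three ordered fixes: span
completion grows a predicted span into adjacent untagged characters and
accepts the longest dictionary-validated extension, capped at 10 characters
of total growth (the cap prevents pathological growth; dictionary terms in
the packaged fixtures are ≤ 6 characters, which also makes the operation
idempotent); type resolution prefers the dictionary's type when the final
span is a dictionary term, otherwise the majority type among the model's
per-character predictions, ties breaking toward the type of the `B-` tag;
finally valid B-I-O labels are re-emitted. A fresh `B-` tag inside a tagged
run starts a new entity instance, so two adjacent correct entities are never
merged, while dangling `I-` runs (the classic inconsistent-tagging mistake)
are treated as one instance.

**Property values.** Recognition is regex-driven with two rule flavours:
self-contained patterns (e.g. `一日(0-9)+次` for a daily frequency) and bare
number+unit patterns that are only retained when a context keyword occurs in
the same clause. The context window is the clause (split on `，。；`) because
drug-label sentences pack several fields into comma-separated clauses; a
fixed character window is available where clause structure is absent.
Prohibition contexts (`禁用`, `禁止`, …, configurable) flip a hit's polarity
to `prohibited`, excluding it from dosing entries — dosage statements and
prohibition statements about a population would otherwise be
indistinguishable. Numeric payloads normalize ranges (`0.4-0.6`),
per-weight doses (`mg/kg`), and simple Chinese numerals (一…十, 半);
anything beyond that stays raw.

**Combination.** Hits combine into one medication entry per
(population, indication) context: hits within a sentence combine directly; a
field missing from the current context inherits from the previous entry; and
a change of population starts a new entry in which indication, frequency,
and duration are never inherited, since those change along with the
population. Every affirmative hit ends up in exactly one entry or in a
discard log with a reason — nothing is silently dropped.

**Interaction sentences.** After entity mentions are replaced by type
placeholders, classification rules run in file order and the first match
wins; this makes rule conflicts explicit and reproducible. The shipped rule
set covers the standard phrasings (prohibited combination, compatibility
taboo, interference with action, enhancement of effect/efficacy, no
interaction, unchanged action) plus three lower-priority fallbacks
(`禁忌` alone, combination-raises-risk, bare no-change) needed for common
label prose that the specific patterns miss.

## Entity linking

Claim terms arrive from heterogeneous hospital systems with typos,
transliteration variants, and elided components. The linker combines two
signals.

**Multilevel string distance.** A weighted edit distance in which
substituting two characters that share an attribute on some level costs that
level's discounted rate instead of the full substitution cost. Shipped
levels: pronunciation (homophone typos, discount 0.2) and radical
(semantically sibling characters, discount 0.5), with insert = delete =
full substitution = 1. The three levels are realized as a single dynamic
program whose substitution cost is the minimum over applicable levels —
the alternative (three separate distances combined afterwards) is less
sharp and was rejected; this is an interpretation choice, recorded here.
With no attribute maps the distance reduces exactly to plain weighted edit
distance and never exceeds it. Similarity normalizes by
`max(len) × max unit cost` so it lands in [0, 1].

**Semantic units.** Names decompose by greedy longest match against
category lexicons (11 categories: body structure, laterality/position,
negation, degree adverb, type/stage, pathogen/etiology, age group, sex,
temporal course, morphology, and the residual core term — the exact
taxonomy is configurable, and the packaged lexicons cover the fixture
vocabulary only). Same-category units compare through a per-category
synonym graph (direct edge weight, else best 2-hop product, else the string
similarity as fallback), so 手部 and 手 score 1.0 despite different surface
forms. The composite score is the weight-normalized sum of the string-level
similarity and per-category unit similarities (categories present on one
side only contribute 0); defaults weight everything equally (`w0 = w_k =
1`). A mismatch in a *critical* category — type/stage and negation by
default — caps the score at 0.3: type 1 and type 2 diabetes differ by one
character yet are different diseases, and no amount of surface similarity
should link them.

**Retrieval and thresholds.** Candidates come from an inverted index keyed
by characters *and* their attribute values (so a homophone typo still
retrieves its target), ranked by distinct-key overlap with ties toward
shorter names; the top k = 20 nodes are reranked with the composite score
against every name and synonym. An exact name/synonym match short-circuits
retrieval — identical strings score 1 by construction and must never fall
out of the candidate cut. The linking threshold is τ = 0.75 with a curation
band [0.5, 0.75): best scores in the band are exported for human review,
and applied decisions (synonym, new entity) feed the next linking round —
the self-learning loop. τ and the band are conventions, not fitted values;
they sit comfortably between the exact-match regime (≥ 0.9 for one
discounted typo in a 3-character name) and the unrelated-string regime
(≤ 0.5).

## Reasoning and detectors

Reasoning rules are bounded path patterns in a Cypher-like syntax, parsed
into node labels and edge constraints (type, direction, hop range).
Variable-length segments match simple paths only, which guarantees
termination on cyclic graphs; a `*0..k` segment matched at 0 hops collapses
its two node slots onto one node, whose already-verified label stands in
for the collapsed slot's label (without this waiver the fraud rule could
never accept the claimed drug itself as the indicating drug).

The detectors implement the three rules with one deliberate extension each,
all configurable:

* **Fraud diagnosis.** A claimed disease counts as covered when the claimed
  drug — or a drug sharing an ATC parent within one `is_a` hop — has an
  indication edge to the disease or to a disease one undirected taxonomy
  step away. The identity (0-step) disease case is included even though the
  rule as written has a mandatory step: an exact indication match must never
  be missed. Subtypes: `uncovered_disease` (an absence finding, empty
  evidence), `contraindicated` (edge evidence), `no_indication` (a drug
  covering none of the claimed diseases; its known indications attach as
  context evidence). Diagnosis-only claims are skipped by default (nothing
  to justify against; `fraud_on_drugless` enables the strict reading).
* **Excess prescription.** At least `excess_threshold = 2` claimed drugs
  under one direct ATC parent, each itself indicated for the same claimed
  disease. Requiring per-drug indication (rather than the single indication
  the rule as written names) avoids flagging two same-class drugs where one
  treats a different claimed diagnosis. A plain-count mode is not provided:
  "many drugs for one disease" without class duplication is medically
  routine (combination therapy).
* **Irrational prescription.** Drug pairs expand to ATC ancestors (free
  hops through the drug levels, then at most `atc_extra_hops = 3` ATC
  levels) and flag when an interaction edge with subtype ≠ `none` connects
  the expanded sets (or the drugs directly). Contraindication-subtype
  interactions are `high` severity, promotions `info`. Read literally the
  rule as written contains only `is_a` steps meeting at a common ATC node —
  shared ancestry alone would flag every same-class pair — so the default
  requires the explicit interaction edge; `strict_literal_irrational = TRUE`
  restores the literal reading.

Findings are ordered deterministically (fraud, excess, irrational; stable
within detector), every evidence path re-validates against the graph, and
batch screening is claim-independent and free of randomness, so reports are
byte-identical across reruns and safe to parallelize.

## Synthetic fixtures: what they emulate and what they do not

The generators exist so that every module is testable offline. A toy graph
is an ATC taxonomy of configurable depth/branching (default 2 × 4 plus a
root: 21 ATC nodes) with generic drugs attached round-robin to its leaves
(default 85), a two-level disease taxonomy (90 leaf diseases under organ-
and body-site family parents), Bernoulli-sampled indication (0.04 per
drug–disease pair; about 3.4 indicated drugs per disease, echoing the
roughly 2:1 drug-to-diagnosis ratio of real claim corpora),
contraindication (0.01), and ATC-level interaction edges (0.10 per ATC
pair; subtypes 0.4/0.4/0.2). Every drug is guaranteed one indication and a
few ATC leaves are guaranteed a drug pair with a shared indication so
excess events are always plantable; generation errors name the missing
structure when a requested event type has nothing to build on.

Claim batches draw diagnosis/drug counts as `1 + Poisson(mean − 1)` with
means 1.5 and 2.3 — the published per-claim averages of a large claim
corpus — and are *clean by construction*: every claimed disease directly
indicated by a claimed drug, every drug covering a claimed disease, no
shared ATC parents, no expanded-set interactions, no contraindicated
pairs. Diagnoses are drawn one at a time and an uncoverable disease is
redrawn individually, so the count distribution is preserved; the drug
count is truncated from above when the claimed diseases have too few
distinct compatible drugs, which leaves the empirical drug mean slightly
below nominal (≈ 2.0–2.1). Planted events are mutually exclusive per claim
(drawn by rate bands) so one planted structure can never mask another. The
typo model applies exactly one corruption per affected term: homophone
substitution, radical-sibling substitution, or component drop (手部擦伤 →
手擦伤), all via the packaged attribute tables.

What passing tests on these fixtures show: the detectors implement their
rule premises exactly (planted recall 1.0, clean-claim false positives 0 at
typo rate 0), and the multilevel linker strictly dominates plain edit
distance under the typo model. What they do not show: performance on real
ICD-10/ATC content, real label prose (the fixture vocabulary is a closed
~200-term synthetic set), OCR noise, or corpus-scale graphs — the fixture
statistics carry no claim beyond the published per-claim means.

## Numerical and degenerate-input conventions

Distances and scores are plain doubles; score ties in candidate ranking
break toward shorter names then lexicographically, and rule conflicts break
by file order — every tie-break is deterministic. Two empty strings are
defined maximally similar (1). Empty claims produce no findings rather than
errors; unknown terms are data (they feed curation), not failures. Problem
sizes in the shipped tests and acceptance script — 500-claim batches, a
~200-node graph, 100 random graphs of ≤ 30 nodes for the matcher oracle,
sampled string pairs for the distance oracle — were chosen to exercise
every code path at desk scale.

## Known limitations

Dosage-overdose and population-suitability checks are out of scope (the
extraction module recovers the fields a future detector would need). The
linker's unit alignment concatenates multiple units of one category before
comparison — adequate for short clinical names, lossy for long composite
ones. The evaluation harness matches findings to planted events by scenario
and entity overlap, which is exact on the fixtures but would need entity
weighting on real data, where one claim can hold several events of one
scenario.
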