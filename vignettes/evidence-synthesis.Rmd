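---
title: "Synthesising causal DAGs from reviewed evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesising causal DAGs from reviewed evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dagsynth)
```

## The problem

Covariate adjustment in observational studies is only as good as the
causal diagram that justifies it, yet most published directed acyclic
graphs (DAGs) are built informally: the analyst draws arrows from
intuition and the reader has no way to audit why any particular edge is
present, absent, or pointed the way it is. dagsynth operationalises a
protocol that derives the DAG from the primary literature instead. Every
edge decision is made by an explicit criterion, recorded in an
append-only log, and carried forward with provenance, so the final
graph is a transparent, contestable synthesis of the evidence rather
than an opaque drawing.

## The model

A graph in dagsynth is a *mixed graph*: nodes plus unordered node pairs,
each pair carrying at most one edge with

* an **orientation** — `directed`, `bidirectional` (shorthand for an
  unmeasured common cause), or `unassigned` (direction not yet decided);
* a **status** — `candidate` (awaiting assessment), `retained`, or,
  recorded separately, `deleted`;
* a **confidence** (`normal` or `low`) and a **provenance** set of
  `study@stage` tokens.

Graphs move through three stages. *Implied* graphs may contain
candidates and cycles; *translated* and *integrated* graphs must be
acyclic over their directed edges and contain no unresolved candidates —
these invariants are enforced, not advisory. Deletions are first-class:
a deleted pair is remembered with its rationale, which is what makes
"there is no edge here" an auditable claim rather than an omission.

## The procedure

### 1. Mapping

A `study_record()` captures one study's conclusions: exposures,
outcomes, controlled covariates, and any reported mediator or
instrument relationships. `map_study()` renders these as directed
candidate edges (exposure → outcome; each control → every exposure and
outcome; mediator and instrument edges as reported) and then
**saturates** the graph: every remaining pair receives an `unassigned`
candidate edge. Saturation encodes the protocol's key asymmetry —
omitting an edge asserts independence, the stronger claim, so absence
must be argued for every pair, not merely left undrawn.

```{r}
rec <- study_record("hypothetical",
                    exposures = "parental_alc_hist",
                    outcomes = "adol_alc",
                    controls = c("adol_sex", "adol_substance"))
map_study(rec)
```

### 2. Translation

Both directions of every candidate pair are assessed through four
criteria *in order*, stopping at the first failure:

1. **temporality** — can the cause precede the effect? A `no` is
   terminal. An `unknown` (ambiguous ordering) passes but forces the
   direction's confidence to `low`.
2. **face_validity** — is the direction plausible on its face? `no` is
   terminal.
3. **recourse_to_theory** — is there a theoretical account? This
   criterion is *never* terminal; `no` and `unknown` merely inform the
   record. Absence of theory is an observation about the literature,
   not about the world.
4. **counterfactual** — does the effect change in the thought
   experiment where the cause is altered? `no` is terminal.

The two directional outcomes combine mechanically: both retained →
`bidirectional` (the evidence supports an unmeasured common cause);
one retained → keep that direction (reversing the posited edge if
needed); neither → `delete`. `translate_graph()` applies this to every
candidate, records deletions, verifies acyclicity (a cycle among
independently resolved edges is reported as an error naming the cycle —
nothing is auto-deleted, because choosing which edge to sacrifice is a
reviewer judgement), and emits a decision log from which
`replay_translation()` can reconstruct the result exactly.

### 3. Integration

`index_edges()` enters a translated DAG's retained edges into a
*directed edge index* keyed by unordered pair, and `merge_indices()`
combines indices across studies — a commutative, associative operation
in which direction disagreements are flagged as conflicts that must be
resolved explicitly (`resolve_index_conflict()`) before synthesis.
`synthesise()` unions the records into the integrated DAG and returns
the **pending pairs**: pairs of variables that never co-occurred within
one study. These only become assessable once the studies are combined,
and they are resolved by the same translation machinery in I-DAG
context (`resolve_pending()`), with the resulting deletions written
back to the index. The saturation ledger always balances: indexed
edges + deletions + pending pairs = all `choose(n, 2)` pairs.

`recombination_candidates()` proposes node merges — pairs with
identical in- and out-neighbourhoods, or pairs flagged as theoretically
equivalent constructs — and `recombine()` performs the merge, uniting
provenance and aliases, taking worst-case confidence on collapsed
parallel edges, and refusing merges that would create cycles.

### 4. Analysis

Analysis operates on an `analysis_graph()`, in which each bidirectional
edge is expanded into an explicit latent common-cause node, so all
reasoning runs on a plain DAG. `d_separated()` uses the moralised
ancestral graph construction; `backdoor_paths()` enumerates paths into
the exposure and scores each open or blocked under the path rules;
`minimal_adjustment_sets()` enumerates subsets of the eligible
covariates (measured, non-latent, not the exposure, outcome, or a
descendant of the exposure) and keeps the minimal ones that close every
backdoor path; `classify_covariate()` names each covariate's role(s)
(mediator, confounder, collider-on-path; else risk factor, instrument,
or disconnected); and `adjustment_consequences()` reports what a
proposed adjustment set would *break* — causal paths over-controlled
and collider paths opened.

```{r}
res <- alcohol_pipeline()
minimal_adjustment_sets(res$idag, "parental_alc_hist", "adol_alc")
adjustment_consequences(res$dags$hypothetical, "parental_alc_hist",
                        "adol_alc", "adol_substance")
```

## Numerical and design choices

Several points are underdetermined by the protocol; the package's
choices, and the reasoning behind them, are:

* **Deletions and the pending-pair ledger.** A study-level deletion
  means "this study's evidence argues against this edge", but a later
  study may still inform the pair; only deletions made in I-DAG context
  settle it for the synthesis. The edge index therefore records
  retained edges from studies, while deletions enter the index at the
  integrated stage (via `record_deletions()` / `resolve_pending()`).
* **Direction conflicts are never auto-resolved.** Majority voting or
  recency weighting across studies would hide a substantive
  disagreement in the literature. Conflicts block synthesis until a
  reviewer resolves them with a logged rationale.
* **Translated graphs forbid unassigned edges.** An unassigned
  orientation is a to-do item, not a finding, so it cannot survive
  translation; genuinely undecidable directions should resolve as
  bidirectional (ambiguous temporality in both directions) or be
  deleted.
* **Instrument–outcome pairs default to unassigned.** A study that
  reports an instrument asserts instrument → exposure; it makes no
  claim about the instrument–outcome pair, so that pair is left for
  assessment like any other unstated pair.
* **Confidence propagation is worst-case.** A bidirectional resolution
  takes the lower of the two directional confidences, and recombined
  parallel edges take the lowest confidence among the collapsed edges.
  Confidence is a flag for scrutiny, so it must not be averaged away.
* **Adjustment-set enumeration is exact and capped.** Subset
  enumeration is exponential; it is exact up to 20 eligible covariates
  (about 10⁶ subsets, well within the intended problem sizes of tens of
  nodes) and refuses larger problems with an explicit error rather than
  silently approximating.
* **Determinism.** Exports (DAGitty, DOT, CSV) order nodes and edges
  lexicographically, so identical graphs produce byte-identical files,
  and synthesis output is sorted, making order-invariance an identity
  of outputs rather than merely of isomorphism classes.

## The random generators

The test suite and the acceptance script rest on seeded generators:

* `random_dag()` draws a hidden topological order and includes each
  pair with probability `p_edge`, oriented along the order — every draw
  is a DAG by construction.
* `random_ig()` converts such a draw into a saturated candidate graph,
  mimicking a mapped study.
* `random_assessments()` draws criterion verdicts for both directions
  of every pair, honouring the sequential-stop structure and positing a
  hidden temporal order of the variables: directions against the order
  fail temporality except with a small ambiguity probability, which is
  how bidirectional resolutions arise. Draws that still translate into
  a cycle are rejected and redrawn (the count is reported in the
  `redraws` attribute).
* `random_edge_index()` subsamples a complete random DAG's edges,
  flipping some to bidirectional.

These generators are *structurally* realistic — saturated pair
coverage, sequential verdicts, acyclic unions — but make no attempt at
epidemiological realism: verdicts are independent across pairs given
the hidden order, whereas real reviewers' judgements are correlated
through theory; confidence and provenance structure is uniform; and
node counts are kept at ≤ 12 so that the exhaustive oracles
(path-enumeration d-separation, full subset enumeration of adjustment
sets) stay tractable. They are fit for verifying the algorithms'
correctness, not for simulating review workloads.

## Verification

Every graph-theoretic result is cross-checked against an independent
implementation: d-separation (moralised ancestral graph) against
path-rule enumeration over all simple paths, adjustment sets against
full subset enumeration over backdoor paths, acyclicity against a
depth-first search. The worked example's every documented conclusion is
asserted in the test suite, synthesis is checked for invariance under
record permutations, and DAGitty export/import and decision-log replay
are checked for exactness on a random corpus. `scripts/acceptance.R`
re-runs a condensed version of all of this against the installed
package and writes the resulting quantities as JSON.
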