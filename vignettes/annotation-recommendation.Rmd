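---
title: "Recommending ChEBI and Rhea annotations for SBML models"
author: "sbmlannot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recommending ChEBI and Rhea annotations for SBML models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmlannot)
```

## The problem and the model

SBML models describe biochemistry with typed elements: species (chemical
entities) and reactions (sets of reactant and product species). Annotation
links an element to a term in a knowledge resource — ChEBI for small
molecules, Rhea for reactions — via RDF controlled-vocabulary terms. The
obstacle to automating this is that there is no sequence to align: a
species is known only by a short free-text name, and a reaction only by
which species it uses. `sbmlannot` therefore treats annotation as a
recommender problem over two purpose-built match scores, each in [0, 1],
computed between a query element and every element of a reference database.

### Species: character-count cosine (cScore)

A name is normalized (lowercased, everything outside `[a-z0-9]` removed)
and encoded as a 36-dimensional count vector over the letters a–z and
numerals 0–9. The score against a reference term is the maximum cosine
similarity over the term's synonyms. Assumptions worth keeping in mind:

* the encoding is *lossy*: anagrams and re-orderings score 1 against each
  other. This trades specificity for speed and robustness to word order
  ("glucose, D-" vs "D-glucose");
* normalization does not transliterate: a Greek "α" is dropped, not mapped
  to "a", because the vector space has exactly 36 dimensions;
* a query whose normalized form is empty scores 0 against everything (the
  cosine is otherwise undefined on zero vectors).

### Reactions: participant-formula overlap (rScore)

Participant chemical formulas are *simplified* by deleting all hydrogen;
a formula that is pure hydrogen becomes `"H"`. This deliberately merges
protonation states (ATP⁴⁻ and HATP³⁻ should be the same coordinate) and
shrinks the coordinate space. Every reaction — reference or query — is a
binary vector over the distinct simplified formulas, pooling reactants and
products without stoichiometry or direction. The query vector is built
from the *predicted* species terms of the reaction's participants, so
reaction prediction is downstream of species prediction; a participant
with several surviving candidate terms (or a term with several formulas)
sets several coordinates.

The raw similarity is the dot product `Rq · Rr` (the number of shared
simplified formulas). It is normalized by `D`, the smallest participant
count (self-dot-product) among the reference reactions achieving the
maximal dot product `M_q` with the query. Since every such reaction has at
least `M_q` coordinates, `M_q <= D` and the score `Rq·Rr / D` stays in
[0, 1]; `D` shifts score *values* (and hence what survives a cutoff)
without changing the *ranking*. Degenerate case: if the query vector is
empty or overlaps nothing (`M_q = 0`), `D` is set to 0 and all scores are
0 — the prediction set is empty rather than arbitrary.

### Selection, filters and cutoffs

Two selection criteria are offered: **top** (annotations of the reference
element(s) tied at the maximal score, provided that score reaches the
cutoff) and **above** (annotations of every reference element reaching the
cutoff). The cutoff comparison is inclusive (`score >= cutoff`): the
documented default cutoff of 0 then recommends for every scorable element,
and a cutoff of 1.0 still admits exact matches. Tie sets are emitted in
lexicographic id order so output is reproducible.

Elements carrying too little information are filtered out before scoring
and get empty prediction sets: species whose normalized query string is
shorter than `min_len` (default 3 — names like "S1" are noise), and
reactions with fewer than `min_participants` participants (default 0, i.e.
everything is scored; benchmark-style evaluation typically uses 3). The
query string is the SBML display name when present and nonempty after
trimming, else the element id; a nonempty display name is never second-
guessed with the id.

## Iterative refinement

Reaction predictions carry information back to species. For each reaction
with a nonempty prediction set, its top-scoring ("mapped") reference
reaction — all of them, when tied — is used to pair query participants
with reference participants: exact annotation agreements are fixed first,
then the remaining participants are paired greedily by descending cScore
between the species' name and the reference participant's synonyms, with
deterministic (element id, term id) tie-breaks. Each unmatched pair
proposes revising that species to its paired reference term.

The loop then resolves conflicts (a species proposed different terms by
different reactions keeps the term maximizing the summed top rScore over
all reactions that contain it, recomputed under each candidate revision;
remaining ties break lexicographically), applies the accepted revisions —
the species' candidate set is replaced by the single proposed term, scored
with the proposing reaction's top rScore and flagged
`"revised-by-reaction"` so users can distinguish string-derived from
reaction-derived evidence — and re-scores every reaction touching a
revised species. It stops at a fixed point or after `max_iter` rounds
(default 3; fixtures reach a fixed point in 1–2). An accepted revision can
never lower the proposing reaction's score against its mapped reference,
because the revised coordinate is by construction present in that
reference. The pairing/conflict/acceptance rules are deliberately isolated
behind this module's interface: they are the genuinely open part of the
design, and the greedy exact-first scheme was chosen as the simplest rule
that is deterministic, terminates, and never degrades the proposing
reaction.

## Quality metrics

For one element with prediction set `P` and expected set `E`:
`nonempty = [P != {}]`; when nonempty, `accuracy = min(1, |P ∩ E|)`
(binary: did at least one correct term make it in) and
`exactness = 1/|P|` (specificity of the recommendation; 1 iff a single
candidate). Accuracy and exactness are undefined on empty prediction sets,
which is why `nonempty` exists as its own metric — precision would simply
be undefined there. Corpus-level figures pool elements (per-model
averaging is available behind `per_model = TRUE`); `mean_accuracy` and
`mean_exactness` average only over nonempty elements, and the denominators
are reported alongside. Elements whose existing annotations cannot be
resolved against the reference database are excluded from evaluation
rather than counted as failures. As the cutoff rises, prediction sets
shrink and `mean_nonempty` falls monotonically, while accuracy among the
surviving (confidently matched) elements tends to rise — the trade-off
`sweep_metrics()` tabulates.

## The synthetic generator

Testing every stage without shipping ChEBI/Rhea requires a generator that
emulates their structure: `generate_reference_db()` draws species terms
with synonym variants (suffixes, pluralization, digit insertion) and
random formulas over C/N/O/P/S plus hydrogen (the first term is pure H₂ so
the hydrogen rule is always exercised), and reactions as random participant
subsets; `generate_model()` derives a model whose display names are
synonyms perturbed per character at `name_noise_rate` and whose reactions
drop participants at `participant_dropout_rate`, recording ground truth.

Two generator properties matter for what the tests mean:

* synonyms are rejection-sampled so no two terms share a character
  multiset. With zero noise, recovery is then exact *by construction*:
  MSSC top at cutoff 1.0 yields mean accuracy and mean nonempty of 1.0 for
  both element types. This validates the pipeline's plumbing, not its
  discriminative power on real nomenclature, where synonym collisions
  across ChEBI terms are common and exactness suffers accordingly;
* generation is integer-based and threaded through an explicit seed
  (`synth_config(seed = )`), restoring the caller's RNG state, so corpora
  are bit-reproducible.

Default sizes (50 terms, 20 reactions, 2–6 participants) keep every test
and sweep in the seconds range; they are the corpus sizes at which the
package's documented recovery and monotonicity properties are asserted.
What the generator does *not* emulate: real synonym frequency statistics,
shared synonyms between terms, multi-formula ChEBI entries beyond the
mechanism itself, and reaction-size distributions of Rhea.

## Numerical and representational choices

* **Exact cosine at 1.** Scores of parallel integer count vectors are
  returned as exactly 1 (`dot² == |u|²|v|²`, exact in doubles for these
  magnitudes) rather than `1 - ε` from floating square roots; otherwise a
  cutoff of 1.0 would spuriously reject exact matches.
* **Simplified-formula canonical form.** Elements in strict alphabetical
  order, count suffix omitted when 1 ("C6O6", "O"); the hydrogen rule only
  fixes what to drop, a canonical serialization is needed so equal element
  multisets map to one vector coordinate. The formula index is a bijection
  onto 1..n (R-native coordinates).
* **Charge handling.** A trailing charge token (at most one digit and a
  sign, e.g. `+`, `3-`) is stripped before parsing — "PO43-" is P,O₄ with
  charge 3−, not O₄₃ — and parenthesized/isotope notations are rejected
  rather than guessed. Protonation differences are exactly what hydrogen
  removal absorbs.
* **Sparse supports.** Reaction vectors are carried as sorted coordinate
  sets; dot products are intersection sizes, with results identical to
  dense arithmetic (property-tested against a dense oracle).
* **Cached synonym vectors.** Synonym count vectors are precomputed per
  database load; batch scoring is contractually identical to per-term
  scoring (also tested).
* **Degenerate inputs.** Zero vectors score 0; empty reference reaction
  tables are an error for normalization; empty models yield empty maps;
  `max_iter = 0` returns refinement inputs unchanged.

## SBML handling

Reading accepts Level 2 and 3, extracts species ids/names, pools reactants
and products as participants (modifiers are read but are not
participants), and recognizes ChEBI/Rhea/KEGG-reaction/EC annotation URIs
in both identifiers.org dialects and legacy `urn:miriam` form. Writing
emits the modern identifiers.org dialect under a configurable qualifier
(default `bqbiol:is`). The default write mode is **append** — silently
destroying curator annotations is unsafe — with **replace** (superseding
only same-namespace annotations) as an explicit opt-in. KEGG/EC reaction
annotations can be mapped to Rhea ids through a two-column cross-reference
table for evaluation.

## Known limitations

* Only species and reactions are annotated; no model-level, kinetic-law,
  or polymer (protein/mRNA/DNA) annotation, and no use of existing
  annotations as priors.
* ChEBI hierarchical (is-a) relationships are not exploited.
* The count encoding cannot distinguish anagrams, and shared synonyms
  between reference terms cap exactness.
* The refinement conflict/acceptance rules are reasonable deterministic
  choices, not the only defensible ones; they are confined to the `refine`
  module so alternatives can be swapped in.
* Reference databases are loaded fully into memory; the package targets
  curated-model scale, not proteome-scale term sets, in one pass.
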