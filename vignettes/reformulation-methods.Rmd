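---
title: "From concept-based queries to CQL/DCQL: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From concept-based queries to CQL/DCQL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoquery)
```

`ontoquery` turns description-logic-style queries over a domain vocabulary
into executable navigational queries (CQL, DCQL) against annotated UML
information models. This vignette explains the underlying models and the
design decisions taken where the approach leaves room, so that a user can
judge what the package's guarantees do and do not cover.

## The ontological encoding of a model

Every model element is mapped into an EL-style TBox. The choices that
matter:

* **Attributes are OWL classes**, not data properties. A concept-based
  query constrains attributes through their *annotations*
  (`hasAttribute some (Name and hasValue value "17")`), which is only
  expressible if the attribute is itself a class that can sit below a
  domain concept. The attribute class is named `<Class>_<attribute>` to
  avoid collisions; association properties are named
  `<DeclaringClass>_<role>_<RangeClass>` for the same reason.
* **One transitive upper property.** Every association property is a
  sub-property of the transitive `u:hasAssociation`. Queries never name
  concrete roles; the rewriting replaces `hasAssociation` by role chains.
  EL permits transitivity but not universal quantification, and the
  generator never emits a universal restriction, so the lightweight
  reasoner used here (reachability closure plus graph traversal) is
  complete for the constructs that actually occur.
* **Inherited associations are materialised.** UML semantics lets a
  subclass use its ancestors' associations; the generator emits one
  explicit axiom per (association, descendant) pair, keeping the declaring
  class in the property name. Path finding therefore needs no reasoning
  about inheritance at query time.
* **Annotations via a list pattern.** A primary concept with an ordered
  qualifier list becomes `Element ⊑ n:P ⊓ (l:OWLList ⊓ ∃l:hasContents.q1 ⊓
  ∃l:hasNext.(...))`. Order is semantically significant: reversing the
  qualifiers yields a different axiom, and the tests assert this.
* **Module extraction** is syntactic upward closure of the signature under
  asserted subsumption (bottom-locality on the subsumption/disjointness
  fragment). For a toy vocabulary this is provably entailment-preserving
  over the signature, and the suite checks it against brute-force pairwise
  subsumption on random ontologies. Disjointness is stripped before
  generation: annotation subsumption can place one UML class under two
  disjoint branches, and the stripped module keeps the ontology coherent.

## The pipeline and its choice points

Stages run in a fixed order: parse → generate/classify → UML extraction →
value stripping → (federated: join discovery and application) → validation →
path finding → value re-insertion → comprehension translation →
normalization → emission. Three points are user choices in an interactive
setting; `choice_policy()` resolves them reproducibly (`first`, or explicit
indices). One ordering decision deserves a note: for federated queries the
satisfiability check runs *after* the selected joins are applied, because a
cross-service association is unreachable by construction until the join
equivalence exists; for single-service queries validation precedes path
finding as usual. An unsatisfiable query halts the pipeline at validation
and the result bundle carries the diagnosis and no downstream artifacts.

Path search is deterministic graph traversal: all simple paths, shortest
first, ties broken lexicographically on property labels, capped by
`max_paths` (default 25). On these ontologies the justification for two
classes being related through a transitive property is exactly an edge
chain, so traversal and entailment coincide; the suite checks the
enumeration against an independent exhaustive enumerator on random
digraphs. When several query conjuncts route through the same hop to the
same class, the rewriting shares that segment (one chain of intermediate
classes with the divergent tails as branches) — this is what makes the
federated worked example produce one expression per service rather than one
per conjunct, and it reflects the reading that a query's intermediate
objects are shared among its constraints.

Join discovery compares *concept sets*: two classes (then two attributes of
such classes) from different models are candidates when their annotation
concept sets are identical. The candidates are ordered deterministically
and the choice among them is the user's — uniqueness of the joined
attribute's values is a biological judgement, not a structural one.

## The comprehension IR

Rewritten expressions translate compositionally into bag comprehensions: a
class yields a generator over its extent; a role hop yields a generator
over the parent's role path plus a generator re-binding the same variable
over the hop class's extent; attribute restrictions become filters; each
join adds an equality filter between the two services' variables. Fresh
variables are `v0, v1, …` in translation order. A re-binding generator is
evaluated with bag multiplicity (an environment survives once per
occurrence), which is exactly what makes unnesting semantics-preserving.

Normalization implements three rules: unnesting of comprehensions in
generator sources, coalescing of duplicate (variable, source) generators,
and sequential renaming. It deliberately does *not* drop generators whose
variable is otherwise unused: under bag semantics such a generator still
scales multiplicities, so removal would not be equivalence-preserving. The
rule set is validated semantically, not rule-by-rule: on hundreds of random
comprehensions over random object stores, `evaluate(normalize(c))` must
equal `evaluate(c)`.

The join filter is emitted immediately *after* the foreign service's root
extent generator rather than before it, so that every comprehension the
package produces satisfies binding-before-use; generator sources and their
order are unaffected.

## Target emission

CQL's grammar allows at most one child per object; when a class node needs
several (attributes, associations, foreign associations), an `AND` group is
synthesised. Disjunctions translate to `OR` groups within one target;
cross-target disjunction is rejected, since CQL has a single target.
Foreign predicates are restricted to the six-member enum (no `LIKE`,
`IS_NULL`, `IS_NOT_NULL`), enforced at construction and at parse. The XML
dialect (element names `CQLQuery/Target/Object/Attribute/Association/Group`,
`DCQLQuery/TargetObject/ForeignAssociation/JoinCondition/ForeignObject`)
uses package-constant namespaces; the tested contract is the grammar, not
the namespace URI. Emission is byte-deterministic, and `parse_xml ∘
emit_xml` is the identity on grammar-generated queries.

## What the synthetic generator emulates — and what it does not

`generate_synthetic_model()` emulates registry-style projects: class
hierarchies of bounded depth, zero to three typed attributes per class,
annotations drawn uniformly from a supplied vocabulary, and associations
sampled independently per ordered class pair (`assoc_density`, default
regimes in the tests 0.1–0.3, sizes 5–20 classes — small enough that
exhaustive path enumeration stays cheap). Object stores
(`build_store()`) hold a few instances per class with attribute values from
a small pool and 0–2 links per applicable role, so filters sometimes match
and sometimes do not.

Real registry metadata differs in ways the generator does not model:
annotation vocabularies are heavy-tailed (few concepts annotate many
elements), qualifier lists are semantically curated rather than random,
association graphs are far from Erdős–Rényi (hub classes, long attribute
lists), and real models contain errors and stale concept references.
Passing the property suites therefore demonstrates correctness of the
algebra — round trips, entailment preservation, semantic agreement between
the comprehension evaluator and the CQL interpreter — not robustness to
dirty registry exports.

## Numerical and degenerate-input conventions

* Path metrics count *edge-labelled* simple paths of at least one hop;
  journeys are ordered class pairs; pairs with no path are excluded from
  the paths-per-journey denominator; an edgeless graph scores zero on all
  three metrics.
* `find_paths(start = end)` returns a single zero-hop path; in a rewriting
  a zero-hop conjunct merges into its parent node.
* Comparison of attribute values is lexicographic on strings (`LIKE` uses
  `%` wildcards); only `EQUAL_TO` occurs in the worked examples.
* Equivalence cycles among classes are reported as equivalence classes by
  the classifier, not as errors — applied joins create exactly such
  two-element classes on purpose.
* Fixture role names not fixed by any printed material (the SNP-to-location
  role) are package constants (`physicalLocationCollection`); worked-example
  assertions compare class sequences, not that label.

## Known limitations

* Only the bag and boolean-or monoids are implemented; aggregate monoids
  and query modifiers are parsed/emitted but never produced by the
  pipeline.
* The rewriting does not distribute disjunction through path finding; `or`
  is handled by the translation (the or-accumulator) and by CQL `OR`
  groups only where no generic association rewriting is needed inside the
  disjuncts.
* Multiple simultaneous join conditions are supported structurally but only
  the single-join scenario is exercised by a worked example.
* The reasoner is complete only for the EL fragment the generator emits; it
  is not a general OWL reasoner, and `check_el()` enforces that boundary on
  every generated ontology.
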