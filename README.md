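# ontoquery

Ontology-based query reformulation over annotated information models, in R.

## The problem

Biomedical data services in model-driven infrastructures (caGrid-style) each
expose a UML information model — classes, typed attributes, directed
associations — and a *navigational* query language over it: CQL names one
target class and constrains it through role-named associations and attribute
predicates; its distributed extension DCQL adds foreign associations whose
join conditions link classes across services. Writing such queries requires
knowing every model's structure. The same registries, however, annotate every
model element with concepts from a shared domain ontology (ISO/IEC 11179
common data elements). Reading those annotations as Local-As-View mappings —
each source element described as a view over the domain vocabulary — lets a
researcher pose one *concept-based* query,

```
Single_Nucleotide_Polymorphisms and hasAssociation some
  (Chromosome and hasAttribute some (Name and hasValue value "17"))
```

and have a mediator reformulate it into executable CQL or DCQL for the
concrete services.

## The method

`ontoquery` implements that mediator end to end:

1. **UML-to-OWL generation.** Each model becomes an EL-style TBox: classes
   and attributes as OWL classes under `u:UMLClass` / `u:UMLAttribute`
   (attributes must be classes so that *their* concept annotations are
   queryable), every association as an object property under the single
   transitive property `u:hasAssociation`, inherited associations
   materialised explicitly on every descendant, and each annotation (primary
   concept + ordered qualifiers) encoded with an OWL list pattern. Domain
   vocabulary enters as a signature module (upward-closed under subsumption,
   entailment-preserving over the signature) with disjointness stripped.
2. **Reasoning services.** Classification as reachability closure,
   satisfiability of query expressions against the association graph,
   deterministic simple-path enumeration replacing `hasAssociation` with
   concrete role chains, ontology merging, and semantic join discovery:
   classes (then their attributes) from different models annotated with
   identical concept sets are join candidates; an applied join adds an
   Equivalent Class axiom that lets paths cross services.
3. **Monoid-comprehension IR.** Rewritten expressions are translated
   compositionally into bag comprehensions `⊎{v0 | v0 <- Extent(C),
   v1 <- v0.role, v1 <- Extent(D), v1.attr = "x", ...}`, joins become
   equality filters between services' variables, and the result is
   normalised (unnesting, generator coalescing, sequential variable
   renaming) with a reference evaluator guarding semantic equivalence.
4. **Target emission.** Normalised comprehensions map onto the CQL/DCQL
   grammars (target object, nested associations, attribute predicates, AND
   groups, foreign associations with join conditions) and are emitted as
   deterministic XML, with a grammar-checking parser for round-trip
   validation and a direct interpreter used to cross-check query semantics
   against the comprehension evaluator on synthetic object stores.

The package ships reconstructions of two service-model fragments (a
caBIO-like genomic model, a PIR-like protein model) with a toy domain
vocabulary, plus a seeded synthetic-model generator used throughout the
tests.

## Worked example

```r
library(ontoquery)
cabio <- fixture_cabio(); pir <- fixture_pir(); dom <- fixture_domain_ontology()

res <- reformulate_query(fixture_query(2), list(cabio, pir), dom,
                         choice_policy("indexed", extraction = 2, join = 2, path = 1))
for (j in res$join_candidates) print(j)
#> Join: (cabio:Gene, pir:Gene) on cabio:Gene_symbol EQUAL_TO pir:Gene_name
#> Join: (cabio:Protein, pir:Protein) on cabio:Protein_uniProtCode EQUAL_TO pir:Protein_uniprotkbEntryName
n_service_paths(res$rewritten)
#> [1] 2
print(res$normalized)
#> ⊎{v0 | v0 <- gov.nih.nci.cabio.domain.NucleicAcidSequence, v1 <- v0.geneCollection,
#>   v1 <- gov.nih.nci.cabio.domain.Gene, v2 <- v1.proteinCollection,
#>   v2 <- gov.nih.nci.cabio.domain.Protein, v3 <- edu.georgetown.pir.domain.Protein,
#>   v2.uniProtCode = v3.uniprotkbEntryName, v4 <- v3.geneCollection,
#>   v4 <- edu.georgetown.pir.domain.Gene, v4.name = "BRCA1",
#>   v5 <- v3.organismCollection, v5 <- edu.georgetown.pir.domain.Organism,
#>   v5.scientificName = "homo sapiens"}
```

The two join candidates are the semantically equivalent class pairs; the
researcher picks the protein join (UniProt codes are unique, gene symbols
are not), the federated path finder splits the rewriting into one
expression per service, and the six-variable comprehension above is emitted
as a DCQL document whose `JoinCondition` relates `uniProtCode` to
`uniprotkbEntryName` with `EQUAL_TO`. The single-service example
(`fixture_query(1)`) rewrites through the location-class hierarchy and an
inherited association to the spine `SNP / SNPPhysicalLocation / Chromosome`
with the attribute restriction `number EQUAL_TO "17"`.

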