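#' @title Worked-example fixtures
#' @description Reconstructions of two small data-service model fragments —
#'   a caBIO-like genomic model and a PIR-like protein model — together with
#'   the toy domain vocabulary that annotates them. These are the models the
#'   package's worked examples run over: finding SNPs on a named chromosome
#'   (single service) and linking nucleotide sequences to organisms through a
#'   protein join (federated).
#' @name fixtures
NULL

#' Toy domain ontology used by the fixtures
#'
#' A small concept hierarchy standing in for the relevant fragment of a large
#' clinical thesaurus: genomic and protein concepts, naming concepts, and one
#' disjointness pair (nucleic-acid entities vs gene products).
#'
#' @return a [domain_ontology()]
#' @export
fixture_domain_ontology <- function() {
  ids <- c(
    "Single_Nucleotide_Polymorphism", "Single_Nucleotide_Polymorphisms",
    "Chromosome", "Chromosome_Band", "Location", "Name",
    "Nucleotide_Sequences", "Gene", "Gene_Symbol",
    "Protein", "UniProt_Identifier", "Organisms", "Scientific_Name",
    "Genomic_Entity", "Gene_Product"
  )
  domain_ontology(
    concepts = lapply(ids, function(i) concept(i, gsub("_", " ", i))),
    subsumptions = list(
      c("Single_Nucleotide_Polymorphism", "Single_Nucleotide_Polymorphisms"),
      c("Gene", "Genomic_Entity"),
      c("Nucleotide_Sequences", "Genomic_Entity"),
      c("Protein", "Gene_Product")
    ),
    disjointness = list(c("Genomic_Entity", "Gene_Product"))
  )
}

#' caBIO-like information model fixture
#'
#' Nine classes covering the SNP/location hierarchy and the
#' sequence-gene-protein chain. The SNP-to-physical-location role name is not
#' fixed by any source material; this fixture names it
#' `physicalLocationCollection`, and worked-example comparisons are made at
#' the class-sequence level.
#'
#' @return an [information_model()]
#' @export
fixture_cabio <- function() {
  a <- annotation
  information_model(
    project_name = "caBIO", version = "4.2", prefix = "cabio",
    namespace = "gov.nih.nci.cabio.domain",
    service_url = "http://cabio.example.org/wsrf/services/cagrid/CaBIO",
    classes = list(
      class_spec("SNP", a("Single_Nucleotide_Polymorphism")),
      class_spec("Location", a("Location")),
      class_spec("PhysicalLocation", a("Location"), superclasses = "Location"),
      class_spec("SNPPhysicalLocation",
                 a("Location", c("Chromosome", "Single_Nucleotide_Polymorphism")),
                 superclasses = "PhysicalLocation"),
      class_spec("CytogeneticLocation", a("Location", "Chromosome_Band"),
                 superclasses = "Location"),
      class_spec("Chromosome", a("Chromosome"), attributes = list(
        attribute_spec("number", "string", a("Name"))
      )),
      class_spec("NucleicAcidSequence", a("Nucleotide_Sequences")),
      class_spec("Gene", a("Gene"), attributes = list(
        attribute_spec("symbol", "string", a("Gene_Symbol"))
      )),
      class_spec("Protein", a("Protein"), attributes = list(
        attribute_spec("uniProtCode", "string", a("UniProt_Identifier"))
      ))
    ),
    associations = list(
      association_spec("SNP", "SNPPhysicalLocation", "physicalLocationCollection"),
      association_spec("Location", "Chromosome", "chromosome"),
      association_spec("Chromosome", "Location", "locationCollection"),
      association_spec("NucleicAcidSequence", "Gene", "geneCollection"),
      association_spec("Gene", "Protein", "proteinCollection")
    )
  )
}

#' PIR-like information model fixture
#'
#' Protein, gene and organism classes; the protein attribute
#' `uniprotkbEntryName` shares its concept annotation with the caBIO
#' `Protein.uniProtCode` attribute, which is what makes the protein join
#' discoverable.
#'
#' @return an [information_model()]
#' @export
fixture_pir <- function() {
  a <- annotation
  information_model(
    project_name = "PIR", version = "1.2", prefix = "pir",
    namespace = "edu.georgetown.pir.domain",
    service_url = "http://pir.example.org/wsrf/services/cagrid/PIR",
    classes = list(
      class_spec("Protein", a("Protein"), attributes = list(
        attribute_spec("uniprotkbEntryName", "string", a("UniProt_Identifier"))
      )),
      class_spec("Gene", a("Gene"), attributes = list(
        attribute_spec("name", "string", a("Gene_Symbol"))
      )),
      class_spec("Organism", a("Organisms"), attributes = list(
        attribute_spec("scientificName", "string", a("Scientific_Name"))
      ))
    ),
    associations = list(
      association_spec("Protein", "Gene", "geneCollection"),
      association_spec("Protein", "Organism", "organismCollection")
    )
  )
}

#' Canonical worked-example query texts
#'
#' Query 1 asks for single nucleotide polymorphisms associated with the
#' chromosome whose name is "17" (single service); query 2 asks for
#' nucleotide sequences associated with the gene whose symbol is "BRCA1" and
#' whose organism's scientific name is "homo sapiens" (federated).
#'
#' @param n 1 or 2
#' @return character scalar with the concept-based query text
#' @export
fixture_query <- function(n = 1) {
  if (n == 1) {
    paste0('Single_Nucleotide_Polymorphisms and hasAssociation some ',
           '(Chromosome and hasAttribute some (Name and hasValue value "17"))')
  } else if (n == 2) {
    paste0('Nucleotide_Sequences and hasAssociation some ',
           '(Gene and hasAttribute some (Gene_Symbol and hasValue value "BRCA1")) ',
           'and hasAssociation some ',
           '(Organisms and hasAttribute some (Scientific_Name and hasValue value "homo sapiens"))')
  } else stop("no such fixture query: ", n)
}
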