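#' Path to a packaged example file
#'
#' The package ships a reconstructed quad-family case study under
#' `inst/extdata`: the pedigree (`sibship_quad.ped`), the shared recessive
#' candidate variants with their genotypes (`shared_candidates.vcf`), their
#' annotation table (`shared_candidates_annotations.tsv`), a childhood-ALL
#' susceptibility locus list (`all_risk_loci.tsv`) and the sibs' genotypes at
#' those loci (`risk_locus_genotypes.tsv`). Published variant tables are
#' transcriptions with occasional typographic ambiguity; where a cell was
#' ambiguous the fixture records the Mendelian-consistent reading (see the
#' methods vignette).
#'
#' @param file file name under `extdata`; with no argument, lists them.
#' @return Full file path (or vector of available names).
#' @export
quad_example_file <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "quadscreen")))
  path <- system.file("extdata", file, package = "quadscreen")
  if (!nzchar(path)) stop("no packaged example file: ", file)
  path
}

#' Load the packaged quad case study
#'
#' Convenience loader for the shipped example: pedigree, family genotypes
#' and merged annotations for the 17 shared recessive candidate variants
#' (10 compound-heterozygous across 4 genes, 7 homozygous).
#'
#' @return List with `ped`, `fam`, `ann`.
#' @export
load_quad_example <- function() {
  ped <- load_pedigree(quad_example_file("sibship_quad.ped"))
  fam <- load_variants(quad_example_file("shared_candidates.vcf"), ped)
  ann <- merge_annotations(fam, quad_example_file("shared_candidates_annotations.tsv"))
  list(ped = ped, fam = fam, ann = ann)
}

#' The packaged susceptibility-locus table
#' @return Data frame with `gene`, `rsid`, `ref`.
#' @export
all_risk_loci <- function() {
  utils::read.table(quad_example_file("all_risk_loci.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
}
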