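FA_ALIASES <- c(
  SLX4 = "FANCP", BRCA2 = "FANCD1", PALB2 = "FANCN", RAD51C = "FANCO",
  XPF = "FANCQ", ERCC4 = "FANCQ", BRCA1 = "FANCS", BRIP1 = "FANCJ"
)

#' Construct a gene panel
#'
#' @param name panel name.
#' @param genes character vector of gene symbols (uppercased).
#' @param aliases named character vector mapping alternative symbols to
#'   panel symbols.
#' @return A `gene_panel` object.
#' @export
gene_panel <- function(name, genes, aliases = character(0)) {
  genes <- unique(toupper(genes))
  if (!length(genes)) stop("gene panel must be non-empty")
  # composite symbols ("FANCP/SLX4") admit either component
  genes <- unique(c(genes, unlist(strsplit(genes, "/", fixed = TRUE))))
  structure(list(name = name, genes = genes,
                 aliases = stats::setNames(toupper(aliases), toupper(names(aliases)))),
            class = "gene_panel")
}

#' The 17-gene Fanconi anemia panel
#'
#' Genes of the leukemia-predisposing Fanconi anemia (FA) pathway:
#' FANCA, FANCB, FANCC, FANCD1/BRCA2, FANCD2, FANCE, FANCF, FANCG, FANCI,
#' FANCJ, FANCL, FANCM, FANCN/PALB2, FANCO/RAD51C, FANCP/SLX4, FANCQ/XPF and
#' FANCS/BRCA1, with an alias table so that either symbol of a dual-named
#' gene (and composite symbols like `"FANCP/SLX4"`) matches.
#'
#' @return A `gene_panel` of 17 genes.
#' @export
fa_panel <- function() {
  gene_panel(
    "fanconi_anemia",
    c("FANCA", "FANCB", "FANCC", "FANCD1", "FANCD2", "FANCE", "FANCF",
      "FANCG", "FANCI", "FANCJ", "FANCL", "FANCM", "FANCN", "FANCO",
      "FANCP", "FANCQ", "FANCS"),
    FA_ALIASES
  )
}

#' Panel membership with alias resolution
#'
#' Symbol comparison is case-insensitive; composite symbols
#' (`"FANCP/SLX4"`) match if any component does.
#'
#' @param panel a `gene_panel`.
#' @param symbols character vector of gene symbols.
#' @return Logical vector.
#' @export
panel_contains <- function(panel, symbols) {
  one <- function(sym) {
    parts <- toupper(strsplit(sym, "/", fixed = TRUE)[[1]])
    canon <- ifelse(parts %in% names(panel$aliases), panel$aliases[parts], parts)
    any(canon %in% panel$genes)
  }
  vapply(as.character(symbols), one, TRUE, USE.NAMES = FALSE)
}

#' Restrict candidates to a gene panel
#'
#' @param candidates candidate data frame (from [classify_genes()] or
#'   [run_reduction()]).
#' @param panel a `gene_panel`.
#' @return The subset of `candidates` whose gene symbol (or alias) is in the
#'   panel, in the original order.
#' @export
restrict_to_panel <- function(candidates, panel) {
  if (!inherits(panel, "gene_panel") || !length(panel$genes))
    stop("restrict_to_panel requires a non-empty gene panel")
  candidates[panel_contains(panel, candidates$gene), , drop = FALSE]
}

#' Cohort registry
#'
#' Accounting object for a reference cohort made of complete
#' patient-mother-father trios plus singleton patients, with an optional
#' genotype dose matrix (sites x individuals; entries 0/1/2, `NA` missing).
#'
#' @param n_trios,n_singletons non-negative counts.
#' @param genotypes optional dose matrix with rownames = site ids; must have
#'   `3 * n_trios + n_singletons` columns.
#' @return A `cohort_registry` object.
#' @export
cohort_registry <- function(n_trios, n_singletons, genotypes = NULL) {
  if (n_trios < 0 || n_singletons < 0) stop("cohort counts must be non-negative")
  total <- 3L * as.integer(n_trios) + as.integer(n_singletons)
  if (!is.null(genotypes) && ncol(genotypes) != total)
    stop("genotype matrix has ", ncol(genotypes), " individuals; expected ", total)
  structure(list(n_trios = as.integer(n_trios),
                 n_singletons = as.integer(n_singletons),
                 genotypes = genotypes),
            class = "cohort_registry")
}

#' Total individuals in a cohort registry
#' @param registry a [cohort_registry()].
#' @return `3 * n_trios + n_singletons`.
#' @export
cohort_size <- function(registry) {
  3L * registry$n_trios + registry$n_singletons
}

#' Count carriers of one or more variants in a cohort
#'
#' Counts individuals matching a carrier mode across the queried sites:
#' `"any_alt"` -- at least one alternate allele at any queried site;
#' `"hom_alt"` -- homozygous alternate at every queried site;
#' `"het_at_all_sites"` -- heterozygous at every queried site (the
#' double-heterozygote lookup used for compound-het pairs). Missing genotypes
#' count as non-carrier, so the denominator is the full cohort.
#'
#' @param registry a [cohort_registry()] with a genotype matrix.
#' @param site_ids sites to query; all must be rows of the matrix.
#' @param mode carrier mode.
#' @return Integer count of individuals.
#' @export
count_carriers <- function(registry, site_ids,
                           mode = c("any_alt", "hom_alt", "het_at_all_sites")) {
  mode <- match.arg(mode)
  g <- registry$genotypes
  if (is.null(g)) stop("cohort registry has no genotype matrix")
  missing_sites <- setdiff(site_ids, rownames(g))
  if (length(missing_sites))
    stop("site absent from cohort genotype matrix: ", missing_sites[1])
  sub <- g[site_ids, , drop = FALSE]
  sub[is.na(sub)] <- 0L
  hits <- switch(mode,
    any_alt = colSums(sub >= 1L) >= 1L,
    hom_alt = colSums(sub == 2L) == length(site_ids),
    het_at_all_sites = colSums(sub == 1L) == length(site_ids)
  )
  sum(hits)
}

#' Susceptibility-locus genotype report
#'
#' Renders the genotypes of the affected sibs at a supplied table of
#' susceptibility loci (gene, rsid, risk/reference allele). Accepts either a
#' [family_genotypes] object (loci matched by rsid, genotypes rendered as
#' allele letters) or a pre-extracted genotype table with one column per sib.
#' Loci without a genotype render as `"-"` (missing information).
#'
#' @param x a [family_genotypes] object or a data frame with column `rsid`
#'   plus one genotype column per sib.
#' @param loci data frame with columns `gene`, `rsid`, `ref`.
#' @param ped pedigree (required when `x` is a [family_genotypes]).
#' @return Data frame: `gene`, `rsid`, `ref`, one column per affected sib.
#' @export
susceptibility_report <- function(x, loci, ped = NULL) {
  loci <- as.data.frame(loci)
  if (nrow(loci) == 0L)
    return(data.frame(gene = character(), rsid = character(), ref = character()))
  if (inherits(x, "family_genotypes")) {
    if (is.null(ped)) stop("ped required to identify affected sibs")
    sibs <- affected_sibs(ped)$sample_id
    out <- loci[, c("gene", "rsid", "ref")]
    idx <- match(loci$rsid, x$sites$rsid)
    for (sib in sibs) {
      gt <- rep("-", nrow(loci))
      for (i in which(!is.na(idx))) {
        site <- x$sites[idx[i], ]
        call <- x$calls[x$calls$site_id == site$site_id & x$calls$sample_id == sib, ]
        if (nrow(call) == 1L && !call$missing) {
          letters <- c(site$ref, site$alt)
          al <- if (call$hemi) call$a1 else c(call$a1, call$a2)
          gt[i] <- paste(letters[al + 1L], collapse = "")
        }
      }
      out[[sib]] <- gt
    }
    return(out)
  }
  out <- merge(loci, x, by = "rsid", all.x = TRUE, sort = FALSE)
  out <- out[match(loci$rsid, out$rsid), ]
  gt_cols <- setdiff(names(x), "rsid")
  for (col in gt_cols) out[[col]][is.na(out[[col]])] <- "-"
  rownames(out) <- NULL
  out[, c("gene", "rsid", "ref", gt_cols)]
}
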