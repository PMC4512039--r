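#' Sites shared by all affected siblings
#'
#' Under the default `"identity"` rule a site is shared when every affected
#' sib carries the identical non-reference genotype (same unordered allele
#' pair). The looser `"carrier"` rule only requires every affected sib to
#' carry at least one alternate allele. A missing call in any affected sib
#' makes the site not shared.
#'
#' @param fam a [family_genotypes] object.
#' @param ped a [pedigree].
#' @param rule `"identity"` (default) or `"carrier"`.
#' @return Named logical vector over `fam$sites$site_id`.
#' @export
shared_by_affected <- function(fam, ped, rule = c("identity", "carrier")) {
  rule <- match.arg(rule)
  sibs <- affected_sibs(ped)$sample_id
  if (!length(sibs)) stop("pedigree has no affected siblings")
  dm <- dose_matrix(fam)[, sibs, drop = FALSE]
  if (rule == "identity") {
    same <- apply(dm, 1L, function(r) !anyNA(r) && all(r == r[1]))
    shared <- same & dm[, 1] >= 1L
  } else {
    shared <- apply(dm, 1L, function(r) !anyNA(r) && all(r >= 1L))
  }
  shared[is.na(shared)] <- FALSE
  stats::setNames(shared, rownames(dm))
}

#' Parental origin of a shared heterozygous variant
#'
#' For sites where the affected sibs are heterozygous, determines which
#' parent transmitted the alternate allele by enumerating the Mendelian
#' transmissions consistent with the parental genotypes: `"paternal"` when
#' only the father can have transmitted it, `"maternal"` when only the
#' mother, `"ambiguous"` when both parents could have (both carriers of a
#' transmissible alt and a transmissible ref), and `"inconsistent"` when
#' neither transmission is possible.
#'
#' @param fam a [family_genotypes] object.
#' @param ped a [pedigree].
#' @param site_ids sites to resolve; each must have all affected sibs
#'   heterozygous (dose 1, diploid) with non-missing parents, else an error.
#' @return Named character vector of origins.
#' @export
parental_origin <- function(fam, ped, site_ids = NULL) {
  par <- sib_parents(ped)
  dm <- dose_matrix(fam)
  if (is.null(site_ids)) site_ids <- fam$sites$site_id
  idx <- match(site_ids, fam$sites$site_id)
  if (anyNA(idx)) stop("unknown site id: ", site_ids[is.na(idx)][1])
  sib_d <- dm[idx, par$sibs, drop = FALSE]
  if (any(is.na(sib_d)) || any(sib_d != 1L))
    stop("parental origin requires all affected sibs heterozygous at the site")
  f <- dm[idx, par$father]; m <- dm[idx, par$mother]
  if (anyNA(f) || anyNA(m)) stop("parental origin requires non-missing parental calls")
  # father transmits alt, mother ref: needs f >= 1 and m <= 1 (and vice versa)
  pat <- f >= 1L & m <= 1L
  mat <- m >= 1L & f <= 1L
  origin <- ifelse(pat & mat, "ambiguous",
                   ifelse(pat, "paternal",
                          ifelse(mat, "maternal", "inconsistent")))
  stats::setNames(origin, site_ids)
}

new_candidate <- function(gene, klass, site_ids, origins = NULL) {
  data.frame(gene = gene, klass = klass, n_variants = length(site_ids),
             sites = I(list(site_ids)),
             origins = I(list(origins %||% stats::setNames(
               rep(NA_character_, length(site_ids)), site_ids))),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify genes under the recessive disease model
#'
#' Groups (already filtered) variants by gene and assigns one inheritance
#' class per gene: `homozygous_recessive` when some site is homozygous
#' alternate in every affected sib with both parents carriers;
#' `x_hemizygous` for X sites where all affected male sibs are
#' alternate-hemizygous and the mother carries the allele; `compound_het`
#' when at least two shared heterozygous sites have resolved opposite
#' parental origins; `compound_het_ambiguous` when there are two or more
#' shared heterozygous sites but the origins cannot be resolved to opposite
#' parents (phase-ambiguous or same-parent). Genes matching none of these
#' are dropped.
#'
#' @param fam a [family_genotypes] object.
#' @param ped a [pedigree].
#' @param ann annotated variants (from [merge_annotations()]); only rows for
#'   sites present in `fam` are used, and the gene symbol column groups them.
#' @return Data frame of candidates with list-columns `sites` and `origins`.
#' @export
classify_genes <- function(fam, ped, ann) {
  if (nrow(ann) == 0L) stop("classify_genes: empty variant list")
  par <- sib_parents(ped)
  dm <- dose_matrix(fam)
  idx <- match(ann$site_id, fam$sites$site_id)
  if (anyNA(idx)) stop("annotation rows refer to unknown sites")
  x <- is_x_chrom(ann$chrom)
  sib_d <- dm[idx, par$sibs, drop = FALSE]
  f <- dm[idx, par$father]; m <- dm[idx, par$mother]
  male_sibs <- par$sib_sex == "male"

  hom_all <- rowSums(sib_d == 2L, na.rm = FALSE) == ncol(sib_d) & !x
  hom_ok <- hom_all & !is.na(f) & !is.na(m) & f >= 1L & m >= 1L
  het_all <- rowSums(sib_d == 1L, na.rm = FALSE) == ncol(sib_d) & !x &
    !is.na(f) & !is.na(m)
  x_ok <- x & all(male_sibs) &
    rowSums(sib_d == 1L, na.rm = FALSE) == ncol(sib_d) & !is.na(m) & m >= 1L
  hom_ok[is.na(hom_ok)] <- FALSE
  het_all[is.na(het_all)] <- FALSE
  x_ok[is.na(x_ok)] <- FALSE

  keep <- !is.na(ann$gene)
  genes <- split(seq_len(nrow(ann))[keep], ann$gene[keep])
  out <- list()
  for (g in names(genes)) {
    rows <- genes[[g]]
    if (any(hom_ok[rows])) {
      sites <- ann$site_id[rows][hom_ok[rows]]
      out[[g]] <- new_candidate(g, "homozygous_recessive", sites)
    } else if (any(x_ok[rows])) {
      sites <- ann$site_id[rows][x_ok[rows]]
      out[[g]] <- new_candidate(g, "x_hemizygous", sites)
    } else if (sum(het_all[rows]) >= 2L) {
      sites <- ann$site_id[rows][het_all[rows]]
      org <- parental_origin(fam, ped, sites)
      klass <- if (any(org == "paternal") && any(org == "maternal"))
        "compound_het" else "compound_het_ambiguous"
      out[[g]] <- new_candidate(g, klass, sites, org)
    }
  }
  if (!length(out))
    return(data.frame(gene = character(), klass = character(),
                      n_variants = integer(), sites = I(list()),
                      origins = I(list())))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Screen for shared de novo variants
#'
#' Putative de novo events are private variants shared by the affected sibs:
#' (a) every affected sib carries the alternate allele, (b) the site is
#' absent from the supplied population frequency tables (no recorded MAF in
#' either database), (c) neither parent has a single read supporting the
#' alternate allele, and (d) both parents are covered at or above
#' `min_parent_depth` reads (default 8) at the position. Sites where a parent
#' lacks depth information are excluded and counted.
#'
#' @param fam a [family_genotypes] object.
#' @param ped a [pedigree].
#' @param ann annotated variants (population MAF lookup); sites absent from
#'   `ann` count as absent from the databases.
#' @param min_parent_depth minimum parental coverage in reads.
#' @return Data frame of retained sites; attribute `"counts"` records how
#'   many sites failed each criterion.
#' @export
denovo_screen <- function(fam, ped, ann = NULL, min_parent_depth = 8L) {
  par <- sib_parents(ped)
  dm <- dose_matrix(fam)
  sib_d <- dm[, par$sibs, drop = FALSE]
  carry <- rowSums(sib_d >= 1L, na.rm = FALSE) == ncol(sib_d)
  carry[is.na(carry)] <- FALSE
  if (!is.null(ann)) {
    i <- match(fam$sites$site_id, ann$site_id)
    known <- !is.na(i) & (!is.na(ann$maf_1000g[i]) | !is.na(ann$maf_esp[i]))
  } else known <- rep(FALSE, nrow(fam$sites))
  pcalls <- fam$calls[fam$calls$sample_id %in% c(par$father, par$mother), ]
  ord <- fam$sites$site_id
  per_site <- function(x, f) {
    v <- as.logical(tapply(x, pcalls$site_id, f)[ord])
    v[is.na(v)] <- FALSE
    v
  }
  dp_known <- per_site(!is.na(pcalls$depth) & !is.na(pcalls$alt_depth), all)
  ad0 <- per_site(!is.na(pcalls$alt_depth) & pcalls$alt_depth == 0L, all)
  dp_ok <- per_site(!is.na(pcalls$depth) & pcalls$depth >= min_parent_depth, all)
  keep <- carry & !known & dp_known & ad0 & dp_ok
  counts <- c(
    not_shared = sum(!carry),
    in_databases = sum(carry & known),
    no_parental_depth = sum(carry & !known & !dp_known),
    parental_alt_reads = sum(carry & !known & dp_known & !ad0),
    insufficient_parental_coverage = sum(carry & !known & dp_known & ad0 & !dp_ok)
  )
  out <- fam$sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- counts
  out
}

#' Screen the X chromosome in male affected sibships
#'
#' Returns per-gene candidates for X sites where every affected male sib is
#' hemizygous for the alternate allele and the mother carries it. X sites
#' whose hemizygous sibs cannot be explained by a carrier mother
#' (mother homozygous reference) are Mendelian-inconsistent and excluded.
#'
#' @param fam a [family_genotypes] object.
#' @param ped a [pedigree].
#' @param ann annotated variants supplying the gene symbol per site.
#' @return Data frame of `x_hemizygous` candidates (possibly empty).
#' @export
x_linked_screen <- function(fam, ped, ann) {
  par <- sib_parents(ped)
  if (!all(par$sib_sex == "male")) {
    warning("X-linked hemizygous screen requires all affected sibs male; skipping")
    return(data.frame(gene = character(), klass = character(),
                      n_variants = integer(), sites = I(list()), origins = I(list())))
  }
  xi <- which(is_x_chrom(ann$chrom))
  if (!length(xi))
    return(data.frame(gene = character(), klass = character(),
                      n_variants = integer(), sites = I(list()), origins = I(list())))
  sub <- ann[xi, , drop = FALSE]
  res <- classify_genes(fam, ped, sub)
  res[res$klass == "x_hemizygous", , drop = FALSE]
}
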