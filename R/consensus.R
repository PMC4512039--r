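#' Default thresholds for rarity and deleteriousness
#'
#' The in-silico tools call a variant damaging at SIFT score <= 0.05,
#' PolyPhen-2 >= 0.957 and FATHMM < -1.5 (the FATHMM bound is strict, the
#' other two inclusive). `rare_maf` is the "extremely rare" cutoff applied to
#' the maximum of the available population MAFs; `common_cap` bounds the more
#' frequent member of a compound-heterozygous pair; `q2_cap` bounds the
#' population homozygote frequency for homozygous candidates; `siphy_min`
#' flags strongly conserved sites (report-only, never filters).
#'
#' @param rare_maf,common_cap,q2_cap,sift_max,polyphen2_min,fathmm_max,siphy_min
#'   numeric overrides.
#' @return Named list of thresholds.
#' @export
default_thresholds <- function(rare_maf = 0.001, common_cap = 0.10, q2_cap = 0.05,
                               sift_max = 0.05, polyphen2_min = 0.957,
                               fathmm_max = -1.5, siphy_min = 10) {
  list(rare_maf = rare_maf, common_cap = common_cap, q2_cap = q2_cap,
       sift_max = sift_max, polyphen2_min = polyphen2_min,
       fathmm_max = fathmm_max, siphy_min = siphy_min)
}

#' Per-tool deleteriousness verdicts and their consensus
#'
#' Applies the three in-silico tool thresholds to each variant. A missing
#' score yields a `"missing"` verdict and does not count toward
#' `n_available`. Scores outside the documented range of a tool raise a
#' warning but the verdict is still computed.
#'
#' @param ann annotated variants (data frame with `sift`, `polyphen2`,
#'   `fathmm` columns), or a single-row slice.
#' @param thresholds see [default_thresholds()].
#' @return Data frame with per-tool verdicts (`damaging`/`benign`/`missing`),
#'   `n_damaging` and `n_available`.
#' @export
damaging_calls <- function(ann, thresholds = default_thresholds()) {
  rng <- function(x, lo, hi, tool) {
    bad <- !is.na(x) & (x < lo | x > hi)
    if (any(bad)) warning(tool, " score outside [", lo, ", ", hi, "]")
  }
  rng(ann$sift, 0, 1, "sift"); rng(ann$polyphen2, 0, 1, "polyphen2")
  verdict <- function(x, damaging) ifelse(is.na(x), "missing",
                                          ifelse(damaging, "damaging", "benign"))
  sift <- verdict(ann$sift, ann$sift <= thresholds$sift_max)
  poly <- verdict(ann$polyphen2, ann$polyphen2 >= thresholds$polyphen2_min)
  fath <- verdict(ann$fathmm, ann$fathmm < thresholds$fathmm_max)
  out <- data.frame(sift = sift, polyphen2 = poly, fathmm = fath,
                    stringsAsFactors = FALSE)
  verdicts <- as.matrix(out)
  out$n_damaging <- rowSums(verdicts == "damaging")
  out$n_available <- rowSums(verdicts != "missing")
  if (!is.null(ann$site_id)) out <- cbind(site_id = ann$site_id, out)
  out
}

max_maf <- function(ann) {
  m <- pmax(ann$maf_1000g, ann$maf_esp, na.rm = TRUE)
  m[is.na(ann$maf_1000g) & is.na(ann$maf_esp)] <- NA_real_
  m
}

#' Rarity verdict for a candidate under its inheritance class
#'
#' Heterozygous-type candidates (single het, de novo, X hemizygous) are rare
#' when the maximum available population MAF is at or below `rare_maf`.
#' Homozygous candidates are judged on the population homozygote frequency:
#' rare when `q2_esp <= q2_cap`. A compound-heterozygous pair passes when at
#' least one member is MAF-rare and every member stays at or below
#' `common_cap`. Variants with no recorded frequency are treated as rare
#' (absence from the databases is itself evidence of rarity), with the basis
#' recorded as `"missing_treated_rare"`.
#'
#' @param ann one or more annotated-variant rows (several rows only for the
#'   compound-heterozygous classes, where the verdict is joint).
#' @param klass inheritance class string.
#' @param thresholds see [default_thresholds()].
#' @return List with `is_rare`, `basis` and `values_used`.
#' @export
is_rare <- function(ann, klass, thresholds = default_thresholds()) {
  mm <- max_maf(ann)
  if (klass %in% c("compound_het", "compound_het_ambiguous")) {
    member_rare <- is.na(mm) | mm <= thresholds$rare_maf
    capped <- is.na(mm) | mm <= thresholds$common_cap
    verdict <- any(member_rare) && all(capped)
    basis <- if (all(is.na(mm))) "missing_treated_rare" else "maf_max"
    return(list(is_rare = verdict, basis = basis, values_used = mm))
  }
  if (klass == "homozygous_recessive") {
    q2 <- ann$q2_esp
    if (all(is.na(q2)))
      return(list(is_rare = TRUE, basis = "missing_treated_rare", values_used = q2))
    return(list(is_rare = all(is.na(q2) | q2 <= thresholds$q2_cap),
                basis = "q2", values_used = q2))
  }
  # het-type classes: single het, de_novo, x_hemizygous
  if (all(is.na(mm)))
    return(list(is_rare = TRUE, basis = "missing_treated_rare", values_used = mm))
  list(is_rare = all(is.na(mm) | mm <= thresholds$rare_maf),
       basis = "maf_max", values_used = mm)
}

#' Functional-consequence filter
#'
#' Keeps non-synonymous and frame-shift variants: `missense`, `stop_gain`
#' and `frameshift`. Synonymous, other and unannotated consequences fail.
#'
#' @param consequence character vector of consequence labels (or an annotated
#'   variant data frame).
#' @return Logical vector.
#' @export
consequence_filter <- function(consequence) {
  if (is.data.frame(consequence)) consequence <- consequence$consequence
  !is.na(consequence) & consequence %in% c("missense", "stop_gain", "frameshift")
}

#' Conservation flag from SiPhy
#'
#' Report-only annotation: `TRUE` when the SiPhy score (larger = more
#' conserved) is at or above `siphy_min`. Never used as a filter.
#'
#' @param ann annotated variants (or numeric SiPhy scores).
#' @param siphy_min threshold, default 10.
#' @return Logical vector; missing scores give `FALSE`.
#' @export
conservation_flag <- function(ann, siphy_min = 10) {
  s <- if (is.data.frame(ann)) ann$siphy else ann
  !is.na(s) & s >= siphy_min
}
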