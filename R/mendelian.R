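# dose-indexed consistency lookups, built once at load from gamete logic:
# a diploid parent with dose 0/1/2 can transmit {0}/{0,1}/{1}
.gamete_set <- function(dose) switch(dose + 1L, 0L, 0:1, 1L)

.build_auto_ok <- function() {
  ok <- array(FALSE, c(3, 3, 3)) # [child+1, father+1, mother+1]
  for (f in 0:2) for (m in 0:2) for (c in 0:2)
    ok[c + 1, f + 1, m + 1] <-
      any(outer(.gamete_set(f), .gamete_set(m), `+`) == c)
  ok
}
AUTO_OK <- .build_auto_ok()

# male X: the single maternal gamete must supply the child's allele
XM_OK <- rbind(c(TRUE, TRUE, FALSE), c(FALSE, TRUE, TRUE))

.build_xf_ok <- function() {
  ok <- array(FALSE, c(3, 2, 3)) # [child dose+1, father allele+1, mother dose+1]
  for (f in 0:1) for (m in 0:2) for (c in 0:2)
    ok[c + 1, f + 1, m + 1] <- any(f + .gamete_set(m) == c)
  ok
}
XF_OK <- .build_xf_ok()

norm_gt_arg <- function(g, what) {
  g <- as.integer(g)
  if (!length(g) %in% 1:2 || anyNA(g) || any(!g %in% 0:1))
    stop(what, " genotype must be 1 or 2 allele indices in {0, 1}")
  g
}

#' Mendelian consistency of a child-father-mother genotype trio
#'
#' A trio is consistent when the child genotype can be formed from one gamete
#' of each parent (autosomes), or -- for a male child on the X chromosome --
#' from a single maternal gamete (the paternal X is not transmitted to sons).
#' Used as a sequencing-error filter: inconsistent trios are far more likely
#' to be genotyping artefacts than true events.
#'
#' @param child,father,mother genotypes as integer allele-index vectors
#'   (`c(0, 1)` for a heterozygote; a single index for a hemizygous call).
#'   Diploid-coded homozygous male X genotypes are accepted and collapsed to
#'   hemizygous.
#' @param chrom chromosome label; `"Y"`, `"M"`/`"MT"` are unsupported.
#' @param child_sex `"male"` or `"female"`; only consulted on the X.
#' @return `TRUE` if the trio is Mendelian-consistent.
#' @export
mendelian_consistent <- function(child, father, mother, chrom = "1",
                                 child_sex = c("male", "female")) {
  chrom <- norm_chrom(chrom)
  if (is_unsupported_chrom(chrom))
    stop("Mendelian check unsupported on chromosome ", chrom)
  child_sex <- match.arg(child_sex)
  mother <- norm_gt_arg(mother, "mother")
  if (length(mother) != 2L) stop("mother genotype must be diploid")
  if (!is_x_chrom(chrom)) {
    child <- norm_gt_arg(child, "child")
    father <- norm_gt_arg(father, "father")
    if (length(child) != 2L || length(father) != 2L)
      stop("hemizygous genotypes only supported on the X")
    return(AUTO_OK[sum(child) + 1L, sum(father) + 1L, sum(mother) + 1L])
  }
  if (child_sex == "male") {
    child <- norm_gt_arg(child, "child")
    if (length(child) == 2L) {
      if (child[1] != child[2]) stop("heterozygous male X child genotype")
      child <- child[1]
    }
    return(XM_OK[child + 1L, sum(mother) + 1L])
  }
  father <- norm_gt_arg(father, "father")
  if (length(father) == 2L) {
    if (father[1] != father[2]) stop("heterozygous male X father genotype")
    father <- father[1]
  }
  child <- norm_gt_arg(child, "child")
  if (length(child) != 2L) stop("female child X genotype must be diploid")
  XF_OK[sum(child) + 1L, father + 1L, sum(mother) + 1L]
}

# vectorized over all sites for every affected sib: logical matrix
# sites x sibs; NA where any member of the trio is missing. Y/MT sites must be
# removed upstream.
mendelian_flags <- function(fam, ped) {
  par <- sib_parents(ped)
  dm <- dose_matrix(fam)
  x <- is_x_chrom(fam$sites$chrom)
  f <- dm[, par$father]; m <- dm[, par$mother]
  out <- matrix(NA, nrow(fam$sites), length(par$sibs),
                dimnames = list(fam$sites$site_id, par$sibs))
  for (sib in par$sibs) {
    cdose <- dm[, sib]
    ok <- rep(NA, length(cdose))
    a <- !x & !is.na(cdose) & !is.na(f) & !is.na(m)
    ok[a] <- AUTO_OK[cbind(cdose[a] + 1L, f[a] + 1L, m[a] + 1L)]
    if (par$sib_sex[sib] == "male") {
      xm <- x & !is.na(cdose) & !is.na(m)
      ok[xm] <- XM_OK[cbind(cdose[xm] + 1L, m[xm] + 1L)]
    } else {
      xf <- x & !is.na(cdose) & !is.na(f) & !is.na(m)
      ok[xf] <- XF_OK[cbind(cdose[xf] + 1L, f[xf] + 1L, m[xf] + 1L)]
    }
    out[, sib] <- ok
  }
  out
}
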