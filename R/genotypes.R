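#' Family genotype container
#'
#' Holds biallelic variant sites and one genotype call per (site, sample)
#' pair. Calls are unphased; allele indices are 0 (reference) and 1
#' (alternate). Male X calls are stored hemizygous (`a2 = NA`, `hemi = TRUE`).
#'
#' @param sites data frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `rsid`; a `site_id` key (`chrom:pos:ref:alt`) is added.
#' @param calls data frame with columns `site_id`, `sample_id`, `a1`, `a2`,
#'   `hemi`, `missing`, `depth`, `alt_depth`. Every (site, sample) pair must
#'   appear exactly once.
#' @param samples character vector of sample ids covered by `calls`.
#' @return An object of class `family_genotypes`.
#' @export
family_genotypes <- function(sites, calls, samples) {
  sites <- as.data.frame(sites)
  if (is.null(sites$rsid)) sites$rsid <- NA_character_
  if (is.null(sites$site_id))
    sites$site_id <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
  stopifnot(all(c("site_id", "sample_id", "a1", "a2", "hemi", "missing") %in% names(calls)))
  if (is.null(calls$depth)) calls$depth <- NA_integer_
  if (is.null(calls$alt_depth)) calls$alt_depth <- NA_integer_
  if (nrow(sites)) {
    if (any(sites$ref == sites$alt)) stop("site with ref == alt")
    if (any(sites$pos < 1L)) stop("site with pos < 1")
    if (anyDuplicated(sites$site_id)) stop("duplicate site after normalization")
    key <- paste(calls$site_id, calls$sample_id)
    want <- paste(rep(sites$site_id, each = length(samples)),
                  rep(samples, times = nrow(sites)))
    if (length(key) != length(want) || !setequal(key, want) || anyDuplicated(key))
      stop("calls must contain exactly one entry per (site, sample) pair")
    bad_ad <- !is.na(calls$alt_depth) & !is.na(calls$depth) & calls$alt_depth > calls$depth
    if (any(bad_ad)) stop("alt_depth exceeds depth at ", calls$site_id[bad_ad][1])
  }
  structure(list(sites = sites, calls = as.data.frame(calls), samples = samples),
            class = "family_genotypes")
}

#' @export
print.family_genotypes <- function(x, ...) {
  cat("FamilyGenotypes:", nrow(x$sites), "sites x", length(x$samples),
      "samples (", paste(x$samples, collapse = ", "), ")\n")
  invisible(x)
}

# strip an optional "chr" prefix; karyotype-style labels
norm_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

is_x_chrom <- function(chrom) norm_chrom(chrom) == "X"
is_unsupported_chrom <- function(chrom) norm_chrom(chrom) %in% c("Y", "M", "MT")

# allele dose per call: 0..2 diploid, 0..1 hemizygous, NA missing
call_dose <- function(calls) {
  ifelse(calls$missing, NA_integer_,
         ifelse(calls$hemi, calls$a1, calls$a1 + calls$a2))
}

# sites x samples integer dose matrix (NA = missing call)
dose_matrix <- function(fam) {
  d <- call_dose(fam$calls)
  m <- matrix(NA_integer_, nrow(fam$sites), length(fam$samples),
              dimnames = list(fam$sites$site_id, fam$samples))
  m[cbind(match(fam$calls$site_id, fam$sites$site_id),
          match(fam$calls$sample_id, fam$samples))] <- d
  m
}

parse_gt_field <- function(gt) {
  # returns list of integer allele vectors; NA element for missing/malformed
  parts <- strsplit(gt, "[/|]")
  lapply(parts, function(p) {
    if (length(p) == 0L || all(p == ".")) return(NULL)
    a <- suppressWarnings(as.integer(p))
    if (anyNA(a)) return(NA) # malformed
    a
  })
}

#' Load a multi-sample VCF into a family genotype container
#'
#' Reads a VCF 4.2 file (via \pkg{vcfR}), keeps the samples named in the
#' pedigree, splits multiallelic records into biallelic sites (genotypes
#' remapped so that, at the site for alternate allele *j*, allele *j* maps to
#' 1 and every other allele to 0 -- allele counts are conserved across the
#' split), and normalizes male X genotypes to hemizygous calls. Positions stay
#' 1-based as in the VCF. Missing genotypes (`./.`) become missing-flagged
#' calls; malformed genotypes raise a warning and become missing.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @param ped a [pedigree]; every sample in it must be in the VCF header.
#' @return A [family_genotypes] object.
#' @export
load_variants <- function(path, ped) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  header_samples <- colnames(v@gt)[-1]
  absent <- setdiff(ped$sample_id, header_samples)
  if (length(absent))
    stop("pedigree sample(s) absent from VCF header: ", paste(absent, collapse = ", "))
  samples <- ped$sample_id
  fix <- v@fix
  n_rec <- nrow(fix)
  site_rows <- list(); call_rows <- list(); n_malformed <- 0L; n_het_male_x <- 0L
  male <- stats::setNames(ped$sex == "male", ped$sample_id)

  k <- 0L
  if (n_rec) for (i in seq_len(n_rec)) {
    fmt <- strsplit(v@gt[i, "FORMAT"], ":", fixed = TRUE)[[1]]
    gi <- match("GT", fmt); adi <- match("AD", fmt); dpi <- match("DP", fmt)
    raw <- unname(v@gt[i, samples])
    raw[is.na(raw)] <- "." # vcfR renders fully-missing cells as NA
    cells <- strsplit(raw, ":", fixed = TRUE)
    gts <- parse_gt_field(vapply(cells, function(x) {
      if (length(x) >= gi) x[gi] else "."
    }, ""))
    malformed <- vapply(gts, function(g) length(g) == 1L && !is.null(g) && is.na(g[1]), TRUE)
    n_malformed <- n_malformed + sum(malformed)
    ad <- lapply(cells, function(x) {
      if (is.na(adi) || length(x) < adi || x[adi] %in% c(".", "")) return(NULL)
      suppressWarnings(as.integer(strsplit(x[adi], ",", fixed = TRUE)[[1]]))
    })
    dp <- vapply(cells, function(x) {
      if (is.na(dpi) || length(x) < dpi) return(NA_integer_)
      suppressWarnings(as.integer(x[dpi]))
    }, 0L)
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    chrom <- norm_chrom(fix[i, "CHROM"])
    x_site <- is_x_chrom(chrom)
    for (j in seq_along(alts)) {
      k <- k + 1L
      site_rows[[k]] <- data.frame(
        chrom = chrom, pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[j],
        rsid = if (is.na(fix[i, "ID"]) || fix[i, "ID"] == ".") NA_character_ else fix[i, "ID"],
        stringsAsFactors = FALSE
      )
      a1 <- a2 <- rep(NA_integer_, length(samples))
      hemi <- rep(FALSE, length(samples))
      miss <- rep(TRUE, length(samples))
      for (s in seq_along(samples)) {
        g <- gts[[s]]
        if (is.null(g) || (length(g) == 1L && is.na(g[1]))) next
        mapped <- as.integer(g == j)
        if (x_site && male[samples[s]]) {
          if (length(mapped) == 1L || mapped[1] == mapped[length(mapped)]) {
            a1[s] <- mapped[1]; hemi[s] <- TRUE; miss[s] <- FALSE
          } else {
            n_het_male_x <- n_het_male_x + 1L # heterozygous male X: unusable
          }
        } else if (length(mapped) == 2L) {
          a1[s] <- min(mapped); a2[s] <- max(mapped); miss[s] <- FALSE
        } else if (length(mapped) == 1L) {
          a1[s] <- mapped[1]; hemi[s] <- TRUE; miss[s] <- FALSE
        }
      }
      alt_depth <- vapply(seq_along(samples), function(s) {
        if (is.null(ad[[s]]) || length(ad[[s]]) < j + 1L) NA_integer_ else ad[[s]][j + 1L]
      }, 0L)
      depth <- vapply(seq_along(samples), function(s) {
        if (!is.na(dp[s])) dp[s]
        else if (!is.null(ad[[s]]) && !anyNA(ad[[s]])) sum(ad[[s]])
        else NA_integer_
      }, 0L)
      call_rows[[k]] <- data.frame(
        site_id = paste(chrom, fix[i, "POS"], fix[i, "REF"], alts[j], sep = ":"),
        sample_id = samples, a1 = a1, a2 = a2, hemi = hemi, missing = miss,
        depth = depth, alt_depth = alt_depth, stringsAsFactors = FALSE
      )
    }
  }
  if (n_malformed) warning(n_malformed, " malformed genotype(s) set to missing")
  if (n_het_male_x) warning(n_het_male_x, " heterozygous male X genotype(s) set to missing")
  if (k == 0L) {
    return(family_genotypes(
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), rsid = character()),
      data.frame(site_id = character(), sample_id = character(), a1 = integer(),
                 a2 = integer(), hemi = logical(), missing = logical(),
                 depth = integer(), alt_depth = integer()),
      samples
    ))
  }
  family_genotypes(do.call(rbind, site_rows), do.call(rbind, call_rows), samples)
}

#' Write a family genotype container as VCF text
#'
#' Emits an uncompressed VCF 4.2 file with `GT` (and `AD`/`DP` when depths are
#' present). Hemizygous calls are written as single-allele genotypes. The
#' output re-parses with [load_variants()] to the identical genotype matrix.
#'
#' @param fam a [family_genotypes] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(fam, path) {
  has_depth <- any(!is.na(fam$calls$depth)) || any(!is.na(fam$calls$alt_depth))
  fmt <- if (has_depth) "GT:AD:DP" else "GT"
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_depth) c(
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">"
    ),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", fam$samples), collapse = "\t")
  )
  calls <- fam$calls
  gt <- ifelse(calls$missing, "./.",
               ifelse(calls$hemi, as.character(calls$a1),
                      paste0(calls$a1, "/", calls$a2)))
  cell <- gt
  if (has_depth) {
    ad <- ifelse(is.na(calls$alt_depth) | is.na(calls$depth), ".",
                 paste0(calls$depth - calls$alt_depth, ",", calls$alt_depth))
    dp <- ifelse(is.na(calls$depth), ".", as.character(calls$depth))
    cell <- paste(gt, ad, dp, sep = ":")
  }
  cell_mat <- matrix(NA_character_, nrow(fam$sites), length(fam$samples))
  cell_mat[cbind(match(calls$site_id, fam$sites$site_id),
                 match(calls$sample_id, fam$samples))] <- cell
  body <- character(0)
  if (nrow(fam$sites)) {
    body <- paste(fam$sites$chrom, fam$sites$pos,
                  ifelse(is.na(fam$sites$rsid), ".", fam$sites$rsid),
                  fam$sites$ref, fam$sites$alt, ".", "PASS", ".", fmt,
                  apply(cell_mat, 1L, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}
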