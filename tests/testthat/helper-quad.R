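# shared test helpers: tiny in-code fixtures

quad_ped <- function() quad_pedigree()

ped_lines <- c(
  "FAM SIBA FATHER MOTHER 1 2",
  "FAM SIBB FATHER MOTHER 1 2",
  "FAM FATHER 0 0 1 1",
  "FAM MOTHER 0 0 2 1"
)

# write a VCF from header + body lines, return the path
mini_vcf <- function(body, samples = c("SIBA", "SIBB", "FATHER", "MOTHER"),
                     format_defs = "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">") {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", format_defs,
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               body), path)
  path
}

vcf_row <- function(chrom, pos, id, ref, alt, fmt, ...) {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", fmt, ...), collapse = "\t")
}

# build a family_genotypes object directly from per-sample dose vectors
fam_from_doses <- function(doses, chrom = "1", hemi_samples = character(0),
                           depth = NA_integer_, alt_depth = NA_integer_) {
  n <- length(doses[[1]])
  sites <- data.frame(chrom = rep_len(chrom, n), pos = seq_len(n) * 10L,
                      ref = "A", alt = "G", rsid = NA_character_)
  sites$site_id <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
  calls <- do.call(rbind, lapply(names(doses), function(s) {
    d <- doses[[s]]
    hemi <- s %in% hemi_samples & is_x(sites$chrom)
    data.frame(site_id = sites$site_id, sample_id = s,
               a1 = ifelse(is.na(d), NA_integer_,
                           ifelse(hemi, d, as.integer(d >= 1L))),
               a2 = ifelse(is.na(d) | hemi, NA_integer_, as.integer(d == 2L)),
               hemi = hemi, missing = is.na(d),
               depth = rep_len(depth, n), alt_depth = rep_len(alt_depth, n),
               stringsAsFactors = FALSE)
  }))
  family_genotypes(sites, calls, names(doses))
}

is_x <- function(chrom) sub("^chr", "", chrom) == "X"

# minimal annotation rows keyed to a fam built by fam_from_doses
ann_for <- function(fam, gene = "G1", consequence = "missense",
                    maf_1000g = NA_real_, maf_esp = NA_real_, q2_esp = NA_real_,
                    sift = NA_real_, polyphen2 = NA_real_, fathmm = NA_real_,
                    siphy = NA_real_) {
  n <- nrow(fam$sites)
  cbind(fam$sites,
        data.frame(gene = rep_len(gene, n),
                   consequence = rep_len(consequence, n),
                   aa_change = NA_character_,
                   maf_1000g = rep_len(maf_1000g, n),
                   maf_esp = rep_len(maf_esp, n), q2_esp = rep_len(q2_esp, n),
                   sift = rep_len(sift, n), polyphen2 = rep_len(polyphen2, n),
                   fathmm = rep_len(fathmm, n), siphy = rep_len(siphy, n),
                   stringsAsFactors = FALSE))
}

# independent gamete-enumeration oracle for trio consistency, working on
# explicit allele pairs (not dose lookups)
oracle_trio_consistent <- function(child, father, mother) {
  for (gf in father) for (gm in mother)
    if (identical(sort(c(gf, gm)), sort(child))) return(TRUE)
  FALSE
}

oracle_male_x_consistent <- function(child_allele, mother) child_allele %in% mother
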