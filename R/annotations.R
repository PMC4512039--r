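ANNOTATION_COLS <- c("chrom", "pos", "ref", "alt", "rsid", "gene", "consequence",
                     "aa_change", "maf_1000g", "maf_esp", "q2_esp",
                     "sift", "polyphen2", "fathmm", "siphy")

CONSEQUENCE_LEVELS <- c("missense", "stop_gain", "frameshift", "synonymous", "other")

#' Read a per-variant annotation table
#'
#' Tab-separated table with header columns `chrom, pos, ref, alt, rsid, gene,
#' consequence, aa_change, maf_1000g, maf_esp, q2_esp, sift, polyphen2,
#' fathmm, siphy`. A `"-"` or empty cell means missing (the convention of
#' published variant tables). A stop-gain consequence is inferred from an
#' amino-acid change ending in `*` when the consequence cell is empty.
#'
#' @param path TSV path.
#' @return A data frame of annotations.
#' @export
load_annotations <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           na.strings = c("-", "", "NA", "."),
                           colClasses = "character", stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  missing_cols <- setdiff(ANNOTATION_COLS, names(tab))
  if (length(missing_cols))
    stop("annotation table lacks column(s): ", paste(missing_cols, collapse = ", "))
  tab <- tab[ANNOTATION_COLS]
  tab$chrom <- norm_chrom(tab$chrom)
  tab$pos <- as.integer(tab$pos)
  for (col in c("maf_1000g", "maf_esp", "q2_esp", "sift", "polyphen2", "fathmm", "siphy"))
    tab[[col]] <- as.numeric(tab[[col]])
  infer <- is.na(tab$consequence) & !is.na(tab$aa_change) & grepl("\\*$", tab$aa_change)
  tab$consequence[infer] <- "stop_gain"
  bad <- !is.na(tab$consequence) & !tab$consequence %in% CONSEQUENCE_LEVELS
  if (any(bad))
    stop("unknown consequence value: ", paste(unique(tab$consequence[bad]), collapse = ", "))
  for (col in c("maf_1000g", "maf_esp", "q2_esp")) {
    out <- !is.na(tab[[col]]) & (tab[[col]] < 0 | tab[[col]] > 1)
    if (any(out)) stop(col, " outside [0, 1] at row ", which(out)[1])
  }
  tab
}

#' Join annotations onto family genotype sites
#'
#' Left-joins an annotation table onto the sites of a [family_genotypes]
#' object, keyed on (chrom, pos, ref, alt) with an rsid fallback for rows that
#' do not match on coordinates. Sites absent from the table get all-missing
#' annotation fields. Duplicate annotation keys are a hard error.
#'
#' @param fam a [family_genotypes] object.
#' @param table annotation data frame (from [load_annotations()]) or TSV path.
#' @return A data frame of annotated variants: one row per site, columns
#'   `site_id`, the site fields and the annotation fields.
#' @export
merge_annotations <- function(fam, table) {
  if (is.character(table)) table <- load_annotations(table)
  key <- paste(table$chrom, table$pos, table$ref, table$alt, sep = ":")
  if (anyDuplicated(key[!grepl("NA", key, fixed = TRUE)]))
    stop("duplicate annotation key: ", key[duplicated(key)][1])
  rs <- table$rsid[!is.na(table$rsid)]
  if (anyDuplicated(rs)) stop("duplicate annotation rsid: ", rs[duplicated(rs)][1])
  idx <- match(fam$sites$site_id, key)
  fallback <- is.na(idx) & !is.na(fam$sites$rsid)
  idx[fallback] <- match(fam$sites$rsid[fallback], table$rsid)
  ann_cols <- setdiff(ANNOTATION_COLS, c("chrom", "pos", "ref", "alt", "rsid"))
  out <- cbind(fam$sites, table[idx, ann_cols, drop = FALSE])
  rownames(out) <- NULL
  out
}
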