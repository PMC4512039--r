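#' Construct a pedigree
#'
#' A pedigree is a data frame with one row per individual and columns
#' `sample_id`, `father_id`, `mother_id`, `sex` and `affected`. Parent ids are
#' `NA` for founders; when present they must refer to another individual in the
#' same pedigree. The canonical design supported downstream is a nuclear family
#' with at least one affected child (the quad -- two affected siblings plus
#' both parents -- being the motivating case).
#'
#' @param sample_id character vector of unique individual ids.
#' @param father_id,mother_id character vectors of parent ids (`NA` = founder).
#' @param sex one of `"male"`, `"female"`, `"unknown"` per individual.
#' @param affected one of `"affected"`, `"unaffected"`, `"unknown"`.
#' @return An object of class `pedigree` (a data frame).
#' @export
pedigree <- function(sample_id, father_id = NA_character_,
                     mother_id = NA_character_, sex = "unknown",
                     affected = "unknown") {
  ped <- data.frame(
    sample_id = as.character(sample_id),
    father_id = rep_len(as.character(father_id), length(sample_id)),
    mother_id = rep_len(as.character(mother_id), length(sample_id)),
    sex       = rep_len(as.character(sex), length(sample_id)),
    affected  = rep_len(as.character(affected), length(sample_id)),
    stringsAsFactors = FALSE
  )
  validate_pedigree(ped)
}

validate_pedigree <- function(ped) {
  if (nrow(ped) == 0L) stop("no samples in pedigree")
  if (anyDuplicated(ped$sample_id))
    stop("duplicate sample id: ",
         paste(unique(ped$sample_id[duplicated(ped$sample_id)]), collapse = ", "))
  ok_sex <- c("male", "female", "unknown")
  ok_aff <- c("affected", "unaffected", "unknown")
  if (!all(ped$sex %in% ok_sex)) stop("sex must be one of ", paste(ok_sex, collapse = "/"))
  if (!all(ped$affected %in% ok_aff))
    stop("affected must be one of ", paste(ok_aff, collapse = "/"))
  for (col in c("father_id", "mother_id")) {
    dangling <- setdiff(stats::na.omit(ped[[col]]), ped$sample_id)
    if (length(dangling))
      stop("parent id not in pedigree: ", paste(dangling, collapse = ", "))
  }
  # no sample may be its own ancestor
  parent_of <- function(id) {
    row <- ped[ped$sample_id == id, , drop = FALSE]
    stats::na.omit(c(row$father_id, row$mother_id))
  }
  for (id in ped$sample_id) {
    frontier <- parent_of(id)
    seen <- character(0)
    while (length(frontier)) {
      if (id %in% frontier) stop("pedigree cycle: ", id, " is its own ancestor")
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(lapply(frontier, parent_of))), seen)
    }
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Read a PLINK-style PED file
#'
#' Expects the 6-column whitespace-delimited PED layout
#' `FID IID PAT MAT SEX PHENO` with sex coded 1 = male, 2 = female,
#' 0 = unknown and phenotype coded 2 = affected, 1 = unaffected,
#' 0 or -9 = unknown. A parent id of `"0"` means founder.
#'
#' @param path path to a PED file, or a character vector of PED lines.
#' @return A [pedigree] object.
#' @export
load_pedigree <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no samples in PED input")
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(fields) < 6L)
  if (length(bad)) stop("malformed PED line ", bad[1], ": fewer than 6 fields")
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  sex <- c("0" = "unknown", "1" = "male", "2" = "female")[m[, 5]]
  aff <- c("2" = "affected", "1" = "unaffected", "0" = "unknown", "-9" = "unknown")[m[, 6]]
  if (anyNA(sex)) stop("unrecognized sex code in PED: ", m[is.na(sex), 5][1])
  if (anyNA(aff)) stop("unrecognized phenotype code in PED: ", m[is.na(aff), 6][1])
  pedigree(
    sample_id = m[, 2],
    father_id = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
    mother_id = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
    sex = unname(sex), affected = unname(aff)
  )
}

#' Write a pedigree as PLINK PED text
#' @param ped a [pedigree].
#' @param path output file; the family id column is written as `"FAM"`.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  sex <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  aff <- c(affected = "2", unaffected = "1", unknown = "0")[ped$affected]
  lines <- paste("FAM", ped$sample_id,
                 ifelse(is.na(ped$father_id), "0", ped$father_id),
                 ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                 sex, aff, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Affected siblings of a pedigree
#'
#' Children (individuals with both parents recorded) whose status is
#' `affected`. The recessive-model machinery requires at least one.
#'
#' @param ped a [pedigree].
#' @return The subset of `ped` rows for affected children.
#' @export
affected_sibs <- function(ped) {
  kids <- ped[!is.na(ped$father_id) & !is.na(ped$mother_id) &
                ped$affected == "affected", , drop = FALSE]
  kids
}

# parents of the affected sibship; errors unless all affected sibs share both
# parents (the nuclear-family design the filters assume)
sib_parents <- function(ped) {
  sibs <- affected_sibs(ped)
  if (nrow(sibs) == 0L) stop("pedigree has no affected siblings with recorded parents")
  fa <- unique(sibs$father_id); mo <- unique(sibs$mother_id)
  if (length(fa) != 1L || length(mo) != 1L)
    stop("affected siblings do not share both parents")
  list(father = fa, mother = mo, sibs = sibs$sample_id,
       sib_sex = stats::setNames(sibs$sex, sibs$sample_id))
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "individuals,",
      sum(x$affected == "affected"), "affected\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
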