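#' Parse an ISCN-style karyotype string
#'
#' Handles the numeric-prefix comma-delimited form used in clinical
#' cytogenetics reports, e.g. `"53,XY,+4,+6,+12,+15,+17,+18,+21"`: a declared
#' modal chromosome number, a sex-chromosome complement, and whole-chromosome
#' gains (`+N`) and losses (`-N`). Structural rearrangement tokens
#' (`inv(...)`, `t(...)`, `del(...)`, ...) are carried verbatim as notes,
#' not interpreted.
#'
#' @param s karyotype string.
#' @return A `karyotype` object with fields `modal_declared`, `sex`, `gains`,
#'   `losses`, `notes` and `raw`.
#' @export
parse_iscn <- function(s) {
  if (!is.character(s) || length(s) != 1L || !nzchar(trimws(s)))
    stop("karyotype string required")
  tokens <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  tokens <- gsub("−", "-", tokens) # unicode minus
  if (length(tokens) < 2L) stop("unparseable karyotype: ", s)
  modal <- suppressWarnings(as.integer(tokens[1]))
  if (is.na(modal)) stop("unparseable modal number in karyotype: ", tokens[1])
  sex <- tokens[2]
  if (!grepl("^[XY]+$", sex)) stop("unparseable sex complement: ", sex)
  gains <- character(0); losses <- character(0); notes <- character(0)
  valid <- c(as.character(1:22), "X", "Y")
  for (tok in tokens[-(1:2)]) {
    if (grepl("\\(", tok)) { notes <- c(notes, tok); next }
    if (grepl("^\\+", tok)) {
      lab <- sub("^\\+", "", tok)
      if (!lab %in% valid) stop("invalid chromosome label in gain: ", tok)
      gains <- c(gains, lab)
    } else if (grepl("^-", tok)) {
      lab <- sub("^-", "", tok)
      if (!lab %in% valid) stop("invalid chromosome label in loss: ", tok)
      losses <- c(losses, lab)
    } else stop("unparseable karyotype token: ", tok)
  }
  structure(list(modal_declared = modal, sex = sex, gains = gains,
                 losses = losses, notes = notes, raw = s),
            class = "karyotype")
}

#' Render a karyotype model back to ISCN form
#' @param m a `karyotype` object.
#' @return Character string (gains/losses round-trip through [parse_iscn()]).
#' @export
format_iscn <- function(m) {
  paste(c(m$modal_declared, m$sex,
          if (length(m$gains)) paste0("+", m$gains),
          if (length(m$losses)) paste0("-", m$losses),
          m$notes), collapse = ",")
}

#' Modal chromosome number of a parsed karyotype
#'
#' Computed as 46 + gains - losses. When the declared modal number disagrees
#' with the computed count, a validation warning is raised and the mismatch
#' is flagged on the result (never silently corrected).
#'
#' @param m a `karyotype` object from [parse_iscn()].
#' @return Integer count, with attribute `declared_mismatch`.
#' @export
chromosome_count <- function(m) {
  n <- 46L + length(m$gains) - length(m$losses)
  mismatch <- !is.na(m$modal_declared) && m$modal_declared != n
  if (mismatch)
    warning("declared modal number ", m$modal_declared,
            " != computed count ", n)
  structure(n, declared_mismatch = mismatch)
}

#' Classify ploidy from a chromosome count
#'
#' Conventional cytogenetic bands: hypodiploid < 46, diploid 46,
#' low-hyperdiploid 47-50, high-hyperdiploid 51-67, near-triploid and above
#' > 67. Band boundaries are overridable.
#'
#' @param n chromosome count (>= 1).
#' @param high_range inclusive bounds of the high-hyperdiploid band.
#' @return Category string.
#' @export
classify_ploidy <- function(n, high_range = c(51L, 67L)) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("chromosome count must be >= 1")
  if (n < 46L) "hypodiploid"
  else if (n == 46L) "diploid"
  else if (n < high_range[1]) "low-hyperdiploid"
  else if (n <= high_range[2]) "high-hyperdiploid"
  else "near-triploid+"
}

#' Summarize one or more karyotype strings
#'
#' Convenience wrapper: parse, count, classify.
#'
#' @param strings named character vector of ISCN karyotype strings.
#' @return Data frame with declared and computed modal numbers, mismatch
#'   flags and ploidy categories.
#' @export
karyotype_summary <- function(strings) {
  rows <- lapply(seq_along(strings), function(i) {
    m <- parse_iscn(strings[[i]])
    n <- suppressWarnings(chromosome_count(m))
    data.frame(
      id = if (!is.null(names(strings))) names(strings)[i] else as.character(i),
      declared = m$modal_declared, computed = as.integer(n),
      mismatch = attr(n, "declared_mismatch"),
      ploidy = classify_ploidy(as.integer(n)),
      gains = paste(m$gains, collapse = "+"),
      losses = paste(m$losses, collapse = "-"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
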