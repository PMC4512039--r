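#' Configuration of the data-reduction cascade
#'
#' @param thresholds rarity/deleteriousness thresholds, see
#'   [default_thresholds()].
#' @param shared_rule sib-sharing rule, see [shared_by_affected()].
#' @param missing_policy `"strict"` drops any site with a missing call in a
#'   required family member; `"lenient"` lets missing calls pass the
#'   Mendelian stage as unknown (sites still need non-missing calls to be
#'   classified).
#' @param min_parent_depth parental coverage floor for the de novo screen.
#' @param min_damaging minimum per-variant count of damaging tool calls for a
#'   candidate to pass the consensus stage (variants with no available score
#'   pass unassessed).
#' @param apply_consequence apply the non-synonymous/frameshift filter stage.
#' @param apply_rare_damaging apply the final rarity + consensus stage (when
#'   off, verdicts are still annotated but nothing is dropped).
#' @param run_denovo run the de novo branch.
#' @param stage_order order of the Mendelian and shared-by-affected stages
#'   (pure set filters: the order changes trace counts, not the result).
#' @return A `reduction_config` list.
#' @export
reduction_config <- function(thresholds = default_thresholds(),
                             shared_rule = c("identity", "carrier"),
                             missing_policy = c("strict", "lenient"),
                             min_parent_depth = 8L, min_damaging = 1L,
                             apply_consequence = TRUE,
                             apply_rare_damaging = TRUE, run_denovo = TRUE,
                             stage_order = c("mendelian", "shared")) {
  stopifnot(setequal(stage_order, c("mendelian", "shared")))
  list(thresholds = thresholds, shared_rule = match.arg(shared_rule),
       missing_policy = match.arg(missing_policy),
       min_parent_depth = as.integer(min_parent_depth),
       min_damaging = as.integer(min_damaging),
       apply_consequence = apply_consequence,
       apply_rare_damaging = apply_rare_damaging,
       run_denovo = run_denovo, stage_order = stage_order)
}

empty_candidates <- function() {
  data.frame(gene = character(), klass = character(), n_variants = integer(),
             sites = I(list()), origins = I(list()), rare = logical(),
             rarity_basis = character(), consensus_ok = logical(),
             min_n_damaging = integer(), conserved = logical(),
             passes = logical())
}

#' Section of a published candidate table for an inheritance class
#'
#' Maps the fine-grained inheritance classes onto the two recessive report
#' sections: both compound-heterozygous classes (resolved-trans and
#' phase-unresolved) report under `"compound_heterozygous"`, homozygous
#' candidates under `"homozygous"`; the screens keep their own sections.
#'
#' @param klass character vector of inheritance classes.
#' @return Character vector of section names.
#' @export
candidate_section <- function(klass) {
  c(compound_het = "compound_heterozygous",
    compound_het_ambiguous = "compound_heterozygous",
    homozygous_recessive = "homozygous",
    x_hemizygous = "x_linked",
    de_novo = "de_novo")[klass]
}

#' Run the data-reduction cascade
#'
#' Applies, in order: QC (supported chromosomes, missingness policy), the
#' Mendelian-inconsistency filter, the shared-by-affected reduction, the
#' consequence filter, recessive-model gene classification, and the rarity +
#' deleteriousness-consensus stage; the de novo screen runs as a parallel
#' branch on the unfiltered input (its candidate sites are Mendelian-
#' inconsistent by definition). Every stage logs its input/output site count
#' in the filter trace, which is the audit artifact of the run.
#'
#' @param fam a [family_genotypes].
#' @param ped a [pedigree].
#' @param ann annotated variants for the sites of `fam` (from
#'   [merge_annotations()] or [simulate_sites()]).
#' @param config a [reduction_config()].
#' @return A `reduction_result` list: `candidates` (with rarity/consensus
#'   verdicts and a `passes` flag), `trace`, `denovo`.
#' @export
run_reduction <- function(fam, ped, ann, config = reduction_config()) {
  stage_rows <- list()
  add_stage <- function(stage, n_in, n_out)
    stage_rows[[length(stage_rows) + 1L]] <<-
      data.frame(stage = stage, n_in = n_in, n_out = n_out)
  site_ids <- fam$sites$site_id
  n0 <- length(site_ids)

  keep <- !is_unsupported_chrom(fam$sites$chrom)
  if (config$missing_policy == "strict" && n0) {
    par <- sib_parents(ped)
    members <- c(par$sibs, par$father, par$mother)
    mc <- fam$calls[fam$calls$sample_id %in% members, ]
    any_missing <- tapply(mc$missing, mc$site_id, any)[site_ids]
    keep <- keep & !as.logical(any_missing)
  }
  add_stage("qc", n0, sum(keep))

  if (n0) {
    mflags <- mendelian_flags(fam, ped)
    if (config$missing_policy == "lenient") mflags[is.na(mflags)] <- TRUE
    mendel_ok <- rowSums(mflags, na.rm = FALSE) == ncol(mflags)
    mendel_ok[is.na(mendel_ok)] <- FALSE
    shared <- shared_by_affected(fam, ped, config$shared_rule)
    for (stage in config$stage_order) {
      flag <- if (stage == "mendelian") mendel_ok else shared
      nm <- if (stage == "mendelian") "mendelian" else "shared_by_affected"
      n_in <- sum(keep); keep <- keep & flag
      add_stage(nm, n_in, sum(keep))
    }
    cons_ok <- consequence_filter(ann$consequence[match(site_ids, ann$site_id)])
    if (config$apply_consequence) {
      n_in <- sum(keep); keep <- keep & cons_ok
      add_stage("consequence", n_in, sum(keep))
    }
  } else {
    add_stage("mendelian", 0L, 0L); add_stage("shared_by_affected", 0L, 0L)
    if (config$apply_consequence) add_stage("consequence", 0L, 0L)
  }

  sub_ann <- ann[match(site_ids[keep], ann$site_id), , drop = FALSE]
  sub_ann <- sub_ann[!is.na(sub_ann$site_id), , drop = FALSE]
  cands <- if (nrow(sub_ann)) classify_genes(fam, ped, sub_ann) else empty_candidates()
  n_class_sites <- if (nrow(cands)) sum(cands$n_variants) else 0L
  add_stage("classification", sum(keep), n_class_sites)

  if (nrow(cands)) {
    thr <- config$thresholds
    verdicts <- lapply(seq_len(nrow(cands)), function(i) {
      rows <- ann[match(cands$sites[[i]], ann$site_id), , drop = FALSE]
      rv <- is_rare(rows, cands$klass[i], thr)
      dc <- damaging_calls(rows, thr)
      list(rare = rv$is_rare, basis = rv$basis,
           consensus_ok = all(dc$n_damaging >= config$min_damaging |
                                dc$n_available == 0L),
           min_n_damaging = min(dc$n_damaging),
           conserved = any(conservation_flag(rows, thr$siphy_min)))
    })
    cands$rare <- vapply(verdicts, `[[`, TRUE, "rare")
    cands$rarity_basis <- vapply(verdicts, `[[`, "", "basis")
    cands$consensus_ok <- vapply(verdicts, `[[`, TRUE, "consensus_ok")
    cands$min_n_damaging <- vapply(verdicts, function(v) as.integer(v$min_n_damaging), 1L)
    cands$conserved <- vapply(verdicts, `[[`, TRUE, "conserved")
    cands$passes <- cands$rare & cands$consensus_ok
  } else cands <- empty_candidates()
  if (config$apply_rare_damaging) {
    n_pass_sites <- if (nrow(cands)) sum(cands$n_variants[cands$passes]) else 0L
    add_stage("rarity_consensus", n_class_sites, n_pass_sites)
  }

  denovo <- if (config$run_denovo)
    denovo_screen(fam, ped, ann, config$min_parent_depth)
  else fam$sites[0, , drop = FALSE]

  trace <- do.call(rbind, stage_rows)
  structure(list(candidates = cands, trace = trace, denovo = denovo,
                 config = config), class = "reduction_result")
}

#' @export
print.reduction_result <- function(x, ...) {
  cat("Reduction cascade:\n")
  print(x$trace, row.names = FALSE)
  cat(nrow(x$candidates), "candidate gene(s);",
      sum(x$candidates$passes), "pass rarity + consensus;",
      nrow(x$denovo), "de novo site(s)\n")
  invisible(x)
}

#' Candidates passing the rarity and consensus stage
#' @param result a `reduction_result`.
#' @return Subset of the candidate table with `passes == TRUE`.
#' @export
passing_candidates <- function(result) {
  result$candidates[result$candidates$passes, , drop = FALSE]
}

# ---- full pipeline over files -------------------------------------------

#' Run the full prioritization pipeline from a configuration
#'
#' Orchestrates loading (PED, VCF, annotation TSV), the reduction cascade,
#' panel screening, the optional susceptibility-locus report and karyotype
#' summaries, and writes `report.tsv`, `report.json` and `trace.tsv` to the
#' output directory. All referenced input paths are checked before any
#' computation.
#'
#' @param config a named list (or YAML/JSON file path) with elements:
#'   `vcf`, `ped`, `annotations` (paths, required); `panel` (`"fa"` or a path
#'   to a one-symbol-per-line file); `risk_loci` and `risk_genotypes`
#'   (paths); `karyotypes` (named character vector of ISCN strings);
#'   `out_dir`; plus optional `thresholds` and reduction toggles
#'   (`shared_rule`, `missing_policy`, `min_parent_depth`, `min_damaging`).
#' @return A `candidate_report` list (also serialized when `out_dir` given).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  for (key in c("vcf", "ped", "annotations")) {
    if (is.null(config[[key]])) stop("config lacks required path: ", key)
    if (!file.exists(config[[key]]))
      stop("config path does not exist: ", key, " = ", config[[key]])
  }
  for (key in c("risk_loci", "risk_genotypes"))
    if (!is.null(config[[key]]) && !file.exists(config[[key]]))
      stop("config path does not exist: ", key, " = ", config[[key]])

  thr <- do.call(default_thresholds, as.list(config$thresholds %||% list()))
  red_cfg <- reduction_config(
    thresholds = thr,
    shared_rule = config$shared_rule %||% "identity",
    missing_policy = config$missing_policy %||% "strict",
    min_parent_depth = config$min_parent_depth %||% 8L,
    min_damaging = config$min_damaging %||% 1L
  )
  ped <- load_pedigree(config$ped)
  fam <- load_variants(config$vcf, ped)
  ann <- merge_annotations(fam, config$annotations)
  red <- run_reduction(fam, ped, ann, red_cfg)

  panel <- if (is.null(config$panel) || identical(config$panel, "fa")) fa_panel()
  else gene_panel(basename(config$panel), readLines(config$panel))
  panel_hits <- restrict_to_panel(red$candidates, panel)

  susceptibility <- NULL
  if (!is.null(config$risk_loci)) {
    loci <- utils::read.table(config$risk_loci, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    susceptibility <- if (!is.null(config$risk_genotypes)) {
      gts <- utils::read.table(config$risk_genotypes, header = TRUE, sep = "\t",
                               na.strings = c("-", ""), stringsAsFactors = FALSE)
      susceptibility_report(gts, loci)
    } else susceptibility_report(fam, loci, ped)
  }

  karyotypes <- if (!is.null(config$karyotypes))
    karyotype_summary(config$karyotypes) else NULL

  report <- structure(list(
    candidates = red$candidates, trace = red$trace, denovo = red$denovo,
    panel = list(name = panel$name, hits = panel_hits$gene),
    susceptibility = susceptibility, karyotypes = karyotypes
  ), class = "candidate_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

flatten_candidates <- function(cands) {
  data.frame(
    gene = cands$gene, klass = cands$klass,
    section = unname(candidate_section(cands$klass)),
    n_variants = cands$n_variants,
    sites = vapply(cands$sites, paste, "", collapse = ";"),
    origins = vapply(cands$origins, function(o)
      paste(ifelse(is.na(o), ".", o), collapse = ";"), ""),
    rare = cands$rare, rarity_basis = cands$rarity_basis,
    consensus_ok = cands$consensus_ok, min_n_damaging = cands$min_n_damaging,
    conserved = cands$conserved, passes = cands$passes,
    stringsAsFactors = FALSE
  )
}

#' Serialize a candidate report
#'
#' Writes `report.tsv` (flattened candidate table), `report.json` (the full
#' report) and `trace.tsv` into a directory. The TSV and JSON carry the same
#' candidate set.
#'
#' @param report a `candidate_report` from [run_pipeline()].
#' @param out_dir output directory.
#' @return Named vector of paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(tsv = file.path(out_dir, "report.tsv"),
             json = file.path(out_dir, "report.json"),
             trace = file.path(out_dir, "trace.tsv"))
  flat <- flatten_candidates(report$candidates)
  utils::write.table(flat, paths["tsv"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$trace, paths["trace"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  json <- list(
    candidates = flat, trace = report$trace,
    denovo = report$denovo$site_id %||% character(0),
    panel = report$panel,
    susceptibility = report$susceptibility,
    karyotypes = report$karyotypes
  )
  jsonlite::write_json(json, paths["json"], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Structural validation of a serialized report
#'
#' Checks a report JSON against the schema shipped in
#' `inst/schema/report-schema.json`: required top-level members and required
#' per-candidate fields.
#'
#' @param path path to a `report.json`.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(path) {
  schema <- jsonlite::read_json(system.file("schema", "report-schema.json",
                                            package = "quadscreen"))
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  missing_keys <- setdiff(unlist(schema$required), names(x))
  if (length(missing_keys))
    stop("report lacks required member(s): ", paste(missing_keys, collapse = ", "))
  req_cand <- unlist(schema$properties$candidates$items$required)
  for (cand in x$candidates) {
    miss <- setdiff(req_cand, names(cand))
    if (length(miss))
      stop("candidate lacks required field(s): ", paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}
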