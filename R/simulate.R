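#' Canonical quad pedigree
#'
#' Two affected male siblings plus their parents, the study design the
#' reduction cascade targets.
#'
#' @param sibs,father,mother sample ids.
#' @return A [pedigree].
#' @export
quad_pedigree <- function(sibs = c("SIBA", "SIBB"), father = "FATHER",
                          mother = "MOTHER") {
  pedigree(
    sample_id = c(sibs, father, mother),
    father_id = c(rep(father, length(sibs)), NA, NA),
    mother_id = c(rep(mother, length(sibs)), NA, NA),
    sex = c(rep("male", length(sibs)), "male", "female"),
    affected = c(rep("affected", length(sibs)), "unaffected", "unaffected")
  )
}

#' Spike-in scenario specification
#' @param scenario one of `"compound_het"`, `"hom_recessive"`, `"de_novo"`,
#'   `"x_linked"`.
#' @param gene optional gene symbol for the spiked gene.
#' @return A spike-in spec list.
#' @export
spike_in <- function(scenario = c("compound_het", "hom_recessive", "de_novo",
                                  "x_linked"), gene = NULL) {
  list(scenario = match.arg(scenario), gene = gene)
}

#' Simulation configuration
#'
#' Defaults emulate the exome-wide statistical structure the filters assume:
#' a site-frequency mixture with a rare tail (fraction `frac_rare` with MAF
#' log-uniform on \[1e-5, 1e-3\], remainder uniform on \[0.01, 0.5\]),
#' Hardy-Weinberg parental genotypes, fair Mendelian transmission, a per-call
#' genotype flip error, and Poisson read depths around sequencing-run means
#' (sibship 28.1X, parents 19.4X). Spike-ins overwrite designated sites with
#' a disease configuration and are recorded as truth.
#'
#' @param n_sites number of background sites.
#' @param seed mandatory RNG seed (integer < 2^31).
#' @param frac_rare fraction of sites in the rare MAF stratum.
#' @param frac_x fraction of background sites placed on the X chromosome.
#' @param genotyping_error per-call flip probability: with this probability a
#'   diploid call is replaced by one of the other two genotypes (uniformly),
#'   a hemizygous call by the other allele.
#' @param depth_sibs,depth_parents Poisson means for read depth.
#' @param p_missing per-call missingness probability.
#' @param frac_synonymous fraction of background sites annotated synonymous.
#' @param p_background_damaging probability that a background site draws
#'   tool scores in the damaging range (default 0: background benign).
#' @param min_parent_depth floor forced on parental depth at de novo spikes.
#' @param spike_ins list of [spike_in()] specs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sites = 1000L, seed, frac_rare = 0.3, frac_x = 0.05,
                       genotyping_error = 0, depth_sibs = 28.1,
                       depth_parents = 19.4, p_missing = 0,
                       frac_synonymous = 0.3, p_background_damaging = 0,
                       min_parent_depth = 8L, spike_ins = list()) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot(seed == as.integer(seed), abs(seed) < 2^31 - 10)
  for (p in c(frac_rare, frac_x, genotyping_error, p_missing, frac_synonymous,
              p_background_damaging))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  structure(list(n_sites = as.integer(n_sites), seed = as.integer(seed),
                 frac_rare = frac_rare, frac_x = frac_x,
                 genotyping_error = genotyping_error, depth_sibs = depth_sibs,
                 depth_parents = depth_parents, p_missing = p_missing,
                 frac_synonymous = frac_synonymous,
                 p_background_damaging = p_background_damaging,
                 min_parent_depth = as.integer(min_parent_depth),
                 spike_ins = spike_ins),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

#' Simulate annotated variant sites
#'
#' Draws background sites from the configured MAF mixture with
#' chromosome-coherent gene assignment, consequence labels, and tool scores
#' (benign by default; damaging with probability `p_background_damaging`),
#' then appends one gene per spike-in scenario with rare, all-damaging
#' annotation (SIFT 0, PolyPhen-2 1, FATHMM -3). The generative frequency is
#' kept in `maf_sim`; spiked rows are flagged in `spiked`/`scenario`.
#'
#' @param cfg a [sim_config()].
#' @return Annotated-variant data frame (one row per site).
#' @export
simulate_sites <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_sites
  draw_scores <- function(k, p_damaging) {
    dmg <- stats::runif(k) < p_damaging
    data.frame(
      sift = ifelse(dmg, stats::runif(k, 0, 0.05), stats::runif(k, 0.06, 1)),
      polyphen2 = ifelse(dmg, stats::runif(k, 0.957, 1), stats::runif(k, 0, 0.9)),
      fathmm = ifelse(dmg, stats::runif(k, -4, -1.6), stats::runif(k, -1, 5)),
      siphy = stats::runif(k, 0, 20)
    )
  }
  if (n > 0L) {
    chrom <- ifelse(stats::runif(n) < cfg$frac_x, "X",
                    as.character(sample.int(22L, n, replace = TRUE)))
    pos <- sample.int(2^26, n) # globally unique positions
    ref <- sample(BASES, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), "")
    rare <- stats::runif(n) < cfg$frac_rare
    maf <- ifelse(rare, 10^stats::runif(n, -5, -3), stats::runif(n, 0.01, 0.5))
    ord <- order(chrom, pos)
    gene <- character(n)
    for (ch in unique(chrom)) {
      in_ch <- ord[chrom[ord] == ch]
      gene[in_ch] <- sprintf("G%s_%03d", ch, ceiling(seq_along(in_ch) / 5))
    }
    consequence <- sample(c("missense", "synonymous", "other"), n, replace = TRUE,
                          prob = c(1 - cfg$frac_synonymous - 0.1,
                                   cfg$frac_synonymous, 0.1))
    bg <- cbind(
      data.frame(chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
                 rsid = sprintf("sim%06d", seq_len(n)), gene = gene,
                 consequence = consequence, aa_change = NA_character_,
                 maf_1000g = maf, maf_esp = maf, q2_esp = maf^2,
                 stringsAsFactors = FALSE),
      draw_scores(n, cfg$p_background_damaging)
    )
    bg$maf_sim <- maf; bg$spiked <- FALSE; bg$scenario <- NA_character_
  } else bg <- NULL

  spikes <- list()
  for (i in seq_along(cfg$spike_ins)) {
    sp <- cfg$spike_ins[[i]]
    k <- if (sp$scenario == "compound_het") 2L else 1L
    gene <- sp$gene %||% sprintf("SPIKE_%s_%d", toupper(sp$scenario), i)
    chrom <- if (sp$scenario == "x_linked") "X" else as.character(sample.int(22L, 1L))
    pos <- 2^26 + i * 10L + seq_len(k) # disjoint from background positions
    ref <- sample(BASES, k, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), "")
    ann <- switch(sp$scenario,
      hom_recessive = list(maf1 = 0.14, maf2 = 0.14, q2 = 0.025, maf_sim = 0.14),
      de_novo = list(maf1 = NA_real_, maf2 = NA_real_, q2 = NA_real_, maf_sim = 0),
      list(maf1 = 1e-4, maf2 = 1e-4, q2 = 1e-8, maf_sim = 1e-4)
    )
    spikes[[i]] <- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
      rsid = if (sp$scenario == "de_novo") NA_character_ else
        sprintf("spike%03d_%d", i, seq_len(k)),
      gene = gene, consequence = "missense", aa_change = NA_character_,
      maf_1000g = ann$maf1, maf_esp = ann$maf2, q2_esp = ann$q2,
      sift = 0, polyphen2 = 1, fathmm = -3, siphy = 15,
      maf_sim = ann$maf_sim, spiked = TRUE, scenario = sp$scenario,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, c(list(bg), spikes))
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), rsid = character(), gene = character(),
                      consequence = character(), aa_change = character(),
                      maf_1000g = numeric(), maf_esp = numeric(),
                      q2_esp = numeric(), sift = numeric(), polyphen2 = numeric(),
                      fathmm = numeric(), siphy = numeric(), maf_sim = numeric(),
                      spiked = logical(), scenario = character())
  out$site_id <- paste(out$chrom, out$pos, out$ref, out$alt, sep = ":")
  rownames(out) <- NULL
  out
}

# one gamete per individual per site given dose (fair transmission)
.draw_gamete <- function(dose) {
  (dose == 2L) + (dose == 1L) * stats::rbinom(length(dose), 1L, 0.5)
}

#' Simulate genotypes for a nuclear family
#'
#' Parental genotypes are drawn Hardy-Weinberg from each site's generative
#' MAF; children receive one fair Mendelian gamete per parent (male children
#' receive only the maternal gamete on the X and are hemizygous there).
#' Sibling genotypes are independent given the parents (no linkage). Each
#' call is then perturbed by the per-call flip error, read depths are Poisson
#' around the configured means and alternate-read counts binomial given the
#' (observed) genotype. Spike-ins overwrite their designated sites with the
#' scenario's genotype pattern and are recorded in the returned truth set.
#'
#' @param cfg a [sim_config()].
#' @param sites output of [simulate_sites()] (or any site table with
#'   `maf_sim`, `spiked`, `scenario` columns).
#' @param ped a nuclear-family [pedigree]; defaults to the canonical quad.
#' @return List with elements `fam` (a [family_genotypes]) and `truth`
#'   (data frame of spiked gene / scenario / site ids).
#' @export
simulate_family <- function(cfg, sites, ped = quad_pedigree()) {
  set.seed(cfg$seed + 1L)
  par <- sib_parents(ped)
  if (any(par$sib_sex == "unknown")) stop("sib sex must be known for simulation")
  n <- nrow(sites)
  x <- is_x_chrom(sites$chrom)
  maf <- sites$maf_sim
  dose <- list()
  dose[[par$father]] <- ifelse(x, stats::rbinom(n, 1L, maf), stats::rbinom(n, 2L, maf))
  dose[[par$mother]] <- stats::rbinom(n, 2L, maf)
  for (sib in par$sibs) {
    gp <- .draw_gamete(ifelse(x, 2L * dose[[par$father]], dose[[par$father]]))
    gm <- .draw_gamete(dose[[par$mother]])
    d <- gp + gm
    if (par$sib_sex[sib] == "male") d[x] <- gm[x]
    dose[[sib]] <- d
  }

  # spike-in overwrites (before error so spikes are exact when error = 0;
  # the error model still applies to spiked calls)
  truth <- list()
  for (sc in unique(stats::na.omit(sites$scenario))) {
    for (g in unique(sites$gene[sites$spiked & sites$scenario == sc])) {
      rows <- which(sites$spiked & sites$gene == g)
      if (sc == "x_linked" && !any(par$sib_sex == "male"))
        stop("x_linked spike-in infeasible: no male sib in pedigree")
      for (j in seq_along(rows)) {
        r <- rows[j]
        if (sc == "hom_recessive") {
          for (sib in par$sibs) dose[[sib]][r] <- 2L
          dose[[par$father]][r] <- 1L; dose[[par$mother]][r] <- 1L
        } else if (sc == "compound_het") {
          for (sib in par$sibs) dose[[sib]][r] <- 1L
          dose[[par$father]][r] <- if (j %% 2L == 1L) 1L else 0L
          dose[[par$mother]][r] <- if (j %% 2L == 1L) 0L else 1L
        } else if (sc == "de_novo") {
          for (sib in par$sibs) dose[[sib]][r] <- 1L
          dose[[par$father]][r] <- 0L; dose[[par$mother]][r] <- 0L
        } else if (sc == "x_linked") {
          for (sib in par$sibs)
            dose[[sib]][r] <- if (par$sib_sex[sib] == "male") 1L else 2L
          dose[[par$father]][r] <- 0L; dose[[par$mother]][r] <- 1L
        }
      }
      truth[[paste(g, sc)]] <- data.frame(
        gene = g, scenario = sc, sites = I(list(sites$site_id[rows])),
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene = character(), scenario = character(), sites = I(list()))
  rownames(truth) <- NULL

  eps <- cfg$genotyping_error
  samples <- c(par$sibs, par$father, par$mother)
  calls <- list()
  for (s in samples) {
    d <- dose[[s]]
    hemi <- x & ped$sex[ped$sample_id == s] == "male"
    ploidy <- ifelse(hemi, 1L, 2L)
    if (eps > 0) {
      flip <- stats::runif(n) < eps
      shift <- 1L + stats::rbinom(n, 1L, 0.5)
      d <- ifelse(flip, ifelse(hemi, 1L - d, (d + shift) %% 3L), d)
    }
    is_parent <- s %in% c(par$father, par$mother)
    mu <- if (is_parent) cfg$depth_parents else cfg$depth_sibs
    depth <- stats::rpois(n, mu)
    if (is_parent && any(sites$spiked & sites$scenario == "de_novo")) {
      dn <- which(sites$spiked & sites$scenario == "de_novo")
      depth[dn] <- pmax(depth[dn], cfg$min_parent_depth)
    }
    alt_depth <- stats::rbinom(n, depth, d / ploidy)
    if (is_parent) {
      dn <- which(!is.na(sites$scenario) & sites$scenario == "de_novo")
      alt_depth[dn] <- 0L
    }
    miss <- cfg$p_missing > 0 & stats::runif(n) < cfg$p_missing
    calls[[s]] <- data.frame(
      site_id = sites$site_id, sample_id = s,
      a1 = ifelse(miss, NA_integer_, ifelse(hemi, d, as.integer(d >= 1L))),
      a2 = ifelse(miss | hemi, NA_integer_, as.integer(d == 2L)),
      hemi = hemi, missing = miss, depth = depth, alt_depth = alt_depth,
      stringsAsFactors = FALSE
    )
  }
  fam <- family_genotypes(
    sites[, c("chrom", "pos", "ref", "alt", "rsid", "site_id")],
    do.call(rbind, calls), samples
  )
  list(fam = fam, truth = truth)
}

#' Write a simulated dataset as loader-ready fixture files
#'
#' Emits `quad.vcf`, `quad.ped`, `annotations.tsv` and `truth.json` into a
#' directory; output is byte-stable for a given configuration seed.
#'
#' @param fam a [family_genotypes].
#' @param sites annotated site table (from [simulate_sites()]).
#' @param ped a [pedigree].
#' @param out_dir output directory (created if needed).
#' @param truth optional truth data frame (from [simulate_family()]).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture <- function(fam, sites, ped, out_dir, truth = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(out_dir, "quad.vcf"),
             ped = file.path(out_dir, "quad.ped"),
             annotations = file.path(out_dir, "annotations.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_vcf(fam, paths["vcf"])
  write_ped(ped, paths["ped"])
  tab <- sites[, intersect(ANNOTATION_COLS, names(sites))]
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(x)
    ifelse(is.na(x), "-", format(x, digits = 12, trim = TRUE, scientific = FALSE)))
  tab[!num] <- lapply(tab[!num], function(x) ifelse(is.na(x), "-", as.character(x)))
  utils::write.table(tab, paths["annotations"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(
      lapply(seq_len(nrow(truth)), function(i)
        list(gene = truth$gene[i], scenario = truth$scenario[i],
             sites = truth$sites[[i]])),
      paths["truth"], auto_unbox = TRUE, pretty = TRUE)
  } else jsonlite::write_json(list(), paths["truth"])
  invisible(paths)
}
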