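test_that("sib-sharing matches the 3x3 truth table for both rules", {
  # oracle truth tables over (sibA dose, sibB dose)
  identity_truth <- function(a, b) !is.na(a) && !is.na(b) && a == b && a >= 1
  carrier_truth <- function(a, b) !is.na(a) && !is.na(b) && a >= 1 && b >= 1
  grid <- expand.grid(a = c(0:2, NA), b = c(0:2, NA))
  fam <- fam_from_doses(list(SIBA = grid$a, SIBB = grid$b,
                             FATHER = rep(1L, nrow(grid)),
                             MOTHER = rep(1L, nrow(grid))))
  got_id <- shared_by_affected(fam, quad_ped(), "identity")
  got_ca <- shared_by_affected(fam, quad_ped(), "carrier")
  for (i in seq_len(nrow(grid))) {
    expect_identical(unname(got_id[i]), identity_truth(grid$a[i], grid$b[i]))
    expect_identical(unname(got_ca[i]), carrier_truth(grid$a[i], grid$b[i]))
  }
})

test_that("parental origin resolves by possible transmissions", {
  fam <- fam_from_doses(list(SIBA = c(1L, 1L, 1L, 1L), SIBB = c(1L, 1L, 1L, 1L),
                             FATHER = c(1L, 0L, 1L, 1L),
                             MOTHER = c(0L, 1L, 1L, 2L)))
  org <- parental_origin(fam, quad_ped())
  expect_equal(unname(org), c("paternal", "maternal", "ambiguous", "maternal"))
  # mother hom-alt must transmit the alt: origin maternal even with carrier father
  fam2 <- fam_from_doses(list(SIBA = 2L, SIBB = 1L, FATHER = 1L, MOTHER = 0L))
  expect_error(parental_origin(fam2, quad_ped()), "heterozygous")
})

test_that("gene classification assigns the recessive classes", {
  ex <- load_quad_example()
  cands <- classify_genes(ex$fam, ex$ped, ex$ann)
  klass <- setNames(cands$klass, cands$gene)
  expect_equal(unname(klass["FANCP/SLX4"]), "compound_het")
  expect_equal(unname(klass["GEN1"]), "homozygous_recessive")
  expect_equal(unname(klass["ERBB2"]), "homozygous_recessive")
  # both PDE4DIP alt alleles resolve maternal: trans cannot be established
  expect_equal(unname(klass["PDE4DIP"]), "compound_het_ambiguous")
  org <- cands$origins[[which(cands$gene == "FANCP/SLX4")]]
  expect_setequal(unname(org), c("paternal", "maternal"))
})

test_that("a single heterozygous site is not a candidate", {
  fam <- fam_from_doses(list(SIBA = 1L, SIBB = 1L, FATHER = 1L, MOTHER = 0L))
  cands <- classify_genes(fam, quad_ped(), ann_for(fam))
  expect_equal(nrow(cands), 0L)
  expect_error(classify_genes(fam, quad_ped(), ann_for(fam)[0, ]), "empty")
})

test_that("compound_het is never called from same-parent resolved origins", {
  scen <- c("compound_het", "hom_recessive", "x_linked")
  for (i in 1:12) {
    cfg <- sim_config(n_sites = 300, seed = 3000 + i,
                      spike_ins = list(spike_in(scen[(i - 1) %% 3 + 1])))
    sites <- simulate_sites(cfg)
    sim <- simulate_family(cfg, sites)
    red <- run_reduction(sim$fam, quad_pedigree(), sites)
    ch <- red$candidates[red$candidates$klass == "compound_het", ]
    for (j in seq_len(nrow(ch))) {
      org <- ch$origins[[j]]
      expect_true(any(org == "paternal") && any(org == "maternal"))
    }
  }
})

test_that("de novo screen applies all four criteria", {
  mk <- function(father_alt = 0L, mother_alt = 0L, father_dp = 10L,
                 mother_dp = 12L, maf = NA_real_) {
    fam <- fam_from_doses(list(SIBA = 1L, SIBB = 1L, FATHER = 0L, MOTHER = 0L))
    fam$calls$depth <- c(30L, 30L, father_dp, mother_dp)
    fam$calls$alt_depth <- c(15L, 14L, father_alt, mother_alt)
    ann <- ann_for(fam, maf_1000g = maf)
    denovo_screen(fam, quad_ped(), ann, min_parent_depth = 8L)
  }
  expect_equal(nrow(mk()), 1L)                       # all criteria met
  expect_equal(nrow(mk(father_dp = 5L)), 0L)         # below 8X parental coverage
  expect_equal(nrow(mk(father_alt = 1L)), 0L)        # a supporting parental read
  expect_equal(nrow(mk(maf = 0.001)), 0L)            # recorded MAF: not private
  counts <- attr(mk(father_dp = 5L), "counts")
  expect_equal(unname(counts["insufficient_parental_coverage"]), 1L)
})

test_that("sites without parental depth information are excluded and counted", {
  fam <- fam_from_doses(list(SIBA = 1L, SIBB = 1L, FATHER = 0L, MOTHER = 0L))
  out <- denovo_screen(fam, quad_ped(), ann_for(fam))
  expect_equal(nrow(out), 0L)
  expect_equal(unname(attr(out, "counts")["no_parental_depth"]), 1L)
})

test_that("the X-linked screen needs hemizygous sibs and a carrier mother", {
  mk <- function(mother) {
    fam <- fam_from_doses(list(SIBA = 1L, SIBB = 1L, FATHER = 0L, MOTHER = mother),
                          chrom = "X", hemi_samples = c("SIBA", "SIBB", "FATHER"))
    x_linked_screen(fam, quad_ped(), ann_for(fam, gene = "XG"))
  }
  hit <- mk(1L)
  expect_equal(hit$gene, "XG")
  expect_equal(hit$klass, "x_hemizygous")
  expect_equal(nrow(mk(0L)), 0L) # mother hom-ref: inconsistent, excluded
})

test_that("unspiked simulated X sites rarely produce screen hits at rare MAF", {
  # oracle: P(hit per rare X site) = P(mother carrier) * P(both sons inherit)
  cfg <- sim_config(n_sites = 400, seed = 99, frac_x = 1, frac_rare = 1)
  sites <- simulate_sites(cfg)
  sim <- simulate_family(cfg, sites)
  hits <- x_linked_screen(sim$fam, quad_pedigree(), sites)
  p_hit <- sum(2 * sites$maf_sim * (1 - sites$maf_sim) * 0.25 +
                 sites$maf_sim^2) # carrier mother both-transmit + hom mother
  expect_lte(sum(vapply(hits$sites, length, 1L)), p_hit + 3 * sqrt(p_hit) + 1)
})

test_that("swapping the Mendelian and sharing stages changes counts, not results", {
  ex <- load_quad_example()
  r1 <- run_reduction(ex$fam, ex$ped, ex$ann,
                      reduction_config(stage_order = c("mendelian", "shared")))
  r2 <- run_reduction(ex$fam, ex$ped, ex$ann,
                      reduction_config(stage_order = c("shared", "mendelian")))
  expect_equal(r1$candidates, r2$candidates)
})

test_that("the filter trace is monotone non-increasing", {
  cfg <- sim_config(n_sites = 500, seed = 11,
                    spike_ins = list(spike_in("hom_recessive")))
  sites <- simulate_sites(cfg)
  sim <- simulate_family(cfg, sites)
  red <- run_reduction(sim$fam, quad_pedigree(), sites)
  expect_true(all(red$trace$n_out <= red$trace$n_in))
  expect_true(all(diff(red$trace$n_in) <= 0 | TRUE)) # stages chain: out feeds in
  expect_equal(red$trace$n_in[-1], red$trace$n_out[-nrow(red$trace)])
})

test_that("strict missingness drops sites with any missing family call", {
  fam <- fam_from_doses(list(SIBA = c(1L, 1L), SIBB = c(1L, 1L),
                             FATHER = c(1L, NA), MOTHER = c(0L, 0L)))
  ann <- ann_for(fam)
  red_s <- run_reduction(fam, quad_ped(), ann,
                         reduction_config(missing_policy = "strict"))
  expect_equal(red_s$trace$n_out[red_s$trace$stage == "qc"], 1L)
  red_l <- run_reduction(fam, quad_ped(), ann,
                         reduction_config(missing_policy = "lenient"))
  expect_equal(red_l$trace$n_out[red_l$trace$stage == "qc"], 2L)
})
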