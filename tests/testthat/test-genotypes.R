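test_that("the shipped candidate VCF loads with the published genotypes", {
  ex <- load_quad_example()
  expect_equal(nrow(ex$fam$sites), 17L)
  dm <- quadscreen:::dose_matrix(ex$fam)
  # 16:3656625 G>A: sibs het, father het, mother hom-ref
  expect_equal(unname(dm["16:3656625:G:A", ]),
               c(SIBA = 1L, SIBB = 1L, FATHER = 1L, MOTHER = 0L),
               ignore_attr = TRUE)
  expect_equal(ex$fam$sites$rsid[ex$fam$sites$site_id == "16:3656625:G:A"],
               "rs79842542")
})

test_that("missing and malformed genotypes become missing-flagged calls", {
  path <- mini_vcf(c(
    vcf_row(1, 100, ".", "G", "A", "GT", "0/1", "0/1", "0/1", "./."),
    vcf_row(1, 200, ".", "G", "A", "GT", "0/1", "0/1", "q/x", "0/0")
  ))
  ped <- quad_ped()
  expect_warning(fam <- load_variants(path, ped), "malformed")
  calls <- fam$calls
  expect_true(calls$missing[calls$site_id == "1:100:G:A" & calls$sample_id == "MOTHER"])
  expect_true(calls$missing[calls$site_id == "1:200:G:A" & calls$sample_id == "FATHER"])
  expect_false(calls$missing[calls$site_id == "1:200:G:A" & calls$sample_id == "SIBA"])
})

test_that("pedigree samples absent from the VCF header are a hard error", {
  path <- mini_vcf(vcf_row(1, 100, ".", "G", "A", "GT", "0/1", "0/1", "0/1"),
                   samples = c("SIBA", "SIBB", "FATHER"))
  expect_error(load_variants(path, quad_ped()), "MOTHER")
})

test_that("multiallelic records split into biallelic sites per the remap oracle", {
  # oracle: at the site for alt j, allele j maps to 1, everything else to 0
  gts <- c("0/0", "0/1", "0/2", "1/1", "1/2", "2/2")
  oracle_dose <- function(gt, j) sum(as.integer(strsplit(gt, "/")[[1]]) == j)
  ped <- pedigree(paste0("S", 1:6), sex = "male", affected = "affected")
  ped$father_id <- NA; ped$mother_id <- NA
  path <- mini_vcf(vcf_row(1, 500, ".", "A", "G,T", "GT", gts[1], gts[2],
                           gts[3], gts[4], gts[5], gts[6]),
                   samples = paste0("S", 1:6))
  fam <- load_variants(path, ped)
  expect_equal(nrow(fam$sites), 2L)
  dm <- quadscreen:::dose_matrix(fam)
  for (s in 1:6) {
    expect_equal(dm["1:500:A:G", paste0("S", s)], oracle_dose(gts[s], 1L),
                 ignore_attr = TRUE)
    expect_equal(dm["1:500:A:T", paste0("S", s)], oracle_dose(gts[s], 2L),
                 ignore_attr = TRUE)
  }
  # allele counts conserved: summed alt dose over split sites = non-ref dose
  nonref <- vapply(gts, function(g) sum(strsplit(g, "/")[[1]] != "0"), 0L)
  expect_equal(unname(colSums(dm)), unname(nonref))
})

test_that("male X diploid-homozygous encodings normalize to hemizygous", {
  path <- mini_vcf(c(
    vcf_row("X", 100, ".", "G", "A", "GT", "1/1", "1", "0/0", "0/1"),
    vcf_row("X", 200, ".", "G", "A", "GT", "0/1", "0/0", "0", "0/1")
  ))
  expect_warning(fam <- load_variants(path, quad_ped()), "heterozygous male X")
  calls <- fam$calls
  siba <- calls[calls$site_id == "X:100:G:A" & calls$sample_id == "SIBA", ]
  expect_true(siba$hemi); expect_equal(siba$a1, 1L)
  # heterozygous male X is unusable -> missing
  expect_true(calls$missing[calls$site_id == "X:200:G:A" & calls$sample_id == "SIBA"])
  # mother stays diploid
  mo <- calls[calls$site_id == "X:100:G:A" & calls$sample_id == "MOTHER", ]
  expect_false(mo$hemi); expect_equal(mo$a1 + mo$a2, 1L)
})

test_that("genotype matrices round-trip through write_vcf", {
  cfg <- sim_config(n_sites = 150, seed = 42, frac_x = 0.1,
                    spike_ins = list(spike_in("de_novo")))
  sites <- simulate_sites(cfg)
  sim <- simulate_family(cfg, sites)
  path <- tempfile(fileext = ".vcf")
  write_vcf(sim$fam, path)
  fam2 <- load_variants(path, quad_pedigree())
  expect_equal(quadscreen:::dose_matrix(fam2), quadscreen:::dose_matrix(sim$fam))
  o <- order(sim$fam$calls$site_id, sim$fam$calls$sample_id)
  o2 <- order(fam2$calls$site_id, fam2$calls$sample_id)
  expect_equal(fam2$calls[o2, c("depth", "alt_depth", "hemi", "missing")],
               sim$fam$calls[o, c("depth", "alt_depth", "hemi", "missing")],
               ignore_attr = TRUE)
})

test_that("depth fields honour AD/DP and alt_depth <= depth is enforced", {
  path <- mini_vcf(
    vcf_row(1, 100, ".", "G", "A", "GT:AD:DP",
            "0/1:5,6:11", "0/1:4,4:8", "0/0:10,0:10", "0/0:.:12"),
    format_defs = c(
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">"))
  fam <- load_variants(path, quad_ped())
  calls <- fam$calls
  expect_equal(calls$alt_depth[calls$sample_id == "SIBA"], 6L)
  expect_equal(calls$depth[calls$sample_id == "SIBA"], 11L)
  expect_true(is.na(calls$alt_depth[calls$sample_id == "MOTHER"]))
  expect_equal(calls$depth[calls$sample_id == "MOTHER"], 12L)
  bad <- data.frame(site_id = "1:1:A:G", sample_id = "S", a1 = 0L, a2 = 1L,
                    hemi = FALSE, missing = FALSE, depth = 3L, alt_depth = 5L)
  sites <- data.frame(chrom = "1", pos = 1L, ref = "A", alt = "G")
  expect_error(family_genotypes(sites, bad, "S"), "alt_depth")
})

test_that("an empty VCF yields an empty container", {
  path <- mini_vcf(character(0))
  fam <- load_variants(path, quad_ped())
  expect_equal(nrow(fam$sites), 0L)
  expect_equal(nrow(fam$calls), 0L)
})
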