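test_that("the generator is deterministic given a seed", {
  cfg <- sim_config(n_sites = 200, seed = 5, spike_ins = list(spike_in("compound_het")))
  s1 <- simulate_sites(cfg); s2 <- simulate_sites(cfg)
  expect_identical(s1, s2)
  f1 <- simulate_family(cfg, s1); f2 <- simulate_family(cfg, s2)
  expect_identical(f1, f2)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  write_fixture(f1$fam, s1, quad_pedigree(), d1, f1$truth)
  write_fixture(f2$fam, s2, quad_pedigree(), d2, f2$truth)
  for (f in c("quad.vcf", "quad.ped", "annotations.tsv", "truth.json"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("site frequencies follow the configured rare/common mixture", {
  cfg <- sim_config(n_sites = 2000, seed = 8, frac_rare = 0.3)
  sites <- simulate_sites(cfg)
  frac <- mean(sites$maf_sim <= 1e-3)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
  expect_true(all(sites$maf_sim[sites$maf_sim <= 1e-3] >= 1e-5))
  expect_equal(nrow(simulate_sites(sim_config(n_sites = 0, seed = 1))), 0L)
})

test_that("error-free transmission yields zero Mendelian inconsistencies", {
  cfg <- sim_config(n_sites = 800, seed = 13, genotyping_error = 0, frac_x = 0)
  sites <- simulate_sites(cfg)
  sim <- simulate_family(cfg, sites)
  flags <- quadscreen:::mendelian_flags(sim$fam, quad_pedigree())
  expect_true(all(flags))
})

test_that("spike-ins write their scenario's genotype pattern", {
  cfg <- sim_config(n_sites = 50, seed = 3,
                    spike_ins = list(spike_in("hom_recessive"),
                                     spike_in("compound_het"),
                                     spike_in("x_linked"),
                                     spike_in("de_novo")))
  sites <- simulate_sites(cfg)
  sim <- simulate_family(cfg, sites)
  dm <- quadscreen:::dose_matrix(sim$fam)
  hr <- sim$truth$sites[[which(sim$truth$scenario == "hom_recessive")]]
  expect_equal(unname(dm[hr, ]), c(2L, 2L, 1L, 1L)) # sibs hom-alt, parents het
  ch <- sim$truth$sites[[which(sim$truth$scenario == "compound_het")]]
  expect_equal(unname(dm[ch, c("SIBA", "SIBB")]), matrix(1L, 2, 2))
  expect_equal(unname(dm[ch, "FATHER"] + dm[ch, "MOTHER"]), c(1L, 1L))
  expect_equal(unname(dm[ch[1], "FATHER"]), 1L)
  expect_equal(unname(dm[ch[2], "MOTHER"]), 1L)
  xl <- sim$truth$sites[[which(sim$truth$scenario == "x_linked")]]
  expect_equal(unname(dm[xl, ]), c(1L, 1L, 0L, 1L))
  dn <- sim$truth$sites[[which(sim$truth$scenario == "de_novo")]]
  pc <- sim$fam$calls[sim$fam$calls$site_id == dn &
                        sim$fam$calls$sample_id %in% c("FATHER", "MOTHER"), ]
  expect_equal(pc$alt_depth, c(0L, 0L))
  expect_true(all(pc$depth >= 8L))
})

test_that("an x_linked spike is infeasible without a male sib", {
  ped <- pedigree(c("S1", "F", "M"), father_id = c("F", NA, NA),
                  mother_id = c("M", NA, NA), sex = c("female", "male", "female"),
                  affected = c("affected", "unaffected", "unaffected"))
  cfg <- sim_config(n_sites = 10, seed = 4, spike_ins = list(spike_in("x_linked")))
  sites <- simulate_sites(cfg)
  expect_error(simulate_family(cfg, sites, ped), "infeasible")
})

test_that("sib sharing of alt alleles matches the exact transmission oracle", {
  # oracle: P(child carries alt | parental doses) squared, weighted by HWE
  cfg <- sim_config(n_sites = 3000, seed = 17, frac_x = 0, frac_rare = 0.2)
  sites <- simulate_sites(cfg)
  sim <- simulate_family(cfg, sites)
  dm <- quadscreen:::dose_matrix(sim$fam)
  obs <- sum(dm[, "SIBA"] >= 1L & dm[, "SIBB"] >= 1L)
  q <- sites$maf_sim
  g0 <- function(d) c(1, 0.5, 0)[d + 1] # P(transmit ref | dose)
  p_site <- vapply(q, function(qq) {
    hw <- c((1 - qq)^2, 2 * qq * (1 - qq), qq^2)
    p <- 0
    for (f in 0:2) for (m in 0:2) {
      p_carry <- 1 - g0(f) * g0(m)
      p <- p + hw[f + 1] * hw[m + 1] * p_carry^2
    }
    p
  }, 0)
  expect_lt(abs(obs - sum(p_site)), 3 * sqrt(sum(p_site * (1 - p_site))))
})

test_that("fixture files round-trip through the loaders with coherent truth", {
  cfg <- sim_config(n_sites = 100, seed = 6,
                    spike_ins = list(spike_in("hom_recessive")))
  sites <- simulate_sites(cfg)
  sim <- simulate_family(cfg, sites)
  out <- file.path(tempdir(), "fixdir")
  paths <- write_fixture(sim$fam, sites, quad_pedigree(), out, sim$truth)
  ped <- load_pedigree(paths[["ped"]])
  fam <- load_variants(paths[["vcf"]], ped)
  expect_equal(quadscreen:::dose_matrix(fam), quadscreen:::dose_matrix(sim$fam))
  ann <- merge_annotations(fam, paths[["annotations"]])
  expect_equal(sum(is.na(ann$gene)), 0L)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_true(all(truth$gene %in% ann$gene))
})
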