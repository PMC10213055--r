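# CSR and attraction field generators, cohort simulation, fixture bundle

test_that("CSR fields have Poisson counts at the configured intensity", {
  withr::local_seed(311)
  cfg <- fieldSimConfig(intensities = c(CD8 = 1e-3))
  counts <- replicate(1000, nCells(simulateCSRField(cfg)))
  mu <- 1e-3 * 669 * 500  # 334.5
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - mu), 3 * se)
  # same seed, same field; zero intensity, empty field
  f1 <- simulateCSRField(cfg, seed = 5)
  f2 <- simulateCSRField(cfg, seed = 5)
  expect_identical(cells(f1), cells(f2))
  expect_warning(
    f0 <- simulateCSRField(fieldSimConfig(intensities = c(CD8 = 0))),
    "zero")
  expect_equal(nCells(f0), 0)
})

test_that("generated fields validate and carry class-consistent markers", {
  withr::local_seed(313)
  cfg <- fieldSimConfig(intensities = c(CD8_CD127 = 2e-4, CD4_FoxP3 = 1e-4,
                                        B_cell = 1e-4, other = 5e-4))
  f <- simulateCSRField(cfg)
  expect_true(methods::validObject(f))
  df <- cells(assignPhenotypes(f))
  expect_true(all(df$CD8[df$CD127 & !df$CD4]))   # CD127 simulated on CD8 here
  expect_true(all(df$CD4[df$FoxP3]))
  expect_equal(sum(df$phenotype == "CD8_T"), sum(df$CD8))
  expect_false(any(df$ambiguous))
})

test_that("attraction concentrates offspring near parents at sigma = 10", {
  withr::local_seed(317)
  kap <- 2e-4; mu <- 2
  cfg <- fieldSimConfig(intensities = NULL, attraction = list(
    parent_phenotypes = "CD4", parent_intensity = kap,
    offspring_phenotype = "CD8", mean_offspring = mu,
    dispersion = 10, background_fraction = 0))
  prox <- replicate(200, {
    f <- assignPhenotypes(simulateAttractionField(cfg))
    if (!any(phenotypeMask(f, "CD4_T"))) return(NA_real_)
    proximityDensity(f, "CD4_T", "CD8_T", r = 30)
  })
  csr <- kap * mu * pi * 30^2  # expected count under CSR at the same intensity
  expect_gte(mean(prox, na.rm = TRUE), 1.5 * csr)
})

test_that("attraction degenerates to CSR at huge sigma and at rho = 1", {
  withr::local_seed(331)
  kBar <- function(cfg, n) {
    ks <- replicate(n, {
      f <- assignPhenotypes(simulateAttractionField(cfg))
      if (sum(phenotypeMask(f, "CD4_T")) < 1 ||
          sum(phenotypeMask(f, "CD8_T")) < 1) return(NA_real_)
      unname(kValues(bivariateK(f, "CD4_T", "CD8_T", radii = 30)))
    })
    ks[!is.na(ks)]
  }
  base <- list(parent_phenotypes = "CD4", parent_intensity = 3e-4,
               offspring_phenotype = "CD8", mean_offspring = 1.5,
               dispersion = 700, background_fraction = 0)
  ks <- kBar(fieldSimConfig(intensities = NULL, attraction = base,
                            boundary = "toroidal"), 300)
  expect_lt(abs(mean(ks) - pi * 900), 3 * sd(ks) / sqrt(length(ks)))

  base$dispersion <- 15; base$background_fraction <- 1
  ks1 <- kBar(fieldSimConfig(intensities = NULL, attraction = base), 300)
  expect_lt(abs(mean(ks1) - pi * 900), 3 * sd(ks1) / sqrt(length(ks1)))
})

test_that("attraction preserves the configured marginal intensities", {
  withr::local_seed(337)
  kap <- 2.5e-4; mu <- 1.8; rho <- 0.4
  cfg <- fieldSimConfig(intensities = c(other = 3e-4), attraction = list(
    parent_phenotypes = "B_cell", parent_intensity = kap,
    offspring_phenotype = "CD8_KLRG1", mean_offspring = mu,
    dispersion = 15, background_fraction = rho))
  area <- 669 * 500
  offCounts <- replicate(300, {
    f <- assignPhenotypes(simulateAttractionField(cfg))
    sum(phenotypeMask(f, "CD8_T+KLRG1"))
  })
  expect_lt(abs(mean(offCounts) - kap * mu * area),
            3 * sd(offCounts) / sqrt(length(offCounts)))
  expect_error(
    fieldSimConfig(intensities = c(CD8 = 1e-4), attraction = list(
      parent_phenotypes = "CD4", parent_intensity = 1e-4,
      offspring_phenotype = "CD8", mean_offspring = 1,
      dispersion = 0, background_fraction = 0)),
    class = "til_contract_error")
})

test_that("cohort MPR rates are calibrated to the configured marginals", {
  withr::local_seed(401)
  cfg <- cohortSimConfig()
  rates <- replicate(500, {
    sim <- simulateCohort(cfg, fields = FALSE)
    tr <- sim$truth
    c(napc = mean(tr$mpr[tr$arm == "NAPC"]),
      nac = mean(tr$mpr[tr$arm == "NAC"]),
      pcr = mean(tr$pcr[tr$arm == "NAPC"]))
  })
  for (row in rownames(rates)) {
    target <- c(napc = 23 / 35, nac = 0.20, pcr = 16 / 35)[[row]]
    se <- sd(rates[row, ]) / sqrt(ncol(rates))
    expect_lt(abs(mean(rates[row, ]) - target), 3 * se)
  }
  # viable percentages are consistent witnesses of the label
  sim <- simulateCohort(cfg, seed = 7, fields = FALSE)
  calls <- responseTable(sim$clinical)
  expect_identical(calls$category %in% c("MPR", "pCR"), sim$truth$mpr)
  expect_identical(calls$category == "pCR", sim$truth$pcr)
})

test_that("pipeline on latent densities recovers the configured HR", {
  withr::local_seed(409)
  cfg <- cohortSimConfig(n_per_arm = c(NAC = 200, NAPC = 200))
  hits <- replicate(100, {
    sim <- simulateCohort(cfg, fields = FALSE)
    grp <- medianSplit(sim$truth$cd8_density_post)
    hr <- logrankTest(sim$clinical$dfs_time, sim$clinical$dfs_event,
                      factor(grp, levels = c("high", "low")))$hazard_ratio
    hr >= 0.2 && hr <= 0.45
  })
  expect_gte(mean(hits), 0.9)
})

test_that("null cohorts give ~5% pre/post Wilcoxon rejections", {
  withr::local_seed(419)
  nullCfg <- cohortSimConfig(
    fold_change = list(
      NAC = cohortSimConfig()$fold_change$NAC * 0 + 1,
      NAPC = cohortSimConfig()$fold_change$NAC * 0 + 1),
    attraction = NULL)
  rej <- replicate(300, {
    sim <- simulateCohort(nullCfg, fields = FALSE)
    tr <- sim$truth
    wilcoxonSignedRank(log(tr$cd8_density_pre),
                       log(tr$cd8_density_post))$p.value < 0.05
  })
  # 3 binomial SEs around 0.05 at 300 replicates
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("fixture bundle is byte-identical at a fixed seed and round-trips", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- makeFixtureBundle(d1, seed = 42)
  b2 <- makeFixtureBundle(d2, seed = 42)
  files <- list.files(d1, recursive = TRUE)
  expect_identical(files, list.files(d2, recursive = TRUE))
  for (fl in files)
    expect_identical(unname(tools::md5sum(file.path(d1, fl))),
                     unname(tools::md5sum(file.path(d2, fl))))

  # every generated file validates cleanly
  expect_length(validateInputs(file.path(d1, "cells"),
                               file.path(d1, "clinical.csv")), 0)

  # manifest ground truth matches an independent regeneration
  manifest <- jsonlite::read_json(file.path(d1, "truth.json"),
                                  simplifyVector = TRUE)
  regen <- simulateCohort(cohortSimConfig(n_per_arm = c(NAC = 4, NAPC = 4),
                                          fields_per_specimen = 3),
                          seed = 42, fields = TRUE)
  expect_equal(manifest$truth$cd8_density_post, regen$truth$cd8_density_post)
  expect_equal(manifest$truth$mpr, regen$truth$mpr)

  # and the bundle reads back into consistent objects
  back <- readFixtureBundle(d1)
  expect_length(back$specimens, 16)
  expect_equal(sum(vapply(back$specimens,
                          function(s) length(fields(s)), integer(1))), 48)
  expect_equal(nrow(back$clinical), 8)
})
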