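# marker gating, density ratios, nesting and aggregation

.cellRequiredColsForTest <- function() c("cell_id", "x_um", "y_um", tilMarkers())

test_that("exclusive gating assigns lineages and flags conflicts", {
  f <- makeField(
    x = c(10, 20, 30, 40, 50), y = rep(10, 5),
    markers = list(CD8 = c(1, 2), CD127 = 1, CD4 = c(3, 5), FoxP3 = 3,
                   CD20 = 4))
  ph <- cells(f)$phenotype
  expect_equal(ph, c("CD8_T", "CD8_T", "CD4_T", "B_cell", "CD4_T"))
  expect_true(all(phenotypeMask(f, "CD8_T+CD127") ==
                  c(TRUE, FALSE, FALSE, FALSE, FALSE)))
  # CD4+FoxP3+ is the Treg subset
  expect_equal(which(phenotypeMask(f, "CD4_T+FoxP3")), 3L)

  # lineage conflicts go to "other" with a warning, never dropped
  df <- cells(f); df$phenotype <- NULL; df$ambiguous <- NULL
  df$CD4[1] <- TRUE  # CD4+CD8+ double positive
  expect_warning(
    f2 <- assignPhenotypes(TILField("f2", 100, 100, df)),
    "conflicting")
  expect_equal(cells(f2)$phenotype[1], "other")
  expect_true(cells(f2)$ambiguous[1])
  expect_equal(nCells(f2), 5)
})

test_that("illegal subset selectors are rejected", {
  f <- makeField(10, 10, list(CD8 = 1))
  expect_error(phenotypeMask(f, "CD8_T+FoxP3"), class = "til_contract_error")
  expect_error(phenotypeMask(f, "B_cell+CD127"), class = "til_contract_error")
  expect_error(fieldDensity(f, "NK_cell"), class = "til_contract_error")
})

test_that("densities are ratios to DAPI with subset nesting", {
  # 10 DAPI cells, 2 CD8 T of which 1 CD127+
  f <- makeField(seq(5, 95, by = 10), rep(50, 10),
                 markers = list(CD8 = c(1, 2), CD127 = 1))
  expect_equal(fieldDensity(f, "CD8_T"), 0.2)
  expect_equal(fieldDensity(f, "CD8_T+CD127"), 0.1)
  expect_equal(fieldDensity(f, "B_cell"), 0)
  expect_equal(fieldDensity(f, "DAPI"), 1)

  empty <- TILField("e", 10, 10, cells(f)[0, setdiff(names(cells(f)),
                                                     c("phenotype",
                                                       "ambiguous"))])
  expect_error(fieldDensity(assignPhenotypes(empty), "CD8_T"),
               class = "til_validation_error")
})

test_that("lineage counts partition DAPI and subsets nest, on random fields", {
  withr::local_seed(11)
  for (rep in 1:20) {
    cfg <- fieldSimConfig(intensities = runif(8, 0, 3e-4) |>
                            setNames(simClasses()))
    f <- assignPhenotypes(simulateCSRField(cfg))
    if (nCells(f) == 0) next
    lineages <- c("B_cell", "CD4_T", "CD8_T", "other")
    counts <- vapply(lineages, function(p) sum(phenotypeMask(f, p)),
                     numeric(1))
    expect_equal(sum(counts), nCells(f))
    for (p in c("CD4_T", "CD8_T"))
      for (s in if (p == "CD4_T") c("CD127", "FoxP3") else c("CD127", "KLRG1"))
        expect_lte(fieldDensity(f, paste0(p, "+", s)), fieldDensity(f, p))
    # permutation invariance
    shuf <- cells(f)[sample(nCells(f)), ]
    f2 <- assignPhenotypes(TILField("s", fieldWidth(f), fieldHeight(f),
                                    shuf[, .cellRequiredColsForTest()]))
    expect_equal(fieldDensity(f2, "CD8_T+KLRG1"),
                 fieldDensity(f, "CD8_T+KLRG1"))
  }
})

test_that("specimen aggregation matches an independent recomputation", {
  withr::local_seed(21)
  mk <- function(dens, n = 10) {
    # field with given CD8 ratio out of n cells
    makeField(runif(n, 0, 100), runif(n, 0, 100),
              list(CD8 = seq_len(round(dens * n))))
  }
  sp <- TILSpecimen("P1", "NAC", "pre", list(mk(0.1), mk(0.3)))
  tab <- specimenDensityTable(list(sp), phenotypes = "CD8_T")
  expect_equal(tab$density, 0.2)

  # single field: specimen ratio equals the field ratio
  sp1 <- TILSpecimen("P2", "NAC", "pre", list(mk(0.4)))
  expect_equal(specimenDensityTable(list(sp1), phenotypes = "CD8_T")$density,
               0.4)

  # randomized fields against brute-force mean and pooled recomputation
  for (rep in 1:10) {
    flds <- lapply(1:5, function(i)
      randomTwoTypeField(sample.int(30, 1), sample.int(30, 1)))
    sp <- TILSpecimen("P3", "NAPC", "post", flds)
    ratios <- vapply(flds, function(f)
      sum(cells(f)$phenotype == "CD8_T") / nCells(f), numeric(1))
    expect_equal(
      specimenDensityTable(list(sp), phenotypes = "CD8_T")$density,
      mean(ratios))
    pooled <- sum(vapply(flds, function(f)
      sum(cells(f)$phenotype == "CD8_T"), numeric(1))) /
      sum(vapply(flds, nCells, integer(1)))
    expect_equal(
      specimenDensityTable(list(sp), phenotypes = "CD8_T",
                           aggregate = "pooled")$density, pooled)
  }
})

test_that("density table joins response labels from a clinical table", {
  withr::local_seed(5)
  sim <- simulateCohort(cohortSimConfig(n_per_arm = c(NAC = 2, NAPC = 2),
                                        fields_per_specimen = 2))
  specimens <- lapply(sim$specimens, assignPhenotypes)
  tab <- specimenDensityTable(specimens, phenotypes = c("CD8_T", "B_cell"),
                              clinical = sim$clinical)
  expect_true(all(tab$response %in% c("pCR", "MPR", "non-MPR")))
  expect_equal(nrow(tab), length(specimens) * 2)
  expect_true(all(tab$density >= 0 & tab$density <= 1))
})
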