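# distances, neighbour counts, K estimator, proximity density, sweeps

test_that("Euclidean distance satisfies the formula and metric axioms", {
  expect_equal(euclideanDistance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclideanDistance(c(7, 7), c(7, 7)), 0)
  expect_equal(euclideanDistance(c(10, 10), c(90, 90)), sqrt(2) * 80)
  expect_equal(euclideanDistance(c(10, 10), c(90, 90)),
               euclideanDistance(c(90, 90), c(10, 10)))
  expect_error(euclideanDistance(c(Inf, 0), c(0, 0)),
               class = "til_contract_error")
})

test_that("within-radius counts are inclusive and self-excluding", {
  ref <- data.frame(x_um = 0, y_um = 0)
  tg <- data.frame(x_um = c(10, 0, 31), y_um = c(0, 29, 0))
  expect_equal(countWithinRadius(ref, tg, 30), 2L)
  expect_equal(countWithinRadius(ref, tg, 31), 3L)  # d <= r inclusive
  expect_error(countWithinRadius(ref, tg, 0), class = "til_contract_error")

  # the same physical cell in both sets is excluded by cell_id
  ref$cell_id <- "c1"
  tg2 <- data.frame(cell_id = c("c1", "c9"), x_um = c(0, 5), y_um = c(0, 0))
  expect_equal(countWithinRadius(ref, tg2, 30), 1L)
})

test_that("grid-accelerated counts equal exhaustive enumeration exactly", {
  withr::local_seed(31)
  for (rep in 1:30) {
    n1 <- sample.int(200, 1); n2 <- sample.int(200, 1)
    W <- runif(1, 50, 700); H <- runif(1, 50, 700)
    ref <- data.frame(x_um = runif(n1, 0, W), y_um = runif(n1, 0, H))
    tg <- data.frame(x_um = runif(n2, 0, W), y_um = runif(n2, 0, H))
    r <- runif(1, 5, 100)
    expect_identical(countWithinRadius(ref, tg, r, width = W, height = H),
                     as.integer(bruteCounts(ref, tg, r)))
    expect_identical(
      countWithinRadius(ref, tg, r, torus = TRUE, width = W, height = H),
      as.integer(bruteCounts(ref, tg, r, torus = TRUE, W = W, H = H)))
  }
})

test_that("proximity density averages neighbour counts; self pairs excluded", {
  # two reference cells with 2 and 4 neighbours -> mean 3
  f <- makeField(
    x = c(0, 100, 1, 2, 99, 98, 97, 96), y = rep(0, 8), width = 200,
    markers = list(CD4 = 1:2, CD8 = 3:8))
  expect_equal(proximityDensity(f, "CD4_T", "CD8_T", r = 10), 3)

  # a single CD8+CD127+ cell is both reference and target: count 0
  f1 <- makeField(50, 50, list(CD8 = 1, CD127 = 1))
  expect_equal(proximityDensity(f1, "CD8_T", "CD8_T+CD127"), 0)

  f2 <- makeField(50, 50, list(CD8 = 1))
  expect_error(proximityDensity(f2, "B_cell", "CD8_T"),
               class = "til_validation_error")
})

test_that("K estimator reproduces hand-enumerated examples", {
  # two pairs within r=15 on a 100x100 field, cross normalization, no
  # correction: K = 10000 / (2*2) * 2 = 5000
  f <- makeField(x = c(10, 90, 10, 90), y = c(10, 90, 20, 80),
                 markers = list(CD4 = 1:2, CD8 = 3:4))
  k <- bivariateK(f, "CD4_T", "CD8_T", radii = 15,
                  normalization = "cross", correction = "none")
  expect_equal(unname(kValues(k)), 5000)

  # same point set, n = 2 at distance 10, r = 10, area 100:
  # K = 100 / (2*1) * 2 = 100
  f2 <- makeField(x = c(0, 10), y = c(5, 5), width = 10, height = 10,
                  markers = list(CD8 = 1:2))
  k2 <- bivariateK(f2, "CD8_T", "CD8_T", radii = 10,
                   normalization = "as_printed", correction = "none")
  expect_equal(unname(kValues(k2)), 100)

  # as_printed for distinct phenotypes is a normalization mismatch
  expect_error(bivariateK(f, "CD4_T", "CD8_T",
                          normalization = "as_printed"),
               regexp = "normalization", class = "til_contract_error")
  expect_error(bivariateK(f, "B_cell", "CD8_T"),
               class = "til_validation_error")
})

test_that("K estimator equals the literal double sum on random fields", {
  withr::local_seed(57)
  for (rep in 1:15) {
    f <- randomTwoTypeField(sample(2:80, 1), sample(2:80, 1))
    df <- cells(f)
    m1 <- phenotypeMask(f, "CD4_T"); m2 <- phenotypeMask(f, "CD8_T")
    r <- runif(1, 10, 80)
    for (corr in c("none", "translation")) {
      k <- bivariateK(f, "CD4_T", "CD8_T", radii = r, correction = corr)
      expect_equal(unname(kValues(k)),
                   bruteK(df$x_um[m1], df$y_um[m1], which(m1),
                          df$x_um[m2], df$y_um[m2], which(m2),
                          r, fieldWidth(f), fieldHeight(f),
                          "cross", corr))
    }
    # univariate as_printed with self-exclusion
    k1 <- bivariateK(f, "CD8_T", "CD8_T", radii = r,
                     normalization = "as_printed", correction = "none")
    expect_equal(unname(kValues(k1)),
                 bruteK(df$x_um[m2], df$y_um[m2], which(m2),
                        df$x_um[m2], df$y_um[m2], which(m2),
                        r, fieldWidth(f), fieldHeight(f),
                        "as_printed", "none"))
  }
})

test_that("cross K with no correction is symmetric and scale-equivariant", {
  withr::local_seed(77)
  f <- randomTwoTypeField(40, 60)
  rads <- c(10, 20, 30, 40, 60, 80)
  k12 <- bivariateK(f, "CD4_T", "CD8_T", rads, correction = "none")
  k21 <- bivariateK(f, "CD8_T", "CD4_T", rads, correction = "none")
  expect_equal(kValues(k12), kValues(k21))
  # K with correction "none" is non-decreasing in r
  expect_true(!is.unsorted(as.numeric(kValues(k12))))

  cc <- 2.5
  df <- cells(f)
  df$x_um <- df$x_um * cc; df$y_um <- df$y_um * cc
  fs <- assignPhenotypes(TILField("sc", fieldWidth(f) * cc,
                                  fieldHeight(f) * cc,
                                  df[, c("cell_id", "x_um", "y_um",
                                         tilMarkers())]))
  for (corr in c("none", "translation")) {
    ks <- bivariateK(fs, "CD4_T", "CD8_T", rads * cc, correction = corr)
    k <- bivariateK(f, "CD4_T", "CD8_T", rads, correction = corr)
    expect_equal(unname(kValues(ks)), cc^2 * unname(kValues(k)))
  }
  # within-(c*r) counts unchanged under scaling
  m1 <- phenotypeMask(f, "CD4_T"); m2 <- phenotypeMask(f, "CD8_T")
  expect_identical(
    countWithinRadius(cells(f)[m1, ], cells(f)[m2, ], 30),
    countWithinRadius(cells(fs)[m1, ], cells(fs)[m2, ], 30 * cc))
})

test_that("radius sweep equals independent single-radius calls", {
  withr::local_seed(91)
  f <- randomTwoTypeField(50, 50)
  rads <- c(10, 20, 30, 40, 60, 80)
  sw <- radiusSweep(f, "CD4_T", "CD8_T", rads)
  expect_length(kValues(sw$k), 6)
  expect_equal(nrow(sw$proximity), 6)
  for (i in seq_along(rads)) {
    k1 <- bivariateK(f, "CD4_T", "CD8_T", rads[i])
    expect_equal(unname(kValues(sw$k))[i], unname(kValues(k1)))
    expect_equal(sw$proximity$mean_count[i],
                 proximityDensity(f, "CD4_T", "CD8_T", rads[i]))
  }
  expect_error(radiusSweep(f, "CD4_T", "CD8_T", c(30, 20)),
               class = "til_contract_error")
})

test_that("uncorrected K under CSR shows the edge deficit", {
  withr::local_seed(13)
  cfg <- fieldSimConfig(intensities = c(CD4 = 8e-4, CD8 = 8e-4))
  kk <- replicate(100, {
    f <- assignPhenotypes(simulateCSRField(cfg))
    unname(kValues(bivariateK(f, "CD4_T", "CD8_T", radii = 50,
                              correction = "none")))
  })
  expect_lt(mean(kk), pi * 50^2)
})

test_that("cohort proximity summarises per-specimen means and drops empties", {
  withr::local_seed(17)
  mk <- function(n4, n8) randomTwoTypeField(n4, n8)
  sp1 <- TILSpecimen("P1", "NAC", "post", list(mk(10, 10), mk(5, 8)))
  # specimen with a single eligible field: mean equals that field's value
  f <- mk(6, 9)
  sp2 <- TILSpecimen("P2", "NAC", "post", list(f))
  pairs <- data.frame(ref = "CD4_T", target = "CD8_T")
  px <- cohortProximity(list(sp1, sp2), pairs, r = 30)
  expect_equal(nrow(px), 2)
  expect_equal(px$mean_count[px$patient_id == "P2"],
               proximityDensity(f, "CD4_T", "CD8_T", 30))

  # specimen whose fields lack reference cells is dropped with a message
  noref <- makeField(c(10, 20), c(10, 20), list(CD8 = 1:2))
  sp3 <- TILSpecimen("P3", "NAPC", "post", list(noref))
  expect_message(
    px2 <- cohortProximity(list(sp1, sp3), pairs, r = 30),
    "dropped")
  expect_false("P3" %in% px2$patient_id)
})
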