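test_that("computeGrid shapes, cell agreement and determinism", {
  ds <- toyDataset(nGenes = 3, nMirnas = 2, n = 10)
  grid <- computeGrid(ds)
  expect_identical(dim(partialR(grid)), c(3L, 2L))
  expect_identical(dim(improvement(grid)), c(3L, 2L))
  expect_length(bivariateP(grid), 3L)

  # every cell agrees with the scalar reference implementation
  for (g in 1:3) for (z in 1:2) {
    ref <- partialWithP(mrna(ds)[g, ], protein(ds)[g, ], mirna(ds)[z, ])
    expect_equal(partialR(grid)[g, z], ref$r, tolerance = 1e-12)
    expect_equal(partialP(grid)[g, z], ref$p, tolerance = 1e-12)
  }
  for (g in 1:3)
    expect_equal(bivariateP(grid)[[g]],
                 pearsonWithP(mrna(ds)[g, ], protein(ds)[g, ])$p,
                 tolerance = 1e-12)
  expect_equal(improvement(grid),
               matrix(bivariateP(grid), 3, 2) - partialP(grid),
               ignore_attr = TRUE)

  # duplicating a miRNA row under a new ID duplicates its grid column
  mi2 <- rbind(mirna(ds), `miR-dup` = mirna(ds)[1, ])
  grid2 <- computeGrid(new("OmicsDataset", mrna = mrna(ds),
                           protein = protein(ds), mirna = mi2))
  expect_equal(partialP(grid2)[, "miR-dup"], partialP(grid2)[, "miR-1"],
               ignore_attr = TRUE)
})

test_that("degenerate cells are marked NA and excluded, not zero-filled", {
  ds <- toyDataset(nGenes = 3, nMirnas = 2, n = 10)
  mi <- mirna(ds)
  mi[2, ] <- 5                               # constant miRNA profile
  dsc <- new("OmicsDataset", mrna = mrna(ds), protein = protein(ds),
             mirna = mi)
  expect_message(grid <- computeGrid(dsc), "degenerate")
  expect_true(all(is.na(partialP(grid)[, 2])))
  expect_true(all(!is.na(partialP(grid)[, 1])))
  expect_identical(length(buildUniverse(grid)), 3L)
})

test_that("selection thresholds the positive-improvement distribution", {
  # four candidates with known improvements: type-7 quantile keeps one
  imp <- c(0.1, 0.2, 0.3, 0.4)
  thr <- quantile(imp, 0.75, type = 7, names = FALSE)
  expect_equal(thr, 0.325)
  grid <- new("CorrelationGrid", genes = sprintf("G%d", 1:4),
              mirnas = "m1",
              partialR = matrix(0.9, 4, 1),
              partialP = matrix(0.05, 4, 1),
              bivariateR = rep(0.1, 4), bivariateP = 0.05 + imp,
              improvement = matrix(imp, 4, 1), nSamples = 20L)
  tab <- selectInteractions(grid, quartile = 0.75)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$gene, "G4")
  expect_true(all(tab$partial_p_fdr >= tab$partial_p))

  # all improvements non-positive -> empty table with a warning
  gneg <- new("CorrelationGrid", genes = c("G1", "G2"), mirnas = "m1",
              partialR = matrix(0.1, 2, 1), partialP = matrix(0.6, 2, 1),
              bivariateR = rep(0.1, 2), bivariateP = c(0.6, 0.5),
              improvement = matrix(c(0, -0.1), 2, 1), nSamples = 20L)
  expect_warning(t0 <- selectInteractions(gneg), "no pair")
  expect_identical(nrow(t0), 0L)
})

test_that("FDR is computed over all tested cells, not the selected subset", {
  ds <- toyDataset(nGenes = 6, nMirnas = 3, n = 12, seed = 21)
  grid <- computeGrid(ds)
  tab <- selectInteractions(grid)
  full <- matrix(benjaminiHochberg(as.vector(partialP(grid))),
                 nrow = 6, dimnames = list(genes(grid), mirnas(grid)))
  for (i in seq_len(nrow(tab)))
    expect_equal(tab$partial_p_fdr[i], full[tab$gene[i], tab$mirna[i]])
})

test_that("selected fraction of candidates tracks 1 - quartile", {
  set.seed(14)
  for (rep in 1:5) {
    nG <- sample(20:40, 1); nZ <- sample(5:12, 1)
    imp <- matrix(runif(nG * nZ, -0.5, 0.5), nG, nZ)   # all distinct a.s.
    grid <- new("CorrelationGrid",
                genes = sprintf("G%d", seq_len(nG)),
                mirnas = sprintf("m%d", seq_len(nZ)),
                partialR = matrix(0.5, nG, nZ),
                partialP = matrix(0.5, nG, nZ) - imp,
                bivariateR = rep(0.5, nG), bivariateP = rep(0.5, nG),
                improvement = imp, nSamples = 30L)
    ncand <- sum(imp > 0)
    tab <- selectInteractions(grid, quartile = 0.75)
    expect_lt(abs(nrow(tab) / ncand - 0.25), 1 / ncand)
  }
})
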