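test_that("missingness filter keeps features strictly below the threshold", {
  m <- namedMatrix(rnorm(60), c("a", "b", "c"), sprintf("s%d", 1:20))
  m["a", 1] <- NA                  # 5% missing -> kept
  m["b", 1:2] <- NA                # exactly 10% -> dropped (strict <)
  out <- filterByMissingness(m, 0.10)
  expect_identical(rownames(out), c("a", "c"))
  expect_identical(filterByMissingness(m["c", , drop = FALSE]),
                   m["c", , drop = FALSE])
  allna <- m; allna[] <- NA
  expect_warning(res <- filterByMissingness(allna), "no feature")
  expect_identical(nrow(res), 0L)
})

test_that("median imputation fills gaps with the per-feature median", {
  m <- matrix(c(1, 2, NA, 4), 1, dimnames = list("r1", sprintf("s%d", 1:4)))
  expect_identical(as.vector(imputeMedian(m)), c(1, 2, 2, 4))
  single <- matrix(c(5, NA), 1, dimnames = list("r", c("s1", "s2")))
  expect_identical(as.vector(imputeMedian(single)), c(5, 5))
  clean <- namedMatrix(1:6 + 0, c("a", "b"), c("s1", "s2", "s3"))
  expect_identical(imputeMedian(clean), clean)
  allna <- matrix(NA_real_, 1, 3, dimnames = list("x", c("a", "b", "c")))
  expect_error(imputeMedian(allna), "all values missing")
})

test_that("log2 transform applies the pseudocount and guards its domain", {
  m <- matrix(c(7, 0), 1, dimnames = list("g", c("s1", "s2")))
  expect_equal(as.vector(log2Transform(m, 1)), c(3, 0))
  expect_error(log2Transform(m, 0), "non-positive")
})

test_that("top-variance selection uses ceiling and a deterministic tie-break", {
  m <- rbind(w = c(10, 0, 10, 0), x = c(3, 0, 3, 0),
             y = c(2, 0, 2, 0), z = c(1, 0, 1, 0))
  colnames(m) <- sprintf("s%d", 1:4)
  expect_identical(rownames(selectTopVariance(m, 0.5)), c("w", "x"))
  expect_identical(selectTopVariance(m, 1), m)
  m5 <- rbind(m, v = c(0.5, 0, 0.5, 0))
  expect_identical(nrow(selectTopVariance(m5, 0.5)), 3L)   # ceiling(2.5)
  ties <- namedMatrix(rep(c(1, 0), each = 3), c("b", "a", "c"),
                      c("s1", "s2"))
  # equal variances: lexicographically smaller IDs win, input order kept
  expect_identical(rownames(selectTopVariance(ties, 2 / 3)), c("b", "a"))
})

test_that("alignment intersects samples and genes into a canonical order", {
  s <- sprintf("S%d", 1:9)
  M <- namedMatrix(rnorm(12 * 9), sprintf("G%02d", 1:12), s)
  P <- namedMatrix(rnorm(15 * 8), sprintf("G%02d", 3:17), s[1:8])
  MI <- namedMatrix(rnorm(2 * 9), c("m1", "m2"), rev(s))
  ds <- suppressMessages(alignDataset(M, P, MI))
  expect_s4_class(ds, "OmicsDataset")
  expect_identical(nrow(mrna(ds)), 10L)            # genes 3..12
  expect_identical(nSamples(ds), 8L)
  expect_identical(colnames(mrna(ds)), sort(s[1:8]))
  expect_identical(colnames(mirna(ds)), colnames(protein(ds)))
  # idempotence: aligning aligned content is the identity
  ds2 <- suppressMessages(alignDataset(mrna(ds), protein(ds), mirna(ds)))
  expect_identical(mrna(ds2), mrna(ds))
  expect_identical(mirna(ds2), mirna(ds))

  MIbad <- namedMatrix(rnorm(2), c("m1", "m2"), "T1")
  expect_error(alignDataset(M, P, MIbad), "no sample")
  Pbad <- namedMatrix(rnorm(8), "H1", s[1:8])
  expect_error(alignDataset(M, Pbad, MI), "no gene")
})

test_that("the full recipe is idempotent and permutation-invariant downstream", {
  ds <- generateDataset(synthSpec(nSamples = 30L, nGenes = 12L,
                                  nMirnas = 4L, planted = 4L, seed = 5L))
  d1 <- suppressMessages(preprocessDataset(ds$M, ds$P, ds$MI,
                                           pseudocount = 0))
  # the cleaning stages reach a fixed point: re-running the recipe on its
  # own output (transform and variance cut already applied) changes nothing
  d2 <- suppressMessages(
    preprocessDataset(mrna(d1), protein(d1), mirna(d1), pseudocount = 0,
                      keepFraction = 1, log2Layers = character()))
  expect_equal(mrna(d2), mrna(d1))
  expect_equal(protein(d2), protein(d1))
  expect_equal(mirna(d2), mirna(d1))

  # permuting samples consistently yields the identical correlation grid
  perm <- sample(seq_len(nSamples(d1)))
  dp <- new("OmicsDataset", mrna = mrna(d1)[, perm],
            protein = protein(d1)[, perm], mirna = mirna(d1)[, perm])
  expect_equal(partialP(computeGrid(dp)), partialP(computeGrid(d1)))
})
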