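test_that("validation flags are per-database membership plus their OR", {
  tab <- data.frame(gene = c("G1", "G2", "G3"),
                    mirna = c("m1", "m2", "m3"))
  dbs <- list(TargetDatabase("m1", "G1", name = "A"),
              TargetDatabase(c("m1", "m2"), c("G1", "G2"), name = "B"))
  out <- annotateValidated(tab, dbs)
  expect_identical(out$validated_A, c(TRUE, FALSE, FALSE))
  expect_identical(out$validated_B, c(TRUE, TRUE, FALSE))
  expect_identical(out$validated_any, c(TRUE, TRUE, FALSE))
  bare <- annotateValidated(tab, list())
  expect_identical(bare$validated_any, rep(FALSE, 3))
})

test_that("hypergeometric enrichment is exact against tail-sum enumeration", {
  expect_equal(hyperTailP(100, 20, 10, 5), oracleHyperTail(100, 20, 10, 5))
  expect_equal(hyperTailP(100, 20, 10, 0), 1)
  expect_equal(hyperTailP(50, 0, 10, 0), 1)
  # monotone nonincreasing in the overlap
  ps <- vapply(0:10, function(k) hyperTailP(60, 25, 10, k), numeric(1))
  expect_true(all(diff(ps) <= 0))
  # agrees with the enumeration oracle across a random sample of shapes
  set.seed(6)
  for (i in 1:50) {
    N <- sample(5:400, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hyperTailP(N, K, n, k), oracleHyperTail(N, K, n, k),
                 tolerance = 1e-12)
  }
})

test_that("enrichment wiring counts overlaps within the tested universe", {
  universe <- pairKey(rep(c("m1", "m2"), each = 3),
                      rep(c("G1", "G2", "G3"), 2))
  db <- TargetDatabase(c("m1", "m1", "m9"), c("G1", "G2", "G9"),
                       name = "db")
  pred <- pairKey(c("m1", "m2"), c("G1", "G3"))
  res <- hypergeometricEnrichment(pred, db, universe)
  expect_identical(res$universe_size, 6L)
  expect_identical(res$database_in_universe, 2L)   # m9/G9 outside
  expect_identical(res$overlap, 1L)
  expect_equal(res$p_value, oracleHyperTail(6, 2, 2, 1))
  expect_error(hypergeometricEnrichment(pairKey("mX", "GX"), db, universe),
               "subset")
})

test_that("null enrichment p-values are super-uniform", {
  set.seed(17)
  universe <- pairKey(rep(sprintf("m%d", 1:10), each = 20),
                      rep(sprintf("G%d", 1:20), 10))
  hits <- replicate(1000, {
    db <- sample(universe, 30)
    pred <- sample(universe, 25)
    N <- length(universe)
    hyperTailP(N, 30, 25, sum(pred %in% db)) <= 0.05
  })
  expect_lte(mean(hits), 0.07)
})

test_that("bivariate baseline selects by FDR and stays calibrated on noise", {
  set.seed(30)
  s <- sprintf("S%d", 1:50)
  expr <- namedMatrix(rnorm(50 * 50), sprintf("G%d", 1:50), s)
  MI <- namedMatrix(rnorm(20 * 50), sprintf("m%d", 1:20), s)
  # a perfectly correlated pair is always picked up
  expr["G1", ] <- MI["m1", ]
  res <- bivariateBaseline(expr, MI, alpha = 0.05)
  expect_true(pairKey("m1", "G1") %in% res$pairs)
  expect_identical(res$tested, 1000L)
  # alpha = 0 selects nothing
  expect_length(bivariateBaseline(expr, MI, alpha = 0)$pairs, 0L)
  # pure-noise matrices: selected fraction bounded near the nominal level
  fr <- vapply(1:4, function(i) {
    set.seed(100 + i)
    e <- namedMatrix(rnorm(50 * 50), sprintf("G%d", 1:50), s)
    z <- namedMatrix(rnorm(20 * 50), sprintf("m%d", 1:20), s)
    bivariateBaseline(e, z, alpha = 0.05)$fraction
  }, numeric(1))
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_true(all(fr <= 0.05 + 3 * se))
})

test_that("the validation summary mirrors the three-method comparison table", {
  enr <- function(nm, p) list(database_name = nm, universe_size = 100L,
                              database_in_universe = 10L, predicted = 20L,
                              overlap = 5L, p_value = p)
  mk <- function(p1, p2, p3) list(enr("dbA", p1), enr("dbB", p2),
                                  enr("dbC", p3))
  fr <- c("mRNA-miRNA bivariate" = 0.30, "protein-miRNA bivariate" = 0.41,
          "partial correlation" = 0.18)
  s <- summarizeValidation(partial = mk(1e-5, 1e-3, 1e-8),
                           baselineMrna = mk(0.1, 0.2, 0.3),
                           baselineProtein = mk(0.4, 0.5, 0.6),
                           fractions = fr)
  expect_identical(dim(as.data.frame(s)), c(4L, 3L))
  expect_equal(s["% of predicted miRNA-targets", "partial correlation"], 18)
  expect_equal(s["dbC enrichment", "partial correlation"], 1e-8)
  txt <- capture.output(print(s))
  expect_true(any(grepl("18.00%", txt)))

  s0 <- summarizeValidation(partial = list(), fractions = fr)
  expect_identical(nrow(as.data.frame(s0)), 1L)
})
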