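test_that("the RSCU matrix has 59 columns, stable rows and neutral imputation", {
  sim <- generateGenes(syntheticSpec(nGenes = 10, seed = 3))
  counts <- countCodons(sim$sequences, dropTerminalStop = TRUE)
  m <- buildRscuMatrix(counts)
  expect_identical(ncol(m), 59L)
  expect_false(any(colnames(m) %in% c(stopCodons(), "ATG", "TGG")))
  expect_true(all(m >= 0))
  # identical genes give identical rows
  two <- countCodons(dss(c(a = "ATGAAAAAGTAA", b = "ATGAAAAAGTAA")),
                     dropTerminalStop = TRUE)
  m2 <- buildRscuMatrix(two)
  expect_equal(m2[1, ], m2[2, ])
  # family absent from a gene: its codons imputed at the neutral value 1
  expect_true(all(m2[, "GGG"] == 1))
  expect_identical(attr(m2, "imputed_families"), c(a = 17L, b = 17L))
  # family sums equal family size for observed families, by the rscu oracle
  fams <- geneticCodeFamilies()
  deg <- geneticCodeDegeneracy()
  set.seed(8)
  for (f in fams[deg[names(fams)] >= 2]) {
    sums <- rowSums(m[, f, drop = FALSE])
    expect_equal(sums, setNames(rep(length(f), nrow(m)), rownames(m)),
                 tolerance = 1e-9)
  }
})

test_that("correspondence analysis degenerates correctly on identical rows", {
  x <- matrix(rep(c(3, 1, 2, 6), each = 4), nrow = 4)
  coa <- correspondenceAnalysis(x)
  expect_equal(totalInertia(coa), 0, tolerance = 1e-12)
  expect_identical(coa@rank, 0L)
  expect_identical(ncol(rowCoords(coa)), 0L)
})

test_that("total inertia equals chi-square over the grand total", {
  set.seed(21)
  for (i in 1:5) {
    x <- matrix(sample(1:40, 6 * 59, replace = TRUE), nrow = 6)
    coa <- correspondenceAnalysis(x, nAxes = 5)
    expect_equal(totalInertia(coa), chisqStat(x) / sum(x), tolerance = 1e-9)
  }
})

test_that("CA coordinates match a brute-force eigen-decomposition", {
  x <- rbind(a = c(3, 1), b = c(1, 3))
  coa <- correspondenceAnalysis(x)
  orc <- oracleCa(x)
  expect_identical(coa@rank, 1L)
  expect_equal(totalInertia(coa), orc$totalInertia, tolerance = 1e-12)
  expect_equal(abs(as.vector(rowCoords(coa))), abs(as.vector(orc$rowCoords)),
               tolerance = 1e-9)
  # larger random case, axis by axis up to sign
  set.seed(5)
  y <- matrix(sample(1:30, 8 * 12, replace = TRUE), nrow = 8)
  coaY <- correspondenceAnalysis(y, nAxes = 4)
  orcY <- oracleCa(y)
  for (k in 1:4)
    expect_equal(abs(rowCoords(coaY)[, k]), abs(orcY$rowCoords[, k]),
                 tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("CA matches MASS::corresp principal coordinates up to sign", {
  skip_if_not_installed("MASS")
  set.seed(14)
  x <- matrix(sample(1:25, 7 * 10, replace = TRUE), nrow = 7)
  coa <- correspondenceAnalysis(x, nAxes = 3)
  mc <- MASS::corresp(x, nf = 3)
  # corresp returns standard coordinates; principal = standard * singular value
  prin <- sweep(mc$rscore, 2, mc$cor, "*")
  for (k in 1:3)
    expect_equal(abs(rowCoords(coa)[, k]), abs(prin[, k]),
                 tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("row coordinates reproduce chi-square distances at full rank", {
  set.seed(33)
  x <- matrix(sample(1:20, 5 * 9, replace = TRUE), nrow = 5)
  coa <- correspondenceAnalysis(x, nAxes = 10)  # all axes
  P <- x / sum(x)
  rp <- P / rowSums(P)
  cm <- colSums(P)
  d2chi <- as.matrix(dist(sweep(rp, 2, sqrt(cm), "/")))
  d2coord <- as.matrix(dist(rowCoords(coa)))
  expect_equal(d2coord, d2chi, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("permuting genes permutes row coordinates and sign choice is stable", {
  set.seed(4)
  x <- matrix(sample(1:30, 6 * 8, replace = TRUE), nrow = 6,
              dimnames = list(letters[1:6], NULL))
  coa1 <- correspondenceAnalysis(x)
  perm <- c(4, 1, 6, 2, 5, 3)
  coa2 <- correspondenceAnalysis(x[perm, ])
  expect_equal(rowCoords(coa2), rowCoords(coa1)[perm, ], tolerance = 1e-9)
  expect_equal(colCoords(coa2), colCoords(coa1), tolerance = 1e-9)
})

test_that("correlation report is symmetric with exact self- and anti-correlations", {
  df <- data.frame(x = 1:10, y = -(1:10), z = rnorm(10))
  rep <- correlationReport(df, method = "spearman")
  expect_equal(unname(diag(rep$estimate)), rep(1, 3))
  expect_equal(rep$estimate["x", "y"], -1)
  expect_equal(rep$estimate, t(rep$estimate))
  repP <- correlationReport(df, method = "pearson")
  expect_equal(repP$estimate["x", "y"], -1)
  expect_warning(correlationReport(data.frame(a = rep(1, 5), b = 1:5)),
                 "constant")
})

test_that("selection strength induces the expected CAI-ENC sign structure", {
  # genes spanning neutral to strongly selected: CAI rises as ENC falls
  spec <- syntheticSpec(nGenes = 60, seed = 17,
                        selectionStrength = rep(c(0, 1.5, 4), each = 20))
  sim <- generateGenes(spec)
  idx <- geneIndices(sim$sequences)
  coa <- correspondenceAnalysis(
    buildRscuMatrix(countCodons(sim$sequences, dropTerminalStop = TRUE)))
  rep <- correlationReport(idx[, c("enc", "cai", "gc3s")], coa)
  expect_lt(rep$estimate["cai", "enc"], 0)
  expect_lt(rep$p.value["cai", "enc"], 0.05)
})
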