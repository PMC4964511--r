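test_that("codon counting skips ambiguous codons and pools additively", {
  m <- countCodons(dss(c(g = "ATGAAAAAATAA")))
  expect_identical(unname(m[1, c("ATG", "AAA", "TAA")]), c(1L, 2L, 1L))
  ss <- senseStopCounts(m)
  expect_identical(ss$nSense, 3)
  expect_identical(ss$nStop, 1)
  # ANA falls in no bin
  m2 <- countCodons(dss(c(g = "ATGANAAAATAA")))
  expect_identical(sum(m2), 3L)
  # pooling two genes sums element-wise
  two <- countCodons(dss(c(a = "ATGAAATAA", b = "ATGAAATAA")))
  expect_identical(pooledCounts(two), colSums(two))
  expect_equal(unname(pooledCounts(two)[c("ATG", "AAA")]), c(2, 2))
  # terminal stop dropped only when asked, internal stops kept
  m3 <- countCodons(dss(c(g = "ATGTAAAAATAA")), dropTerminalStop = TRUE)
  expect_identical(unname(m3[1, "TAA"]), 1L)
})

test_that("RSCU matches hand computations and conserves family sums", {
  r <- rscu(c(AAA = 1, AAG = 3))
  expect_equal(unname(r["AAA"]), 0.5)
  expect_equal(unname(r["AAG"]), 1.5)
  # uniform usage in every family gives RSCU 1 everywhere
  uni <- setNames(rep(7, 64), geneticCodeCodons())
  ru <- rscu(uni, includeStops = TRUE)
  expect_equal(unname(ru), rep(1, 64))
  # family-sum conservation on random tables
  fams <- geneticCodeFamilies()
  set.seed(101)
  for (i in 1:25) {
    v <- randomCountVector()
    r <- rscu(v)
    for (f in fams) {
      if (sum(v[f]) > 0)
        expect_equal(sum(r[f]), length(f), tolerance = 1e-9)
      else
        expect_true(all(is.na(r[f])))
    }
  }
  # stop codons form a 3-membered family only on request
  v <- setNames(rep(2, 64), geneticCodeCodons())
  expect_true(all(is.na(rscu(v)[stopCodons()])))
  expect_equal(unname(rscu(v, includeStops = TRUE)[stopCodons()]), rep(1, 3))
})

test_that("family homozygosity follows Wright's corrected estimator", {
  expect_equal(familyHomozygosity(c(2, 2)), 1 / 3)
  expect_equal(familyHomozygosity(c(4, 0)), 1)
  expect_true(is.na(familyHomozygosity(c(1))))
  expect_true(is.na(familyHomozygosity(c(1, 0))))
})

test_that("ENC hits its theoretical endpoints", {
  # one codon per amino acid at count 10: maximal bias, ENC = 20
  fams <- geneticCodeFamilies()
  oneEach <- setNames(integer(64), geneticCodeCodons())
  for (f in fams) oneEach[f[1]] <- 10L
  expect_equal(enc(oneEach), 20)
  # equal use of all 59 multi-family codons: estimator slightly above 61,
  # capped to the theoretical maximum
  deg <- geneticCodeDegeneracy()
  uniform <- setNames(integer(64), geneticCodeCodons())
  for (a in names(fams)) if (deg[[a]] >= 2) uniform[fams[[a]]] <- 1000L
  expect_equal(enc(uniform), 61)
  # closed form of the uncapped estimator at count 1000 per codon:
  # F(k) = 999 / (1000k - 1) for a k-fold family, slightly below 1/k
  fk <- function(k) 999 / (1000 * k - 1)
  expect_gt(2 + 9 / fk(2) + 1 / fk(3) + 5 / fk(4) + 3 / fk(6), 61)
})

test_that("ENC agrees with an independent oracle on random small genes", {
  set.seed(2024)
  for (i in 1:200) {
    v <- randomGeneCounts()
    got <- enc(v)
    want <- oracleEnc(v)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("ENC is nearly scale-invariant for large counts and stays in [20, 61]", {
  set.seed(7)
  for (i in 1:20) {
    # large-count regime: the small-sample correction is already tiny
    v <- setNames(sample(100:500, 64, replace = TRUE), geneticCodeCodons())
    e1 <- enc(v)
    e10 <- enc(v * 10L)
    if (!is.na(e1) && !is.na(e10)) expect_lt(abs(e1 - e10), 0.5)
    if (!is.na(e1)) expect_true(e1 >= 20 && e1 <= 61)
  }
})

test_that("CAI weights and values match the Sharp-Li construction", {
  # a reference covering only Lys warns about the other families
  expect_warning(w <- caiWeights(c(AAA = 75, AAG = 25)), "absent")
  expect_equal(unname(w["AAA"]), 1)
  expect_equal(unname(w["AAG"]), 1 / 3)
  # zero-count reference codon floored
  wf <- suppressWarnings(caiWeights(c(AAA = 50, AAG = 0)))
  expect_equal(unname(wf["AAG"]), 0.01)
  # uniform reference: all weights 1
  wu <- caiWeights(setNames(rep(3, 64), geneticCodeCodons()))
  expect_true(all(wu == 1))
  expect_error(caiWeights(setNames(rep(0, 64), geneticCodeCodons())), "empty")
  # hand value: gene AAA+AAG under w = (1, 1/3)
  expect_equal(cai(c(AAA = 1, AAG = 1), w), sqrt(1 / 3))
  # scale invariance of the geometric mean
  expect_equal(cai(c(AAA = 2, AAG = 2), w), cai(c(AAA = 1, AAG = 1), w))
  # gene of family-maximal codons reaches the upper bound exactly
  sim <- generateGenes(syntheticSpec(nGenes = 40, seed = 9))
  ref <- pooledCounts(countCodons(sim$sequences, dropTerminalStop = TRUE))
  wAll <- caiWeights(ref)
  fams <- geneticCodeFamilies()
  best <- vapply(fams, function(f) f[which.max(wAll[f])], character(1))
  gene <- setNames(integer(64), geneticCodeCodons())
  gene[best] <- 5L
  expect_equal(cai(gene, wAll), 1)
})

test_that("CAI never decreases when a codon is replaced by a better synonym", {
  set.seed(31)
  sim <- generateGenes(syntheticSpec(nGenes = 30, seed = 31))
  w <- caiWeights(pooledCounts(countCodons(sim$sequences,
                                           dropTerminalStop = TRUE)))
  fams <- geneticCodeFamilies()
  for (i in 1:50) {
    v <- randomGeneCounts()
    f <- sample(fams[lengths(fams) >= 2], 1)[[1]]
    present <- f[v[f] > 0]
    if (!length(present)) next
    from <- present[1]
    to <- f[which.max(w[f])]
    v2 <- v
    v2[to] <- v2[to] + v2[from]
    if (from != to) v2[from] <- 0L
    c1 <- cai(v, w); c2 <- cai(v2, w)
    if (!is.na(c1) && !is.na(c2)) expect_gte(c2, c1 - 1e-12)
  }
})

test_that("GRAVY and aromaticity follow the residue tables", {
  expect_equal(gravy(dss(c(g = strrep("ATT", 20)))), 4.5)   # poly-Ile
  expect_equal(gravy(dss(c(g = strrep("CGT", 20)))), -4.5)  # poly-Arg
  # order invariance: same residues, shuffled codons
  a <- gravy(dss(c(g = "ATTCGTGGGTTT")))
  b <- gravy(dss(c(g = "TTTGGGCGTATT")))
  expect_equal(a, b)
  # 10 residues, 2 Phe + 1 Trp aromatic
  seq10 <- paste0(strrep("TTT", 2), "TGG", strrep("GCA", 7))
  expect_equal(aromo(dss(c(g = seq10))), 0.3)
  expect_equal(aromo(dss(c(g = strrep("GCA", 8)))), 0)
  expect_equal(aromo(dss(c(g = strrep("TAC", 8)))), 1)
  # terminal stop contributes no residue
  expect_equal(gravy(dss(c(g = "ATTATTTAA"))), 4.5)
})
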