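test_that("subset sizing uses the ceiling convention and rejects overlap", {
  expect_identical(selectBiasSubsets(paste0("g", 1:4870),
                                     runif(4870))$subsetSize, 244L)
  expect_identical(selectBiasSubsets(paste0("g", 1:100),
                                     runif(100))$subsetSize, 5L)
  expect_identical(selectBiasSubsets(paste0("g", 1:10),
                                     runif(10))$subsetSize, 1L)
  expect_error(selectBiasSubsets(paste0("g", 1:9), runif(9),
                                 fraction = 0.45), "overlap")
})

test_that("subsets are ordered by ENC ratio with deterministic tie-breaks", {
  ids <- c("d", "b", "a", "c", "e", "f")
  ratios <- c(0.5, 0.5, 0.1, 0.1, 0.3, NA)
  subs <- selectBiasSubsets(ids, ratios, fraction = 0.4)
  expect_identical(subs$highIds, c("b", "d"))   # ties broken by id
  expect_identical(subs$lowIds, c("c", "a"))    # lowest ratios, reverse end
  expect_length(intersect(subs$highIds, subs$lowIds), 0L)
})

test_that("the delta-RSCU rule reproduces the published optimal-codon stars", {
  tb <- efestucaeOptimalCodons()
  delta <- tb$rscu_high - tb$rscu_low
  eligible <- !(tb$amino_acid %in% c("Met", "Trp", "Ter"))
  optimal <- delta > 0.08 & eligible
  expect_identical(sum(optimal), 27L)
  expect_identical(sum(optimal & tb$amino_acid == "Arg"), 3L)
  expect_identical(sort(tb$codon[optimal & tb$amino_acid == "Arg"]),
                   c("AGG", "CGC", "CGG"))
  # row-for-row agreement with the published stars, including the stop codon
  # UAG (delta 0.18, unstarred because stops are never optimal)
  expect_identical(optimal, tb$starred)
  # spot values quoted in the source: UUC optimal, GGG not
  expect_true(optimal[tb$codon == "TTC"])
  expect_false(optimal[tb$codon == "GGG"])
  # ending bases of the starred codons sum to 27 and are all C or G
  third <- substring(tb$codon[optimal], 3, 3)
  expect_identical(sum(third %in% c("C", "G")), 27L)
})

test_that("optimalCodons computes pooled subset RSCU and the strict threshold", {
  hi <- c(TTC = 90, TTT = 10, AAA = 10, AAG = 90)
  lo <- c(TTC = 50, TTT = 50, AAA = 46, AAG = 54)
  tab <- optimalCodons(hi, lo)
  tb <- optimalCodonTable(tab)
  expect_equal(tb$delta_rscu[tb$codon == "TTC"], 1.8 - 1.0)
  expect_identical(sort(optimalCodonSet(tab)), c("AAG", "TTC"))
  # AAG: high 1.8, low 1.08 -> delta 0.72
  expect_equal(tb$delta_rscu[tb$codon == "AAG"], 0.72, tolerance = 1e-9)
  # strictly-greater-than: delta exactly at the threshold is not optimal
  hi2 <- c(AAA = 25, AAG = 75)   # RSCU(AAG) = 1.5
  lo2 <- c(AAA = 50, AAG = 50)   # RSCU(AAG) = 1.0, delta exactly 0.5
  expect_length(optimalCodonSet(optimalCodons(hi2, lo2, threshold = 0.5)), 0L)
  expect_identical(optimalCodonSet(optimalCodons(hi2, lo2, threshold = 0.49)),
                   "AAG")
  # family absent from a subset: NA delta, never optimal
  hi3 <- c(AAA = 10, AAG = 90, TTT = 5)
  lo3 <- c(AAA = 50, AAG = 50)
  tb3 <- optimalCodonTable(optimalCodons(hi3, lo3))
  expect_true(is.na(tb3$delta_rscu[tb3$codon == "TTT"]))
  expect_false(tb3$optimal[tb3$codon == "TTT"])
})

test_that("raising the threshold never adds optimal codons", {
  tb <- efestucaeOptimalCodons()
  hi <- setNames(tb$n_high, tb$codon)
  lo <- setNames(tb$n_low, tb$codon)
  sizes <- vapply(c(0.02, 0.08, 0.2, 0.5),
                  function(t) length(optimalCodonSet(
                    optimalCodons(hi, lo, threshold = t))), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("ending-base tallies count third positions of optimal codons", {
  hi <- c(TTC = 90, TTT = 10)
  lo <- c(TTC = 50, TTT = 50)
  tal <- endingBaseTally(optimalCodons(hi, lo))
  expect_identical(tal, c(A = 0L, C = 1L, G = 0L, T = 0L))
  # empty optimal set: all zero
  tal0 <- endingBaseTally(optimalCodons(c(AAA = 5, AAG = 5),
                                        c(AAA = 5, AAG = 5)))
  expect_identical(sum(tal0), 0L)
})
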