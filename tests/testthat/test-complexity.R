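# The five complexity measures: closed-form cases, hand-computed
# examples, brute-force oracle equivalence and invariance properties.

test_that("degenerate and closed-form inputs give their known values", {
  const <- rep(2.5, 50)
  expect_equal(approxEntropy(const, 2, 0.1), 0)
  expect_equal(sampleEntropy(const, 2, 0.1), 0)
  expect_equal(fuzzyEntropy(const, 2, 0.1, 2), 0)
  # strictly increasing ramp: a single ordinal pattern
  expect_equal(permutationEntropy(1:50, order = 3), 0)
  expect_equal(permutationEntropy(1:50, order = 4, normalize = FALSE), 0)
  # ramp with increments larger than r: no m-matches at all
  expect_error(sampleEntropy(1:20, 2, 0.5), "undefined|no template")
  # constant sequence parses as two LZ76 phrases
  expect_equal(kolmogorovComplexity(rep(1, 10), normalize = FALSE), 2)
})

test_that("hand-computed permutation entropy example is reproduced", {
  # 6 consecutive pairs: 4 ascents, 2 descents
  x <- c(4, 7, 9, 10, 6, 11, 3)
  expected <- -(4 / 6) * log(4 / 6) - (2 / 6) * log(2 / 6)
  expect_equal(permutationEntropy(x, order = 2, delay = 1,
                                  normalize = FALSE), expected)
  # each of the 6 order-3 patterns exactly once -> normalised PE = 1
  y <- c(7, 6, 1, 8, 3, 4, 5, 2)
  pats <- sapply(1:6, function(t) paste(rank(y[t:(t + 2)]), collapse = ""))
  stopifnot(length(unique(pats)) == 6)   # construction check
  expect_equal(permutationEntropy(y, order = 3), 1)
})

test_that("LZ76 phrase counts match manual exhaustive-history parses", {
  # "0101010101" parses as 0 | 1 | 01010101
  alt <- rep(c(0, 1), 5)
  expect_equal(kolmogorovComplexity(alt, normalize = FALSE), 3)
  expect_equal(oracleLZ76(medianBinarize(alt)), 3)
  # normalisation: c(n) * log2(n) / n
  expect_equal(kolmogorovComplexity(alt), 3 * log2(10) / 10)
})

test_that("fast implementations equal brute-force oracles on random data", {
  set.seed(101)
  for (i in 1:10) {
    n <- sample(40:200, 1)
    x <- if (i %% 2) rnorm(n) else runif(n)
    r <- 0.2 * sd(x)
    expect_equal(approxEntropy(x, 2, r), oracleApEn(x, 2, r),
                 tolerance = 1e-12)
    expect_equal(sampleEntropy(x, 2, r), oracleSampEn(x, 2, r),
                 tolerance = 1e-12)
    expect_equal(fuzzyEntropy(x, 2, r, 2), oracleFuzzEn(x, 2, r, 2),
                 tolerance = 1e-12)
    ord <- sample(2:4, 1); del <- sample(1:2, 1)
    # identical ordinal-pattern distributions; summation order may differ
    # by a final bit, hence the near-machine tolerance
    expect_equal(permutationEntropy(x, ord, del, FALSE),
                 oraclePE(x, ord, del, FALSE), tolerance = 1e-14)
    b <- medianBinarize(x)
    expect_identical(kolmogorovComplexity(x, normalize = FALSE),
                     as.numeric(oracleLZ76(b)))
  }
  # explicit spec-style case: integers 1..10, m = 2, r = 0.5
  x10 <- as.numeric(1:10)
  expect_equal(approxEntropy(x10, 2, 0.5), oracleApEn(x10, 2, 0.5),
               tolerance = 1e-12)
})

test_that("entropies are scale-invariant when r tracks the SD", {
  set.seed(7)
  x <- rnorm(150)
  a <- 3.7; b <- -12
  y <- a * x + b
  rx <- 0.2 * sd(x); ry <- 0.2 * sd(y)
  expect_equal(approxEntropy(x, 2, rx), approxEntropy(y, 2, ry),
               tolerance = 1e-9)
  expect_equal(sampleEntropy(x, 2, rx), sampleEntropy(y, 2, ry),
               tolerance = 1e-9)
  expect_equal(fuzzyEntropy(x, 2, rx, 2), fuzzyEntropy(y, 2, ry, 2),
               tolerance = 1e-9)
  # PE and KC invariant under any strictly increasing transform
  z <- exp(x)
  expect_identical(permutationEntropy(x, 3, 1), permutationEntropy(z, 3, 1))
  expect_identical(kolmogorovComplexity(x), kolmogorovComplexity(z))
})

test_that("fuzzy entropy is continuous in r, unlike the hard-threshold entropies", {
  set.seed(11)
  x <- rnorm(120)
  r <- 0.2 * sd(x)
  expect_lt(abs(fuzzyEntropy(x, 2, r, 2) - fuzzyEntropy(x, 2, r + 1e-9, 2)),
            1e-6)
})

test_that("irregular signals score higher than regular ones", {
  set.seed(21)
  noise <- rnorm(400)
  sine <- sin(2 * pi * 5 * seq_len(400) / 400)
  expect_gt(approxEntropy(noise, 2, 0.2 * sd(noise)),
            approxEntropy(sine, 2, 0.2 * sd(sine)))
  se <- sampleEntropy(noise, 2, 0.2 * sd(noise))
  expect_gte(se, 0)
})

test_that("raw and normalised PE respect their ranges", {
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(100)
    pn <- permutationEntropy(x, 3, 1, normalize = TRUE)
    pr <- permutationEntropy(x, 3, 1, normalize = FALSE)
    expect_gte(pn, 0); expect_lte(pn, 1)
    expect_gte(pr, 0); expect_lte(pr, log(factorial(3)))
  }
})

test_that("extractFeatures yields an 8x5 finite matrix with the documented conventions", {
  set.seed(41)
  ep <- makeEpoch(matrix(rnorm(8 * 300), 8, 300))
  fm <- extractFeatures(ep)
  expect_s4_class(fm, "FeatureMatrix")
  expect_identical(dim(featureValues(fm)), c(8L, 5L))
  expect_true(all(is.finite(featureValues(fm))))
  # r is r_frac * per-channel SD: column 2 must match a direct call
  ch1 <- eegData(ep)[1, ]
  expect_equal(featureValues(fm)[1, 2],
               sampleEntropy(ch1, 2, 0.2 * sd(ch1)))
  # constant epoch: the template entropies vanish
  fmC <- extractFeatures(makeEpoch(matrix(5, 8, 100)))
  expect_equal(unname(featureValues(fmC)[, c(1, 2, 4)]), matrix(0, 8, 3))
  # infinite sample entropy (m-matches exist, no m+1 matches) maps to the
  # configurable cap
  xInf <- c(0, 0.001, 5, 0, 0.001, -5)
  expect_identical(sampleEntropy(xInf, 2, 0.2 * sd(xInf)), Inf)
  epInf <- makeEpoch(matrix(rep(xInf, each = 8), 8, 6))
  fmR <- extractFeatures(epInf, complexityParams(sampen_cap = 7))
  expect_true(all(featureValues(fmR)[, 2] == 7))
})

test_that("feature CSVs round-trip through write/read", {
  withr::with_seed(51, {
    fms <- lapply(1:4, function(i)
      makeFeatureMatrix(matrix(abs(rnorm(40)), 8, 5),
                        stage = STAGES[1 + i %% 3], index = i))
    p <- withr::local_tempfile(fileext = ".csv")
    writeFeaturesCSV(fms, p)
    back <- readFeaturesCSV(p)
    expect_length(back, 4)
    for (i in 1:4) {
      expect_equal(featureValues(back[[i]]), featureValues(fms[[i]]),
                   tolerance = 1e-12, ignore_attr = TRUE)
      expect_identical(stage(back[[i]]), stage(fms[[i]]))
      expect_identical(back[[i]]@epochIndex, fms[[i]]@epochIndex)
    }
    expect_error(readFeaturesCSV(system.file("DESCRIPTION",
                                             package = "epistage")),
                 "not a feature CSV")
  })
})

test_that("acute epochs score lower than normal epochs on all five measures", {
  cfg <- generatorConfig(duration = 20, seed = 13)
  colMeansFor <- function(st) {
    rec <- generateRecording(st, cfg)
    eps <- preprocessRecording(rec, 1, bandSpec())
    fms <- extractFeatureList(eps)
    Reduce(`+`, lapply(fms, function(f) colMeans(featureValues(f)))) /
      length(fms)
  }
  mn <- colMeansFor("normal"); ma <- colMeansFor("acute")
  expect_true(all(ma < mn))
})
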