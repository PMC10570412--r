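# Statistical layer: one-way ANOVA, Tukey HSD, PCA scores and moment
# features, cross-checked against base R's aov()/TukeyHSD()/prcomp().

test_that("ANOVA handles identity, two-group and hand-computed cases", {
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  av <- oneWayAnova(g)
  expect_equal(av$F, 0)
  expect_equal(av$p, 1)
  # two groups: F equals the squared pooled-variance t statistic
  a <- c(1.1, 2.3, 0.7, 1.9); b <- c(3.2, 4.1, 2.8, 3.9)
  av2 <- oneWayAnova(list(a, b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(av2$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(av2$p, tt$p.value, tolerance = 1e-12)
  # {1,2},{4,5},{8,9}: SSB and SSW by hand
  g3 <- list(c(1, 2), c(4, 5), c(8, 9))
  av3 <- oneWayAnova(g3)
  gm <- 29 / 6                     # grand mean of the six values
  expect_equal(av3$ssb, 2 * (1.5 - gm)^2 + 2 * (4.5 - gm)^2 +
                 2 * (8.5 - gm)^2)
  expect_equal(av3$ssw, 6 * 0.25)
  expect_equal(av3$F, (av3$ssb / 2) / (av3$ssw / 3))
  expect_error(oneWayAnova(list(1, 2)), ">= 2 values")
  expect_error(oneWayAnova(list(c(1, 1), c(2, 2), c(3, 3))),
               "zero within-group variance")
})

test_that("ANOVA agrees with aov() and is shift-invariant", {
  withr::with_seed(30, {
    for (i in 1:5) {
      g <- lapply(1:3, function(k) rnorm(sample(5:30, 1), mean = k / 2))
      av <- oneWayAnova(g)
      df <- data.frame(y = unlist(g),
                       grp = factor(rep(seq_along(g), lengths(g))))
      ref <- summary(aov(y ~ grp, df))[[1]]
      expect_equal(av$F, ref[["F value"]][1], tolerance = 1e-10)
      expect_equal(av$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
      # adding a constant changes nothing
      av2 <- oneWayAnova(lapply(g, `+`, 100))
      expect_equal(av$F, av2$F, tolerance = 1e-9)
      expect_gte(av$F, 0)
      expect_gt(av$p, 0); expect_lte(av$p, 1)
    }
  })
})

test_that("Tukey HSD matches TukeyHSD() and orders its limits correctly", {
  withr::with_seed(31, {
    g <- list(normal = rnorm(20, 0), acute = rnorm(20, 1),
              chronic = rnorm(20, 0.3))
    tk <- tukeyHSD(g)
    df <- data.frame(y = unlist(g),
                     grp = factor(rep(names(g), lengths(g)),
                                  levels = names(g)))
    ref <- TukeyHSD(aov(y ~ grp, df))$grp
    # base R reports second-minus-first; ours is first-minus-second
    expect_equal(tk$diff[tk$pair == "normal-acute"],
                 -ref["acute-normal", "diff"], tolerance = 1e-10)
    expect_equal(tk$p_adj[tk$pair == "normal-acute"],
                 ref["acute-normal", "p adj"], tolerance = 1e-8)
    expect_equal(tk$p_adj[tk$pair == "acute-chronic"],
                 ref["chronic-acute", "p adj"], tolerance = 1e-8)
    # identical groups: differences 0, adjusted p = 1
    same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
    tks <- tukeyHSD(same)
    expect_true(all(tks$diff == 0))
    expect_true(all(tks$p_adj == 1))
    # widely separated groups: all adjusted p below 1e-6
    far <- list(a = rnorm(10, 0, 0.01), b = rnorm(10, 5, 0.01),
                c = rnorm(10, 10, 0.01))
    expect_true(all(tukeyHSD(far)$p_adj < 1e-6))
    # Tukey adjusted p >= unadjusted pairwise p
    praw <- t.test(g$normal, g$acute, var.equal = TRUE)$p.value
    expect_gte(tk$p_adj[tk$pair == "normal-acute"], praw)
  })
})

test_that("PCA scores agree with prcomp on the correlation matrix", {
  withr::with_seed(32, {
    X <- matrix(rnorm(60), 12, 5) %*% matrix(rnorm(25), 5, 5)
    sc <- pcaScores(X, 2)
    expect_equal(colMeans(sc), c(0, 0), tolerance = 1e-9)
    expect_lt(abs(sum(sc[, 1] * sc[, 2])), 1e-8)
    ref <- prcomp(X, scale. = TRUE)$x[, 1:2]
    # align signs before comparison (conventions differ)
    for (j in 1:2) if (sign(ref[1, j]) != sign(sc[1, j])) ref[, j] <- -ref[, j]
    expect_equal(unname(sc), unname(ref), tolerance = 1e-8)
    # exactly collinear data: PC1 captures everything
    line <- outer(seq(-2, 2, length.out = 9), c(1, 2, 3, 4, 5))
    scl <- pcaScores(line, 2)
    expect_lt(max(abs(scl[, 2])), 1e-8)
  })
})

test_that("general features reproduce hand-computed moments", {
  ep <- makeEpoch(matrix(c(1, 2, 3), 1, 3))
  gf <- generalFeatures(ep)
  expect_equal(unname(gf[1, ]), c(2, 2 / 3, 3, 1, 0))
  # symmetric data: skewness vanishes
  eps <- makeEpoch(matrix(c(-2, -1, 0, 1, 2), 1, 5))
  expect_lt(abs(generalFeatures(eps)[1, "skewness"]), 1e-9)
  expect_warning(gfc <- generalFeatures(makeEpoch(matrix(7, 1, 10))),
                 "zero-variance")
  expect_equal(unname(gfc[1, ]), c(7, 0, 7, 7, 0))
})

test_that("the stage-separation report separates synthetic stages", {
  cfg <- generatorConfig(duration = 20, seed = 17)
  byStage <- lapply(setNames(STAGES, STAGES), function(st) {
    rec <- generateRecording(st, cfg)
    extractFeatureList(preprocessRecording(rec, 1, bandSpec()))
  })
  rep_ <- stageSeparationReport(byStage)
  expect_identical(rep_$table$measure, MEASURES)
  expect_true(all(rep_$table$p < 1e-6))
  expect_true(all(rep_$table$diff_normal_acute > 0))
  expect_identical(nrow(rep_$pca), 3L * 20L * 8L)
  expect_error(stageSeparationReport(byStage[1:2]), "three stages")
})

test_that("permuted stage labels give approximately uniform ANOVA p-values", {
  withr::with_seed(33, {
    # pooled values with no real group structure after permutation
    vals <- rnorm(240)
    frac <- mean(replicate(200, {
      lab <- sample(rep(1:3, each = 80))
      oneWayAnova(split(vals, lab))$p < 0.05
    }))
    expect_lt(abs(frac - 0.05), 0.03)
  })
})
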