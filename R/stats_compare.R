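# Statistical comparison layer: one-way ANOVA across stages, Tukey HSD
# pairwise comparisons, correlation-matrix PCA scores, and the "general"
# moment features used as the complexity features' baseline.
#
# ANOVA and Tukey are computed from textbook sums of squares with pf() /
# ptukey() as the distribution backend, so small examples can be checked
# by hand; aov()/TukeyHSD() serve as independent cross-checks in the test
# suite, never as the implementation.

#' One-way ANOVA across stage groups
#'
#' Classical between/within mean-square ratio with (k - 1, N - k) degrees
#' of freedom; the p-value is the upper tail of the F distribution.
#'
#' @param groups list of numeric vectors (>= 2 groups of >= 2 values).
#' @return List with \code{F}, \code{p}, \code{df} and the sums of squares.
#' @export
oneWayAnova <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) < 2L))
    stop("need >= 2 groups with >= 2 values each")
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  gm <- mean(unlist(groups))
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw == 0 && ssb == 0)
    stop("degenerate input: no variance between or within groups")
  if (ssw == 0)
    stop("degenerate input: zero within-group variance in every group")
  msb <- ssb / (k - 1); msw <- ssw / (N - k)
  Fst <- msb / msw
  list(F = Fst, p = stats::pf(Fst, k - 1, N - k, lower.tail = FALSE),
       df = c(k - 1, N - k), ssb = ssb, ssw = ssw)
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range adjusted p-values for every group pair; mean
#' differences are signed first minus second in the given group order.
#'
#' @param groups named list of numeric vectors (stage order is the list
#'   order, canonically normal, acute, chronic).
#' @return data.frame with columns \code{pair}, \code{diff}, \code{p_adj}.
#' @export
tukeyHSD <- function(groups) {
  av <- oneWayAnova(groups)
  k <- length(groups)
  n <- lengths(groups)
  msw <- av$ssw / av$df[2]
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  means <- vapply(groups, mean, numeric(1))
  pairs <- utils::combn(k, 2)
  out <- data.frame(pair = character(), diff = numeric(), p_adj = numeric())
  for (c_ in seq_len(ncol(pairs))) {
    i <- pairs[1, c_]; j <- pairs[2, c_]
    se <- sqrt(msw / 2 * (1 / n[i] + 1 / n[j]))
    q <- abs(means[i] - means[j]) / se
    p <- stats::ptukey(q, nmeans = k, df = av$df[2], lower.tail = FALSE)
    out <- rbind(out, data.frame(pair = paste(nm[i], nm[j], sep = "-"),
                                 diff = means[i] - means[j], p_adj = p))
  }
  out
}

#' Principal-component scores from the correlation matrix
#'
#' Columns are standardised (correlation PCA), projected onto the top
#' eigenvectors of the sample correlation matrix. Sign convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param X numeric matrix, samples x features (>= 2 samples).
#' @param nComponents number of score columns to return.
#' @return Matrix of scores, samples x nComponents (columns centred and
#'   mutually orthogonal).
#' @export
pcaScores <- function(X, nComponents = 2) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need >= 2 samples")
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, colMeans(X)), 2, sdv, "/")
  R <- stats::cor(Z)
  R[!is.finite(R)] <- 0; diag(R) <- 1
  eg <- eigen(R, symmetric = TRUE)
  V <- eg$vectors[, seq_len(nComponents), drop = FALSE]
  for (j in seq_len(ncol(V)))
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  Z %*% V
}

#' Per-channel moment ("general") features of an epoch
#'
#' Mean, variance, maximum, minimum and skewness per channel. Variance
#' uses the population (1/n) convention, consistent with the moment
#' definition of skewness \code{m3 / m2^(3/2)}; a zero-variance channel
#' gets skewness 0 with a warning.
#'
#' @param epoch an [Epoch-class] with channel length >= 3.
#' @return Matrix channels x 5 with columns mean, variance, max, min,
#'   skewness.
#' @export
generalFeatures <- function(epoch) {
  stopifnot(is(epoch, "Epoch"))
  x <- epoch@data
  if (ncol(x) < 3L) stop("channel length must be >= 3")
  out <- t(apply(x, 1, function(v) {
    mu <- mean(v)
    m2 <- mean((v - mu)^2)
    m3 <- mean((v - mu)^3)
    if (m2 == 0) {
      warning("zero-variance channel: skewness set to 0")
      sk <- 0
    } else sk <- m3 / m2^1.5
    c(mean = mu, variance = m2, max = max(v), min = min(v), skewness = sk)
  }))
  rownames(out) <- epoch@channelNames
  out
}

#' Stage-separation report
#'
#' For each complexity measure, pools the values over epochs and channels
#' per stage and reports the Tukey mean differences and adjusted p-values
#' for normal-acute and normal-chronic, plus the ANOVA F statistic and
#' p-value -- one row per measure. Two-component PCA scores of the pooled
#' per-epoch-channel feature vectors are attached for plotting.
#'
#' @param featuresByStage named list (normal/acute/chronic) of lists of
#'   [FeatureMatrix-class] objects.
#' @return List with \code{table} (data.frame, one row per measure) and
#'   \code{pca} (data.frame of 2-PC scores with stage labels).
#' @export
stageSeparationReport <- function(featuresByStage) {
  if (!all(STAGES %in% names(featuresByStage)))
    stop("featuresByStage must contain all three stages")
  pooled <- lapply(featuresByStage, function(fms)
    do.call(rbind, lapply(fms, featureValues)))
  tab <- NULL
  for (m in seq_along(MEASURES)) {
    groups <- lapply(pooled, function(p) p[, m])[STAGES]
    av <- oneWayAnova(groups)
    tk <- tukeyHSD(groups)
    na <- tk[tk$pair == "normal-acute", ]
    nc <- tk[tk$pair == "normal-chronic", ]
    tab <- rbind(tab, data.frame(
      measure = MEASURES[m],
      diff_normal_acute = na$diff, p_normal_acute = na$p_adj,
      diff_normal_chronic = nc$diff, p_normal_chronic = nc$p_adj,
      F = av$F, p = av$p))
  }
  X <- do.call(rbind, pooled[STAGES])
  lab <- rep(STAGES, vapply(pooled[STAGES], nrow, integer(1)))
  sc <- pcaScores(X, 2)
  list(table = tab,
       pca = data.frame(PC1 = sc[, 1], PC2 = sc[, 2], stage = lab))
}
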