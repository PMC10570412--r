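# Complete-graph samples and dataset splitting.
#
# Every epoch becomes the same K8 topology -- unit edges between all
# channel pairs, no self-loops -- so the classifier sees differences only
# through the node features. Self-connection enters later through the
# identity terms of the Chebyshev filter, not through the adjacency.

#' Build a complete-graph sample from a feature matrix
#'
#' @param fm a [FeatureMatrix-class] with 8 rows and a known stage.
#' @return A [GraphSample-class]: K8 adjacency (28 undirected unit edges),
#'   node features = the complexity values, label from the stage.
#' @export
buildGraph <- function(fm) {
  stopifnot(is(fm, "FeatureMatrix"))
  if (nrow(fm@values) != 8L)
    stop("feature matrix must have 8 channel rows, got ", nrow(fm@values))
  if (!(fm@stage %in% STAGES))
    stop("cannot label a graph from stage '", fm@stage, "'")
  A <- matrix(1, 8, 8); diag(A) <- 0
  new("GraphSample", adjacency = A, nodeFeatures = fm@values,
      label = stageToLabel(fm@stage), subjectId = fm@subjectId,
      epochIndex = fm@epochIndex)
}

#' Stratified train/validation/test split
#'
#' Deterministically shuffles and partitions the samples. With
#' \code{stratify} the ratios are applied within each class (largest
#' remainder rounding), so per-class proportions are within one sample of
#' the requested ratios; the three sets are disjoint and their union is
#' the input.
#'
#' @param samples list of [GraphSample-class] objects.
#' @param ratios train/validation/test fractions summing to 1.
#' @param seed shuffle seed.
#' @param stratify split within class (default) or globally.
#' @return A [DatasetSplit-class].
#' @export
splitDataset <- function(samples, ratios = c(0.5, 0.2, 0.3), seed = 1,
                         stratify = TRUE) {
  if (!length(samples)) stop("no samples to split")
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8)
    stop("ratios must be three fractions summing to 1")
  labels <- vapply(samples, function(s) s@label, integer(1))
  idxSets <- list(integer(), integer(), integer())
  groups <- if (stratify) split(seq_along(samples), labels)
            else list(seq_along(samples))
  g <- 0L
  for (grp in groups) {
    g <- g + 1L
    perm <- withr::with_seed(deriveSeed(seed, g),
                             grp[sample.int(length(grp))])
    sizes <- largestRemainder(length(perm), ratios)
    ends <- cumsum(sizes)
    starts <- c(1L, head(ends, -1L) + 1L)
    for (k in 1:3)
      if (sizes[k] > 0)
        idxSets[[k]] <- c(idxSets[[k]], perm[starts[k]:ends[k]])
  }
  new("DatasetSplit",
      train = samples[sort(idxSets[[1]])],
      validation = samples[sort(idxSets[[2]])],
      test = samples[sort(idxSets[[3]])],
      ratios = as.numeric(ratios), seed = as.integer(seed),
      featureMeans = numeric(), featureSds = numeric())
}

# integer allocation of n into round(n * ratios) preserving the total
largestRemainder <- function(n, ratios) {
  raw <- n * ratios
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_ <- order(raw - base, decreasing = TRUE)
    base[order_[seq_len(rem)]] <- base[order_[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Standardise node features with training-set statistics
#'
#' Per-feature mean and SD are computed on the training set only and
#' applied to all three sets (no leakage); the parameters are stored on
#' the split for later inference. A zero-variance feature has its SD
#' replaced by 1 with a warning.
#'
#' @param split a [DatasetSplit-class] with a non-empty training set.
#' @return The standardised [DatasetSplit-class].
#' @export
standardizeFeatures <- function(split) {
  stopifnot(is(split, "DatasetSplit"))
  if (!length(split@train)) stop("training set is empty")
  trainMat <- do.call(rbind, lapply(split@train, function(s) s@nodeFeatures))
  mu <- colMeans(trainMat)
  sdv <- apply(trainMat, 2, stats::sd)
  if (any(sdv == 0)) {
    warning("zero-variance feature(s): SD replaced by 1")
    sdv[sdv == 0] <- 1
  }
  apply1 <- function(s) {
    s@nodeFeatures <- sweep(sweep(s@nodeFeatures, 2, mu), 2, sdv, "/")
    s
  }
  split@train <- lapply(split@train, apply1)
  split@validation <- lapply(split@validation, apply1)
  split@test <- lapply(split@test, apply1)
  split@featureMeans <- mu
  split@featureSds <- sdv
  split
}

#' Export a dataset split as CSV files
#'
#' Writes one node-feature CSV (one row per sample-channel) plus a
#' manifest CSV (sample id, subject, stage, split membership). The K8
#' adjacency is implied by convention and not stored.
#'
#' @param split a [DatasetSplit-class].
#' @param dir output directory (created if needed).
#' @export
exportSplitCSV <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  one <- function(samples, which) {
    if (!length(samples)) return(NULL)
    do.call(rbind, lapply(seq_along(samples), function(i) {
      s <- samples[[i]]
      cbind(data.frame(sample = paste0(which, i), subject = s@subjectId,
                       stage = STAGES[s@label + 1L], split = which,
                       node = seq_len(nrow(s@nodeFeatures))),
            as.data.frame(s@nodeFeatures) |> `colnames<-`(MEASURES))
    }))
  }
  all <- rbind(one(split@train, "train"), one(split@validation, "validation"),
               one(split@test, "test"))
  utils::write.csv(all, file.path(dir, "node_features.csv"),
                   row.names = FALSE)
  man <- unique(all[, c("sample", "subject", "stage", "split")])
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
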