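# The five complexity measures. Fast C++ implementations live in
# src/complexity.cpp; these wrappers validate arguments and document the
# conventions (natural logs, Chebyshev distance, tolerance in absolute
# units).

#' Approximate entropy (Pincus)
#'
#' \code{Phi^m(r) - Phi^(m+1)(r)} with \code{Phi^m} the mean natural log of
#' the fraction of length-m templates within Chebyshev distance \code{r},
#' self-match included.
#'
#' @param x numeric sequence, length > m + 1.
#' @param m embedding dimension.
#' @param r tolerance in absolute signal units (scale by the SD yourself,
#'   or use [extractFeatures()] which applies \code{r_frac * SD}).
#' @return ApEn value (0 for a constant sequence).
#' @export
approxEntropy <- function(x, m = 2, r) {
  if (length(x) <= m + 1) stop("sequence too short: need length > m + 1")
  assertScalarNum(r, "r", positive = TRUE)
  .apen_cpp(as.numeric(x), as.integer(m), r)
}

#' Sample entropy (Richman-Moorman)
#'
#' \code{-ln(A/B)} where B counts template pairs (i < j, self-matches
#' excluded) matching at length m and A those also matching at length
#' m + 1. Returns \code{+Inf} when A = 0 (no m+1 matches); errors when
#' B = 0 (undefined).
#'
#' @inheritParams approxEntropy
#' @export
sampleEntropy <- function(x, m = 2, r) {
  if (length(x) <= m + 1) stop("sequence too short: need length > m + 1")
  assertScalarNum(r, "r", positive = TRUE)
  .sampen_cpp(as.numeric(x), as.integer(m), r)
}

#' Permutation entropy (Bandt-Pompe)
#'
#' Shannon entropy (natural log) of the empirical ordinal-pattern
#' distribution of the \code{order}-length, \code{delay}-spaced embedded
#' subsequences. Ties are broken by order of occurrence (earlier index
#' ranked lower). When \code{normalize} the value is divided by
#' \code{ln(order!)} so it lies in [0, 1].
#'
#' @param x numeric sequence of length at least
#'   \code{(order - 1) * delay + 1}.
#' @param order ordinal pattern length (>= 2).
#' @param delay embedding delay (>= 1).
#' @param normalize divide by \code{ln(order!)}.
#' @export
permutationEntropy <- function(x, order = 3, delay = 1, normalize = TRUE) {
  if (length(x) < (order - 1) * delay + 1)
    stop("sequence too short for the requested order/delay")
  .pe_cpp(as.numeric(x), as.integer(order), as.integer(delay),
          isTRUE(normalize))
}

#' Fuzzy entropy (Chen)
#'
#' Templates are baseline-removed (their mean subtracted); similarity of a
#' pair is the fuzzy membership \code{exp(-(d/r)^n)} of their Chebyshev
#' distance d. The value is \code{ln(phi^m) - ln(phi^(m+1))} with
#' \code{phi} the mean pairwise similarity (i != j).
#'
#' @inheritParams approxEntropy
#' @param n fuzzy membership exponent (> 0).
#' @export
fuzzyEntropy <- function(x, m = 2, r, n = 2) {
  if (length(x) <= m + 1) stop("sequence too short: need length > m + 1")
  assertScalarNum(r, "r", positive = TRUE)
  assertScalarNum(n, "n", positive = TRUE)
  .fuzzen_cpp(as.numeric(x), as.integer(m), r, n)
}

#' Kolmogorov (Lempel-Ziv) complexity
#'
#' The sequence is binarised at its median (strictly greater -> 1) and
#' parsed by the Lempel-Ziv-76 exhaustive-history scan. An all-equal
#' sequence binarises to all zeros and returns the parse of the constant
#' string (phrase count 2 for length >= 2); this is documented behaviour,
#' not an error.
#'
#' @param x numeric sequence, length >= 2.
#' @param normalize return \code{c(n) * log2(n) / n} instead of the raw
#'   phrase count \code{c(n)}.
#' @export
kolmogorovComplexity <- function(x, normalize = TRUE) {
  n <- length(x)
  if (n < 2) stop("sequence too short: need length >= 2")
  b <- as.integer(x > stats::median(x))
  cc <- .lz76_cpp(b)
  if (normalize) cc * log2(n) / n else as.numeric(cc)
}

#' Complexity parameter set
#'
#' Defaults follow the dominant conventions of the EEG-entropy literature:
#' embedding dimension 2, tolerance 0.2 x SD, ordinal order 3 with delay 1,
#' fuzzy exponent 2, normalised PE and KC. \code{sampen_cap} replaces
#' sample entropy's +Inf/undefined sentinel so feature matrices stay
#' finite for the classifier.
#'
#' @param m_embed embedding dimension for ApEn/SampEn/FuzzEn.
#' @param r_frac tolerance as a fraction of the per-channel SD.
#' @param pe_order,pe_delay ordinal pattern length and delay.
#' @param fuzz_power fuzzy membership exponent.
#' @param pe_normalize,kc_normalize normalisation switches.
#' @param sampen_cap finite stand-in for undefined sample entropy.
#' @export
complexityParams <- function(m_embed = 2, r_frac = 0.2, pe_order = 3,
                             pe_delay = 1, fuzz_power = 2,
                             pe_normalize = TRUE, kc_normalize = TRUE,
                             sampen_cap = 10) {
  stopifnot(m_embed >= 1, r_frac > 0, pe_order >= 2, pe_delay >= 1,
            fuzz_power > 0, sampen_cap > 0)
  list(m_embed = as.integer(m_embed), r_frac = r_frac,
       pe_order = as.integer(pe_order), pe_delay = as.integer(pe_delay),
       fuzz_power = fuzz_power, pe_normalize = isTRUE(pe_normalize),
       kc_normalize = isTRUE(kc_normalize), sampen_cap = sampen_cap)
}

#' Extract the five complexity features of an epoch
#'
#' Computes ApEn, SampEn, PE, FuzzEn and KC for every channel of the
#' epoch. The entropy tolerance is \code{r_frac} times the per-channel
#' sample SD; sample entropy's undefined/infinite cases are mapped to
#' \code{params$sampen_cap} (with this documented cap the matrix is always
#' finite).
#'
#' @param epoch an [Epoch-class] (or channels-x-samples matrix plus
#'   metadata arguments).
#' @param params a [complexityParams()] list.
#' @return A [FeatureMatrix-class], channels x 5, column order
#'   ApEn, SampEn, PE, FuzzEn, KC.
#' @export
extractFeatures <- function(epoch, params = complexityParams()) {
  stopifnot(is(epoch, "Epoch"))
  vals <- .features_cpp(epoch@data, params$m_embed, params$r_frac,
                        params$pe_order, params$pe_delay,
                        params$pe_normalize, params$fuzz_power,
                        params$kc_normalize, params$sampen_cap)
  new("FeatureMatrix", values = vals, measureNames = MEASURES,
      channelNames = epoch@channelNames, stage = epoch@stage,
      subjectId = epoch@subjectId, epochIndex = epoch@index)
}

#' Extract features for a list of epochs
#'
#' @param epochs list of [Epoch-class] objects.
#' @param params a [complexityParams()] list.
#' @return List of [FeatureMatrix-class] objects.
#' @export
extractFeatureList <- function(epochs, params = complexityParams()) {
  lapply(epochs, extractFeatures, params = params)
}

#' Write feature matrices to CSV
#'
#' One row per channel per epoch: subject, stage, epoch index, channel,
#' then the five measures.
#'
#' @param fms list of [FeatureMatrix-class] objects.
#' @param path output CSV path.
#' @export
writeFeaturesCSV <- function(fms, path) {
  rows <- lapply(fms, function(fm) {
    data.frame(subject = fm@subjectId, stage = fm@stage,
               epoch = fm@epochIndex, channel = fm@channelNames,
               fm@values |> `colnames<-`(MEASURES),
               check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read feature matrices back from CSV
#'
#' Inverse of [writeFeaturesCSV()].
#'
#' @param path CSV written by [writeFeaturesCSV()].
#' @return List of [FeatureMatrix-class] objects.
#' @export
readFeaturesCSV <- function(path) {
  tab <- tryCatch(utils::read.csv(path, check.names = FALSE),
                  error = function(e)
                    stop("not a feature CSV (", conditionMessage(e), ")",
                         call. = FALSE))
  need <- c("subject", "stage", "epoch", "channel", MEASURES)
  if (!all(need %in% colnames(tab)))
    stop("not a feature CSV: missing columns ",
         paste(setdiff(need, colnames(tab)), collapse = ", "))
  key <- paste(tab$subject, tab$stage, tab$epoch)
  lapply(split(seq_len(nrow(tab)), factor(key, levels = unique(key))),
         function(idx) {
    d <- tab[idx, ]
    new("FeatureMatrix", values = as.matrix(d[, MEASURES]),
        measureNames = MEASURES, channelNames = as.character(d$channel),
        stage = d$stage[1], subjectId = as.character(d$subject[1]),
        epochIndex = as.integer(d$epoch[1]))
  })
}
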