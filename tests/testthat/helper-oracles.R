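# Independent brute-force oracles for the complexity measures and the
# graph convolution. These deliberately use different code paths from the
# package implementations (dense distance matrices, string searching,
# explicit polynomial expansion) so agreement is meaningful.

# Chebyshev distance matrix between all length-m templates of x
chebDistMatrix <- function(x, m, nTemplates) {
  D <- matrix(0, nTemplates, nTemplates)
  for (k in 0:(m - 1)) {
    v <- x[(1:nTemplates) + k]
    D <- pmax(D, abs(outer(v, v, "-")))
  }
  D
}

oracleApEn <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    nt <- N - mm + 1
    D <- chebDistMatrix(x, mm, nt)
    C <- rowMeans(D <= r)          # self-match on the diagonal included
    mean(log(C))
  }
  phi(m) - phi(m + 1)
}

oracleSampEn <- function(x, m, r) {
  N <- length(x)
  nt <- N - m                      # same template count at both lengths
  count <- function(mm) {
    D <- chebDistMatrix(x, mm, nt)
    (sum(D <= r) - nt) / 2         # unordered pairs, self excluded
  }
  B <- count(m); A <- count(m + 1)
  if (B == 0) return(NaN)
  if (A == 0) return(Inf)
  -log(A / B)
}

oracleFuzzEn <- function(x, m, r, n) {
  N <- length(x)
  nt <- N - m
  phi <- function(mm) {
    E <- sapply(0:(mm - 1), function(k) x[(1:nt) + k])
    E <- E - rowMeans(E)           # baseline removal
    D <- matrix(0, nt, nt)
    for (k in seq_len(mm)) D <- pmax(D, abs(outer(E[, k], E[, k], "-")))
    S <- exp(-(D / r)^n)
    (sum(S) - nt) / (nt * (nt - 1))
  }
  log(phi(m)) - log(phi(m + 1))
}

oraclePE <- function(x, order, delay, normalize) {
  nPat <- length(x) - (order - 1) * delay
  pats <- vapply(seq_len(nPat), function(t) {
    paste(rank(x[t + (0:(order - 1)) * delay], ties.method = "first"),
          collapse = "-")
  }, "")
  p <- as.numeric(table(pats)) / nPat
  H <- -sum(p * log(p))
  if (normalize) H / log(factorial(order)) else H
}

# literal exhaustive-history LZ76 parse via substring search
oracleLZ76 <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  if (n == 1) return(1L)
  cc <- 1L; i <- 1L
  while (i < n) {
    k <- 1L
    while (i + k <= n &&
           grepl(substr(s, i + 1, i + k), substr(s, 1, i + k - 1),
                 fixed = TRUE))
      k <- k + 1L
    cc <- cc + 1L
    if (i + k > n) break
    i <- i + k
  }
  cc
}

medianBinarize <- function(x) as.integer(x > median(x))

# dense Chebyshev-polynomial graph convolution: literal expansion
oracleChebConv <- function(x, Lt, W) {
  K <- dim(W)[1]; Cin <- dim(W)[2]; O <- dim(W)[3]
  B <- dim(x)[1]; N <- dim(x)[3]; F_ <- dim(x)[4]
  Tk <- list(diag(N))
  if (K >= 2) Tk[[2]] <- Lt
  if (K >= 3) for (k in 3:K) Tk[[k]] <- 2 * Lt %*% Tk[[k - 1]] - Tk[[k - 2]]
  y <- array(0, c(B, O, N, F_))
  for (b in seq_len(B)) for (o in seq_len(O)) for (f in seq_len(F_))
    for (k in seq_len(K)) for (ci in seq_len(Cin))
      y[b, o, , f] <- y[b, o, , f] + W[k, ci, o] * (Tk[[k]] %*% x[b, ci, , f])
  y
}

# small helpers used across test files
makeEpoch <- function(data, fs = 1000, stage = "normal", index = 1L,
                      subject = "s1") {
  new("Epoch", data = data, fs = fs, index = as.integer(index),
      channelNames = paste0("ch", seq_len(nrow(data))), stage = stage,
      subjectId = subject)
}

makeFeatureMatrix <- function(values, stage = "normal", subject = "s1",
                              index = 1L) {
  new("FeatureMatrix", values = values, measureNames = MEASURES,
      channelNames = paste0("ch", seq_len(nrow(values))), stage = stage,
      subjectId = subject, epochIndex = as.integer(index))
}

# toy linearly-separable graph samples: three well-separated random class
# centres in feature space (margin ~ offset * sqrt(80) >> noise)
makeToyGraphs <- function(nPerClass = 60, offset = 6, noise = 0.3,
                          seed = 1) {
  withr::with_seed(seed, {
    out <- list()
    centers <- lapply(1:3, function(k) matrix(rnorm(40, 0, offset), 8, 5))
    for (cls in 0:2) {
      for (i in seq_len(nPerClass)) {
        vals <- centers[[cls + 1]] + matrix(rnorm(40, 0, noise), 8, 5)
        out[[length(out) + 1]] <- buildGraph(
          makeFeatureMatrix(vals, stage = STAGES[cls + 1], index = i))
      }
    }
    out
  })
}
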