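# Synthetic stage-labelled EEG generator.
#
# Surrogate model per channel: white Gaussian noise + 1/f-shaped noise
# (together carrying noise_sd^2 variance) + Poisson-timed Hann-windowed
# sinusoidal bursts inside the fast-ripple band (250-500 Hz). The stage
# controls burst density, amplitude and temporal coverage, which moves the
# band-limited complexity in the direction seen during epileptogenesis:
# normal most irregular, acute most regular (high-amplitude rhythm),
# chronic slightly less irregular than normal. Channels share stage
# parameters but use independent noise.

# fraction of the noise variance given to the 1/f component
PINK_FRACTION <- 0.3

#' Default per-stage generator parameters
#'
#' Parameters are chosen so that, after fast-ripple band extraction and
#' sample-entropy summarisation, mean complexity orders
#' normal > chronic > acute, with the normal-chronic gap small relative to
#' the normal-acute gap. \code{regularity} is the expected fraction of time
#' covered by rhythmic bursts; each burst lasts
#' \code{regularity / burst_rate} seconds so coverage equals regularity.
#'
#' @param stage \code{"normal"}, \code{"acute"} or \code{"chronic"}.
#' @return A list with fields \code{stage}, \code{noise_sd} (microvolts),
#'   \code{burst_rate} (bursts/s), \code{burst_freq} (Hz, in 250-500),
#'   \code{burst_amp} (microvolts) and \code{regularity} (0..1).
#' @export
defaultStageParams <- function(stage) {
  assertStage(stage)
  switch(stage,
    normal  = stageParams("normal",  noise_sd = 50, burst_rate = 0.1,
                          burst_freq = 320, burst_amp = 30,
                          regularity = 0.01),
    acute   = stageParams("acute",   noise_sd = 50, burst_rate = 4,
                          burst_freq = 380, burst_amp = 400,
                          regularity = 0.95),
    chronic = stageParams("chronic", noise_sd = 50, burst_rate = 15,
                          burst_freq = 300, burst_amp = 55,
                          regularity = 0.5))
}

#' Construct (and validate) a stage parameter set
#' @param stage stage name.
#' @param noise_sd broadband noise SD, microvolts (> 0).
#' @param burst_rate Poisson burst rate, bursts per second.
#' @param burst_freq burst carrier frequency, Hz; must lie in 250-500.
#' @param burst_amp burst peak amplitude, microvolts.
#' @param regularity expected fraction of time covered by rhythm, in [0,1].
#' @export
stageParams <- function(stage, noise_sd, burst_rate, burst_freq, burst_amp,
                        regularity) {
  assertStage(stage)
  assertScalarNum(noise_sd, "noise_sd", positive = TRUE)
  if (regularity < 0 || regularity > 1)
    stop("regularity must be in [0, 1]")
  if (burst_freq < 250 || burst_freq > 500)
    stop("burst_freq must lie within the 250-500 Hz band")
  list(stage = stage, noise_sd = noise_sd, burst_rate = burst_rate,
       burst_freq = burst_freq, burst_amp = burst_amp,
       regularity = regularity)
}

#' Generator configuration
#'
#' Defaults emulate the study recordings: 8 channels, 1000 Hz, 600 s
#' (600,000 samples per channel).
#'
#' @param fs sampling rate, Hz.
#' @param duration recording length, seconds; \code{fs * duration} must be
#'   an integer.
#' @param nChannels number of channels.
#' @param seed master seed; all randomness fans out deterministically.
#' @param params named list of per-stage parameter sets.
#' @export
generatorConfig <- function(fs = 1000, duration = 600, nChannels = 8,
                            seed = 42,
                            params = list(normal = defaultStageParams("normal"),
                                          acute = defaultStageParams("acute"),
                                          chronic = defaultStageParams("chronic"))) {
  assertScalarNum(fs, "fs", positive = TRUE)
  assertScalarNum(duration, "duration", positive = TRUE)
  n <- fs * duration
  if (abs(n - round(n)) > 1e-9)
    stop("fs * duration must be an integer sample count")
  list(fs = fs, duration = duration, nChannels = as.integer(nChannels),
       seed = as.integer(seed), params = params)
}

# 1/f-shaped noise with unit SD, via spectral shaping of white noise
pinkNoise <- function(n) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k)          # symmetric frequency index
  scale <- ifelse(f == 0, 0, 1 / sqrt(f))
  p <- Re(stats::fft(W * scale, inverse = TRUE)) / n
  p / stats::sd(p)
}

#' Generate one stage-labelled synthetic recording
#'
#' @param stage stage to emulate.
#' @param cfg a [generatorConfig()].
#' @param subjectId subject identifier attached to the recording.
#' @return An [EEGRecording-class] with \code{fs * duration} samples per
#'   channel. Deterministic for a fixed \code{cfg$seed}.
#' @examples
#' cfg <- generatorConfig(duration = 2)
#' rec <- generateRecording("acute", cfg)
#' @export
generateRecording <- function(stage, cfg = generatorConfig(),
                              subjectId = "sim1") {
  assertStage(stage)
  sp <- cfg$params[[stage]]
  n <- as.integer(round(cfg$fs * cfg$duration))
  stageIdx <- match(stage, STAGES)
  x <- matrix(0, cfg$nChannels, n)
  for (ch in seq_len(cfg$nChannels)) {
    chSeed <- deriveSeed(cfg$seed, stageIdx * 1009L + ch)
    x[ch, ] <- withr::with_seed(chSeed,
      synthChannel(n, cfg$fs, cfg$duration, sp))
  }
  EEGRecording(x, fs = cfg$fs, stage = stage, subjectId = subjectId,
               channelNames = if (cfg$nChannels == 8L) CHANNELS
                              else paste0("ch", seq_len(cfg$nChannels)))
}

synthChannel <- function(n, fs, duration, sp) {
  sig <- stats::rnorm(n, 0, sp$noise_sd * sqrt(1 - PINK_FRACTION))
  if (PINK_FRACTION > 0)
    sig <- sig + sp$noise_sd * sqrt(PINK_FRACTION) * pinkNoise(n)
  if (sp$burst_amp > 0 && sp$regularity > 0 && sp$burst_rate > 0) {
    burstLen <- min(sp$regularity / sp$burst_rate, duration)
    L <- max(8L, as.integer(round(burstLen * fs)))
    env <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = L)))  # Hann
    nb <- stats::rpois(1L, sp$burst_rate * duration)
    if (nb > 0) {
      onsets <- sort(as.integer(floor(stats::runif(nb, 0, n - L))) + 1L)
      phases <- stats::runif(nb, 0, 2 * pi)
      tt <- seq_len(L) / fs
      for (b in seq_len(nb)) {
        idx <- onsets[b]:(onsets[b] + L - 1L)
        sig[idx] <- sig[idx] + sp$burst_amp * env *
          sin(2 * pi * sp$burst_freq * tt + phases[b])
      }
    }
  }
  sig
}

#' Generate a balanced stage-labelled dataset
#'
#' @param cfg a [generatorConfig()].
#' @param recordingsPerStage recordings per stage (>= 1).
#' @param subjectId subject identifier shared by all recordings.
#' @return A list of [EEGRecording-class] in stage-major order
#'   (normal, acute, chronic) x recordings, each with a distinct derived
#'   seed; byte-identical on repeat for a fixed \code{cfg$seed}.
#' @export
generateDataset <- function(cfg = generatorConfig(), recordingsPerStage = 1,
                            subjectId = "sim1") {
  if (recordingsPerStage < 1) stop("recordingsPerStage must be >= 1")
  out <- vector("list", 3L * recordingsPerStage)
  k <- 0L
  for (r in seq_len(recordingsPerStage)) {
    for (stage in STAGES) {
      k <- k + 1L
      cfg2 <- cfg
      cfg2$seed <- deriveSeed(cfg$seed, 7919L * r + match(stage, STAGES))
      out[[k]] <- generateRecording(stage, cfg2, subjectId = subjectId)
    }
  }
  out
}
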