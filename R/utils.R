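# Internal helpers: deterministic seed fan-out and input checks.

# Derive a child seed from a parent seed and a stream index. Keeps results
# in (0, 2^31 - 2) so they are valid R integer seeds.
deriveSeed <- function(seed, stream) {
  seed <- as.double(seed %% 2147483647L)
  s <- (seed * 48271 + as.double(stream) * 16807 + 12345) %% 2147483629
  as.integer(s) + 1L
}

assertScalarNum <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}

assertStage <- function(stage, allowUnknown = FALSE) {
  ok <- STAGES
  if (allowUnknown) ok <- c(ok, "unknown")
  if (!is.character(stage) || length(stage) != 1L || !(stage %in% ok))
    stop("'stage' must be one of: ", paste(ok, collapse = ", "), call. = FALSE)
  stage
}

stageToLabel <- function(stage) {
  match(assertStage(stage), STAGES) - 1L
}
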