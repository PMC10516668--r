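#' @include AllClasses.R
NULL

.clamp01 <- function(x) pmin(1, pmax(0, x))

.logistic <- function(x) 1 / (1 + exp(-x))

# Stable per-stage seed derivation from one global seed; keeps results
# independently reproducible per stage and below 2^31.
.deriveSeed <- function(seed, stage) {
  offsets <- c(simulate = 11L, render = 23L, score = 37L, correct = 53L,
               combine = 71L, hits = 89L, overlap = 101L, enrich = 113L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else
    sum(utf8ToInt(stage))
  as.integer((as.numeric(seed) * 48271 + off) %% 2147483647)
}

# minimum grid distance of 0-based (row, col) to the plate border
.ringOf <- function(row, col, nRows, nCols) {
  pmin(row, col, nRows - 1L - row, nCols - 1L - col)
}

# interleave offsets (dr, dc) for replicate slots 1..4
.OFFSETS <- cbind(dr = c(0L, 0L, 1L, 1L), dc = c(0L, 1L, 0L, 1L))

.isMissingRecord <- function(records) {
  records$size_px == 0 | is.na(records$yellowness_raw)
}

# grayscale intensity in [0,1] from 0..255 channels (simple channel mean,
# used for both foreground thresholding and the bright-pixel filter)
.grayscale <- function(r, g, b) (r + g + b) / (3 * 255)

.sigfmt <- function(x, digits = 6) {
  ifelse(is.na(x), NA, signif(x, digits))
}
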