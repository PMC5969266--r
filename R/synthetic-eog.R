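# Synthetic EOG generator: recordings with planted blinks, saccade steps in
# the horizontal channel, broadband muscle noise and amplifier-saturation
# dropouts, all with a recoverable ground truth.

#' Describe the ground truth of a synthetic EOG recording
#'
#' Collects the planted events of a to-be-generated recording: blink onsets
#' and amplitudes on the vertical channel, saccade intervals on the horizontal
#' channel, amplifier-saturation intervals, and the broadband noise level.
#'
#' @param blinkOnsets numeric, blink onset times in seconds (strictly
#'   increasing).
#' @param blinkAmplitudes numeric, peak amplitudes in microvolts (positive);
#'   recycled to the number of onsets.
#' @param saccadeIntervals two-column matrix (or NULL) of (start, end) times in
#'   seconds during which the horizontal channel carries a step deflection.
#' @param saturatedIntervals two-column matrix (or NULL) of (start, end) times
#'   during which the vertical channel is clamped at the amplifier rail.
#' @param noiseSd numeric(1), SD of additive Gaussian noise in microvolts.
#' @param seed integer or NULL, seed for the noise stream.
#' @return a list of class `eogGroundTruth`.
#' @export
#' @examples
#' tr <- makeEogTruth(blinkOnsets = c(5, 20), blinkAmplitudes = 400)
makeEogTruth <- function(blinkOnsets = numeric(), blinkAmplitudes = numeric(),
                         saccadeIntervals = NULL, saturatedIntervals = NULL,
                         noiseSd = 10, seed = NULL) {
  asIv <- function(x) {
    if (is.null(x) || length(x) == 0) return(matrix(numeric(), ncol = 2))
    x <- matrix(as.numeric(x), ncol = 2)
    if (any(x[, 2] <= x[, 1])) stop("intervals must have end > start")
    x
  }
  if (is.unsorted(blinkOnsets, strictly = TRUE))
    stop("blink onsets must be strictly increasing")
  if (length(blinkOnsets) > 0) {
    blinkAmplitudes <- rep_len(blinkAmplitudes, length(blinkOnsets))
    if (any(blinkAmplitudes <= 0)) stop("blink amplitudes must be positive")
  } else blinkAmplitudes <- numeric()
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  structure(list(blinkOnsets = as.numeric(blinkOnsets),
                 blinkAmplitudes = as.numeric(blinkAmplitudes),
                 saccadeIntervals = asIv(saccadeIntervals),
                 saturatedIntervals = asIv(saturatedIntervals),
                 noiseSd = noiseSd, seed = seed),
            class = "eogGroundTruth")
}

#' Random blink ground truth for a recording of given duration
#'
#' Draws `nBlinks` onsets uniformly over the recording with a minimum
#' separation of 1 s (so planted events never merge), with amplitudes jittered
#' around `amplitude`.
#'
#' @param nBlinks integer, number of blinks to plant.
#' @param duration numeric, recording length in seconds.
#' @param amplitude numeric, mean blink amplitude in microvolts.
#' @param amplitudeSd numeric, SD of the amplitude jitter.
#' @param noiseSd numeric, broadband noise SD in microvolts.
#' @param seed integer seed.
#' @return an `eogGroundTruth` list as from [makeEogTruth()].
#' @export
randomEogTruth <- function(nBlinks, duration = 360, amplitude = 400,
                           amplitudeSd = 40, noiseSd = 10, seed = NULL) {
  stopifnot(nBlinks >= 0, duration > 0)
  withSeed(seed, {
    onsets <- numeric()
    if (nBlinks > 0) {
      # uniform with >= 1 s separation, keeping room for the 0.4 s waveform
      gap <- duration - 1 - nBlinks * 1
      if (gap <= 0) stop("too many blinks for this duration")
      u <- sort(runif(nBlinks, 0, gap))
      onsets <- 0.5 + u + (seq_len(nBlinks) - 1) * 1
    }
    amps <- pmax(50, rnorm(nBlinks, amplitude, amplitudeSd))
    makeEogTruth(blinkOnsets = onsets, blinkAmplitudes = amps,
                 noiseSd = noiseSd, seed = seed)
  })
}

# Raised-cosine blink waveform: smooth rise to the peak over riseMs, symmetric
# fall; peak amplitude is reached 200 ms after onset with the default width,
# inside the 150-250 ms physiological range.
blinkPulse <- function(tRel, amplitude, widthS = 0.4) {
  out <- numeric(length(tRel))
  inside <- tRel >= 0 & tRel <= widthS
  out[inside] <- amplitude * 0.5 * (1 - cos(2 * pi * tRel[inside] / widthS))
  out
}

#' Generate a two-channel EOG recording from a ground truth
#'
#' Renders a vertical (vEOG) and a horizontal (hEOG) microvolt trace on a
#' uniform grid: each planted blink is a smooth raised-cosine deflection
#' (400 ms wide, peaking 200 ms after onset); saccade intervals carry a
#' +/-200 uV step on hEOG; saturated intervals are clamped at the +500 uV
#' amplifier rail; Gaussian noise of SD `noiseSd` is added to both channels.
#' The generated object carries its truth for downstream oracle tests.
#'
#' @param truth an `eogGroundTruth` from [makeEogTruth()] /
#'   [randomEogTruth()].
#' @param duration recording length in seconds (default 360, a 6-min rest
#'   recording).
#' @param rate sampling rate in Hz (default 100).
#' @param railUv amplifier rail in microvolts for saturated stretches.
#' @return an [EogRecording-class] with the truth attached.
#' @export
#' @examples
#' rec <- simulateEog(randomEogTruth(30, seed = 1))
#' rec
simulateEog <- function(truth, duration = 360, rate = 100, railUv = 500) {
  stopifnot(inherits(truth, "eogGroundTruth"), duration > 0, rate > 0)
  widthS <- 0.4
  if (length(truth$blinkOnsets) &&
      any(truth$blinkOnsets < 0 | truth$blinkOnsets + widthS > duration))
    stop("blink events must lie within the recording")
  iv <- rbind(truth$saccadeIntervals, truth$saturatedIntervals)
  if (nrow(iv) && any(iv < 0 | iv > duration))
    stop("artifact intervals must lie within the recording")
  if (nrow(truth$saturatedIntervals) && length(truth$blinkOnsets)) {
    for (i in seq_len(nrow(truth$saturatedIntervals))) {
      s <- truth$saturatedIntervals[i, ]
      if (any(truth$blinkOnsets < s[2] & truth$blinkOnsets + widthS > s[1]))
        stop("blink and saturation intervals overlap")
    }
  }
  n <- round(duration * rate)
  tt <- (seq_len(n) - 1) / rate
  v <- numeric(n)
  for (i in seq_along(truth$blinkOnsets))
    v <- v + blinkPulse(tt - truth$blinkOnsets[i], truth$blinkAmplitudes[i],
                        widthS)
  h <- numeric(n)
  if (nrow(truth$saccadeIntervals)) {
    sgn <- rep_len(c(1, -1), nrow(truth$saccadeIntervals))
    for (i in seq_len(nrow(truth$saccadeIntervals))) {
      s <- truth$saccadeIntervals[i, ]
      h[tt >= s[1] & tt < s[2]] <- sgn[i] * 200
    }
  }
  if (truth$noiseSd > 0) {
    noise <- withSeed(truth$seed, matrix(rnorm(2 * n, 0, truth$noiseSd), 2))
    v <- v + noise[1, ]
    h <- h + noise[2, ]
  }
  if (nrow(truth$saturatedIntervals)) {
    for (i in seq_len(nrow(truth$saturatedIntervals))) {
      s <- truth$saturatedIntervals[i, ]
      v[tt >= s[1] & tt < s[2]] <- railUv
    }
  }
  new("EogRecording", time = tt, veog = v, heog = h, rate = rate,
      truth = unclass(truth))
}
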