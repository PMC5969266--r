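# Blink detection and spontaneous eye blink rate (sEBR).
#
# Processing chain: rectify + band-pass the vertical channel, detect voltage
# rises of >= 100 uV within 400 ms, flag events coincident with horizontal
# (saccade) deflections, measure saturation data loss, and normalize the
# blink count by exploitable recording time.

#' Rectify and band-pass filter the vertical EOG channel
#'
#' Removes the median, takes the absolute value (rectification), then applies
#' a 4th-order Butterworth band-pass (0.5-20 Hz) forward and backward
#' (zero-phase, so event onsets are not delayed by the filter).
#'
#' @param rec an [EogRecording-class], or a numeric vEOG vector if `rate` is
#'   given.
#' @param rate sampling rate in Hz (taken from `rec` when it is a recording).
#' @param band numeric(2), pass band in Hz.
#' @return numeric vector, the filtered signal (same length as input).
#' @export
preprocessVeog <- function(rec, rate = NULL, band = c(0.5, 20)) {
  if (is(rec, "EogRecording")) {
    v <- veog(rec)
    rate <- samplingRate(rec)
  } else {
    v <- as.numeric(rec)
    if (is.null(rate)) stop("rate is required for a bare numeric signal")
  }
  if (rate <= 2 * band[2])
    stop("sampling rate too low: the ", band[2],
         " Hz band edge must be below Nyquist")
  v[!is.finite(v)] <- stats::median(v[is.finite(v)])
  x <- abs(v - stats::median(v))
  bf <- signal::butter(4, band / (rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Trailing running minimum over a w-sample window, vectorized via pmin over
# shifted copies (w is small: 400 ms at 100 Hz = 40 samples).
runningMin <- function(x, w) {
  m <- x
  n <- length(x)
  for (k in seq_len(w - 1))
    m <- pmin(m, c(rep(Inf, k), x[seq_len(n - k)]))
  m
}

#' Detect blinks as threshold voltage rises within a time window
#'
#' An event is triggered wherever the (preprocessed) vertical signal rises by
#' at least `thresholdUv` relative to its minimum over the trailing
#' `windowMs` interval. Trigger runs are merged, events whose onsets fall
#' within the refractory period of the previous event are merged into it, and
#' each event's peak is the local maximum following the trigger. The onset is
#' estimated as the last sample before the peak at which the signal sat
#' within 5% of the event amplitude above the local baseline.
#'
#' @param x numeric filtered vEOG (from [preprocessVeog()]) or an
#'   [EogRecording-class] (preprocessed internally).
#' @param rate sampling rate in Hz (taken from the recording if given).
#' @param thresholdUv detection threshold in microvolts (default 100;
#'   200/300 give the conservative high-specificity modes).
#' @param windowMs rise-time window in milliseconds (default 400).
#' @param refractoryMs minimum onset separation; closer events merge
#'   (default 200).
#' @return data.frame of blink events: `onset`, `peak` (seconds),
#'   `amplitude` (microvolts), `rejected` (logical), `reason` (NA, "saccade"
#'   or "muscle"); sorted by onset.
#' @export
#' @examples
#' rec <- simulateEog(randomEogTruth(10, seed = 1))
#' ev <- detectBlinks(rec)
#' nrow(ev)
detectBlinks <- function(x, rate = NULL, thresholdUv = 100, windowMs = 400,
                         refractoryMs = 200) {
  if (is(x, "EogRecording")) {
    rate <- samplingRate(x)
    x <- preprocessVeog(x)
  }
  if (is.null(rate)) stop("rate is required for a bare numeric signal")
  stopifnot(thresholdUv > 0, windowMs > 0)
  w <- round(windowMs / 1000 * rate)
  if (w < 2) stop("window must span at least 2 samples")
  n <- length(x)
  emptyEv <- data.frame(onset = numeric(), peak = numeric(),
                        amplitude = numeric(), rejected = logical(),
                        reason = character(), stringsAsFactors = FALSE)
  if (n < w) return(emptyEv)
  base <- runningMin(x, w)
  rise <- x - base
  trig <- which(rise >= thresholdUv & c(TRUE, rise[-n] < thresholdUv))
  if (!length(trig)) return(emptyEv)
  refr <- refractoryMs / 1000
  onsets <- peaks <- amps <- numeric()
  lastOnset <- -Inf
  for (i in trig) {
    span <- i:min(n, i + w)
    p <- span[which.max(x[span])]
    # baseline and onset are anchored at the peak, not the trigger, so the
    # estimated event times do not depend on the detection threshold
    pre <- max(1, p - w):p
    b0 <- min(x[pre])
    amp <- x[p] - b0
    below <- pre[x[pre] <= b0 + 0.05 * amp]
    on <- if (length(below)) max(below) else max(1, i - 1)
    onT <- (on - 1) / rate
    if (onT - lastOnset < refr && length(onsets)) {
      # refractory merge: extend the previous event if this peak is higher
      j <- length(onsets)
      if (amp > amps[j]) {
        peaks[j] <- (p - 1) / rate
        amps[j] <- amp
      }
      next
    }
    onsets <- c(onsets, onT)
    peaks <- c(peaks, (p - 1) / rate)
    amps <- c(amps, amp)
    lastOnset <- onT
  }
  ord <- order(onsets)
  data.frame(onset = onsets[ord], peak = peaks[ord], amplitude = amps[ord],
             rejected = FALSE, reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Flag blink events coincident with horizontal-channel deflections
#'
#' Implements the artifact-exclusion step usually performed by visual
#' inspection: any event whose peak falls within +/-100 ms of an hEOG
#' deflection exceeding `heogThresholdUv` (relative to the channel median) is
#' flagged as a rejected saccade artifact. `heogThresholdUv = Inf` disables
#' rejection.
#'
#' @param events blink-event data.frame from [detectBlinks()].
#' @param heog numeric horizontal channel, or an [EogRecording-class].
#' @param rate sampling rate in Hz (from the recording if given).
#' @param heogThresholdUv deflection threshold in microvolts (default 100).
#' @param windowMs half-width of the coincidence window in ms (default 100).
#' @return the events data.frame with `rejected` / `reason` updated.
#' @export
rejectSaccadeArtifacts <- function(events, heog, rate = NULL,
                                   heogThresholdUv = 100, windowMs = 100) {
  if (is(heog, "EogRecording")) {
    rate <- samplingRate(heog)
    heog <- slot(heog, "heog")
  }
  if (is.null(rate)) stop("rate is required for a bare numeric signal")
  if (!nrow(events) || !is.finite(heogThresholdUv)) return(events)
  d <- abs(heog - stats::median(heog, na.rm = TRUE))
  bad <- which(d > heogThresholdUv)
  if (!length(bad)) return(events)
  badT <- (bad - 1) / rate
  halfW <- windowMs / 1000
  for (i in seq_len(nrow(events))) {
    if (any(abs(badT - events$peak[i]) <= halfW)) {
      events$rejected[i] <- TRUE
      events$reason[i] <- "saccade"
    }
  }
  events
}

#' Quantify data loss from amplifier saturation
#'
#' Samples are counted as lost when they are non-finite or sit in a
#' constant-valued run at the amplifier rail (|value| >= `railUv`) longer
#' than `minRunMs` -- the signature of the amplifier exceeding its operating
#' range. Subjects whose loss fraction exceeds 0.5 are flagged for exclusion
#' (strictly greater: exactly half lost is still retained).
#'
#' @param rec an [EogRecording-class].
#' @param railUv amplifier rail magnitude in microvolts (default 500).
#' @param minRunMs minimum constant-run length counted as saturation
#'   (default 100).
#' @return list: `lossFraction`, `exploitableMinutes`,
#'   `exploitableIntervals` (data.frame start/end in seconds), `excluded`
#'   (lossFraction > 0.5), `lostSamples`.
#' @export
assessDataLoss <- function(rec, railUv = 500, minRunMs = 100) {
  stopifnot(is(rec, "EogRecording"))
  v <- veog(rec)
  rate <- samplingRate(rec)
  lost <- !is.finite(v)
  r <- rle(ifelse(is.finite(v), v, NA_real_))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  satRun <- !is.na(r$values) & abs(r$values) >= railUv &
    r$lengths / rate > minRunMs / 1000
  for (j in which(satRun)) lost[starts[j]:ends[j]] <- TRUE
  lossFraction <- mean(lost)
  keep <- rle(!lost)
  kEnds <- cumsum(keep$lengths)
  kStarts <- kEnds - keep$lengths + 1
  okRuns <- which(keep$values)
  intervals <- data.frame(start = (kStarts[okRuns] - 1) / rate,
                          end = kEnds[okRuns] / rate)
  list(lossFraction = lossFraction,
       exploitableMinutes = sum(!lost) / rate / 60,
       exploitableIntervals = intervals,
       excluded = lossFraction > 0.5,
       lostSamples = sum(lost))
}

#' Spontaneous eye blink rate from detected events
#'
#' Blinks per exploitable minute: the count of non-rejected events divided by
#' the exploitable recording time, so subjects with partial data loss are
#' rated over the time actually recorded.
#'
#' @param events blink-event data.frame ([detectBlinks()], optionally after
#'   [rejectSaccadeArtifacts()]).
#' @param exploitableMinutes minutes of usable recording (> 0).
#' @param lossFraction optional data-loss fraction to carry into the result.
#' @return list of class `sebrResult`: `blinkCount`, `exploitableMinutes`,
#'   `rate` (blinks/min), `excluded`, `lossFraction`.
#' @export
#' @examples
#' computeSebr(data.frame(rejected = logical(30)), 6)$rate  # 5 blinks/min
computeSebr <- function(events, exploitableMinutes, lossFraction = NA_real_) {
  if (!is.finite(exploitableMinutes) || exploitableMinutes <= 0)
    stop("subject has no exploitable recording time (excluded)")
  count <- sum(!events$rejected)
  structure(list(blinkCount = count,
                 exploitableMinutes = exploitableMinutes,
                 rate = count / exploitableMinutes,
                 excluded = isTRUE(lossFraction > 0.5),
                 lossFraction = lossFraction),
            class = "sebrResult")
}

#' @export
print.sebrResult <- function(x, ...) {
  cat(sprintf("sEBR: %.2f blinks/min (%d blinks / %.2f min)%s\n", x$rate,
              x$blinkCount, x$exploitableMinutes,
              if (isTRUE(x$excluded)) " [EXCLUDED: >50% data loss]" else ""))
  invisible(x)
}

#' Average two raters' sEBR measures and compute their reliability
#'
#' Per-subject mean of the two raters plus Cronbach's alpha for the two-item
#' (rater) matrix, `alpha = k/(k-1) * (1 - sum(var_items) / var_total)` with
#' k = 2; alpha near 1 means the raters are interchangeable and their average
#' is a faithful consensus measure.
#'
#' @param sebrA,sebrB numeric vectors of per-subject sEBR from each rater
#'   (same subjects, same order; names checked when present).
#' @return list: `sebr` (averaged vector), `alpha` (Cronbach's alpha),
#'   `n` subjects.
#' @export
#' @examples
#' mergeRaters(c(10, 20, 30), c(12, 19, 33))$alpha
mergeRaters <- function(sebrA, sebrB) {
  if (length(sebrA) != length(sebrB))
    stop("raters must score the same subjects")
  if (!is.null(names(sebrA)) && !is.null(names(sebrB)) &&
      !identical(names(sebrA), names(sebrB)))
    stop("rater subject lists differ")
  vt <- stats::var(sebrA + sebrB)
  alpha <- if (vt > 0)
    2 * (1 - (stats::var(sebrA) + stats::var(sebrB)) / vt)
  else NA_real_
  list(sebr = (sebrA + sebrB) / 2, alpha = alpha, n = length(sebrA))
}
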