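# Trace preprocessing: smoothing, truncation at stimulation, downsampling,
# and responder filtering.

#' Moving-average smoothing
#'
#' Centred moving average with a window of `window_s` seconds. Boundary
#' windows are truncated (the mean runs over the points that exist), so no
#' data are fabricated at the edges; output length equals input length.
#' With `align = "trailing"` the window covers the preceding `window_s`
#' points instead.
#'
#' @param x a [CaTraces-class] or a numeric vector (one trace).
#' @param window_s window size in seconds (default 20); must be >= 1 and
#'   no longer than the trace.
#' @param align `"centered"` (default) or `"trailing"`.
#' @return Same type as `x`, smoothed.
#' @export
smoothMovingAverage <- function(x, window_s = 20,
                                align = c("centered", "trailing")) {
    align <- match.arg(align)
    if (is(x, "CaTraces")) {
        dt <- if (length(x@times) > 1) x@times[2] - x@times[1] else 1
        w <- max(1L, round(window_s / dt))
        sm <- t(apply(x@values, 1, .moving_avg, w = w, align = align))
        rownames(sm) <- rownames(x@values)
        return(new("CaTraces", times = x@times, values = sm, kind = x@kind))
    }
    if (!length(x)) stop("empty trace")
    if (window_s > length(x)) stop("window longer than trace")
    .moving_avg(as.numeric(x), max(1L, round(window_s)), align)
}

.moving_avg <- function(v, w, align = "centered") {
    n <- length(v)
    if (n == 0) stop("empty trace")
    if (w <= 1) return(v)
    if (align == "centered") {
        lo <- pmax(1L, seq_len(n) - floor((w - 1) / 2))
        hi <- pmin(n, seq_len(n) + ceiling((w - 1) / 2))
    } else {
        lo <- pmax(1L, seq_len(n) - (w - 1L))
        hi <- seq_len(n)
    }
    cs <- c(0, cumsum(v))
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Truncate at stimulation and downsample the tail
#'
#' Removes all points before `stim_s`, keeps native (1 s) resolution from
#' `stim_s` through `cut_s`, and keeps every `factor`-th point after
#' `cut_s` (the trace is at or near steady state there). On the canonical
#' 1 Hz, 0-1000 s protocol with stimulation at 200 s this yields the
#' 171-point grid t = 200, ..., 300, 310, ..., 1000.
#'
#' @param x a [CaTraces-class] (raw) or numeric vector with `times`.
#' @param stim_s stimulation onset (s), default 200.
#' @param cut_s end of the native-resolution window (s), default 300.
#' @param factor downsampling factor after `cut_s`, default 10.
#' @param times time grid when `x` is a plain vector.
#' @return A [CaTraces-class] of kind `"processed"`.
#' @export
truncateAndDownsample <- function(x, stim_s = 200, cut_s = 300, factor = 10,
                                  times = NULL) {
    if (is(x, "CaTraces")) {
        times <- x@times
        vals <- x@values
    } else {
        if (is.null(times)) stop("'times' required for a plain trace")
        vals <- matrix(as.numeric(x), nrow = 1,
                       dimnames = list("cell_1", NULL))
    }
    if (max(times) < cut_s)
        stop("trace ends before cut_s = ", cut_s)
    if (min(times) > stim_s)
        stop("trace does not cover the stimulation time ", stim_s)
    keep_native <- which(times >= stim_s & times <= cut_s)
    after <- which(times > cut_s)
    keep_tail <- after[seq_along(after) %% factor == 0]
    keep <- c(keep_native, keep_tail)
    new("CaTraces", times = times[keep],
        values = vals[, keep, drop = FALSE], kind = "processed")
}

#' Filter non-responding cells
#'
#' A cell is removed iff its peak height is strictly below `threshold`
#' (equality kept). The default 1.8 separates responders from cells with
#' very low overall responses.
#'
#' @param traces a [CaTraces-class] of processed traces.
#' @param threshold minimum peak height, default 1.8.
#' @return list with `kept` and `removed` ([CaTraces-class] each; the
#'   two partition the input, order preserved).
#' @export
responderFilter <- function(traces, threshold = 1.8) {
    stopifnot(is(traces, "CaTraces"))
    peaks <- peakHeight(traces)
    keep <- peaks >= threshold
    list(kept = new("CaTraces", times = traces@times,
                    values = traces@values[keep, , drop = FALSE],
                    kind = traces@kind),
         removed = new("CaTraces", times = traces@times,
                       values = traces@values[!keep, , drop = FALSE],
                       kind = traces@kind))
}

#' Full preprocessing pipeline for raw traces
#'
#' Smooth (20 s centred moving average), truncate at stimulation,
#' downsample the tail. Responder filtering is a separate step
#' ([responderFilter()]) so callers can inspect what was removed.
#'
#' @param raw a [CaTraces-class] of raw traces.
#' @inheritParams smoothMovingAverage
#' @inheritParams truncateAndDownsample
#' @return A processed [CaTraces-class].
#' @export
#' @examples
#' raw <- caTraces(matrix(rnorm(1001, 2), 1), 0:1000, "raw")
#' length(traceTimes(preprocessTraces(raw)))  # 171
preprocessTraces <- function(raw, window_s = 20, stim_s = 200, cut_s = 300,
                             factor = 10, align = "centered") {
    truncateAndDownsample(smoothMovingAverage(raw, window_s, align),
                          stim_s = stim_s, cut_s = cut_s, factor = factor)
}
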