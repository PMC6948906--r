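#' Signal-time enhancement curve
#'
#' Raw MR signal intensity over a uniform dynamic frame grid, with the
#' injection time recorded so descriptors can be measured from injection
#' rather than from scan start.
#'
#' @param times frame times in seconds, strictly increasing, uniformly
#'   spaced.
#' @param signal signal intensities (arbitrary MR units), finite.
#' @param injection_time bolus injection time in seconds; at least one
#'   frame must precede it.
#' @param frame_interval frame spacing in seconds; defaults to the grid
#'   spacing.
#' @param check_spacing verify uniform spacing (default TRUE).
#' @return an object of class `enhancement_curve`.
#' @examples
#' p <- dce_protocol()
#' enhancement_curve(protocol_times(p), rep(100, p$n_frames),
#'                   injection_time = p$baseline_s)
#' @export
enhancement_curve <- function(times, signal, injection_time = 10,
                              frame_interval = NULL, check_spacing = TRUE) {
  times <- as.numeric(times); signal <- as.numeric(signal)
  if (length(times) != length(signal))
    stop("times and signal must have equal length", call. = FALSE)
  if (length(times) < 2 || any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (!all(is.finite(signal)))
    stop("signal must be finite", call. = FALSE)
  d <- diff(times)
  if (check_spacing && max(d) - min(d) > 1e-6 * mean(d))
    stop("times must be uniformly spaced", call. = FALSE)
  if (is.null(frame_interval)) frame_interval <- d[1]
  if (sum(times < injection_time) < 1)
    stop("at least one pre-injection frame is required", call. = FALSE)
  structure(list(times = times, signal = signal,
                 injection_time = injection_time,
                 frame_interval = frame_interval),
            class = "enhancement_curve")
}

#' @export
print.enhancement_curve <- function(x, ...) {
  cat(sprintf(
    "Enhancement curve: %d frames x %.1f s, injection at %.1f s, signal [%.4g, %.4g]\n",
    length(x$times), x$frame_interval, x$injection_time,
    min(x$signal), max(x$signal)))
  invisible(x)
}

#' @export
plot.enhancement_curve <- function(x, ...) {
  graphics::plot(x$times, x$signal, type = "b", pch = 20,
                 xlab = "time (s)", ylab = "signal intensity", ...)
  graphics::abline(v = x$injection_time, lty = 2, col = "grey40")
  invisible(x)
}

#' Semi-quantitative enhancement-curve descriptors
#'
#' Computes the standard curve descriptors from a signal-time curve:
#' \describe{
#'   \item{si0}{baseline signal, the mean of pre-injection frames.}
#'   \item{si_max}{maximum raw post-injection signal.}
#'   \item{si_peak}{maximum of the 3-point moving-average smoothed curve,
#'     a noise-robust peak (typically slightly below si_max).}
#'   \item{si_end}{signal of the last dynamic frame.}
#'   \item{si_rel}{relative enhancement (si_max - si0)/si0 x 100 (percent).}
#'   \item{ttp}{time to peak, from injection to the si_max frame (s).}
#'   \item{wir}{wash-in rate (si_max - si0)/ttp (signal units per s).}
#'   \item{wor}{wash-out rate (si_max - si_end)/(si_max - si0), a
#'     dimensionless fraction of the enhancement washed out by the final
#'     frame.}
#'   \item{iauc60}{trapezoidal integral of baseline-subtracted signal over
#'     the first 60 s after injection (signal units x s).}
#' }
#' A flat curve (si_max equal to si0) returns ttp, wir and wor of 0 with
#' the `flat` flag set. A zero baseline makes si_rel undefined and is an
#' error.
#'
#' @param curve an [enhancement_curve()].
#' @return an object of class `semiquant_params` (a named list; also
#'   coercible with `as.data.frame`).
#' @examples
#' p <- dce_protocol()
#' t <- protocol_times(p)
#' sig <- ifelse(t < p$baseline_s, 100, 100 + 150 * (1 - exp(-(t - 10) / 40)))
#' compute_descriptors(enhancement_curve(t, sig, p$baseline_s))
#' @export
compute_descriptors <- function(curve) {
  stopifnot(inherits(curve, "enhancement_curve"))
  t <- curve$times; y <- curve$signal
  inj <- curve$injection_time
  pre <- t < inj
  si0 <- mean(y[pre])
  post <- which(!pre)
  si_max <- max(y[post])
  si_end <- y[length(y)]

  if (si0 == 0)
    stop("zero baseline signal: si_rel undefined", call. = FALSE)

  flat <- si_max <= si0
  if (flat) {
    ttp <- 0; wir <- 0; wor <- 0
  } else {
    ipk <- post[which.max(y[post])]
    ttp <- t[ipk] - inj
    wir <- (si_max - si0) / ttp
    wor <- (si_max - si_end) / (si_max - si0)
  }
  si_rel <- (si_max - si0) / si0 * 100

  # 3-point moving average; endpoints keep their 2-point mean
  n <- length(y)
  sm <- y
  if (n >= 3) {
    sm[2:(n - 1)] <- (y[1:(n - 2)] + y[2:(n - 1)] + y[3:n]) / 3
    sm[1] <- mean(y[1:2]); sm[n] <- mean(y[(n - 1):n])
  }
  si_peak <- max(sm[post])

  iauc60 <- .iauc(t, y - si0, from = inj, to = inj + 60)

  structure(list(si0 = si0, si_max = si_max, si_peak = si_peak,
                 si_end = si_end, si_rel = si_rel, ttp = ttp, wir = wir,
                 wor = wor, iauc60 = iauc60, flat = flat),
            class = "semiquant_params")
}

# trapezoidal integral of a sampled curve over [from, to], linearly
# interpolating at the window edges; window clipped to the sampled range
.iauc <- function(t, y, from, to) {
  to <- min(to, max(t))
  from <- max(from, min(t))
  if (to <= from) return(0)
  yf <- stats::approx(t, y, xout = from)$y
  yt <- stats::approx(t, y, xout = to)$y
  inside <- t > from & t < to
  tt <- c(from, t[inside], to)
  yy <- c(yf, y[inside], yt)
  sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2)
}

#' @export
print.semiquant_params <- function(x, ...) {
  cat("Semi-quantitative descriptors:\n")
  cat(sprintf("  SI0 %.4g | SImax %.4g | SIpeak %.4g | SIend %.4g\n",
              x$si0, x$si_max, x$si_peak, x$si_end))
  cat(sprintf("  SIrel %.4g%% | TTP %.4g s | WIR %.4g /s | WOR %.4g | iAUC60 %.6g\n",
              x$si_rel, x$ttp, x$wir, x$wor, x$iauc60))
  if (x$flat) cat("  [flat curve: no enhancement]\n")
  invisible(x)
}

#' @export
as.data.frame.semiquant_params <- function(x, ...) {
  data.frame(si0 = x$si0, si_max = x$si_max, si_peak = x$si_peak,
             si_end = x$si_end, si_rel = x$si_rel, ttp = x$ttp,
             wir = x$wir, wor = x$wor, iauc60 = x$iauc60)
}
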