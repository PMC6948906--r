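#' DCE-MRI acquisition protocol
#'
#' Describes the timing of a dynamic contrast-enhanced series: a uniform
#' frame grid starting at scan time 0, with the contrast bolus injected
#' `baseline_s` seconds into the scan, and a standard gadolinium dose.
#' The default protocol is 50 frames at 7.6 s per frame with a 10 s
#' pre-injection lead and 0.1 mmol/kg gadoterate meglumine.
#'
#' @param frame_interval frame spacing in seconds.
#' @param n_frames number of dynamic frames.
#' @param baseline_s seconds of pre-injection acquisition (injection time).
#' @param dose contrast dose in mmol per kg body weight.
#' @return an object of class `dce_protocol`.
#' @examples
#' p <- dce_protocol()
#' protocol_times(p)[1:5]
#' @export
dce_protocol <- function(frame_interval = 7.6, n_frames = 50,
                         baseline_s = 10, dose = 0.1) {
  stopifnot(frame_interval > 0, n_frames >= 2, baseline_s >= 0, dose > 0)
  if (baseline_s >= frame_interval * (n_frames - 1))
    stop("baseline_s must fall inside the acquisition window", call. = FALSE)
  structure(list(frame_interval = frame_interval, n_frames = n_frames,
                 baseline_s = baseline_s, dose = dose),
            class = "dce_protocol")
}

#' Frame acquisition times of a protocol
#'
#' @param protocol a [dce_protocol()].
#' @return numeric vector of frame times in seconds, starting at 0.
#' @export
protocol_times <- function(protocol) {
  stopifnot(inherits(protocol, "dce_protocol"))
  seq(0, by = protocol$frame_interval, length.out = protocol$n_frames)
}

#' Number of pre-injection (baseline) frames
#'
#' Frames acquired strictly before the injection time.
#'
#' @param protocol a [dce_protocol()].
#' @return integer count, at least 1.
#' @export
n_baseline_frames <- function(protocol) {
  n <- sum(protocol_times(protocol) < protocol$baseline_s)
  max(1L, as.integer(n))
}

#' @export
print.dce_protocol <- function(x, ...) {
  cat(sprintf(
    "DCE protocol: %d frames x %.1f s (%.0f s total), injection at %.0f s, dose %.2f mmol/kg\n",
    x$n_frames, x$frame_interval,
    x$frame_interval * (x$n_frames - 1), x$baseline_s, x$dose))
  invisible(x)
}
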