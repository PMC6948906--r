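#' Convert a signal curve to relative enhancement
#'
#' Under the low-dose linearity assumption the tissue concentration is
#' proportional to the relative enhancement (SI(t) - SI0)/SI0, with the
#' proportionality constant taken as 1 (relative concentration units).
#' SI0 is the mean of the pre-injection frames.
#'
#' @param curve an [enhancement_curve()].
#' @return a tissue [conc_curve()].
#' @export
signal_to_concentration <- function(curve) {
  stopifnot(inherits(curve, "enhancement_curve"))
  pre <- curve$times < curve$injection_time
  si0 <- mean(curve$signal[pre])
  if (si0 <= 0) stop("non-positive baseline signal", call. = FALSE)
  conc_curve(curve$times, (curve$signal - si0) / si0, "tissue",
             onset_time = curve$injection_time)
}

#' Voxelwise extended Tofts fitting of a 4D dynamic series
#'
#' Converts each masked voxel's signal curve to relative enhancement and
#' fits the extended Tofts model, producing 3D parameter maps. Voxels
#' outside the mask are flagged absent (`status = "absent"`, parameter
#' values NA); failed fits keep their flag rather than being silently
#' zeroed.
#'
#' @param series 4D numeric array (x, y, z, time) of signal intensities.
#' @param cp plasma [conc_curve()] on the series' time grid.
#' @param mask 3D logical (or 0/1) array matching the spatial dimensions.
#' @param protocol the [dce_protocol()] describing the time axis.
#' @param delay_grid,bounds passed to [tofts_fit()].
#' @param voxel_size voxel edge lengths in mm (length 3).
#' @return an object of class `parameter_map`: a list of 3D arrays
#'   `ktrans`, `kep`, `ve`, `vp`, `delta`, `sse`, `r2`, plus a character
#'   `status` array and `voxel_size`.
#' @export
fit_voxelwise <- function(series, cp, mask, protocol = dce_protocol(),
                          delay_grid = 0:5,
                          bounds = list(ktrans = c(0, 5), kep = c(0, 50),
                                        vp = c(0, 1)),
                          voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(series)) == 4)
  dims <- dim(series)[1:3]
  if (!all(dim(mask) == dims))
    stop("mask dimensions must match the series", call. = FALSE)
  mask <- array(as.logical(mask), dim = dims)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  times <- protocol_times(protocol)
  if (dim(series)[4] != length(times))
    stop("series time axis does not match the protocol", call. = FALSE)

  blank <- array(NA_real_, dim = dims)
  maps <- list(ktrans = blank, kep = blank, ve = blank, vp = blank,
               delta = blank, sse = blank, r2 = blank)
  status <- array("absent", dim = dims)

  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    sig <- series[i, j, k, ]
    fit <- tryCatch({
      ec <- enhancement_curve(times, sig,
                              injection_time = protocol$baseline_s)
      ct <- signal_to_concentration(ec)
      tofts_fit(ct, cp, delay_grid = delay_grid, bounds = bounds)
    }, error = function(e) NULL)
    if (is.null(fit)) {
      status[i, j, k] <- "failed"
      next
    }
    cf <- coef(fit)
    maps$ktrans[i, j, k] <- cf["ktrans"]
    maps$kep[i, j, k]    <- cf["kep"]
    maps$ve[i, j, k]     <- cf["ve"]
    maps$vp[i, j, k]     <- cf["vp"]
    maps$delta[i, j, k]  <- cf["delta"]
    maps$sse[i, j, k]    <- fit$sse
    maps$r2[i, j, k]     <- fit$r2
    status[i, j, k] <- fit$status
  }
  structure(c(maps, list(status = status, voxel_size = voxel_size,
                         dims = dims)),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  n_ok <- sum(x$status == "ok" | x$status == "zero")
  cat(sprintf("Parameter map %s, %d fitted voxels (%d failed)\n",
              paste(x$dims, collapse = "x"), n_ok,
              sum(x$status == "failed")))
  if (n_ok > 0)
    cat(sprintf("  Ktrans median %.4g /min (range %.4g-%.4g)\n",
                stats::median(x$ktrans, na.rm = TRUE),
                min(x$ktrans, na.rm = TRUE), max(x$ktrans, na.rm = TRUE)))
  invisible(x)
}

#' Display one slice of a Ktrans map as a color-coded image
#'
#' @param x a `parameter_map`.
#' @param slice z index of the slice to show.
#' @param what which parameter map to display (default `"ktrans"`).
#' @param ... passed to [graphics::image()].
#' @export
plot.parameter_map <- function(x, slice = 1, what = "ktrans", ...) {
  m <- x[[what]][, , slice]
  graphics::image(m, col = grDevices::hcl.colors(64, "Spectral", rev = TRUE),
                  axes = FALSE, main = sprintf("%s, slice %d", what, slice),
                  ...)
  invisible(x)
}
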