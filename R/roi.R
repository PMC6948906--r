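#' Hot-spot ROI selection on a Ktrans map
#'
#' Emulates the radiologist's placement of a few small regions of
#' interest on the most enhancing (highest Ktrans) part of a lesion:
#' greedily selects `n_rois` pairwise-disjoint, 6-connected neighborhoods
#' of `roi_voxels` voxels each, maximizing mean Ktrans, returned in
#' descending order of mean. Each candidate region is grown greedily from
#' every remaining voxel as a seed (add the highest-valued available
#' neighbor until the target size is reached) and the best-scoring region
#' is kept, so on maps with distinct hot spots the greedy choice matches
#' the exhaustive optimum.
#'
#' If the lesion is too small for the requested total, the ROI count is
#' reduced with a warning.
#'
#' @param ktrans_map a `parameter_map` (from [fit_voxelwise()]) or a bare
#'   3D numeric array of Ktrans values.
#' @param lesion_mask 3D logical array delimiting the lesion.
#' @param n_rois number of ROIs (default 3).
#' @param roi_voxels voxels per ROI (default 9, "a few pixels").
#' @return an object of class `roi_set`: a list of integer matrices of
#'   voxel indices (arr.ind style), with per-ROI mean Ktrans.
#' @export
find_hotspots <- function(ktrans_map, lesion_mask, n_rois = 3,
                          roi_voxels = 9) {
  k <- if (inherits(ktrans_map, "parameter_map")) ktrans_map$ktrans
       else ktrans_map
  stopifnot(length(dim(k)) == 3)
  if (!all(dim(lesion_mask) == dim(k)))
    stop("lesion mask dimensions must match the map", call. = FALSE)
  lesion_mask <- array(as.logical(lesion_mask), dim = dim(k))
  lesion_mask[is.na(k)] <- FALSE
  n_avail <- sum(lesion_mask)
  if (n_avail == 0) stop("empty lesion mask", call. = FALSE)
  if (n_rois * roi_voxels > n_avail) {
    n_rois <- max(1L, n_avail %/% roi_voxels)
    if (n_rois * roi_voxels > n_avail)
      stop("lesion smaller than a single ROI", call. = FALSE)
    warning(sprintf("lesion too small for requested ROIs; reduced to %d",
                    n_rois), call. = FALSE)
  }

  avail <- lesion_mask
  rois <- list()
  means <- numeric(0)
  for (r in seq_len(n_rois)) {
    reg <- .best_greedy_region(k, avail, roi_voxels)
    if (is.null(reg)) break
    rois[[length(rois) + 1]] <- reg$idx
    means <- c(means, reg$mean)
    avail[reg$idx] <- FALSE
  }
  if (length(rois) < n_rois)
    warning("fewer ROIs placed than requested (lesion fragmented)",
            call. = FALSE)
  ord <- order(means, decreasing = TRUE)
  structure(list(rois = rois[ord], means = means[ord],
                 roi_voxels = roi_voxels, dims = dim(k)),
            class = "roi_set")
}

# 6-connected neighbors of a linear voxel index within dims
.neighbors6 <- function(lin, dims) {
  ai <- arrayInd(lin, dims)
  out <- integer(0)
  for (d in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- ai
      nb[d] <- nb[d] + s
      if (nb[d] >= 1 && nb[d] <= dims[d])
        out <- c(out, nb[1] + (nb[2] - 1) * dims[1] +
                   (nb[3] - 1) * dims[1] * dims[2])
    }
  }
  out
}

# grow a connected region of given size greedily from each candidate
# seed; return the region with the highest mean (ties: first found)
.best_greedy_region <- function(k, avail, size) {
  dims <- dim(k)
  cand <- which(avail)
  if (length(cand) < size) return(NULL)
  best <- NULL
  for (seed in cand[order(k[cand], decreasing = TRUE)]) {
    reg <- seed
    frontier <- setdiff(.neighbors6(seed, dims), reg)
    frontier <- frontier[avail[frontier]]
    while (length(reg) < size && length(frontier) > 0) {
      nxt <- frontier[which.max(k[frontier])]
      reg <- c(reg, nxt)
      frontier <- union(setdiff(frontier, nxt),
                        Filter(function(v) avail[v] && !(v %in% reg),
                               .neighbors6(nxt, dims)))
    }
    if (length(reg) == size) {
      m <- mean(k[reg])
      if (is.null(best) || m > best$mean) best <- list(idx = reg, mean = m)
      # a region seeded at a voxel whose value already exceeds the best
      # mean cannot be improved upon by lower seeds only if values sorted;
      # keep scanning all seeds for correctness on plateaus
    }
  }
  best
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("ROI set: %d ROIs x %d voxels; mean Ktrans %s\n",
              length(x$rois), x$roi_voxels,
              paste(signif(x$means, 4), collapse = ", ")))
  invisible(x)
}

#' Summarize a lesion from its hot-spot ROIs
#'
#' Aggregates quantitative maps over the ROI set (the per-lesion value of
#' each kinetic parameter is the unweighted mean of the per-ROI means)
#' and recomputes the semi-quantitative descriptors on the ROI-mean
#' signal curve extracted from the dynamic series. Voxels flagged failed
#' or absent inside an ROI are excluded with a warning; a fully failed
#' ROI is an error.
#'
#' @param roiset an `roi_set` from [find_hotspots()].
#' @param maps a `parameter_map` from [fit_voxelwise()].
#' @param series the 4D dynamic series the maps were fitted from.
#' @param protocol the [dce_protocol()].
#' @return a list with `pk` (named numeric: ktrans, kep, ve, vp, delta),
#'   `semiquant` (a `semiquant_params`), and `roi_means` per parameter.
#' @export
lesion_summary <- function(roiset, maps, series,
                           protocol = dce_protocol()) {
  stopifnot(inherits(roiset, "roi_set"), inherits(maps, "parameter_map"))
  pars <- c("ktrans", "kep", "ve", "vp", "delta")
  roi_means <- sapply(pars, function(p) {
    vapply(roiset$rois, function(idx) {
      ok <- maps$status[idx] %in% c("ok", "zero")
      if (!any(ok)) stop("ROI contains no successfully fitted voxels",
                         call. = FALSE)
      if (!all(ok))
        warning("failed voxels inside ROI excluded from summary",
                call. = FALSE)
      mean(maps[[p]][idx][ok])
    }, numeric(1))
  })
  roi_means <- matrix(roi_means, nrow = length(roiset$rois),
                      dimnames = list(NULL, pars))
  pk <- colMeans(roi_means)

  # ROI-mean signal curve over all ROI voxels, descriptors recomputed
  all_idx <- unlist(roiset$rois)
  nt <- dim(series)[4]
  dims <- dim(series)[1:3]
  sig <- vapply(seq_len(nt), function(tt) {
    vol <- series[, , , tt]
    mean(vol[all_idx])
  }, numeric(1))
  ec <- enhancement_curve(protocol_times(protocol), sig,
                          injection_time = protocol$baseline_s)
  sq <- compute_descriptors(ec)
  list(pk = pk, semiquant = sq, roi_means = roi_means)
}
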