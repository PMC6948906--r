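# shared fixtures: default protocol grid, AIF and plasma input

default_protocol <- function() dce_protocol()

default_times <- function(p = default_protocol()) protocol_times(p)

default_cp <- function(p = default_protocol(), aif = cohort_aif(p)) {
  blood_to_plasma(population_blood_curve(aif, protocol_times(p)), aif$hct)
}

# analytic mean of a zero-truncated normal, oracle for the sampler tests
truncnorm_mean <- function(mu, sigma, lower = 0) {
  a <- (lower - mu) / sigma
  mu + sigma * dnorm(a) / (1 - pnorm(a))
}

# brute-force AUC: fraction of positive-negative pairs correctly ordered,
# ties counted one half
pairwise_auc <- function(values, positive) {
  x <- values[positive]; y <- values[!positive]
  s <- 0
  for (xi in x) for (yi in y)
    s <- s + if (xi > yi) 1 else if (xi == yi) 0.5 else 0
  s / (length(x) * length(y))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
permutation_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  dev_obs <- abs(u_obs - length(a) * length(b) / 2)
  combs <- utils::combn(n, na)
  cnt <- 0
  for (j in seq_len(ncol(combs))) {
    u <- sum(r[combs[, j]]) - na * (na + 1) / 2
    if (abs(u - length(a) * length(b) / 2) >= dev_obs - 1e-9) cnt <- cnt + 1
  }
  cnt / ncol(combs)
}

# all 6-connected voxel subsets of a mask with a given size (small masks
# only), as a list of sorted linear-index vectors
enumerate_connected_regions <- function(mask, size) {
  dims <- dim(mask)
  vox <- which(mask)
  nb <- lapply(vox, function(v) {
    ai <- arrayInd(v, dims)
    out <- integer(0)
    for (d in 1:3) for (s in c(-1L, 1L)) {
      x <- ai; x[d] <- x[d] + s
      if (x[d] >= 1 && x[d] <= dims[d]) {
        lin <- x[1] + (x[2] - 1) * dims[1] + (x[3] - 1) * dims[1] * dims[2]
        if (mask[lin]) out <- c(out, lin)
      }
    }
    out
  })
  names(nb) <- as.character(vox)
  seen <- new.env(parent = emptyenv())
  res <- list()
  grow <- function(region, frontier) {
    if (length(region) == size) {
      key <- paste(sort(region), collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        res[[length(res) + 1]] <<- sort(region)
      }
      return(invisible())
    }
    for (f in frontier) {
      newf <- union(setdiff(frontier, f),
                    setdiff(nb[[as.character(f)]], c(region, f)))
      grow(c(region, f), newf)
    }
  }
  for (v in vox) grow(v, nb[[as.character(v)]])
  res
}
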