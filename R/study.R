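#' Study run configuration
#'
#' Collects everything a full pipeline run needs: acquisition protocol,
#' AIF, cohort specification (for synthetic input), fitting settings and
#' output location. All randomness in [run_study()] flows from the single
#' `seed`.
#'
#' @param protocol a [dce_protocol()].
#' @param aif an [aif_model()].
#' @param cohort a [cohort_spec()].
#' @param delay_grid integer frame lags for the Tofts fit.
#' @param bounds fitting bounds, see [tofts_fit()].
#' @param outdir output directory, or NULL to keep results in memory.
#' @param seed integer seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(protocol = dce_protocol(),
                       aif = cohort_aif(protocol),
                       cohort = cohort_spec(),
                       delay_grid = 0:5,
                       bounds = list(ktrans = c(0, 5), kep = c(0, 50),
                                     vp = c(0, 1)),
                       outdir = NULL, seed = 0) {
  structure(list(protocol = protocol, aif = aif, cohort = cohort,
                 delay_grid = delay_grid, bounds = bounds,
                 outdir = outdir, seed = seed),
            class = "run_config")
}

# parameters evaluated in the group-comparison and ROC tables
.study_params <- c("age", "ktrans", "kep", "ve", "vp", "ttp", "si_max",
                   "si_peak", "si_rel", "wir", "wor", "iauc60")

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a lesion cohort, fits the extended Tofts model
#' to every lesion curve against the plasma AIF, computes the
#' semi-quantitative descriptors, and evaluates each parameter with
#' three-group comparisons and binary ROC analysis (benign vs
#' borderline/malignant). Produces a per-lesion table, a group-statistics
#' table and a diagnostic-performance table; with `outdir` set, all three
#' are written as CSV together with a JSON run manifest (package version,
#' seed, config hash).
#'
#' @param config a [run_config()].
#' @param cohort optionally, a pre-built `dce_cohort` to analyze instead
#'   of generating one.
#' @return an object of class `dce_study` with components `per_lesion`,
#'   `table_groups`, `table_roc`, `cohort`, `manifest`.
#' @examples
#' \donttest{
#' st <- run_study(run_config(seed = 0))
#' st$table_roc[, c("parameter", "auc", "cutoff")]
#' }
#' @export
run_study <- function(config = run_config(), cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort))
    cohort <- generate_cohort(config$cohort, config$protocol, config$aif,
                              seed = config$seed)
  stopifnot(inherits(cohort, "dce_cohort"))

  times <- protocol_times(config$protocol)
  cp <- blood_to_plasma(population_blood_curve(config$aif, times),
                        config$aif$hct)

  rows <- vector("list", nrow(cohort$manifest))
  for (i in seq_len(nrow(cohort$manifest))) {
    cv <- cohort$curves[[i]]
    ct <- signal_to_concentration(cv)
    fit <- tofts_fit(ct, cp, delay_grid = config$delay_grid,
                     bounds = config$bounds)
    sq <- compute_descriptors(cv)
    cf <- coef(fit)
    rows[[i]] <- data.frame(
      ktrans = cf["ktrans"], kep = cf["kep"], ve = cf["ve"],
      vp = cf["vp"], delta = cf["delta"], r2 = fit$r2,
      as.data.frame(sq), row.names = NULL)
  }
  per_lesion <- cbind(cohort$manifest, do.call(rbind, rows))

  labels <- per_lesion$class
  has_binary <- any(labels == "benign") && any(labels != "benign")
  g_list <- list(); r_list <- list()
  for (p in .study_params) {
    v <- per_lesion[[p]]
    gc <- compare_groups(v, labels)
    g_list[[p]] <- cbind(parameter = p, as.data.frame(gc))
    if (has_binary) {
      rc <- roc_with_cutoff(v, labels)
      r_list[[p]] <- cbind(parameter = p, as.data.frame(rc))
    }
  }
  table_groups <- do.call(rbind, g_list)
  rownames(table_groups) <- NULL
  if (all(labels != "borderline")) {
    drop <- grep("^borderline_", names(table_groups))
    if (length(drop)) table_groups <- table_groups[, -drop]
  }
  table_roc <- if (has_binary) {
    tr <- do.call(rbind, r_list); rownames(tr) <- NULL; tr
  } else NULL

  manifest <- list(package = "dcetofts",
                   version = as.character(utils::packageVersion("dcetofts")),
                   seed = config$seed,
                   n_lesions = nrow(per_lesion),
                   n_patients = length(unique(per_lesion$patient_id)),
                   config_hash = .config_hash(config))

  st <- structure(list(per_lesion = per_lesion,
                       table_groups = table_groups,
                       table_roc = table_roc, cohort = cohort,
                       manifest = manifest, config = config),
                  class = "dce_study")
  if (!is.null(config$outdir)) write_study(st, config$outdir)
  st
}

# md5 of the deparsed config (seed excluded from nothing: the hash
# identifies the full run setup)
.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[setdiff(names(config), "outdir")]), f)
  unname(tools::md5sum(f))
}

#' Write study outputs to a directory
#'
#' Per-lesion CSV, group-statistics CSV, diagnostic-performance CSV, the
#' cohort files, and a JSON manifest.
#'
#' @param study a `dce_study`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "dce_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    per_lesion = file.path(dir, "per_lesion.csv"),
    groups = file.path(dir, "table_groups.csv"),
    roc = file.path(dir, "table_roc.csv"),
    manifest = file.path(dir, "manifest.json"))
  utils::write.csv(study$per_lesion, paths["per_lesion"],
                   row.names = FALSE)
  utils::write.csv(study$table_groups, paths["groups"], row.names = FALSE)
  if (!is.null(study$table_roc))
    utils::write.csv(study$table_roc, paths["roc"], row.names = FALSE)
  jsonlite::write_json(study$manifest, paths["manifest"],
                       auto_unbox = TRUE, pretty = TRUE)
  write_cohort(study$cohort, dir)
  invisible(paths)
}

#' @export
print.dce_study <- function(x, ...) {
  cat(sprintf("DCE study: %d lesions, %d patients (seed %d)\n",
              x$manifest$n_lesions, x$manifest$n_patients,
              x$manifest$seed))
  if (!is.null(x$table_roc)) {
    ord <- order(x$table_roc$auc, decreasing = TRUE)
    top <- x$table_roc[ord[1:min(4, nrow(x$table_roc))],
                       c("parameter", "auc", "cutoff", "accuracy")]
    cat("Top discriminators (benign vs borderline/malignant):\n")
    print(top, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Read a measured arterial curve from CSV
#'
#' Expects columns `time_s` and `value`; returns a blood-compartment
#' concentration curve for use in [calibrate_aif()].
#'
#' @param path CSV file path.
#' @param onset_time bolus onset metadata for the curve (s).
#' @return a [conc_curve()].
#' @export
read_aif_csv <- function(path, onset_time = 0) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(d)))
    stop("CSV must have columns time_s and value", call. = FALSE)
  conc_curve(d$time_s, d$value, "blood", onset_time = onset_time)
}

#' Read lesion enhancement curves from CSV
#'
#' Expects a `time_s` column plus one column per lesion, as written by
#' [write_cohort()].
#'
#' @param path CSV file path.
#' @param injection_time bolus injection time in seconds.
#' @return a named list of [enhancement_curve()]s.
#' @export
read_curves_csv <- function(path, injection_time = 10) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(d))
    stop("CSV must have a time_s column", call. = FALSE)
  ids <- setdiff(names(d), "time_s")
  out <- lapply(ids, function(id)
    enhancement_curve(d$time_s, d[[id]], injection_time = injection_time))
  names(out) <- ids
  out
}
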