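#' Three-group comparison of a lesion-level parameter
#'
#' Compares a parameter across benign, borderline and malignant lesions:
#' one-way ANOVA across the three groups, then two pairwise contrasts —
#' benign vs malignant and benign vs (borderline + malignant) — by
#' two-tailed Student's t-test when both groups pass the Shapiro-Wilk
#' normality test at alpha = 0.05, otherwise by the Mann-Whitney U test.
#' No multiple-testing correction is applied. A comparison involving a
#' group with fewer than 2 observations is reported absent (NA).
#'
#' @param values numeric vector of per-lesion parameter values.
#' @param labels factor or character with levels `benign`, `borderline`,
#'   `malignant`.
#' @param shapiro_alpha normality-gate significance level.
#' @return an object of class `group_comparison` (named list; coercible
#'   with `as.data.frame`): per-group n/mean/sd, `p_anova`,
#'   `p_benign_vs_malignant`, `p_benign_vs_bm`, and the test used for
#'   each pairwise contrast.
#' @export
compare_groups <- function(values, labels, shapiro_alpha = 0.05) {
  labels <- factor(as.character(labels),
                   levels = c("benign", "borderline", "malignant"))
  if (anyNA(labels)) stop("labels must be benign/borderline/malignant",
                          call. = FALSE)
  stopifnot(length(values) == length(labels))
  ok <- is.finite(values)
  values <- values[ok]; labels <- labels[ok]

  grp <- split(values, labels)
  stats_tab <- lapply(grp, function(v)
    c(n = length(v), mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1) stats::sd(v) else NA_real_))

  present <- names(grp)[vapply(grp, length, integer(1)) >= 2]
  p_anova <- if (length(present) >= 2) {
    sub <- labels %in% present
    stats::anova(stats::lm(values[sub] ~ droplevels(labels[sub])))[["Pr(>F)"]][1]
  } else NA_real_

  pw <- function(a, b) {
    if (length(a) < 2 || length(b) < 2)
      return(list(p = NA_real_, test = NA_character_))
    normal <- .shapiro_ok(a, shapiro_alpha) && .shapiro_ok(b, shapiro_alpha)
    if (normal) {
      list(p = stats::t.test(a, b, var.equal = TRUE)$p.value, test = "t")
    } else {
      list(p = .mann_whitney_p(a, b), test = "mann-whitney")
    }
  }
  bm <- pw(grp$benign, grp$malignant)
  bbm <- pw(grp$benign, c(grp$borderline, grp$malignant))

  structure(list(groups = stats_tab, p_anova = p_anova,
                 p_benign_vs_malignant = bm$p, test_benign_vs_malignant = bm$test,
                 p_benign_vs_bm = bbm$p, test_benign_vs_bm = bbm$test),
            class = "group_comparison")
}

# Shapiro-Wilk gate; constant samples (sd 0) are degenerate, treated as
# non-normal so the rank test handles them
.shapiro_ok <- function(v, alpha) {
  if (length(v) < 3 || stats::sd(v) == 0) return(FALSE)
  stats::shapiro.test(v)$p.value > alpha
}

# two-sided Mann-Whitney U p-value: exact (matching full permutation
# enumeration) for small tie-free samples via wilcox.test; normal
# approximation with tie correction otherwise; all-tied input -> p = 1
.mann_whitney_p <- function(a, b) {
  if (stats::sd(c(a, b)) == 0 || all(outer(a, b, "=="))) return(1)
  suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                      correct = TRUE)$p.value)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison\n")
  for (g in names(x$groups)) {
    s <- x$groups[[g]]
    cat(sprintf("  %-10s n=%2d  mean %.4g (SD %.4g)\n", g, s["n"],
                s["mean"], s["sd"]))
  }
  cat(sprintf("  ANOVA p = %.4g\n", x$p_anova))
  cat(sprintf("  benign vs malignant: p = %.4g (%s)\n",
              x$p_benign_vs_malignant, x$test_benign_vs_malignant))
  cat(sprintf("  benign vs borderline+malignant: p = %.4g (%s)\n",
              x$p_benign_vs_bm, x$test_benign_vs_bm))
  invisible(x)
}

#' @export
as.data.frame.group_comparison <- function(x, ...) {
  g <- x$groups
  data.frame(
    benign_n = g$benign["n"], benign_mean = g$benign["mean"],
    benign_sd = g$benign["sd"],
    borderline_n = g$borderline["n"], borderline_mean = g$borderline["mean"],
    borderline_sd = g$borderline["sd"],
    malignant_n = g$malignant["n"], malignant_mean = g$malignant["mean"],
    malignant_sd = g$malignant["sd"],
    p_anova = x$p_anova,
    p_benign_vs_malignant = x$p_benign_vs_malignant,
    p_benign_vs_bm = x$p_benign_vs_bm,
    row.names = NULL)
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Evaluates a parameter for separating positives (borderline/malignant)
#' from negatives (benign). The AUC is the Mann-Whitney rank statistic
#' (ties counted 1/2); its p-value comes from the tie-corrected normal
#' approximation of the rank statistic under the null AUC = 0.5. The
#' reported cutoff maximizes Youden's J = sensitivity + specificity - 1
#' over all thresholds (midpoints between adjacent distinct values, plus
#' open ends); ties in J resolve to the lower cutoff. Orientation is
#' fixed: values strictly greater than the cutoff are called positive.
#'
#' @param values numeric per-lesion parameter values.
#' @param labels logical (TRUE = positive) or a factor/character where
#'   `benign` is negative and anything else positive.
#' @param criterion `"youden"` (default) or `"accuracy"` for the cutoff.
#' @return an object of class `diag_performance`: auc, p_auc, cutoff,
#'   sensitivity/specificity/accuracy/npv/ppv (percent), confusion counts
#'   tp/fp/tn/fn, and a `constant` flag.
#' @export
roc_with_cutoff <- function(values, labels,
                            criterion = c("youden", "accuracy")) {
  criterion <- match.arg(criterion)
  if (is.logical(labels)) pos <- labels
  else pos <- as.character(labels) != "benign"
  stopifnot(length(values) == length(pos))
  ok <- is.finite(values)
  values <- values[ok]; pos <- pos[ok]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be non-empty", call. = FALSE)

  x <- values[pos]; y <- values[!pos]
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)

  constant <- stats::sd(values) == 0
  # tie-corrected normal approximation for the null distribution of U
  nn <- n1 + n0
  ties <- table(values)
  sigma2 <- n1 * n0 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  p_auc <- if (sigma2 <= 0) 1 else {
    z <- (u - n1 * n0 / 2) / sqrt(sigma2)
    2 * stats::pnorm(-abs(z))
  }

  sv <- sort(unique(values))
  cuts <- if (length(sv) > 1) {
    c(sv[1] - 1, (sv[-1] + sv[-length(sv)]) / 2, sv[length(sv)] + 1)
  } else c(sv - 1, sv + 1)
  best <- NULL
  # cuts scanned in increasing order and updated only on strict
  # improvement, so score ties resolve to the lower cutoff
  for (cut in cuts) {
    tp <- sum(x > cut); fn <- n1 - tp
    tn <- sum(y <= cut); fp <- n0 - tn
    sens <- tp / n1; spec <- tn / n0
    score <- if (criterion == "youden") sens + spec - 1
             else (tp + tn) / nn
    if (is.null(best) || score > best$score)
      best <- list(score = score, cut = cut, tp = tp, fp = fp,
                   tn = tn, fn = fn)
  }
  met <- confusion_metrics(best$tp, best$fp, best$tn, best$fn)
  structure(list(auc = auc, p_auc = p_auc, cutoff = best$cut,
                 sensitivity = met["sensitivity"],
                 specificity = met["specificity"],
                 accuracy = met["accuracy"],
                 npv = met["npv"], ppv = met["ppv"],
                 tp = best$tp, fp = best$fp, tn = best$tn, fn = best$fn,
                 constant = constant, criterion = criterion),
            class = "diag_performance")
}

#' @export
print.diag_performance <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (p = %.4g), cutoff %.4g (%s)\n",
              x$auc, x$p_auc, x$cutoff, x$criterion))
  cat(sprintf("  sens %.1f%% | spec %.1f%% | acc %.1f%% | NPV %.1f%% | PPV %.1f%%\n",
              x$sensitivity, x$specificity, x$accuracy, x$npv, x$ppv))
  cat(sprintf("  confusion: TP %d FP %d TN %d FN %d\n", x$tp, x$fp,
              x$tn, x$fn))
  if (x$constant) cat("  [constant values: AUC forced to 0.5]\n")
  invisible(x)
}

#' @export
as.data.frame.diag_performance <- function(x, ...) {
  data.frame(auc = x$auc, p_auc = x$p_auc, cutoff = x$cutoff,
             accuracy = unname(x$accuracy),
             sensitivity = unname(x$sensitivity),
             specificity = unname(x$specificity),
             npv = unname(x$npv), ppv = unname(x$ppv),
             tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn, row.names = NULL)
}

#' Diagnostic metrics from a confusion matrix
#'
#' Sensitivity, specificity, accuracy, NPV and PPV in percent, from raw
#' confusion counts. PPV is undefined (NA) when no case tests positive,
#' NPV when none tests negative.
#'
#' @param tp,fp,tn,fn non-negative counts; tp + fn > 0 and tn + fp > 0.
#' @param digits rounding for report output (default 1 decimal); use
#'   `Inf` for unrounded values.
#' @return named numeric vector (percent).
#' @examples
#' confusion_metrics(19, 7, 20, 3)   # accuracy 79.6, NPV 87.0, PPV 73.1
#' @export
confusion_metrics <- function(tp, fp, tn, fn, digits = 1) {
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be >= 0", call. = FALSE)
  if (tp + fn == 0 || tn + fp == 0)
    stop("need at least one positive and one negative case", call. = FALSE)
  out <- c(
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy    = 100 * (tp + tn) / (tp + fp + tn + fn),
    ppv         = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    npv         = if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_)
  if (is.finite(digits)) round(out, digits) else out
}
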