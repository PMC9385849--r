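#' AUC via the tie-corrected Mann-Whitney U statistic
#'
#' `AUC = U / (n_pos * n_neg)` where U credits 1 for each positive score
#' above a negative score and 0.5 for each tie. No orientation flip is
#' applied: the caller chooses score polarity (beta for hypermethylated
#' markers, 1 - beta for hypomethylated ones).
#'
#' @param scores_pos,scores_neg numeric score vectors for the positive
#'   and negative class; each must be non-empty.
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores_pos, scores_neg) {
  n1 <- length(scores_pos); n2 <- length(scores_neg)
  if (n1 < 1 || n2 < 1) stop("auc_mann_whitney: both classes must be non-empty")
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' ROC curve points
#'
#' Thresholds are placed at the distinct observed scores ("score >=
#' threshold" predicts positive). The curve starts at (0, 0), ends at
#' (1, 1), and its trapezoidal area equals [auc_mann_whitney()] exactly.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels logical (or 0/1) class labels, `TRUE` = positive.
#' @return data.frame with columns `threshold` (`Inf` for the (0,0)
#'   point), `fpr`, `tpr`, both non-decreasing.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos < 1 || n_neg < 1) stop("roc_points: both classes must be non-empty")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  last <- !duplicated(s, fromLast = TRUE)  # last index of each distinct score
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp / n_neg),
             tpr = c(0, tp / n_pos))
}

# trapezoidal area under an roc_points() curve
roc_trapezoid_auc <- function(curve) {
  sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-nrow(curve)]) / 2)
}

# DeLong structural components via midranks: V10 over positives, V01 over
# negatives; var(AUC) = var(V10)/n1 + var(V01)/n2.
delong_var <- function(scores_pos, scores_neg) {
  n1 <- length(scores_pos); n2 <- length(scores_neg)
  r_all <- rank(c(scores_pos, scores_neg))
  r_pos <- rank(scores_pos)
  r_neg <- rank(scores_neg)
  v10 <- (r_all[seq_len(n1)] - r_pos) / n2
  v01 <- 1 - (r_all[n1 + seq_len(n2)] - r_neg) / n1
  stats::var(v10) / n1 + stats::var(v01) / n2
}

#' Confidence interval for the AUC
#'
#' DeLong variance-based normal interval by default (deterministic), or a
#' seeded percentile bootstrap. Intervals are truncated to \[0, 1\]. With
#' zero estimated variance (e.g. perfect separation) the interval
#' degenerates to `[auc, auc]` and is flagged.
#'
#' @inheritParams auc_mann_whitney
#' @param method `"delong"` or `"bootstrap"`.
#' @param level confidence level (default 0.95).
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @return list with `auc`, `ci_low`, `ci_high`, `method`, `degenerate`.
#' @export
auc_ci <- function(scores_pos, scores_neg, method = c("delong", "bootstrap"),
                   level = 0.95, n_boot = 2000L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(scores_pos) >= 2, length(scores_neg) >= 2)
  auc <- auc_mann_whitney(scores_pos, scores_neg)
  if (method == "delong") {
    v <- delong_var(scores_pos, scores_neg)
    if (v <= 0) {
      return(list(auc = auc, ci_low = auc, ci_high = auc, method = method,
                  degenerate = TRUE))
    }
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- max(0, auc - z * sqrt(v))
    hi <- min(1, auc + z * sqrt(v))
    return(list(auc = auc, ci_low = lo, ci_high = hi, method = method,
                degenerate = FALSE))
  }
  set.seed(seed)
  n1 <- length(scores_pos); n2 <- length(scores_neg)
  boot <- vapply(seq_len(n_boot), function(i) {
    auc_mann_whitney(scores_pos[sample.int(n1, replace = TRUE)],
                     scores_neg[sample.int(n2, replace = TRUE)])
  }, numeric(1))
  qs <- stats::quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  degen <- qs[1] == qs[2]
  list(auc = auc, ci_low = max(0, qs[1]), ci_high = min(1, qs[2]),
       method = method, degenerate = degen)
}

#' ROC evaluation of candidate probes as single-CpG classifiers
#'
#' For each probe, the raw per-sample beta value is the classifier score
#' (no model fitting; single CpGs are evaluated as-is). The positive
#' class is the case cohort; the negative class pools the listed control
#' cohorts (e.g. unaffected controls plus the other variant cohort).
#'
#' @param beta probes x samples beta matrix.
#' @param samples sample sheet data.frame.
#' @param probes character vector of probe ids to evaluate.
#' @param case_label positive-class group label.
#' @param control_labels negative-class group label(s), pooled.
#' @param method CI method passed to [auc_ci()].
#' @param level confidence level.
#' @param seed bootstrap seed.
#' @return data.frame: `probe_id`, `auc`, `ci_low`, `ci_high`, `n_pos`,
#'   `n_neg`, `method`.
#' @export
roc_table <- function(beta, samples, probes, case_label, control_labels,
                      method = "delong", level = 0.95, seed = 1L) {
  pos_ids <- samples$sample_id[samples$group == case_label]
  neg_ids <- samples$sample_id[samples$group %in% control_labels]
  pi_ <- match(pos_ids, colnames(beta))
  ni <- match(neg_ids, colnames(beta))
  stopifnot(!anyNA(pi_), !anyNA(ni), length(pi_) >= 2, length(ni) >= 2)
  rows <- lapply(probes, function(p) {
    ri <- match(p, rownames(beta))
    if (is.na(ri)) stop("roc_table: probe not in beta matrix: ", p)
    ci <- auc_ci(beta[ri, pi_], beta[ri, ni], method = method,
                 level = level, seed = seed)
    data.frame(probe_id = p, auc = ci$auc, ci_low = ci$ci_low,
               ci_high = ci$ci_high, n_pos = length(pi_),
               n_neg = length(ni), method = ci$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
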