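#' Beta-value to M-value transform
#'
#' `M = log2((beta + epsilon) / (1 - beta + epsilon))`. The M scale is the
#' log2-odds of methylation, used for variance stabilisation in
#' clustering/display; all effect sizes in this package are reported on
#' the beta scale.
#'
#' @param beta numeric vector/matrix of methylation fractions in \[0, 1\].
#' @param epsilon boundary guard, default 1e-6.
#' @return M values, same shape as `beta`.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  stopifnot(epsilon > 0, all(beta >= 0 & beta <= 1, na.rm = TRUE))
  log2((beta + epsilon) / (1 - beta + epsilon))
}

# Row-wise two-sample t machinery shared by all per-probe/per-gene tests.
# X, Y: matrices with matching rows (features x samples). Welch by default;
# var_equal = TRUE gives the pooled-variance test. Rows where both groups
# have zero variance are "degenerate": t = 0 / p = 1 if the means agree,
# p = 0 (signed infinite t) otherwise.
row_t_test <- function(X, Y, var_equal = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  nx <- ncol(X); ny <- ncol(Y)
  stopifnot(nx >= 2, ny >= 2, nrow(X) == nrow(Y))
  mx <- rowMeans(X); my <- rowMeans(Y)
  vx <- rowSums((X - mx)^2) / (nx - 1)
  vy <- rowSums((Y - my)^2) / (ny - 1)
  delta <- mx - my
  degen <- vx == 0 & vy == 0
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se2 <- sp2 * (1 / nx + 1 / ny)
    df <- rep(nx + ny - 2, length(delta))
  } else {
    se2 <- vx / nx + vy / ny
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- delta / sqrt(se2)
  p <- 2 * stats::pt(-abs(t), df)
  if (any(degen)) {
    eq <- degen & delta == 0
    ne <- degen & delta != 0
    t[eq] <- 0; p[eq] <- 1
    t[ne] <- sign(delta[ne]) * Inf; p[ne] <- 0
    df[degen] <- nx + ny - 2
  }
  list(delta = delta, t = t, df = df, p = p, degenerate = degen)
}

#' Two-sample t test (Welch by default)
#'
#' Welch's unequal-variance statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p value. Degenerate input (both samples with
#' zero variance) is given defined behaviour instead of `NaN`: equal means
#' give t = 0, p = 1; unequal means give p = 0 with the `degenerate` flag
#' set.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param var_equal use the pooled-variance statistic instead of Welch.
#' @return list with `t`, `df`, `p`, `delta` (mean(x) - mean(y)),
#'   `degenerate`.
#' @export
welch_t_test <- function(x, y, var_equal = FALSE) {
  r <- row_t_test(matrix(x, nrow = 1), matrix(y, nrow = 1),
                  var_equal = var_equal)
  lapply(r, `[[`, 1L)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Sorted ascending, `q_(i) = min_{j >= i} min(1, p_(j) * n / j)`;
#' returned in input order.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @return adjusted p values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("bh_adjust: p values must lie in [0, 1]")
  }
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(n / (n:1) * p[o]))
  q[order(o)]
}

#' Total repetitive-element methylation comparison
#'
#' The per-sample mean beta across all repeat-resident probes is the
#' "total" methylation of repetitive elements; groups are compared with a
#' two-sided t test on those per-sample means.
#'
#' @param beta probes x samples matrix (probe rownames, sample colnames).
#' @param annotation annotated-probe table from [annotate_probes()].
#' @param samples sample sheet data.frame (`sample_id`, `group`).
#' @param case,control group labels; delta_beta = case mean - control mean.
#' @param var_equal pooled-variance t instead of Welch.
#' @return list with `delta_beta`, `t`, `df`, `p`, `n_probes`,
#'   `per_sample_means` (named vector over case+control samples).
#' @export
total_re_methylation <- function(beta, annotation, samples, case, control,
                                 var_equal = FALSE) {
  resident <- is_repeat_resident(annotation)
  idx <- match(annotation$probe_id[resident], rownames(beta))
  if (!length(idx) || all(is.na(idx))) {
    stop("total_re_methylation: no repeat-resident probes in the beta matrix")
  }
  idx <- idx[!is.na(idx)]
  ci <- group_cols(beta, samples, case)
  ki <- group_cols(beta, samples, control)
  msub <- beta[idx, c(ci, ki), drop = FALSE]
  per_sample <- colMeans(msub)
  r <- welch_t_test(per_sample[seq_along(ci)],
                    per_sample[-seq_along(ci)], var_equal = var_equal)
  list(delta_beta = r$delta, t = r$t, df = r$df, p = r$p,
       n_probes = length(idx), per_sample_means = per_sample)
}

#' Family- or age-class-level differential methylation
#'
#' For each named family (or age class) with at least one probe, the
#' per-sample mean beta over that group's probes is compared between case
#' and control with a two-sided t test. p values are reported unadjusted
#' (the asterisk p < 0.05 convention); an optional BH-adjusted column is
#' added with `adjust = TRUE`. Probes with unclassified repeat names are
#' excluded from family aggregation.
#'
#' @inheritParams total_re_methylation
#' @param group_by `"family"` or `"age_class"`.
#' @param adjust also report BH-adjusted p across the emitted groups.
#' @return data.frame: `group`, `delta_beta`, `t`, `df`, `p`, `n_probes`
#'   (and `p_bh` when `adjust = TRUE`).
#' @export
family_methylation <- function(beta, annotation, samples, case, control,
                               group_by = c("family", "age_class"),
                               var_equal = FALSE, adjust = FALSE) {
  group_by <- match.arg(group_by)
  keep <- is_repeat_resident(annotation) &
    annotation[[group_by]] != "unclassified"
  ann <- annotation[keep, , drop = FALSE]
  ci <- group_cols(beta, samples, case)
  ki <- group_cols(beta, samples, control)
  groups <- sort(unique(ann[[group_by]]))
  rows <- lapply(groups, function(g) {
    idx <- match(ann$probe_id[ann[[group_by]] == g], rownames(beta))
    idx <- idx[!is.na(idx)]
    if (!length(idx)) return(NULL)
    pm_case <- colMeans(beta[idx, ci, drop = FALSE])
    pm_ctrl <- colMeans(beta[idx, ki, drop = FALSE])
    r <- welch_t_test(pm_case, pm_ctrl, var_equal = var_equal)
    data.frame(group = g, delta_beta = r$delta, t = r$t, df = r$df, p = r$p,
               n_probes = length(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(group = character(), delta_beta = numeric(),
                      t = numeric(), df = numeric(), p = numeric(),
                      n_probes = integer(), stringsAsFactors = FALSE)
  }
  if (adjust && nrow(out)) out$p_bh <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Call differentially methylated positions (DMPs)
#'
#' Per-probe two-sided t test (Welch by default) over repeat-resident
#' probes, with BH adjustment applied separately within each element
#' class (LINE-1 and Alu analysed separately; `stratify_fdr = FALSE`
#' pools all resident probes into one adjustment). A probe is significant
#' when `p_fdr < alpha_fdr`; direction is the sign of delta_beta.
#'
#' @inheritParams total_re_methylation
#' @param alpha_fdr FDR significance threshold (default 0.05).
#' @param stratify_fdr adjust within element classes (default) or pooled.
#' @return data.frame, one row per repeat-resident probe: `probe_id`,
#'   `repeat_name`, `element_class`, `family`, `age_class`, `delta_beta`,
#'   `t`, `df`, `p`, `p_fdr`, `direction` ("hyper"/"hypo"/"none"),
#'   `significant`, `degenerate`.
#' @export
call_dmps <- function(beta, annotation, samples, case, control,
                      alpha_fdr = 0.05, stratify_fdr = TRUE,
                      var_equal = FALSE) {
  resident <- is_repeat_resident(annotation)
  ann <- annotation[resident, , drop = FALSE]
  idx <- match(ann$probe_id, rownames(beta))
  ok <- !is.na(idx)
  ann <- ann[ok, , drop = FALSE]
  idx <- idx[ok]
  ci <- group_cols(beta, samples, case)
  ki <- group_cols(beta, samples, control)
  r <- row_t_test(beta[idx, ci, drop = FALSE], beta[idx, ki, drop = FALSE],
                  var_equal = var_equal)
  out <- data.frame(probe_id = ann$probe_id, repeat_name = ann$repeat_name,
                    element_class = ann$element_class, family = ann$family,
                    age_class = ann$age_class, delta_beta = r$delta,
                    t = r$t, df = r$df, p = r$p, stringsAsFactors = FALSE)
  if (stratify_fdr) {
    out$p_fdr <- NA_real_
    for (cl in unique(out$element_class)) {
      sel <- out$element_class == cl
      out$p_fdr[sel] <- bh_adjust(out$p[sel])
    }
  } else {
    out$p_fdr <- bh_adjust(out$p)
  }
  out$direction <- ifelse(out$delta_beta > 0, "hyper",
                          ifelse(out$delta_beta < 0, "hypo", "none"))
  out$significant <- out$p_fdr < alpha_fdr
  out$degenerate <- r$degenerate
  rownames(out) <- NULL
  out
}
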