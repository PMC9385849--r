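#' Three-set Venn partition
#'
#' Exact seven-region partition of three sets (unique to each set, the
#' three pairwise-only intersections, and the triple intersection).
#' Regions are pairwise disjoint and their union is the union of the
#' inputs.
#'
#' @param setA,setB,setC character vectors (duplicates ignored).
#' @param names labels for the three sets.
#' @return list with `regions` (named list of member vectors, names like
#'   `"A_only"`, `"A_B"`, `"A_B_C"`) and `counts` (data.frame
#'   region/count).
#' @export
venn_partition <- function(setA, setB, setC, names = c("A", "B", "C")) {
  A <- unique(setA); B <- unique(setB); C <- unique(setC)
  all_ids <- union(union(A, B), C)
  inA <- all_ids %in% A; inB <- all_ids %in% B; inC <- all_ids %in% C
  key <- paste0(ifelse(inA, "1", "0"), ifelse(inB, "1", "0"),
                ifelse(inC, "1", "0"))
  region_names <- c(`100` = paste0(names[1], "_only"),
                    `010` = paste0(names[2], "_only"),
                    `001` = paste0(names[3], "_only"),
                    `110` = paste(names[1], names[2], sep = "_"),
                    `101` = paste(names[1], names[3], sep = "_"),
                    `011` = paste(names[2], names[3], sep = "_"),
                    `111` = paste(names[1], names[2], names[3], sep = "_"))
  regions <- lapply(names(region_names), function(k) all_ids[key == k])
  names(regions) <- region_names
  counts <- data.frame(region = unname(region_names),
                       count = lengths(regions), stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  list(regions = regions, counts = counts)
}

#' Select variant-unique target loci
#'
#' Implements the two-filter target-locus rule: start from probes that
#' are significant DMPs *only* in the variant cohort's comparison against
#' control (Venn-unique across the three case-vs-control DMP tables),
#' then re-test each of those probes between the variant cohort and the
#' heterogeneous case cohort, BH-adjust over the re-tested set, and keep
#' probes with re-test `p_fdr < alpha`.
#'
#' @param dmp_tables named list of [call_dmps()] outputs, one per case
#'   cohort (names are the cohort labels), all versus the same control.
#' @param beta probes x samples beta matrix.
#' @param samples sample sheet data.frame.
#' @param variant_label case-cohort label whose unique loci are sought.
#' @param heterogeneous_label label of the heterogeneous case cohort used
#'   for the re-test.
#' @param alpha FDR threshold for the re-test (default 0.05).
#' @param var_equal pooled-variance t instead of Welch for the re-test.
#' @return data.frame: `probe_id`, `variant_cohort`, `delta_beta`
#'   (variant vs control, from the DMP table), `p_fdr_vs_control`,
#'   `delta_beta_vs_heterogeneous`, `p_vs_heterogeneous`,
#'   `p_fdr_vs_heterogeneous`, `selected`; only selected rows are
#'   returned.
#' @export
select_variant_target_loci <- function(dmp_tables, beta, samples,
                                       variant_label, heterogeneous_label,
                                       alpha = 0.05, var_equal = FALSE) {
  stopifnot(variant_label %in% names(dmp_tables))
  vi <- group_cols(beta, samples, variant_label)
  hi <- group_cols(beta, samples, heterogeneous_label)
  sig_sets <- lapply(dmp_tables, function(d) d$probe_id[d$significant])
  others <- unlist(sig_sets[setdiff(names(sig_sets), variant_label)],
                   use.names = FALSE)
  unique_ids <- setdiff(sig_sets[[variant_label]], others)
  empty <- data.frame(probe_id = character(), variant_cohort = character(),
                      delta_beta = numeric(), p_fdr_vs_control = numeric(),
                      delta_beta_vs_heterogeneous = numeric(),
                      p_vs_heterogeneous = numeric(),
                      p_fdr_vs_heterogeneous = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(unique_ids)) return(empty)
  idx <- match(unique_ids, rownames(beta))
  stopifnot(!anyNA(idx))
  r <- row_t_test(beta[idx, vi, drop = FALSE], beta[idx, hi, drop = FALSE],
                  var_equal = var_equal)
  p_fdr <- bh_adjust(r$p)
  vt <- dmp_tables[[variant_label]]
  vrow <- match(unique_ids, vt$probe_id)
  out <- data.frame(probe_id = unique_ids,
                    variant_cohort = variant_label,
                    delta_beta = vt$delta_beta[vrow],
                    p_fdr_vs_control = vt$p_fdr[vrow],
                    delta_beta_vs_heterogeneous = r$delta,
                    p_vs_heterogeneous = r$p,
                    p_fdr_vs_heterogeneous = p_fdr,
                    stringsAsFactors = FALSE)
  out <- out[out$p_fdr_vs_heterogeneous < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments
# (handles ties via midranks); used when both groups are small.
mwu_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  center <- n1 * n2 / 2
  mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
}

# Normal approximation with tie correction (no continuity correction).
mwu_approx_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  N <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * (N + 1 - tie_term)
  if (sigma2 == 0) return(1)
  z <- (u - n1 * n2 / 2) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration over all group assignments when both groups have at
#' most `exact_max` observations (ties handled via midranks), otherwise a
#' normal approximation with tie correction.
#'
#' @param x,y numeric vectors.
#' @param exact_max largest per-group size for exact enumeration
#'   (default 8).
#' @return list with `U` (statistic for `x`), `p`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    list(U = u, p = mwu_exact_p(x, y), method = "exact")
  } else {
    list(U = u, p = mwu_approx_p(x, y), method = "normal")
  }
}

#' Cohort covariate-balance checks
#'
#' Pearson chi-square test (no continuity correction) of sex-by-group
#' independence over the listed groups, and pairwise two-sided
#' Mann-Whitney U tests of age between the control group and each case
#' group. Missing covariate columns skip the corresponding test with a
#' message.
#'
#' @param samples sample sheet data.frame (`sample_id`, `group`, optional
#'   `sex`, `age`).
#' @param control control-group label.
#' @param case_groups case-group labels; default all non-control groups.
#' @return list with `sex` (list: statistic, df, p, table) or `NULL`, and
#'   `age` (data.frame: comparison, U, p, method) or `NULL`.
#' @export
covariate_balance <- function(samples, control,
                              case_groups = setdiff(unique(samples$group),
                                                    control)) {
  groups <- c(control, case_groups)
  ss <- samples[samples$group %in% groups, , drop = FALSE]
  out <- list(sex = NULL, age = NULL)
  if ("sex" %in% names(ss)) {
    tab <- table(ss$sex, factor(ss$group, levels = groups))
    exp_ <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - exp_)^2 / exp_)
    df <- (nrow(tab) - 1) * (ncol(tab) - 1)
    out$sex <- list(statistic = stat, df = df,
                    p = if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE) else 1,
                    table = tab)
  } else {
    message("covariate_balance: no 'sex' column; chi-square test skipped")
  }
  if ("age" %in% names(ss)) {
    rows <- lapply(case_groups, function(g) {
      r <- mann_whitney_u(ss$age[ss$group == control],
                          ss$age[ss$group == g])
      data.frame(comparison = paste(control, "vs", g), U = r$U, p = r$p,
                 method = r$method, stringsAsFactors = FALSE)
    })
    out$age <- do.call(rbind, rows)
    rownames(out$age) <- NULL
  } else {
    message("covariate_balance: no 'age' column; Mann-Whitney tests skipped")
  }
  out
}
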