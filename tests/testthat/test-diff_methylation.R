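test_that("beta_to_m is the log2-odds transform", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2, tolerance = 1e-4)    # log2(0.8/0.2)
  expect_equal(beta_to_m(0.2), -2, tolerance = 1e-4)   # antisymmetry
  b <- seq(0, 1, by = 0.05)
  expect_true(all(diff(beta_to_m(b)) > 0))             # monotone
  expect_true(all(is.finite(beta_to_m(c(0, 1)))))      # epsilon guard
})

test_that("welch_t_test matches the hand-computed example and stats::t.test", {
  r0 <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  r <- welch_t_test(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
  expect_equal(r$t, -0.3 / sqrt(0.01 / 3 + 0.01 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4)

  for (i in 1:30) {
    set.seed(i)
    x <- rnorm(sample(2:20, 1)); y <- rnorm(sample(2:20, 1), sd = runif(1, 0.5, 2))
    mine <- welch_t_test(x, y)
    ref <- t.test(x, y)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    pooled <- welch_t_test(x, y, var_equal = TRUE)
    refp <- t.test(x, y, var.equal = TRUE)
    expect_equal(pooled$p, refp$p.value, tolerance = 1e-10)
  }
})

test_that("welch degenerate inputs have the defined behaviour", {
  same <- welch_t_test(c(2, 2, 2), c(2, 2))
  expect_true(same$degenerate)
  expect_equal(same$p, 1)
  diff_ <- welch_t_test(c(2, 2, 2), c(3, 3))
  expect_true(diff_$degenerate)
  expect_equal(diff_$p, 0)
  expect_equal(diff_$t, -Inf)
})

test_that("welch type-I error is nominal (Monte-Carlo)", {
  set.seed(42)
  n_rep <- 10000
  X <- matrix(rnorm(n_rep * 10), n_rep)
  Y <- matrix(rnorm(n_rep * 10), n_rep)
  p <- retromethyl:::row_t_test(X, Y)$p
  expect_equal(mean(p < 0.05), 0.05, tolerance = 0.01)
})

test_that("bh_adjust equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.73), 0.73)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  for (i in 1:50) {
    set.seed(i)
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, brute_force_bh(p))
    expect_true(all(q >= p & q <= 1))
  }
})

test_that("total RE methylation compares per-sample means over resident probes", {
  ann <- make_annotation(sprintf("p%02d", 1:6),
                         repeat_name = c("AluY", "AluY", "L1M5", "MER41B",
                                         NA, NA))
  samples <- make_samples(c(control = 4L, case = 4L))
  beta <- make_beta(ann, samples, base = 0.5)
  r <- total_re_methylation(beta, ann, samples, "case", "control")
  expect_equal(r$delta_beta, 0)
  expect_equal(r$p, 1)
  expect_equal(r$n_probes, 4L)  # unclassified MER41B still resident

  beta2 <- make_beta(ann, samples, base = 0.5, noise_sd = 0.001,
                     offsets = list(list(probes = sprintf("p%02d", 1:4),
                                         group = "case", delta = 0.2)))
  r2 <- total_re_methylation(beta2, ann, samples, "case", "control")
  expect_equal(r2$delta_beta, 0.2, tolerance = 0.01)

  ann_none <- make_annotation("q1")
  expect_error(total_re_methylation(make_beta(ann_none, samples), ann_none,
                                    samples, "case", "control"),
               "no repeat-resident")
})

test_that("family deltas are differences of group means of per-sample
          family means, unclassified excluded", {
  ann <- make_annotation(sprintf("p%02d", 1:8),
                         repeat_name = c("AluSx", "AluSg", "AluY", "L1M5",
                                         "L1M5", "MER41B", NA, "HAL1"))
  samples <- make_samples(c(control = 5L, case = 5L))
  set.seed(3)
  beta <- matrix(runif(8 * 10, 0.2, 0.9), 8, 10,
                 dimnames = list(ann$probe_id, samples$sample_id))
  fam <- family_methylation(beta, ann, samples, "case", "control")
  expect_setequal(fam$group, c("AluS", "AluY", "L1M", "HAL1"))
  for (g in fam$group) {
    idx <- ann$family == g & !is.na(ann$repeat_name)
    pm <- colMeans(beta[idx, , drop = FALSE])
    want <- mean(pm[samples$group == "case"]) -
      mean(pm[samples$group == "control"])
    expect_equal(fam$delta_beta[fam$group == g], want)
  }
  # age-class grouping covers the same probes
  age <- family_methylation(beta, ann, samples, "case", "control",
                            group_by = "age_class")
  expect_setequal(age$group, c("intermediate", "young", "old", "related"))
  expect_equal(sum(age$n_probes), sum(fam$n_probes))

  ident <- family_methylation(make_beta(ann, samples, base = 0.4), ann,
                              samples, "case", "control")
  expect_true(all(ident$delta_beta == 0))
  expect_true(all(ident$p == 1))
})

test_that("call_dmps: antisymmetry, stratified FDR, degenerate handling", {
  ann <- make_annotation(sprintf("p%03d", 1:60),
                         repeat_name = rep(c("AluY", "L1PA3", "MER41B"), 20))
  samples <- make_samples(c(control = 8L, case = 8L))
  set.seed(7)
  beta <- matrix(runif(60 * 16, 0.3, 0.9), 60, 16,
                 dimnames = list(ann$probe_id, samples$sample_id))
  d1 <- call_dmps(beta, ann, samples, "case", "control")
  d2 <- call_dmps(beta, ann, samples, "control", "case")
  expect_equal(d1$delta_beta, -d2$delta_beta)
  expect_equal(d1$p, d2$p)
  expect_equal(d1$p_fdr, d2$p_fdr)
  # stratification: adjustment within each element class independently
  for (cl in unique(d1$element_class)) {
    sel <- d1$element_class == cl
    expect_equal(d1$p_fdr[sel], bh_adjust(d1$p[sel]))
  }
  pooled <- call_dmps(beta, ann, samples, "case", "control",
                      stratify_fdr = FALSE)
  expect_equal(pooled$p_fdr, bh_adjust(pooled$p))
  # direction is the sign of delta_beta
  expect_true(all(d1$direction[d1$delta_beta > 0] == "hyper"))
  expect_true(all(d1$direction[d1$delta_beta < 0] == "hypo"))

  flat <- matrix(0.5, 60, 16, dimnames = dimnames(beta))
  dflat <- call_dmps(flat, ann, samples, "case", "control")
  expect_true(all(dflat$degenerate))
  expect_false(any(dflat$significant))
})

test_that("call_dmps recovers strong planted loci on a small fixture", {
  ann <- make_annotation(sprintf("p%03d", 1:200),
                         repeat_name = rep(c("AluY", "L1PA3"), 100))
  samples <- make_samples(c(control = 12L, case = 12L))
  planted <- sprintf("p%03d", 1:20)
  beta <- make_beta(ann, samples, base = 0.6, noise_sd = 0.04,
                    offsets = list(list(probes = planted, group = "case",
                                        delta = 0.15)), seed = 5)
  d <- call_dmps(beta, ann, samples, "case", "control")
  hits <- d$probe_id[d$significant]
  expect_gte(sum(planted %in% hits) / 20, 0.9)
  expect_true(all(d$direction[d$probe_id %in% planted & d$significant] ==
                    "hyper"))
})
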