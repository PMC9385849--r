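test_that("fixture generation is byte-deterministic under a fixed seed", {
  cfg <- sim_config(n_probes = 200L,
                    group_sizes = c(control = 5L, heterogeneous = 6L),
                    candidates = data.frame(gene = "CANDG1", direction = 1,
                                            stringsAsFactors = FALSE))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- simulate_dataset(cfg, seed = 7, dir = d1)$files
  f2 <- simulate_dataset(cfg, seed = 7, dir = d2)$files
  for (k in names(f1)) {
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]), label = k)
  }
  # a different seed changes the data
  f3 <- simulate_dataset(cfg, seed = 8, dir = withr::local_tempdir())$files
  expect_false(identical(readLines(f1$beta), readLines(f3$beta)))
})

test_that("fraction_in_repeats and pool restriction behave as declared", {
  cfg <- sim_config(n_probes = 300L, fraction_in_repeats = 1,
                    repeat_name_pool = c(AluY = 1))
  ann <- simulate_annotation(cfg, seed = 3)
  annotated <- annotate_probes(ann$probes, ann$repeats)
  expect_true(all(!is.na(annotated$repeat_name)))
  expect_true(all(annotated$age_class == "young"))
  expect_true(all(annotated$overlap_bp >= 1))

  cfg2 <- sim_config(n_probes = 400L, fraction_in_repeats = 0.5)
  ann2 <- simulate_annotation(cfg2, seed = 3)
  a2 <- annotate_probes(ann2$probes, ann2$repeats)
  expect_equal(sum(!is.na(a2$repeat_name)), 200L)
  # pool decoys are present and unclassified
  expect_true(any(a2$repeat_name %in% c("MER41B", "MIRb", "L2a")))
})

test_that("beta values are strictly inside (0,1), no NaN, correct shape", {
  cfg <- sim_config(n_probes = 150L,
                    group_sizes = c(control = 4L, heterogeneous = 4L))
  ds <- simulate_dataset(cfg, seed = 2)
  expect_false(anyNA(ds$beta))
  expect_true(all(ds$beta > 0 & ds$beta < 1))
  expect_equal(dim(ds$beta), c(150L, 8L))
  expect_equal(rownames(ds$beta), ds$annotation$probe_id)
})

test_that("null construction: family deltas stay within sampling noise", {
  cfg <- sim_config(n_probes = 500L, fraction_in_repeats = 1,
                    group_sizes = c(control = 20L, heterogeneous = 20L))
  ann <- simulate_annotation(cfg, seed = 11)
  annotated <- annotate_probes(ann$probes, ann$repeats)
  samples <- simulate_sample_sheet(cfg, seed = 12)
  n_ok <- 0; n_tot <- 0
  for (s in 1:5) {
    beta <- simulate_beta(cfg, annotated, samples, seed = s)$beta
    fam <- family_methylation(beta, annotated, samples,
                              "heterogeneous", "control")
    se <- abs(fam$delta_beta / fam$t)
    ok <- abs(fam$delta_beta) < 3 * se
    n_ok <- n_ok + sum(ok); n_tot <- n_tot + length(ok)
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("planted logit shift gives the computed mean and delta", {
  # invlogit(logit(0.8) + 0.5) = 0.868332... so expected delta 0.068332
  ef <- effect_spec("AluS", "heterogeneous", 0.5, baseline_mu = 0.8)
  expect_equal(ef$expected_delta_beta, 0.0683324, tolerance = 1e-5)
  cfg <- sim_config(n_probes = 400L, fraction_in_repeats = 1,
                    baseline_mu_logit_sd = 0,  # pin baseline at exactly 0.8
                    group_sizes = c(control = 30L, heterogeneous = 30L),
                    effects = list(ef))
  ann <- simulate_annotation(cfg, seed = 5)
  annotated <- annotate_probes(ann$probes, ann$repeats)
  samples <- simulate_sample_sheet(cfg, seed = 6)
  bt <- simulate_beta(cfg, annotated, samples, seed = 7)
  idx <- annotated$family == "AluS"
  case <- samples$group == "heterogeneous"
  planted_mean <- mean(bt$beta[idx, case])
  expect_lt(abs(planted_mean - 0.868332), 0.01)
  expect_lt(abs(mean(bt$beta[idx, case]) - mean(bt$beta[idx, !case]) -
                  0.068332), 0.01)
  expect_equal(unique(bt$truth$expected_delta_beta), 0.0683324,
               tolerance = 1e-5)
})

test_that("precision controls the beta noise scale", {
  # Var = mu(1-mu)/(nu+1); at nu = 1e5, mu = 0.8 the sd is ~0.0013
  cfg <- sim_config(n_probes = 50L, baseline_mu_logit_sd = 0,
                    precision = 1e5,
                    group_sizes = c(control = 50L, heterogeneous = 2L))
  ann <- simulate_annotation(cfg, seed = 1)
  annotated <- annotate_probes(ann$probes, ann$repeats)
  samples <- simulate_sample_sheet(cfg, seed = 1)
  beta <- simulate_beta(cfg, annotated, samples, seed = 1)$beta
  expect_true(all(apply(beta, 1, sd) < 0.005))
})

test_that("planted-effect direction matches delta_logit sign across seeds", {
  base_cfg <- sim_config(n_probes = 300L, fraction_in_repeats = 1,
                         precision = 150,
                         group_sizes = c(control = 10L, heterogeneous = 10L))
  for (s in 1:20) {
    dl <- if (s %% 2) 0.45 else -0.45   # |expected delta beta| ~ 0.06
    cfg <- base_cfg
    cfg$effects <- list(effect_spec("AluS", "heterogeneous", dl))
    ann <- simulate_annotation(cfg, seed = s)
    annotated <- annotate_probes(ann$probes, ann$repeats)
    samples <- simulate_sample_sheet(cfg, seed = s)
    beta <- simulate_beta(cfg, annotated, samples, seed = s + 100)$beta
    idx <- annotated$family == "AluS"
    case <- samples$group == "heterogeneous"
    realized <- mean(beta[idx, case]) - mean(beta[idx, !case])
    expect_equal(sign(realized), sign(dl), label = paste("seed", s))
  }
})

test_that("effects targeting no probes warn and are skipped; control
          groups are rejected", {
  cfg <- sim_config(n_probes = 100L, fraction_in_repeats = 1,
                    repeat_name_pool = c(AluY = 1),
                    group_sizes = c(control = 3L, heterogeneous = 3L),
                    effects = list(effect_spec("cg_nonexistent",
                                               "heterogeneous", 1)))
  ann <- simulate_annotation(cfg, seed = 1)
  annotated <- annotate_probes(ann$probes, ann$repeats)
  samples <- simulate_sample_sheet(cfg, seed = 1)
  expect_warning(simulate_beta(cfg, annotated, samples, seed = 1),
                 "names no probes")
  cfg$effects <- list(effect_spec("AluY", c("control"), 1))
  expect_error(simulate_beta(cfg, annotated, samples, seed = 1),
               "exclude the control")
})

test_that("expression studies plant the configured shifts", {
  planted <- data.frame(gene = "CANDG1", study_id = c("STUDY01", "STUDY03"),
                        log2fc = -0.5, stringsAsFactors = FALSE)
  cfg <- sim_config(n_gene_pool = 100L, n_expression_studies = 3L,
                    expr_samples_per_group = 15L, planted_genes = planted)
  ex <- simulate_expression_studies(cfg, seed = 4)
  expect_equal(nrow(ex$truth), 2L)   # two supporting studies recorded
  st <- ex$studies$STUDY01
  gi <- match("CANDG1", rownames(st$expr))
  shift <- mean(st$expr[gi, st$groups == "case"]) -
    mean(st$expr[gi, st$groups == "control"])
  expect_equal(shift, -0.5, tolerance = 0.2)
  # untouched study has no shift planted
  st2 <- ex$studies$STUDY02
  shift2 <- mean(st2$expr[gi, st2$groups == "case"]) -
    mean(st2$expr[gi, st2$groups == "control"])
  expect_lt(abs(shift2), 0.3)
  # determinism
  ex2 <- simulate_expression_studies(cfg, seed = 4)
  expect_identical(ex$studies$STUDY01$expr, ex2$studies$STUDY01$expr)
})

test_that("all-null expression yields ~no DEGs after FDR control", {
  cfg <- sim_config(n_gene_pool = 500L, n_expression_studies = 1L,
                    expr_samples_per_group = 20L)
  ex <- simulate_expression_studies(cfg, seed = 9)
  st <- ex$studies$STUDY01
  degs <- simple_deg_caller(st$expr, st$groups, "case", "control",
                            alpha = 0.05, study_id = "STUDY01")
  # BH at 0.05 over 500 null genes: significant calls are rare; allow the
  # binomial 95% bound on 500 raw alpha-level events as a loose ceiling
  expect_lte(sum(degs$significant), qbinom(0.95, 500, 0.05))
})
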