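#' Simulation configuration
#'
#' Defaults describe the stated world the generator emulates: four
#' whole-blood cohorts (control n = 48, heterogeneous case n = 52, two
#' genetically defined variant cohorts n = 7 and n = 15), probes
#' predominantly inside repeats and predominantly methylated (baseline
#' mean beta 0.8 on the logit scale), beta-distributed noise with
#' precision 100 (per-probe sd about 0.04 at beta = 0.8), and a pool of
#' RepeatMasker-style repeat names covering every taxonomy family plus
#' unclassifiable decoys.
#'
#' @param n_probes number of array probes.
#' @param fraction_in_repeats fraction of probes placed inside repeats.
#' @param repeat_name_pool named numeric vector: repeat names with
#'   sampling weights.
#' @param group_sizes named integer vector of cohort sizes; the first
#'   entry is the control cohort.
#' @param control_label label of the control group.
#' @param baseline_mu_logit_mean,baseline_mu_logit_sd per-probe baseline
#'   mean beta is `plogis(Normal(mean, sd^2))`.
#' @param precision precision `nu` of the beta noise
#'   (`Var = mu (1 - mu) / (nu + 1)`).
#' @param effects list of [effect_spec()] objects.
#' @param n_gene_pool size of the background gene-symbol pool.
#' @param n_expression_studies number of synthetic expression studies.
#' @param expr_samples_per_group samples per group in each study.
#' @param expr_sd residual sd of log2 expression.
#' @param planted_genes data.frame (`gene`, `study_id`, `log2fc`) of
#'   per-study planted expression shifts, or `NULL`.
#' @param candidates data.frame (`gene`, `direction`) of genes planted as
#'   true inverse-relationship candidates (direction is the methylation
#'   sign, expression is planted opposite), or `NULL`.
#' @param decoys like `candidates` but with same-direction expression,
#'   so the inverse filter must reject them.
#' @param candidate_abs_delta planted |delta beta| for candidate/decoy
#'   loci (default 0.10).
#' @param candidate_n_support supporting studies per planted candidate
#'   (default 2).
#' @param seed default RNG seed.
#' @return object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_probes = 2000L,
                       fraction_in_repeats = 0.8,
                       repeat_name_pool = NULL,
                       group_sizes = c(control = 48L, heterogeneous = 52L,
                                       variantA = 7L, variantB = 15L),
                       control_label = names(group_sizes)[1],
                       baseline_mu_logit_mean = stats::qlogis(0.8),
                       baseline_mu_logit_sd = 0.5,
                       precision = 100,
                       effects = list(),
                       n_gene_pool = 300L,
                       n_expression_studies = 3L,
                       expr_samples_per_group = 40L,
                       expr_sd = 0.3,
                       planted_genes = NULL,
                       candidates = NULL,
                       decoys = NULL,
                       candidate_abs_delta = 0.10,
                       candidate_n_support = 2L,
                       seed = 1L) {
  if (is.null(repeat_name_pool)) {
    repeat_name_pool <- c(
      L1HS = 1, L1PA3 = 1, L1PA4 = 1, L1PB1 = 1, L1P1 = 1,
      L1M5 = 1, L1MC1 = 1, L1MB3 = 1,
      HAL1 = 1, FLAM_C = 0.5, FRAM = 0.5, FAM = 0.5,
      AluJo = 1.5, AluJb = 1, AluSx = 2, AluSg = 1, AluSq = 1,
      AluY = 2, AluYb8 = 0.5,
      MER41B = 0.5, MIRb = 0.5, L2a = 0.5)
  }
  stopifnot(all(group_sizes >= 2), precision > 0,
            fraction_in_repeats > 0, fraction_in_repeats <= 1)
  cfg <- list(n_probes = as.integer(n_probes),
              fraction_in_repeats = fraction_in_repeats,
              repeat_name_pool = repeat_name_pool,
              group_sizes = group_sizes,
              control_label = control_label,
              baseline_mu_logit_mean = baseline_mu_logit_mean,
              baseline_mu_logit_sd = baseline_mu_logit_sd,
              precision = precision,
              effects = effects,
              n_gene_pool = as.integer(n_gene_pool),
              gene_pool = sprintf("GENE%04d", seq_len(n_gene_pool)),
              n_expression_studies = as.integer(n_expression_studies),
              expr_samples_per_group = as.integer(expr_samples_per_group),
              expr_sd = expr_sd,
              planted_genes = planted_genes,
              candidates = candidates,
              decoys = decoys,
              candidate_abs_delta = candidate_abs_delta,
              candidate_n_support = as.integer(candidate_n_support),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Planted-effect specification
#'
#' An effect shifts the logit of the per-probe mean beta by `delta_logit`
#' for samples of the affected groups, at the probes named by `target`
#' (a set of family names, of age classes, or of explicit probe ids).
#'
#' @param target character vector naming families, age classes, or probe
#'   ids.
#' @param groups affected cohort labels (must not include the control
#'   label; checked at simulation time).
#' @param delta_logit finite shift on the log-odds of the mean beta;
#'   ignored when `delta_beta` is given.
#' @param baseline_mu baseline mean beta used for the bookkeeping
#'   `expected_delta_beta` (default 0.8).
#' @param delta_beta alternatively, a shift stated on the beta scale:
#'   each targeted probe gets the per-probe logit shift that moves *its
#'   own* baseline mean by exactly `delta_beta` (clamped inside (0, 1)),
#'   so the planted effect size is uniform across probes regardless of
#'   their baselines.
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(target, groups, delta_logit = NULL,
                        baseline_mu = 0.8, delta_beta = NULL) {
  stopifnot(length(groups) >= 1)
  if (is.null(delta_beta)) {
    stopifnot(is.finite(delta_logit))
    expected <- stats::plogis(stats::qlogis(baseline_mu) + delta_logit) -
      baseline_mu
  } else {
    stopifnot(is.finite(delta_beta), abs(delta_beta) < 1)
    delta_logit <- NULL
    expected <- delta_beta
  }
  ef <- list(target = target, groups = groups, delta_logit = delta_logit,
             delta_beta = delta_beta, expected_delta_beta = expected)
  class(ef) <- "effect_spec"
  ef
}

# delta_logit that moves the baseline mean beta by delta_beta
delta_logit_for <- function(delta_beta, baseline_mu = 0.8) {
  stats::qlogis(baseline_mu + delta_beta) - stats::qlogis(baseline_mu)
}

#' Simulate a repeat annotation and probe manifest
#'
#' Repeats are laid out in non-overlapping genomic windows over four
#' chromosomes with names drawn from the configured pool (every pool
#' name appears at least once); Alu-like repeats are a few hundred bp,
#' LINE-like repeats up to several kb. `fraction_in_repeats` of probes
#' are placed uniformly inside repeats (positions include both repeat
#' edges, so boundary overlaps of 1 bp occur); the remainder are placed
#' in guaranteed repeat-free zones. Each probe carries 0-2 (gene,
#' feature) pairs with features drawn from the six gene-region
#' categories.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list with `repeats` (BED-like data.frame) and `probes`
#'   (manifest data.frame).
#' @export
simulate_annotation <- function(config, seed = config$seed) {
  set.seed(seed)
  pool <- config$repeat_name_pool
  n_probes <- config$n_probes
  n_in <- round(n_probes * config$fraction_in_repeats)
  n_rep <- max(length(pool), ceiling(n_in / 2))
  nm <- c(names(pool),
          sample(names(pool), max(0, n_rep - length(pool)),
                 replace = TRUE, prob = pool))
  win <- 20000L
  chroms <- paste0("chr", 1:4)
  chrom <- chroms[(seq_len(n_rep) - 1) %% 4 + 1]
  local <- (seq_len(n_rep) - 1) %/% 4
  start <- local * win + sample(0:1000, n_rep, replace = TRUE)
  alu_like <- startsWith(nm, "Alu") | startsWith(nm, "FLAM") |
    startsWith(nm, "FRAM") | startsWith(nm, "FAM") | startsWith(nm, "MIR")
  len <- ifelse(alu_like, sample(150:350, n_rep, replace = TRUE),
                sample(500:6000, n_rep, replace = TRUE))
  repeats <- data.frame(chrom = chrom, start = start, end = start + len,
                        repeat_name = nm,
                        strand = sample(c("+", "-"), n_rep, replace = TRUE),
                        stringsAsFactors = FALSE)
  # resident probes: uniform position inside a random repeat (1-based,
  # both edges included so 1-bp boundary overlaps arise)
  ri <- sample(n_rep, n_in, replace = TRUE)
  pos_in <- repeats$start[ri] + 1L +
    floor(stats::runif(n_in) * (repeats$end[ri] - repeats$start[ri]))
  chrom_in <- repeats$chrom[ri]
  # non-resident probes: windows hold their repeat in [start, start+7000];
  # offsets 12000..18000 are always repeat-free
  n_out <- n_probes - n_in
  wo <- sample(n_rep, n_out, replace = TRUE)
  pos_out <- (wo - 1) %/% 4 * win + 12000L + sample(0:6000, n_out, replace = TRUE)
  chrom_out <- chroms[(wo - 1) %% 4 + 1]
  ord <- sample(n_probes)
  probes <- data.frame(
    probe_id = sprintf("cg%07d", seq_len(n_probes)),
    chrom = c(chrom_in, chrom_out)[ord],
    pos = c(pos_in, pos_out)[ord],
    strand = sample(c("+", "-"), n_probes, replace = TRUE),
    stringsAsFactors = FALSE)
  n_pairs <- sample(0:2, n_probes, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  gene_cols <- vapply(n_pairs, function(k) {
    if (k == 0) return(c("", ""))
    # with-replacement: a probe may list the same gene under two features
    genes <- sample(config$gene_pool, k, replace = TRUE)
    feats <- sample(re_features, k, replace = TRUE)
    c(paste(genes, collapse = ";"), paste(feats, collapse = ";"))
  }, character(2))
  probes$gene_names <- gene_cols[1, ]
  probes$gene_features <- gene_cols[2, ]
  list(repeats = repeats, probes = probes)
}

#' Simulate a sample sheet
#'
#' One row per sample with cohort label, sex (balanced Bernoulli), and
#' age (normal, mean 10, sd 3, floored at 3).
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return data.frame: `sample_id`, `group`, `sex`, `age`.
#' @export
simulate_sample_sheet <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- sum(config$group_sizes)
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    group = rep(names(config$group_sizes), config$group_sizes),
    sex = sample(c("M", "F"), n, replace = TRUE),
    age = pmax(3, round(stats::rnorm(n, 10, 3))),
    stringsAsFactors = FALSE)
}

# rows of `annotation` targeted by an effect: family names, age classes,
# or explicit probe ids
resolve_effect_target <- function(target, annotation) {
  fams <- unique(re_taxonomy$family)
  ages <- unique(re_taxonomy$age_class)
  if (all(target %in% fams)) {
    which(annotation$family %in% target)
  } else if (all(target %in% ages)) {
    which(annotation$age_class %in% target)
  } else {
    which(annotation$probe_id %in% target)
  }
}

#' Simulate a beta-value matrix with planted effects
#'
#' Per-probe baseline mean `mu_j = plogis(Normal(m, s^2))`; each effect
#' adds `delta_logit` to the logit mean for probes it targets, for
#' samples in its affected groups; observed values are
#' `Beta(mu nu, (1 - mu) nu)` draws, clamped strictly inside (0, 1).
#'
#' @param config a [sim_config()].
#' @param annotation annotated-probe table from [annotate_probes()].
#' @param samples sample sheet from [simulate_sample_sheet()].
#' @param seed RNG seed.
#' @param mu_logit optional pre-drawn per-probe baseline logit means
#'   (used by [simulate_dataset()] so that candidate probes can be
#'   chosen with knowledge of their baselines); drawn internally when
#'   `NULL`.
#' @return list with `beta` (probes x samples matrix) and `truth`
#'   (data.frame per planted probe: `probe_id`, `target`, `groups`,
#'   `delta_logit`, `baseline_mu`, `expected_delta_beta`).
#' @export
simulate_beta <- function(config, annotation, samples, seed = config$seed,
                          mu_logit = NULL) {
  set.seed(seed)
  n_p <- nrow(annotation)
  n_s <- nrow(samples)
  if (is.null(mu_logit)) {
    mu_logit <- stats::rnorm(n_p, config$baseline_mu_logit_mean,
                             config$baseline_mu_logit_sd)
  }
  stopifnot(length(mu_logit) == n_p)
  L <- matrix(mu_logit, n_p, n_s)
  truth <- list()
  for (ef in config$effects) {
    if (config$control_label %in% ef$groups) {
      stop("simulate_beta: effect groups must exclude the control group")
    }
    idx <- resolve_effect_target(ef$target, annotation)
    if (!length(idx)) {
      warning("simulate_beta: effect target names no probes; skipped: ",
              paste(ef$target, collapse = ","))
      next
    }
    cols <- samples$group %in% ef$groups
    if (is.null(ef$delta_beta)) {
      dl <- rep(ef$delta_logit, length(idx))
    } else {
      # beta-scale effect: per-probe logit shift moving each baseline by
      # exactly delta_beta (target clamped inside (0, 1))
      mu0 <- stats::plogis(mu_logit[idx])
      mu1 <- pmin(pmax(mu0 + ef$delta_beta, 1e-4), 1 - 1e-4)
      dl <- stats::qlogis(mu1) - mu_logit[idx]
    }
    L[idx, cols] <- L[idx, cols] + dl
    truth[[length(truth) + 1]] <- data.frame(
      probe_id = annotation$probe_id[idx],
      target = paste(ef$target, collapse = ";"),
      groups = paste(ef$groups, collapse = ";"),
      delta_logit = dl,
      baseline_mu = stats::plogis(mu_logit[idx]),
      expected_delta_beta = stats::plogis(mu_logit[idx] + dl) -
        stats::plogis(mu_logit[idx]),
      stringsAsFactors = FALSE)
  }
  MU <- stats::plogis(L)
  nu <- config$precision
  B <- matrix(stats::rbeta(n_p * n_s, MU * nu, (1 - MU) * nu), n_p, n_s)
  eps <- 1e-6
  B[B < eps] <- eps
  B[B > 1 - eps] <- 1 - eps
  rownames(B) <- annotation$probe_id
  colnames(B) <- samples$sample_id
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(probe_id = character(), target = character(),
               groups = character(), delta_logit = numeric(),
               baseline_mu = numeric(), expected_delta_beta = numeric(),
               stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(beta = B, truth = truth)
}

#' Simulate expression studies with planted shifts
#'
#' For each study, a gene x sample matrix of log2 expression (gene
#' baselines Normal(7, 1), residual sd `expr_sd`) over a case and a
#' control group; genes listed in `config$planted_genes` for that study
#' get their `log2fc` added to the case samples. All other genes are
#' null.
#'
#' @param config a [sim_config()]; `planted_genes` is a data.frame with
#'   columns `gene`, `study_id`, `log2fc` (may be `NULL` for all-null
#'   studies).
#' @param seed RNG seed.
#' @return list with `studies` (named list; each element has `expr`,
#'   `groups`, `study_id`) and `truth` (the planted_genes table).
#' @export
simulate_expression_studies <- function(config, seed = config$seed) {
  set.seed(seed)
  planted <- config$planted_genes
  genes <- unique(c(if (!is.null(planted)) planted$gene, config$gene_pool))
  n_g <- length(genes)
  n <- config$expr_samples_per_group
  studies <- list()
  for (s in seq_len(config$n_expression_studies)) {
    sid <- sprintf("STUDY%02d", s)
    base <- stats::rnorm(n_g, 7, 1)
    X <- base + matrix(stats::rnorm(n_g * 2 * n, 0, config$expr_sd), n_g)
    groups <- rep(c("case", "control"), each = n)
    rownames(X) <- genes
    colnames(X) <- sprintf("%s_%s%02d", sid, groups, c(seq_len(n), seq_len(n)))
    if (!is.null(planted)) {
      ps <- planted[planted$study_id == sid, , drop = FALSE]
      for (i in seq_len(nrow(ps))) {
        gi <- match(ps$gene[i], genes)
        X[gi, groups == "case"] <- X[gi, groups == "case"] + ps$log2fc[i]
      }
    }
    studies[[sid]] <- list(expr = X, groups = groups, study_id = sid)
  }
  truth <- if (is.null(planted)) {
    data.frame(gene = character(), study_id = character(),
               log2fc = numeric(), stringsAsFactors = FALSE)
  } else planted
  list(studies = studies, truth = truth)
}

#' Simulate a complete linked methylation + expression dataset
#'
#' Wires the pieces together: annotation, sample sheet, beta matrix with
#' the configured effects, and expression studies. When
#' `config$candidates` / `config$decoys` are given, one repeat-resident
#' probe with a named family is picked for each gene, its gene
#' annotation is rewritten to that gene (feature "Body"), a locus-level
#' methylation effect of `candidate_abs_delta` (sign = `direction`) is
#' planted in the heterogeneous cohort, and expression shifts of 0.5
#' log2 units are planted in `candidate_n_support` studies — opposite in
#' sign to the methylation change for candidates (true positives under
#' the inverse filter) and same-signed for decoys (must be rejected).
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; sub-stages use seed, seed + 1, ...
#' @param dir optional output directory; when given, all fixtures are
#'   written as plain-text files (see Details).
#' @param case_group cohort receiving the candidate/decoy methylation
#'   effects (default `"heterogeneous"`).
#' @return list: `repeats`, `manifest`, `annotation` (annotated probes),
#'   `samples`, `beta`, `beta_truth`, `expression`, `candidate_truth`,
#'   `config`, and `files` (named paths) when `dir` was given.
#' @export
simulate_dataset <- function(config, seed = config$seed, dir = NULL,
                             case_group = "heterogeneous") {
  ann <- simulate_annotation(config, seed)
  annotated <- annotate_probes(ann$probes, ann$repeats)
  samples <- simulate_sample_sheet(config, seed + 1L)

  planted <- config$planted_genes
  effects <- config$effects
  cand_truth <- data.frame(gene = character(), probe_id = character(),
                           direction = numeric(), n_support = integer(),
                           role = character(), stringsAsFactors = FALSE)
  wired <- rbind(
    if (!is.null(config$candidates))
      cbind(config$candidates, role = "candidate", stringsAsFactors = FALSE),
    if (!is.null(config$decoys))
      cbind(config$decoys, role = "decoy", stringsAsFactors = FALSE))
  # baselines are drawn up front so candidate probes can be placed where
  # the stated beta-scale shift is physically plantable
  set.seed(seed + 3L)
  mu_logit <- stats::rnorm(nrow(annotated), config$baseline_mu_logit_mean,
                           config$baseline_mu_logit_sd)
  if (!is.null(wired) && nrow(wired)) {
    set.seed(seed + 2L)
    mu0 <- stats::plogis(mu_logit)
    picks <- integer(nrow(wired))
    taken <- logical(nrow(annotated))
    for (i in seq_len(nrow(wired))) {
      target_mu <- mu0 + wired$direction[i] * config$candidate_abs_delta
      eligible <- which(is_repeat_resident(annotated) &
                          annotated$family != "unclassified" & !taken &
                          target_mu > 0.02 & target_mu < 0.98)
      stopifnot(length(eligible) >= 1)
      picks[i] <- if (length(eligible) == 1) eligible else
        sample(eligible, 1)
      taken[picks[i]] <- TRUE
    }
    for (i in seq_len(nrow(wired))) {
      pi_ <- picks[i]
      annotated$gene_names[pi_] <- wired$gene[i]
      annotated$gene_features[pi_] <- "Body"
      ann$probes$gene_names[match(annotated$probe_id[pi_],
                                  ann$probes$probe_id)] <- wired$gene[i]
      ann$probes$gene_features[match(annotated$probe_id[pi_],
                                     ann$probes$probe_id)] <- "Body"
      effects <- c(effects, list(effect_spec(
        annotated$probe_id[pi_], case_group,
        delta_beta = wired$direction[i] * config$candidate_abs_delta)))
      expr_sign <- if (wired$role[i] == "candidate") -1 else 1
      sids <- sprintf("STUDY%02d",
                      sample(config$n_expression_studies,
                             config$candidate_n_support))
      planted <- rbind(planted, data.frame(
        gene = wired$gene[i], study_id = sids,
        log2fc = expr_sign * wired$direction[i] * 0.5,
        stringsAsFactors = FALSE))
      cand_truth <- rbind(cand_truth, data.frame(
        gene = wired$gene[i], probe_id = annotated$probe_id[pi_],
        direction = wired$direction[i],
        n_support = config$candidate_n_support,
        role = wired$role[i], stringsAsFactors = FALSE))
    }
  }
  cfg2 <- config
  cfg2$effects <- effects
  cfg2$planted_genes <- planted
  bt <- simulate_beta(cfg2, annotated, samples, seed + 3L,
                      mu_logit = mu_logit)
  expr <- simulate_expression_studies(cfg2, seed + 4L)
  out <- list(repeats = ann$repeats, manifest = ann$probes,
              annotation = annotated, samples = samples,
              beta = bt$beta, beta_truth = bt$truth,
              expression = expr, candidate_truth = cand_truth,
              config = cfg2)
  if (!is.null(dir)) out$files <- write_sim_dataset(out, dir)
  out
}

# write every fixture of a simulate_dataset() result as plain text
write_sim_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- list(
    repeats = file.path(dir, "repeats.bed"),
    manifest = file.path(dir, "manifest.csv"),
    annotation = file.path(dir, "annotation.tsv"),
    samples = file.path(dir, "samples.csv"),
    beta = file.path(dir, "beta.tsv"),
    beta_truth = file.path(dir, "beta_truth.tsv"),
    expression_truth = file.path(dir, "expression_truth.tsv"),
    candidate_truth = file.path(dir, "candidate_truth.tsv"))
  utils::write.table(ds$repeats, f$repeats, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(ds$manifest, f$manifest, row.names = FALSE, quote = FALSE)
  write_annotation(ds$annotation, f$annotation)
  utils::write.csv(ds$samples, f$samples, row.names = FALSE, quote = FALSE)
  write_beta_matrix(ds$beta, f$beta)
  write_tsv(ds$beta_truth, f$beta_truth)
  write_tsv(ds$expression$truth, f$expression_truth)
  write_tsv(ds$candidate_truth, f$candidate_truth)
  for (sid in names(ds$expression$studies)) {
    st <- ds$expression$studies[[sid]]
    ef <- file.path(dir, sprintf("expr_%s.tsv", sid))
    df <- data.frame(gene = rownames(st$expr), st$expr, check.names = FALSE)
    utils::write.table(df, ef, sep = "\t", quote = FALSE, row.names = FALSE)
    gf <- file.path(dir, sprintf("expr_%s_groups.csv", sid))
    utils::write.csv(data.frame(sample_id = colnames(st$expr),
                                group = st$groups),
                     gf, row.names = FALSE, quote = FALSE)
    f[[paste0("expr_", sid)]] <- ef
    f[[paste0("expr_", sid, "_groups")]] <- gf
  }
  f
}
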