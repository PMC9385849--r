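#' Pipeline configuration
#'
#' Collects file paths, group labels, and every threshold the analysis
#' uses under its published default (FDR 0.05, |delta beta| >= 0.05,
#' >= 2 supporting studies, DEG q < 0.05). Configurations can also be
#' loaded from a JSON file with [read_pipeline_config()].
#'
#' @param repeats,manifest,beta,samples input file paths (BED-like repeat
#'   annotation, probe-manifest CSV, beta-matrix TSV, sample-sheet CSV).
#' @param expression named list of expression studies, each a list with
#'   `expr` (TSV path) and `groups` (CSV path); or `NULL`.
#' @param deg_tables paths of precomputed DEG TSVs (`study_id`, `gene`,
#'   `log2FC`, `q`); used instead of `expression` when given.
#' @param control,heterogeneous,variants group labels (variants is a
#'   character vector of variant-cohort labels).
#' @param alpha_fdr DMP significance threshold.
#' @param min_abs_delta,min_studies,q_max integration-filter thresholds.
#' @param stratify_fdr BH within element classes (default) or pooled.
#' @param var_equal pooled-variance t instead of Welch.
#' @param ci_method ROC CI method, `"delong"` or `"bootstrap"`.
#' @param gene_list optional reference gene-list file for candidate
#'   flagging.
#' @param seed RNG seed recorded in outputs and used for any stochastic
#'   step.
#' @param out_dir output directory.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(repeats, manifest, beta, samples,
                            expression = NULL, deg_tables = NULL,
                            control = "control",
                            heterogeneous = "heterogeneous",
                            variants = c("variantA", "variantB"),
                            alpha_fdr = 0.05, min_abs_delta = 0.05,
                            min_studies = 2L, q_max = 0.05,
                            stratify_fdr = TRUE, var_equal = FALSE,
                            ci_method = "delong", gene_list = NULL,
                            seed = 1L, out_dir = tempfile("retromethyl_run")) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with fields named as in [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  do.call(pipeline_config, x[intersect(names(x), known)])
}

#' Validate a pipeline configuration
#'
#' Non-throwing structural checks: files exist, thresholds lie in valid
#' ranges, group labels are distinct and present in the sample sheet.
#'
#' @param config a [pipeline_config()].
#' @return character vector of violations (empty when valid).
#' @export
validate_config <- function(config) {
  v <- character()
  chk <- function(cond, msg) if (isTRUE(cond)) v else c(v, msg)
  for (f in c("repeats", "manifest", "beta", "samples")) {
    p <- config[[f]]
    v <- chk(is.character(p) && length(p) == 1 && file.exists(p),
             sprintf("input file '%s' missing or not found: %s", f,
                     paste(p, collapse = ",")))
  }
  for (th in c("alpha_fdr", "q_max")) {
    v <- chk(is.numeric(config[[th]]) && config[[th]] > 0 && config[[th]] <= 1,
             sprintf("%s must be in (0, 1]: %s", th, config[[th]]))
  }
  v <- chk(is.numeric(config$min_abs_delta) && config$min_abs_delta >= 0 &&
             config$min_abs_delta <= 1,
           "min_abs_delta must be in [0, 1]")
  v <- chk(config$min_studies >= 1, "min_studies must be >= 1")
  labels <- c(config$control, config$heterogeneous, config$variants)
  v <- chk(!anyDuplicated(labels),
           "group labels (control/heterogeneous/variants) must be distinct")
  if (is.character(config$samples) && length(config$samples) == 1 &&
      file.exists(config$samples)) {
    ss <- tryCatch(read_sample_sheet(config$samples), error = function(e) NULL)
    if (!is.null(ss)) {
      miss <- setdiff(labels, unique(ss$group))
      v <- chk(length(miss) == 0,
               paste("labels absent from sample sheet:",
                     paste(miss, collapse = ", ")))
    }
  }
  v
}

#' Run the full repetitive-element methylation pipeline
#'
#' Stages, in order: probe annotation; total/family/locus differential
#' methylation for each case cohort against control; gene-region feature
#' enrichment of the heterogeneous DMPs; Venn partition of the three
#' significant sets and variant-unique target-locus selection;
#' DMP-to-gene mapping and the inverse-relationship candidate filter
#' against the DEG tables; ROC evaluation of each variant's target loci
#' against the pooled remaining cohorts. Every intermediate table is
#' written as TSV with its thresholds in the header; a `run_log.txt`
#' records per-stage row counts. Rerunning with identical config and
#' inputs reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of all result tables plus `out_dir`.
#' @export
run_pipeline <- function(config) {
  viol <- validate_config(config)
  if (length(viol)) {
    stop("invalid pipeline config:\n  - ", paste(viol, collapse = "\n  - "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run_log.txt")
  cat(sprintf("retromethyl %s | seed=%d | alpha_fdr=%g\n",
              as.character(utils::packageVersion("retromethyl")),
              config$seed, config$alpha_fdr), file = logf)
  say <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                           append = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  meta <- list(seed = config$seed, alpha_fdr = config$alpha_fdr)

  # --- annotation ------------------------------------------------------
  res <- list()
  annotation <- stage("annotate", {
    repeats <- read_repeat_annotation(config$repeats)
    probes <- read_probe_manifest(config$manifest)
    annotate_probes(probes, repeats)
  })
  res$annotation <- annotation
  write_annotation(annotation, file.path(config$out_dir, "annotation.tsv"),
                   meta = meta)
  say("annotate: %d probes, %d repeat-resident",
      nrow(annotation), sum(is_repeat_resident(annotation)))

  beta <- stage("load_beta", read_beta_matrix(config$beta))
  samples <- stage("load_samples", read_sample_sheet(config$samples))

  # --- differential methylation per comparison -------------------------
  cases <- c(config$heterogeneous, config$variants)
  res$total <- list(); res$family <- list(); res$dmps <- list()
  for (case in cases) {
    tot <- stage(paste0("total_", case),
                 total_re_methylation(beta, annotation, samples, case,
                                      config$control,
                                      var_equal = config$var_equal))
    fam <- stage(paste0("family_", case),
                 family_methylation(beta, annotation, samples, case,
                                    config$control,
                                    var_equal = config$var_equal))
    dmp <- stage(paste0("dmp_", case),
                 call_dmps(beta, annotation, samples, case, config$control,
                           alpha_fdr = config$alpha_fdr,
                           stratify_fdr = config$stratify_fdr,
                           var_equal = config$var_equal))
    res$total[[case]] <- tot; res$family[[case]] <- fam
    res$dmps[[case]] <- dmp
    write_tsv(data.frame(comparison = paste(case, "vs", config$control),
                         delta_beta = tot$delta_beta, t = tot$t, df = tot$df,
                         p = tot$p, n_probes = tot$n_probes),
              file.path(config$out_dir, sprintf("total_%s.tsv", case)),
              meta = meta)
    write_tsv(fam, file.path(config$out_dir, sprintf("family_%s.tsv", case)),
              meta = meta)
    write_tsv(dmp, file.path(config$out_dir, sprintf("dmps_%s.tsv", case)),
              meta = c(meta, list(stratify_fdr = config$stratify_fdr)))
    say("dmp_%s: %d probes tested, %d significant at FDR %g", case,
        nrow(dmp), sum(dmp$significant), config$alpha_fdr)
  }

  # --- feature enrichment (heterogeneous signatures) -------------------
  res$enrichment <- stage("enrich", do.call(rbind, lapply(
    c("LINE1", "Alu"), function(cl) {
      feature_enrichment(res$dmps[[config$heterogeneous]], annotation, cl)
    })))
  write_tsv(res$enrichment, file.path(config$out_dir, "enrichment.tsv"),
            meta = meta)

  # --- Venn partition and variant-unique target loci -------------------
  sig_sets <- lapply(res$dmps, function(d) d$probe_id[d$significant])
  res$venn <- stage("venn", venn_partition(sig_sets[[cases[1]]],
                                           sig_sets[[cases[2]]],
                                           sig_sets[[cases[3]]],
                                           names = cases))
  write_tsv(res$venn$counts, file.path(config$out_dir, "venn_counts.tsv"),
            meta = meta)
  res$targets <- list()
  for (v in config$variants) {
    tl <- stage(paste0("targets_", v),
                select_variant_target_loci(res$dmps, beta, samples, v,
                                           config$heterogeneous,
                                           alpha = config$alpha_fdr,
                                           var_equal = config$var_equal))
    res$targets[[v]] <- tl
    write_tsv(tl, file.path(config$out_dir, sprintf("targets_%s.tsv", v)),
              meta = meta)
    say("targets_%s: %d unique loci selected", v, nrow(tl))
  }

  # --- integration -----------------------------------------------------
  degs <- stage("degs", {
    if (!is.null(config$deg_tables)) {
      do.call(rbind, lapply(config$deg_tables, read_tsv))
    } else if (!is.null(config$expression)) {
      do.call(rbind, lapply(names(config$expression), function(sid) {
        st <- config$expression[[sid]]
        expr <- read_beta_matrix(st$expr)  # same layout: feature x sample
        grp <- utils::read.csv(st$groups, stringsAsFactors = FALSE)
        simple_deg_caller(expr, grp$group[match(colnames(expr),
                                                grp$sample_id)],
                          case = "case", control = "control",
                          alpha = config$q_max, study_id = sid)
      }))
    } else NULL
  })
  if (!is.null(degs)) {
    write_tsv(degs, file.path(config$out_dir, "degs.tsv"), meta = meta)
    dmgs <- stage("map_dmgs",
                  map_dmps_to_genes(res$dmps[[config$heterogeneous]],
                                    annotation))
    res$dmgs <- dmgs
    cand <- stage("candidates",
                  candidate_target_genes(dmgs, degs,
                                         min_abs_delta = config$min_abs_delta,
                                         min_studies = config$min_studies,
                                         q_max = config$q_max))
    if (!is.null(config$gene_list)) {
      cand$candidates <- stage("flag_reference",
                               flag_reference_genes(cand$candidates,
                                                    config$gene_list))
    }
    res$candidates <- cand
    write_tsv(cand$candidates, file.path(config$out_dir, "candidates.tsv"),
              meta = c(meta, list(min_abs_delta = config$min_abs_delta,
                                  min_studies = config$min_studies,
                                  q_max = config$q_max)))
    write_tsv(cand$support, file.path(config$out_dir,
                                      "candidate_support.tsv"), meta = meta)
    say("integration: %d DMG rows, %d candidate rows", nrow(dmgs),
        nrow(cand$candidates))
  }

  # --- ROC of variant-unique target loci -------------------------------
  res$roc <- list()
  for (v in config$variants) {
    tl <- res$targets[[v]]
    if (!nrow(tl)) next
    neg <- c(config$control, setdiff(config$variants, v))
    rt <- stage(paste0("roc_", v),
                roc_table(beta, samples, tl$probe_id, v, neg,
                          method = config$ci_method, seed = config$seed))
    res$roc[[v]] <- rt
    write_tsv(rt, file.path(config$out_dir, sprintf("roc_%s.tsv", v)),
              meta = meta)
    say("roc_%s: %d probes, AUC range [%.3f, %.3f]", v, nrow(rt),
        min(rt$auc), max(rt$auc))
  }
  res$out_dir <- config$out_dir
  say("done")
  invisible(res)
}
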