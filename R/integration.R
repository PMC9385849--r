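#' Simple differential-expression caller for synthetic studies
#'
#' Per-gene two-sided t test (Welch by default) on log2 expression with
#' BH-adjusted q values. `log2FC` is case mean minus control mean, i.e.
#' the same case-vs-control orientation as delta_beta on the methylation
#' side. Zero-variance genes are flagged and never called significant.
#' This is a stand-in caller for simulated expression studies, not a
#' replacement for a dedicated RNA-seq model.
#'
#' @param expr genes x samples matrix of log2 expression (gene rownames).
#' @param groups character vector of group labels, one per column.
#' @param case,control group labels.
#' @param alpha significance threshold on q (default 0.05).
#' @param study_id optional study identifier stored in the output.
#' @return data.frame: `study_id`, `gene`, `log2FC`, `t`, `p`, `q`,
#'   `significant`, `degenerate`.
#' @export
simple_deg_caller <- function(expr, groups, case, control, alpha = 0.05,
                              study_id = NA_character_) {
  ci <- which(groups == case)
  ki <- which(groups == control)
  stopifnot(length(ci) >= 2, length(ki) >= 2)
  r <- row_t_test(expr[, ci, drop = FALSE], expr[, ki, drop = FALSE])
  q <- rep(NA_real_, nrow(expr))
  ok <- !r$degenerate
  q[ok] <- bh_adjust(r$p[ok])
  data.frame(study_id = study_id, gene = rownames(expr), log2FC = r$delta,
             t = r$t, p = r$p, q = q,
             significant = !r$degenerate & !is.na(q) & q < alpha,
             degenerate = r$degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Map DMPs to their annotated genes
#'
#' One row per (probe, distinct gene) pair taken from the probe's
#' gene-name annotation; probes without gene annotation are dropped (the
#' count of dropped probes is reported with a message).
#'
#' @param dmps DMP table ([call_dmps()] output or any data.frame with
#'   `probe_id`; a `significant` column, when present, restricts to
#'   significant rows).
#' @param annotation annotated-probe table from [annotate_probes()].
#' @return data.frame: `probe_id`, `gene`, `family`, `element_class`,
#'   `delta_beta` and `p_fdr` when available in `dmps`.
#' @export
map_dmps_to_genes <- function(dmps, annotation) {
  ids <- if ("significant" %in% names(dmps)) {
    dmps$probe_id[dmps$significant]
  } else {
    dmps$probe_id
  }
  ann <- annotation[match(ids, annotation$probe_id), , drop = FALSE]
  genes <- lapply(split_genes(ann$gene_names), unique)
  n_genes <- lengths(genes)
  dropped <- sum(n_genes == 0)
  if (dropped) {
    message("map_dmps_to_genes: ", dropped,
            " probe(s) without gene annotation dropped")
  }
  out <- data.frame(
    probe_id = rep(ids, n_genes),
    gene = unlist(genes, use.names = FALSE),
    family = rep(ann$family, n_genes),
    element_class = rep(ann$element_class, n_genes),
    stringsAsFactors = FALSE)
  for (col in c("delta_beta", "p_fdr")) {
    if (col %in% names(dmps)) {
      out[[col]] <- dmps[[col]][match(out$probe_id, dmps$probe_id)]
    }
  }
  rownames(out) <- NULL
  out
}

#' Inverse-relationship multi-study candidate filter
#'
#' A (probe, gene) pair is a candidate when the methylation change is
#' substantial (`|delta_beta| >= min_abs_delta`, default 5% on the beta
#' scale) and the gene is differentially expressed in at least
#' `min_studies` studies with `q < q_max` and a log2 fold change whose
#' sign is *opposite* to the methylation change (both effects oriented
#' case vs control). Studies whose expression change has the same sign as
#' the methylation change never count as support; several qualifying
#' records from one study count that study once.
#'
#' @param dmgs DMP-to-gene table from [map_dmps_to_genes()]; must carry
#'   `delta_beta`.
#' @param degs DEG table(s): data.frame (or list of data.frames, rbound)
#'   with `study_id`, `gene`, `log2FC`, `q`.
#' @param min_abs_delta minimum |delta_beta| (default 0.05).
#' @param min_studies minimum distinct supporting studies (default 2).
#' @param q_max DEG significance threshold (default 0.05).
#' @return list with `candidates` (data.frame sorted by |delta_beta|
#'   descending: `probe_id`, `gene`, `family`, `element_class`,
#'   `delta_beta`, `n_supporting`, plus `p_fdr`/`reference_flag` when
#'   available) and `support` (long data.frame of the supporting DEG
#'   records per candidate).
#' @export
candidate_target_genes <- function(dmgs, degs, min_abs_delta = 0.05,
                                   min_studies = 2L, q_max = 0.05) {
  if (is.list(degs) && !is.data.frame(degs)) degs <- do.call(rbind, degs)
  need <- c("study_id", "gene", "log2FC", "q")
  stopifnot(all(need %in% names(degs)), "delta_beta" %in% names(dmgs))
  empty <- list(
    candidates = data.frame(probe_id = character(), gene = character(),
                            family = character(), element_class = character(),
                            delta_beta = numeric(), n_supporting = integer(),
                            stringsAsFactors = FALSE),
    support = degs[0, need])
  if (!nrow(dmgs)) return(empty)
  keep <- abs(dmgs$delta_beta) >= min_abs_delta
  dmgs <- dmgs[keep, , drop = FALSE]
  if (!nrow(dmgs)) return(empty)
  sig <- degs[!is.na(degs$q) & degs$q < q_max, , drop = FALSE]
  rows <- vector("list", nrow(dmgs))
  supp <- vector("list", nrow(dmgs))
  for (i in seq_len(nrow(dmgs))) {
    rec <- sig[sig$gene == dmgs$gene[i] &
                 sign(sig$log2FC) == -sign(dmgs$delta_beta[i]), ,
               drop = FALSE]
    n_support <- length(unique(rec$study_id))
    if (n_support >= min_studies) {
      row <- dmgs[i, , drop = FALSE]
      row$n_supporting <- n_support
      rows[[i]] <- row
      rec$probe_id <- dmgs$probe_id[i]
      supp[[i]] <- rec
    }
  }
  cand <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(cand)) return(empty)
  cand <- cand[order(-abs(cand$delta_beta), cand$probe_id, cand$gene), ,
               drop = FALSE]
  rownames(cand) <- NULL
  support <- do.call(rbind, supp[!vapply(supp, is.null, logical(1))])
  rownames(support) <- NULL
  list(candidates = cand, support = support)
}

#' Flag candidate genes present in a reference gene list
#'
#' Case-sensitive exact symbol matching against a plain-text list (one
#' symbol per line), e.g. a user-supplied autism-gene reference list.
#'
#' @param candidates candidate data.frame with a `gene` column.
#' @param gene_list path to the list file, or a character vector.
#' @return `candidates` with a logical `reference_flag` column added.
#' @export
flag_reference_genes <- function(candidates, gene_list) {
  looks_like_path <- length(gene_list) == 1 &&
    grepl("[/\\\\]|\\.(txt|tsv|csv|lst)$", gene_list)
  if (length(gene_list) == 1 && file.exists(gene_list)) {
    gene_list <- readLines(gene_list)
  } else if (looks_like_path) {
    stop("flag_reference_genes: gene list file not found: ", gene_list)
  }
  gene_list <- unique(trimws(gene_list))
  gene_list <- gene_list[nzchar(gene_list)]
  candidates$reference_flag <- candidates$gene %in% gene_list
  message("flag_reference_genes: ", sum(candidates$reference_flag), " of ",
          nrow(candidates), " candidate rows match the reference list")
  candidates
}
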