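#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p value obtained by summing, over the hypergeometric
#' support with the observed margins, the probabilities of all tables at
#' most as probable as the observed one (the standard "sum of small
#' probabilities" two-sided rule). The odds ratio is the sample odds
#' ratio `(a d) / (b c)`, reported as `Inf`/`0` on zero off-/on-diagonal
#' cells and flagged undefined when both products are zero.
#'
#' @param a,b,c,d non-negative integer cell counts; rows are (in/out of
#'   the feature), columns are (DMP / background).
#' @return list with `odds_ratio`, `p`, `undefined_or` flag.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("fisher_exact_2x2: cells must be non-negative integers")
  }
  m <- a + b        # row-1 margin (white balls)
  n2 <- c + d       # row-2 margin (black balls)
  k <- a + c        # column-1 margin (draws)
  ad <- a * d; bc <- b * c
  or_ <- if (ad == 0 && bc == 0) NaN else if (bc == 0) Inf else ad / bc
  if (sum(cells) == 0) {
    return(list(odds_ratio = NaN, p = 1, undefined_or = TRUE))
  }
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  pobs <- stats::dhyper(a, m, n2, k)
  # relative tolerance guards against ties lost to floating point
  p <- min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
  list(odds_ratio = or_, p = p, undefined_or = is.nan(or_))
}

# gene-region feature categories assigned to array probes
re_features <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR")

#' Gene-region feature enrichment of DMPs
#'
#' For each gene-region feature, tests whether significant DMPs of an
#' element class are enriched in that feature relative to the background
#' of non-DMP repeat-resident probes of the same class, by a two-sided
#' Fisher exact test. A probe counts once per distinct feature even when
#' the feature is listed for several genes; intergenic probes belong to
#' no feature and count against every feature.
#'
#' @param dmps DMP table from [call_dmps()] (only rows with
#'   `significant == TRUE` are used) or any data.frame with a `probe_id`
#'   column giving the DMP set.
#' @param annotation annotated-probe table from [annotate_probes()].
#' @param element_class `"LINE1"` or `"Alu"` (any class present works).
#' @param features feature categories to test (default the six standard
#'   gene-region categories).
#' @return data.frame: `element_class`, `feature`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p`, `p_bh` — empty when the class has no probes.
#' @export
feature_enrichment <- function(dmps, annotation, element_class,
                               features = re_features) {
  universe <- annotation[is_repeat_resident(annotation) &
                           annotation$element_class == element_class, ,
                         drop = FALSE]
  if (!nrow(universe)) {
    return(data.frame(element_class = character(), feature = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), odds_ratio = numeric(), p = numeric(),
                      p_bh = numeric(), stringsAsFactors = FALSE))
  }
  dmp_ids <- if ("significant" %in% names(dmps)) {
    dmps$probe_id[dmps$significant]
  } else {
    dmps$probe_id
  }
  is_dmp <- universe$probe_id %in% dmp_ids
  feats <- lapply(split_genes(universe$gene_features), unique)
  rows <- lapply(features, function(f) {
    has <- vapply(feats, function(x) f %in% x, logical(1))
    a <- sum(is_dmp & has)
    b <- sum(is_dmp & !has)
    cc <- sum(!is_dmp & has)
    dd <- sum(!is_dmp & !has)
    ft <- fisher_exact_2x2(a, b, cc, dd)
    data.frame(element_class = element_class, feature = f, a = a, b = b,
               c = cc, d = dd, odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
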