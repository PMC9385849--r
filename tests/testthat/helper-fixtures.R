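# Shared fixture builders. Everything is generated in code; no stored data.

# annotation table row(s) built directly (bypassing file IO) -----------------
make_annotation <- function(probe_id, repeat_name = NA_character_,
                            gene_names = "", gene_features = "",
                            chrom = "chr1", pos = seq_along(probe_id) * 100,
                            overlap_bp = ifelse(is.na(repeat_name), 0L, 2L)) {
  ann <- data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
                    strand = "+", gene_names = gene_names,
                    gene_features = gene_features,
                    repeat_name = repeat_name,
                    repeat_start = NA_integer_, repeat_end = NA_integer_,
                    overlap_bp = overlap_bp, stringsAsFactors = FALSE)
  tax <- classify_repeat_name(ann$repeat_name)
  ann$element_class <- tax$element_class
  ann$family <- tax$family
  ann$age_class <- tax$age_class
  ann
}

# sample sheet with given group sizes ----------------------------------------
make_samples <- function(sizes) {
  data.frame(sample_id = sprintf("S%03d", seq_len(sum(sizes))),
             group = rep(names(sizes), sizes), stringsAsFactors = FALSE)
}

# beta matrix from a base value plus per-group offsets on chosen probes ------
make_beta <- function(annotation, samples, base = 0.5, noise_sd = 0,
                      offsets = list(), seed = 1) {
  set.seed(seed)
  m <- matrix(base + rnorm(nrow(annotation) * nrow(samples), 0, noise_sd),
              nrow(annotation), nrow(samples))
  for (of in offsets) {  # of: list(probes=, group=, delta=)
    ri <- match(of$probes, annotation$probe_id)
    ci <- which(samples$group == of$group)
    m[ri, ci] <- m[ri, ci] + of$delta
  }
  m <- pmin(pmax(m, 1e-6), 1 - 1e-6)
  rownames(m) <- annotation$probe_id
  colnames(m) <- samples$sample_id
  m
}

# brute-force all-pairs interval oracle for annotate_probes ------------------
# CpG footprint [pos-1, pos+1) vs repeat [start, end), max overlap wins,
# ties by (chrom, start, repeat_name).
brute_force_annotate <- function(probes, repeats) {
  res <- data.frame(probe_id = probes$probe_id,
                    repeat_name = NA_character_, overlap_bp = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(probes))) {
    same <- repeats$chrom == probes$chrom[i]
    if (!any(same)) next
    rr <- repeats[same, , drop = FALSE]
    ov <- pmin(rr$end, probes$pos[i] + 1L) - pmax(rr$start, probes$pos[i] - 1L)
    hit <- ov >= 1L
    if (!any(hit)) next
    rr <- rr[hit, , drop = FALSE]
    ov <- ov[hit]
    o <- order(-ov, rr$chrom, rr$start, rr$repeat_name)
    res$repeat_name[i] <- rr$repeat_name[o[1]]
    res$overlap_bp[i] <- ov[o[1]]
  }
  res
}

# brute-force BH step-up from the definition ---------------------------------
brute_force_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# fisher two-sided p from first principles (lchoose, no dhyper) --------------
brute_force_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  N <- m + n2
  if (N == 0) return(1)
  tab_prob <- function(x) {
    exp(lchoose(m, x) + lchoose(n2, k - x) - lchoose(N, k))
  }
  support <- max(0, k - n2):min(k, m)
  probs <- vapply(support, tab_prob, numeric(1))
  pobs <- tab_prob(a)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}
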