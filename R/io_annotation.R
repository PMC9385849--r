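#' Read a BED-like repeat annotation file
#'
#' Expects at least four tab-separated columns: chrom, start, end, name,
#' optionally followed by score and strand (BED4/BED6). Coordinates are
#' 0-based half-open, as in BED.
#'
#' @param path path to the annotation file.
#' @return data.frame with columns `chrom`, `start`, `end`, `repeat_name`,
#'   `strand` (`*` when absent), rows in file order.
#' @export
read_repeat_annotation <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      repeat_name = character(), strand = character(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4)) {
    stop("malformed repeat annotation at line ", lineno[which(nf < 4)[1]],
         ": expected >= 4 tab-separated columns")
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  name <- vapply(parts, `[[`, "", 4L)
  strand <- ifelse(nf >= 6, vapply(parts, function(p) p[min(6L, length(p))], ""), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  bad <- is.na(start) | is.na(end)
  if (any(bad)) {
    stop("malformed repeat annotation at line ", lineno[which(bad)[1]],
         ": non-integer coordinates")
  }
  bad <- end <= start
  if (any(bad)) {
    stop("malformed repeat annotation at line ", lineno[which(bad)[1]],
         ": end <= start")
  }
  bad <- !nzchar(chrom) | !nzchar(name)
  if (any(bad)) {
    stop("malformed repeat annotation at line ", lineno[which(bad)[1]],
         ": empty chrom or name")
  }
  data.frame(chrom = chrom, start = start, end = end, repeat_name = name,
             strand = strand, stringsAsFactors = FALSE)
}

#' Read a CpG-probe manifest (CSV)
#'
#' Required columns: `probe_id`, `chrom`, `pos` (1-based cytosine
#' position), `strand`, `gene_names`, `gene_features`. The two gene
#' columns are parallel `;`-separated lists (empty string = no gene
#' annotation); unequal list lengths are a parse error naming the probe.
#'
#' @param path path to the manifest CSV.
#' @return data.frame, one row per probe in file order; gene columns kept
#'   as `;`-joined strings.
#' @export
read_probe_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(gene_names = "character",
                                       gene_features = "character"))
  need <- c("probe_id", "chrom", "pos", "strand", "gene_names", "gene_features")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("probe manifest is missing column(s): ", paste(miss, collapse = ", "))
  }
  df$gene_names[is.na(df$gene_names)] <- ""
  df$gene_features[is.na(df$gene_features)] <- ""
  if (any(is.na(df$pos)) || any(df$pos < 1)) {
    stop("probe manifest: pos must be a 1-based integer position")
  }
  ng <- lengths(split_genes(df$gene_names))
  nf <- lengths(split_genes(df$gene_features))
  bad <- ng != nf
  if (any(bad)) {
    stop("probe manifest: gene_names/gene_features length mismatch for probe ",
         df$probe_id[which(bad)[1]])
  }
  df[, need]
}

# ";"-separated parallel lists -> list of character vectors ("" -> empty)
split_genes <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  out[!nzchar(x)] <- list(character(0))
  out
}

#' Annotate CpG probes with their host repeat and taxonomy
#'
#' Each probe's CpG dinucleotide is taken as the 0-based half-open
#' interval `[pos - 1, pos + 1)` (the CG two-base footprint). A probe is
#' repeat-resident iff that interval overlaps a repeat by at least 1 bp,
#' ignoring strand. When several repeats overlap, the repeat with maximal
#' overlap wins; ties are broken deterministically by (chrom, start,
#' repeat_name), so the result does not depend on annotation file order.
#'
#' @param probes data.frame as from [read_probe_manifest()].
#' @param repeats data.frame as from [read_repeat_annotation()].
#' @return data.frame, one row per probe in probe order, with columns
#'   `probe_id`, `chrom`, `pos`, `strand`, `gene_names`, `gene_features`,
#'   `repeat_name` (`NA` for non-resident probes), `repeat_start`,
#'   `repeat_end`, `overlap_bp` (0 for non-resident), `element_class`,
#'   `family`, `age_class`.
#' @export
annotate_probes <- function(probes, repeats) {
  out <- probes[, c("probe_id", "chrom", "pos", "strand",
                    "gene_names", "gene_features")]
  rownames(out) <- NULL
  out$repeat_name <- NA_character_
  out$repeat_start <- NA_integer_
  out$repeat_end <- NA_integer_
  out$overlap_bp <- 0L
  if (nrow(repeats) && nrow(probes)) {
    seqs <- union(unique(probes$chrom), unique(repeats$chrom))
    pr <- GenomicRanges::GRanges(
      factor(probes$chrom, seqs),
      IRanges::IRanges(start = probes$pos, end = probes$pos + 1L))
    rr <- GenomicRanges::GRanges(
      factor(repeats$chrom, seqs),
      IRanges::IRanges(start = repeats$start + 1L, end = repeats$end))
    hits <- GenomicRanges::findOverlaps(pr, rr, ignore.strand = TRUE)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(pr)[q], IRanges::ranges(rr)[s]))
      ord <- order(q, -ov, repeats$chrom[s], repeats$start[s],
                   repeats$repeat_name[s])
      best <- ord[!duplicated(q[ord])]
      qb <- q[best]; sb <- s[best]
      out$repeat_name[qb] <- repeats$repeat_name[sb]
      out$repeat_start[qb] <- repeats$start[sb]
      out$repeat_end[qb] <- repeats$end[sb]
      out$overlap_bp[qb] <- ov[best]
    }
  }
  tax <- classify_repeat_name(out$repeat_name)
  out$element_class <- tax$element_class
  out$family <- tax$family
  out$age_class <- tax$age_class
  out
}

# repeat-resident probe indicator used by total/locus analyses
is_repeat_resident <- function(annotation) {
  !is.na(annotation$repeat_name) & annotation$overlap_bp >= 1L
}

#' Write an annotated-probe table as TSV
#' @param annotation data.frame from [annotate_probes()].
#' @param path output path.
#' @param meta optional `# key=value` header metadata.
#' @return the path, invisibly.
#' @export
write_annotation <- function(annotation, path, meta = NULL) {
  cols <- c("probe_id", "chrom", "pos", "strand", "repeat_name",
            "element_class", "family", "age_class", "overlap_bp",
            "gene_names", "gene_features")
  write_tsv(annotation[, cols], path, meta = meta)
}

#' Read an annotated-probe TSV written by [write_annotation()]
#' @param path file path.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  ann <- read_tsv(path)
  ann$repeat_name[ann$repeat_name %in% c("", "NA")] <- NA_character_
  ann$gene_names[is.na(ann$gene_names)] <- ""
  ann$gene_features[is.na(ann$gene_features)] <- ""
  ann
}
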