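#' @importFrom stats plogis qlogis pt pnorm pchisq rnorm rbeta dhyper var
#' @importFrom utils read.csv read.delim write.table write.csv
NULL

# logit / inverse logit on the beta (methylation fraction) scale
logit <- stats::qlogis
invlogit <- stats::plogis

#' Write a table as TSV with a commented metadata header
#'
#' Output tables carry the thresholds that produced them as `# key=value`
#' comment lines so that any downstream reader can audit the filter chain.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param meta named list/vector written as `# key=value` header lines.
#' @return the path, invisibly.
#' @export
write_tsv <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(sprintf("# %s=%s", names(meta),
                       vapply(meta, function(x) paste(format(x), collapse = ","), "")),
               con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()], skipping `#` comment lines
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a beta-value matrix (probes x samples) as TSV
#'
#' First column `probe_id`, remaining columns one per sample.
#'
#' @param beta numeric matrix with probe rownames and sample colnames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a beta-value matrix written by [write_beta_matrix()]
#' @param path file path.
#' @return numeric matrix, probes x samples.
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a sample sheet (CSV: sample_id, group, optional sex, age)
#' @param path file path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(ss))
  if (length(miss)) {
    stop("sample sheet is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  ss
}

# columns of `beta` belonging to samples of `label`; errors if fewer than `min_n`
group_cols <- function(beta, samples, label, min_n = 2L) {
  ids <- samples$sample_id[samples$group == label]
  cols <- match(ids, colnames(beta))
  if (anyNA(cols)) stop("samples of group '", label, "' missing from beta matrix")
  if (length(cols) < min_n) {
    stop("group '", label, "' has fewer than ", min_n, " samples")
  }
  cols
}
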