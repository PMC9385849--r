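#' LINE-1 / Alu repeat-family taxonomy
#'
#' Fixed family and evolutionary-age taxonomy used throughout the package.
#' RepeatMasker-style names are assigned to families by longest-prefix
#' matching with precedence L1HS > L1PA > L1PB > L1P > L1M for LINE-1 and
#' the AluJ/AluS/AluY prefixes for Alu; the "related" class collects half-L1
#' (HAL1) and the fossil/free Alu monomers (FAM, FLAM, FRAM). Age classes:
#' old = {L1M, AluJ}, intermediate = {L1P, L1PB, AluS},
#' young = {L1HS, L1PA, AluY}, related = {HAL1, FAM, FLAM, FRAM}.
#'
#' @format data.frame with columns `prefix`, `element_class`, `family`,
#'   `age_class`, in matching-precedence order.
#' @export
re_taxonomy <- data.frame(
  prefix        = c("L1HS", "L1PA", "L1PB", "L1P", "L1M",
                    "HAL1", "FLAM", "FRAM", "FAM",
                    "AluJ", "AluS", "AluY"),
  element_class = c(rep("LINE1", 5), rep("related", 4), rep("Alu", 3)),
  family        = c("L1HS", "L1PA", "L1PB", "L1P", "L1M",
                    "HAL1", "FLAM", "FRAM", "FAM",
                    "AluJ", "AluS", "AluY"),
  age_class     = c("young", "young", "intermediate", "intermediate", "old",
                    "related", "related", "related", "related",
                    "old", "intermediate", "young"),
  stringsAsFactors = FALSE
)

#' Classify RepeatMasker-style repeat names into the LINE-1/Alu taxonomy
#'
#' Vectorised prefix classification. Names matching none of the taxonomy
#' prefixes (e.g. "MER41B", DNA transposons, other LINE families) are
#' returned as `unclassified` in all three fields; the function never
#' raises on unmatched input. `NA` names (probes outside any repeat) are
#' also `unclassified`.
#'
#' @param repeat_name character vector of repeat names, e.g. "AluSg7",
#'   "L1PA3", "HAL1".
#' @return data.frame with columns `repeat_name`, `element_class`,
#'   `family`, `age_class`, one row per input in input order.
#' @examples
#' classify_repeat_name(c("AluSg7", "L1PA3", "HAL1", "L1MC1", "MER41B"))
#' @export
classify_repeat_name <- function(repeat_name) {
  n <- length(repeat_name)
  out <- data.frame(repeat_name = repeat_name,
                    element_class = rep("unclassified", n),
                    family = rep("unclassified", n),
                    age_class = rep("unclassified", n),
                    stringsAsFactors = FALSE)
  pending <- !is.na(repeat_name)
  for (i in seq_len(nrow(re_taxonomy))) {
    hit <- pending & startsWith(out$repeat_name, re_taxonomy$prefix[i])
    hit[is.na(hit)] <- FALSE
    if (any(hit)) {
      out$element_class[hit] <- re_taxonomy$element_class[i]
      out$family[hit] <- re_taxonomy$family[i]
      out$age_class[hit] <- re_taxonomy$age_class[i]
      pending <- pending & !hit
    }
  }
  out
}
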