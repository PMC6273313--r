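#' Read a peptide-level SILAC evidence table
#'
#' Reads a tab-separated evidence export (one row per peptide observation
#' with per-channel intensities). Required columns: `peptide`,
#' `protein_id`, `intensity_H`, `intensity_L`, `replicate`. Rows whose
#' intensities cannot be parsed as numbers are dropped with a warning
#' giving the count.
#'
#' @param path Path to a TSV file.
#' @return Data frame of typed evidence records.
#' @export
parse_evidence <- function(path) {
  if (!file.exists(path)) stop("evidence file not found: ", path,
                               call. = FALSE)
  ev <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("peptide", "protein_id", "intensity_H", "intensity_L",
                "replicate")
  missing <- setdiff(required, names(ev))
  if (length(missing) > 0) {
    stop("evidence file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  iH <- suppressWarnings(as.numeric(ev$intensity_H))
  iL <- suppressWarnings(as.numeric(ev$intensity_L))
  bad <- is.na(iH) | is.na(iL)
  if (any(bad)) {
    warning(sum(bad), " row(s) with unparseable intensities dropped",
            call. = FALSE)
  }
  ev <- ev[!bad, , drop = FALSE]
  ev$intensity_H <- iH[!bad]
  ev$intensity_L <- iL[!bad]
  rownames(ev) <- NULL
  ev
}

#' Summarize peptide log2 ratios into one protein ratio
#'
#' A protein satisfies the quantitation criteria when it has at least
#' `min_ratio_count` peptide H/L ratios; its log2 ratio is then the median
#' of the peptide log2 ratios. Below the count criterion the protein is
#' excluded (`NA`).
#'
#' @param peptide_log2_ratios Numeric vector of peptide log2(H/L) values.
#' @param min_ratio_count Minimum number of peptide ratios required.
#' @return The median log2 ratio, or `NA_real_` when excluded.
#' @examples
#' protein_ratio(c(1.0, 1.2, 0.8), min_ratio_count = 2)  # 1.0
#' protein_ratio(0.5, min_ratio_count = 2)               # NA (excluded)
#' @export
protein_ratio <- function(peptide_log2_ratios, min_ratio_count = 2) {
  x <- peptide_log2_ratios[is.finite(peptide_log2_ratios)]
  if (length(x) < min_ratio_count || length(x) == 0) return(NA_real_)
  stats::median(x)
}

#' Quantify one experiment: evidence to protein log2 H/L ratios
#'
#' Computes peptide ratios as `log2(intensity_H / intensity_L)` for rows
#' where both channels are positive (a ratio is undefined when either
#' channel is missing), groups them by protein, and summarizes each group
#' with [protein_ratio()]. Proteins below `min_ratio_count` are excluded.
#'
#' @param evidence Evidence data frame (see [parse_evidence()]).
#' @param min_ratio_count Minimum peptide-ratio count per protein.
#' @return Data frame `protein_id, log2_ratio, n_peptide_ratios,
#'   replicates_present` with one row per quantified protein.
#' @export
quantify_experiment <- function(evidence, min_ratio_count = 2) {
  empty <- data.frame(protein_id = character(0), log2_ratio = numeric(0),
                      n_peptide_ratios = integer(0),
                      replicates_present = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(evidence) || nrow(evidence) == 0) {
    warning("empty evidence table: no proteins quantified", call. = FALSE)
    return(empty)
  }
  ok <- evidence$intensity_H > 0 & evidence$intensity_L > 0
  ev <- evidence[ok, , drop = FALSE]
  if (nrow(ev) == 0) {
    warning("no peptide with both channels observed", call. = FALSE)
    return(empty)
  }
  ev$pep_log2 <- log2(ev$intensity_H / ev$intensity_L)
  grp <- split(seq_len(nrow(ev)), ev$protein_id)
  out <- data.frame(
    protein_id = names(grp),
    log2_ratio = vapply(grp, function(i)
      protein_ratio(ev$pep_log2[i], min_ratio_count), numeric(1)),
    n_peptide_ratios = vapply(grp, length, integer(1)),
    replicates_present = vapply(grp, function(i)
      paste(sort(unique(ev$replicate[i])), collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  out <- out[!is.na(out$log2_ratio), , drop = FALSE]
  out <- out[order(out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge two replicate experiments
#'
#' Keeps exactly the proteins quantified in both replicates (the
#' intersection), combines their log2 ratios by the arithmetic mean, and
#' reports Venn counts of the two identified sets.
#'
#' @param quant_rep1,quant_rep2 Protein quantification tables from
#'   [quantify_experiment()].
#' @return A list with `quant` (merged table: `protein_id, log2_ratio,
#'   n_peptide_ratios, replicates_present`) and `venn` (see
#'   [venn_counts()]).
#' @export
merge_replicates <- function(quant_rep1, quant_rep2) {
  venn <- venn_counts(quant_rep1$protein_id, quant_rep2$protein_id)
  common <- intersect(quant_rep1$protein_id, quant_rep2$protein_id)
  i1 <- match(common, quant_rep1$protein_id)
  i2 <- match(common, quant_rep2$protein_id)
  merged <- data.frame(
    protein_id = common,
    log2_ratio = (quant_rep1$log2_ratio[i1] + quant_rep2$log2_ratio[i2]) / 2,
    n_peptide_ratios = quant_rep1$n_peptide_ratios[i1] +
      quant_rep2$n_peptide_ratios[i2],
    replicates_present = paste(quant_rep1$replicates_present[i1],
                               quant_rep2$replicates_present[i2],
                               sep = ","),
    stringsAsFactors = FALSE
  )
  merged <- merged[order(merged$protein_id), , drop = FALSE]
  rownames(merged) <- NULL
  list(quant = merged, venn = venn)
}

#' Venn counts of two identifier sets
#'
#' @param a,b Character vectors of identifiers (duplicates ignored).
#' @return A list `only_a, only_b, both, union` with
#'   `union = only_a + only_b + both`.
#' @examples
#' venn_counts(letters[1:3], letters[2:5])
#' @export
venn_counts <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  both <- length(intersect(a, b))
  out <- list(only_a = length(a) - both, only_b = length(b) - both,
              both = both, union = length(union(a, b)))
  stopifnot(out$union == out$only_a + out$only_b + out$both)
  out
}

#' Percentage of identified proteins that were quantified
#'
#' @param n_quantified,n_identified Counts with
#'   `0 <= n_quantified <= n_identified` and `n_identified > 0`.
#' @return `100 * n_quantified / n_identified`, rounded to 2 decimals.
#' @examples
#' quantified_fraction(2289, 4649)  # 49.24
#' @export
quantified_fraction <- function(n_quantified, n_identified) {
  if (n_identified <= 0) stop("n_identified must be > 0", call. = FALSE)
  if (n_quantified < 0 || n_quantified > n_identified) {
    stop("n_quantified must be in [0, n_identified]", call. = FALSE)
  }
  round(100 * n_quantified / n_identified, 2)
}
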