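#' Fit the log2-ratio population
#'
#' The z-score denominator and centering source: the mean and sample SD
#' (n - 1 denominator by default) of all quantified proteins' log2 H/L
#' ratios.
#'
#' @param values Numeric vector of log2 H/L ratios (n >= 2, all finite).
#' @param sd_type `"sample"` (n - 1 denominator, default) or
#'   `"population"` (n denominator).
#' @return A list of class `ratio_population` with `values`, `mean`, `sd`
#'   and `n`.
#' @export
fit_population <- function(values, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(values) < 2 || any(!is.finite(values))) {
    stop("degenerate population: need >= 2 finite log2 ratios",
         call. = FALSE)
  }
  m <- mean(values)
  s <- stats::sd(values)
  if (sd_type == "population") s <- s * sqrt((length(values) - 1) / length(values))
  if (s == 0) stop("degenerate population: zero standard deviation",
                   call. = FALSE)
  structure(list(values = values, mean = m, sd = s, n = length(values)),
            class = "ratio_population")
}

#' @export
print.ratio_population <- function(x, ...) {
  cat(sprintf("log2 H/L ratio population: n = %d, mean = %.4f, sd = %.4f\n",
              x$n, x$mean, x$sd))
  invisible(x)
}

#' Population z-score of a log2 H/L ratio
#'
#' `z = (log2_ratio - mean) / sd`, standardizing a protein's log2 H/L
#' ratio against the population of all quantified proteins.
#'
#' @param log2_ratio Numeric vector of log2 H/L ratios.
#' @param population A [fit_population()] result, or any list with `mean`
#'   and `sd`.
#' @return Numeric vector of z-scores (sigma units).
#' @examples
#' pop <- list(mean = -0.146, sd = 1.298)
#' zscore(3.34, pop)   # 2.686: ASSY-like strong upregulation
#' @export
zscore <- function(log2_ratio, population) {
  if (any(!is.finite(log2_ratio))) {
    stop("non-finite log2 ratio", call. = FALSE)
  }
  if (!is.finite(population$sd) || population$sd <= 0) {
    stop("degenerate population: sd must be positive", call. = FALSE)
  }
  (log2_ratio - population$mean) / population$sd
}

#' Two-sided confidence cutoff on the z scale
#'
#' The standard-normal quantile at `(1 + level) / 2`, reported rounded to
#' 3 decimals: 0.95 -> 1.960, 0.99 -> 2.576, 0.999 -> 3.291.
#'
#' @param level Confidence level in (0, 1).
#' @param rounded Round to 3 decimals (the printed convention used for
#'   classification); set `FALSE` for the full-precision quantile.
#' @return z threshold.
#' @export
confidence_cutoff <- function(level, rounded = TRUE) {
  if (any(!is.finite(level) | level <= 0 | level >= 1)) {
    stop("confidence level must be in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm((1 + level) / 2)
  if (rounded) round(z, 3) else z
}

#' Classify z-scores into direction and confidence tier
#'
#' A protein is significant when `|z|` meets the lowest cutoff
#' (comparison is `>=`); its tier is the highest cutoff met and its
#' direction the sign of z. Cutoffs default to the rounded constants
#' 1.960 / 2.576 / 3.291 for the 95 / 99 / 99.9 percent tiers so that
#' printed-precision z-scores classify reproducibly.
#'
#' @param z Numeric vector of z-scores.
#' @param cutoffs Strictly increasing vector of thresholds, named by tier.
#' @return Data frame with `direction` (`"up"`, `"down"`, `"none"`) and
#'   `tier` (`"none"`, `"95"`, `"99"`, `"99.9"`).
#' @examples
#' classify(c(2.686, 0, -4.656))
#' @export
classify <- function(z, cutoffs = c("95" = 1.960, "99" = 2.576,
                                    "99.9" = 3.291)) {
  if (is.null(names(cutoffs))) {
    stop("cutoffs must be named by tier", call. = FALSE)
  }
  if (any(diff(cutoffs) <= 0)) {
    stop("cutoffs must be strictly increasing", call. = FALSE)
  }
  tier <- rep("none", length(z))
  for (i in seq_along(cutoffs)) {
    tier[abs(z) >= cutoffs[i]] <- names(cutoffs)[i]
  }
  direction <- ifelse(tier == "none", "none", ifelse(z > 0, "up", "down"))
  data.frame(direction = direction, tier = tier, stringsAsFactors = FALSE)
}

#' Differential-regulation table and tier summary
#'
#' Fits the log2-ratio population on all quantified proteins (or uses
#' supplied moments), z-scores every protein, classifies each into
#' direction and confidence tier, and tallies up/down counts per tier.
#'
#' @param quant Merged protein quantification table with `protein_id` and
#'   `log2_ratio` columns.
#' @param cutoffs Named tier cutoffs, as in [classify()].
#' @param population Optional `list(mean =, sd =)` overriding the fitted
#'   moments (e.g. previously published population moments).
#' @param sd_type Passed to [fit_population()].
#' @return A list with:
#'   \describe{
#'     \item{table}{data frame `protein_id, log2_ratio, z, direction,
#'       tier`.}
#'     \item{summary}{data frame `tier, cutoff, n_up, n_down` (counts are
#'       cumulative: a 99.9-tier protein counts in all three rows).}
#'     \item{population}{the population used for standardization.}
#'   }
#' @export
differential_table <- function(quant,
                               cutoffs = c("95" = 1.960, "99" = 2.576,
                                           "99.9" = 3.291),
                               population = NULL,
                               sd_type = "sample") {
  if (nrow(quant) < 2 && is.null(population)) {
    stop("degenerate population: need >= 2 proteins", call. = FALSE)
  }
  if (is.null(population)) {
    population <- fit_population(quant$log2_ratio, sd_type = sd_type)
  }
  z <- zscore(quant$log2_ratio, population)
  cls <- classify(z, cutoffs)
  tab <- data.frame(protein_id = quant$protein_id,
                    log2_ratio = quant$log2_ratio,
                    z = z, direction = cls$direction, tier = cls$tier,
                    stringsAsFactors = FALSE)
  summary <- data.frame(
    tier = names(cutoffs),
    cutoff = unname(cutoffs),
    n_up = vapply(cutoffs, function(ct) sum(z >= ct), integer(1)),
    n_down = vapply(cutoffs, function(ct) sum(z <= -ct), integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  list(table = tab, summary = summary, population = population)
}

#' Fraction of proteins varying less than a given fold
#'
#' The reproducibility statistic: the share of proteins whose H/L ratio
#' varied strictly less than `fold`-fold, i.e. `|log2_ratio| < log2(fold)`.
#'
#' @param values Numeric vector of log2 ratios.
#' @param fold Fold threshold, > 1.
#' @return Proportion in `[0, 1]` (0 for an empty vector).
#' @examples
#' fraction_within_fold(c(0.5, 1.5, -2.0, -0.3), fold = 2)  # 0.5
#' @export
fraction_within_fold <- function(values, fold = 2) {
  if (!is.finite(fold) || fold <= 1) stop("fold must be > 1", call. = FALSE)
  if (length(values) == 0) return(0)
  mean(abs(values) < log2(fold))
}

#' Count proteins beyond a fixed log2 threshold
#'
#' Fold-threshold classification: `n_up` is the number of log2 ratios
#' strictly greater than `log2_threshold`, `n_down` strictly less than
#' `-log2_threshold`; boundary values are excluded.
#'
#' @param values Numeric vector of log2 ratios.
#' @param log2_threshold Positive threshold on the log2 scale.
#' @return A list `n_up, n_down`.
#' @examples
#' threshold_classify(c(1.2, -1.3, 0.5), 1)  # 1 up, 1 down
#' @export
threshold_classify <- function(values, log2_threshold = 1) {
  if (!is.finite(log2_threshold) || log2_threshold <= 0) {
    stop("log2_threshold must be > 0", call. = FALSE)
  }
  list(n_up = sum(values > log2_threshold),
       n_down = sum(values < -log2_threshold))
}
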