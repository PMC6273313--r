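#' Synthetic SILAC experiment configuration
#'
#' Builds and validates the configuration of the synthetic SILAC data
#' generator. The defaults emulate the TGF-beta-induced EMT experiment in
#' normal bladder epithelial HCV29 cells: the null (non-regulated) log2 H/L
#' population is Gaussian with mean -0.146 and SD 1.298, each protein is
#' observed through 1-15 peptides over two replicate experiments, and a
#' configurable fraction of proteins carries a true regulation shift of at
#' least `effect_min` log2 units.
#'
#' @param n_proteins Number of proteins to simulate.
#' @param frac_regulated Fraction of proteins that are truly regulated
#'   (split evenly between up and down), in `[0, 1]`.
#' @param null_mean Mean of the null log2 H/L population (log2 units).
#' @param null_sd SD of the null log2 H/L population (log2 units).
#' @param effect_min Minimum absolute log2 shift (from `null_mean`) of a
#'   regulated protein. Shifts are drawn uniformly on
#'   `[effect_min, effect_min + 2]` with random sign.
#' @param peptides_per_protein Mean of the peptide-count distribution per
#'   protein; counts are `1 + Poisson(mean - 1)`, capped at 15.
#' @param peptide_noise_sd SD of the per-peptide measurement noise added to
#'   the protein's true log2 ratio (log2 units).
#' @param channel_dropout_prob Probability that a peptide's heavy or light
#'   channel (independently) is not observed (intensity recorded as 0).
#' @param n_replicates Number of replicate experiments.
#' @param replicate_shift_sd SD of the protein-level shift distinguishing
#'   replicates (log2 units).
#' @param n_go_terms Number of GO terms in the synthetic annotation.
#' @param enriched_terms Number of terms preferentially (5x base odds)
#'   assigned to regulated proteins.
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   dataset exactly.
#'
#' @return A list of class `synth_config`.
#' @seealso [generate_dataset()]
#' @export
synth_config <- function(n_proteins = 1000,
                         frac_regulated = 0.05,
                         null_mean = -0.146,
                         null_sd = 1.298,
                         effect_min = 1.5,
                         peptides_per_protein = 4,
                         peptide_noise_sd = 0.3,
                         channel_dropout_prob = 0.05,
                         n_replicates = 2,
                         replicate_shift_sd = 0.1,
                         n_go_terms = 50,
                         enriched_terms = 5,
                         seed = 1L) {
  cfg <- list(
    n_proteins = n_proteins, frac_regulated = frac_regulated,
    null_mean = null_mean, null_sd = null_sd, effect_min = effect_min,
    peptides_per_protein = peptides_per_protein,
    peptide_noise_sd = peptide_noise_sd,
    channel_dropout_prob = channel_dropout_prob,
    n_replicates = n_replicates, replicate_shift_sd = replicate_shift_sd,
    n_go_terms = n_go_terms, enriched_terms = enriched_terms,
    seed = seed
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) {
      stop("invalid configuration field '", field, "': must be ", what,
           call. = FALSE)
    }
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(cfg$n_proteins) && cfg$n_proteins >= 1, "n_proteins", ">= 1")
  chk(num1(cfg$frac_regulated) && cfg$frac_regulated >= 0 &&
        cfg$frac_regulated <= 1, "frac_regulated", "in [0, 1]")
  chk(num1(cfg$null_mean), "null_mean", "a finite number")
  chk(num1(cfg$null_sd) && cfg$null_sd >= 0, "null_sd", ">= 0")
  chk(num1(cfg$effect_min) && cfg$effect_min >= 0, "effect_min", ">= 0")
  chk(num1(cfg$peptides_per_protein) && cfg$peptides_per_protein >= 1,
      "peptides_per_protein", ">= 1")
  chk(num1(cfg$peptide_noise_sd) && cfg$peptide_noise_sd >= 0,
      "peptide_noise_sd", ">= 0")
  chk(num1(cfg$channel_dropout_prob) && cfg$channel_dropout_prob >= 0 &&
        cfg$channel_dropout_prob <= 1, "channel_dropout_prob", "in [0, 1]")
  chk(num1(cfg$n_replicates) && cfg$n_replicates >= 1, "n_replicates",
      ">= 1")
  chk(num1(cfg$replicate_shift_sd) && cfg$replicate_shift_sd >= 0,
      "replicate_shift_sd", ">= 0")
  chk(num1(cfg$n_go_terms) && cfg$n_go_terms >= 1, "n_go_terms", ">= 1")
  chk(num1(cfg$enriched_terms) && cfg$enriched_terms >= 0 &&
        cfg$enriched_terms <= cfg$n_go_terms, "enriched_terms",
      "in [0, n_go_terms]")
  chk(num1(cfg$seed), "seed", "a finite number")
  invisible(cfg)
}

# Random peptide sequence strings; purely cosmetic identifiers.
random_peptides <- function(n, min_len = 7, max_len = 20) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lens <- sample(min_len:max_len, n, replace = TRUE)
  vapply(lens, function(l) paste(sample(aa, l, replace = TRUE),
                                 collapse = ""), character(1))
}

#' Generate a synthetic SILAC dataset with ground truth
#'
#' Simulates peptide-level heavy/light evidence tables (one per replicate
#' experiment), a per-protein truth table, and protein-to-GO annotations.
#' Each protein draws a true log2 H/L ratio from a Gaussian null or, for
#' regulated proteins, the null mean shifted by at least
#' `effect_min` log2 units. Every peptide observation adds Gaussian
#' measurement noise plus a protein-level replicate shift; light-channel
#' intensities are log-normal and the heavy channel is
#' `light * 2^(peptide log2 ratio)`, so both channels are realistic
#' positive intensities. Either channel independently drops out with
#' probability `channel_dropout_prob` (recorded as intensity 0). GO terms
#' are assigned 1-5 per protein, with the first `enriched_terms` terms
#' assigned to regulated proteins at five times the base odds.
#'
#' @param config A [synth_config()] object.
#' @return A list with components:
#'   \describe{
#'     \item{evidence}{list of data frames, one per replicate, with columns
#'       `peptide, protein_id, charge, intensity_H, intensity_L, replicate`.}
#'     \item{truth}{data frame `protein_id, true_log2_ratio, regulated`
#'       (`"up"`, `"down"` or `"null"`) and `annotated_terms`
#'       (semicolon-separated GO IDs).}
#'     \item{annotations}{data frame `protein_id, go_id, aspect` in long
#'       form (one row per assignment).}
#'   }
#' @examples
#' sim <- generate_dataset(synth_config(n_proteins = 50, seed = 7))
#' nrow(sim$truth)
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  validate_synth_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_proteins)
  protein_id <- sprintf("PROT%05d", seq_len(n))

  n_reg <- round(n * config$frac_regulated)
  regulated <- rep("null", n)
  if (n_reg > 0) {
    idx <- sample.int(n, n_reg)
    regulated[idx] <- sample(c("up", "down"), n_reg, replace = TRUE)
  }
  true_log2 <- stats::rnorm(n, config$null_mean, config$null_sd)
  is_reg <- regulated != "null"
  if (any(is_reg)) {
    shift <- stats::runif(sum(is_reg), config$effect_min,
                          config$effect_min + 2)
    sgn <- ifelse(regulated[is_reg] == "up", 1, -1)
    true_log2[is_reg] <- config$null_mean + sgn * shift
  }

  # GO assignment: 1-5 terms per protein; enriched terms get 5x odds for
  # regulated proteins so the enrichment stage has a detectable signal.
  terms <- sprintf("GO:%07d", seq_len(config$n_go_terms))
  aspects <- sample(c("P", "F", "C"), config$n_go_terms, replace = TRUE)
  w_base <- rep(1, config$n_go_terms)
  w_reg <- w_base
  if (config$enriched_terms > 0) {
    w_reg[seq_len(config$enriched_terms)] <- 5
  }
  n_terms_per <- sample(1:5, n, replace = TRUE)
  ann_terms <- vector("list", n)
  for (i in seq_len(n)) {
    w <- if (is_reg[i]) w_reg else w_base
    ann_terms[[i]] <- sample(terms, min(n_terms_per[i], length(terms)),
                             prob = w)
  }
  annotations <- data.frame(
    protein_id = rep(protein_id, lengths(ann_terms)),
    go_id = unlist(ann_terms),
    stringsAsFactors = FALSE
  )
  annotations$aspect <- aspects[match(annotations$go_id, terms)]

  truth <- data.frame(
    protein_id = protein_id,
    true_log2_ratio = true_log2,
    regulated = regulated,
    annotated_terms = vapply(ann_terms, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )

  k_pep <- pmin(1L + stats::rpois(n, config$peptides_per_protein - 1), 15L)
  evidence <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    rep_shift <- stats::rnorm(n, 0, config$replicate_shift_sd)
    pid <- rep(protein_id, k_pep)
    prot_idx <- rep(seq_len(n), k_pep)
    m <- length(pid)
    pep_log2 <- true_log2[prot_idx] + rep_shift[prot_idx] +
      stats::rnorm(m, 0, config$peptide_noise_sd)
    light <- stats::rlnorm(m, meanlog = log(1e6), sdlog = 1)
    heavy <- light * 2^pep_log2
    drop_h <- stats::runif(m) < config$channel_dropout_prob
    drop_l <- stats::runif(m) < config$channel_dropout_prob
    heavy[drop_h] <- 0
    light[drop_l] <- 0
    evidence[[r]] <- data.frame(
      peptide = random_peptides(m),
      protein_id = pid,
      charge = sample(2:4, m, replace = TRUE),
      intensity_H = heavy,
      intensity_L = light,
      replicate = sprintf("rep%d", r),
      stringsAsFactors = FALSE
    )
  }
  names(evidence) <- sprintf("rep%d", seq_len(config$n_replicates))
  list(evidence = evidence, truth = truth, annotations = annotations)
}

#' Generate a synthetic bladder-cancer reference ratio table
#'
#' Emulates an external cell-line comparison (KK47 vs HCV29 and YTS1 vs
#' HCV29 log2 ratios) correlated with the simulated EMT regulation truth.
#' For a `concordant_frac` share of the regulated proteins both reference
#' ratios share the sign of the protein's true EMT log2 ratio (relative to
#' zero); all other proteins draw both reference ratios from the Gaussian
#' null component.
#'
#' @param truth Truth table from [generate_dataset()].
#' @param concordant_frac Fraction of regulated proteins whose reference
#'   ratios are sign-concordant with the EMT truth, in `[0, 1]`.
#' @param seed Integer seed.
#' @param null_mean,null_sd Moments of the null component the discordant
#'   and non-regulated reference ratios are drawn from.
#' @return Data frame `protein_id, log2_kk47_vs_hcv29, log2_yts1_vs_hcv29`.
#' @export
generate_bc_reference <- function(truth, concordant_frac = 0.8, seed = 1L,
                                  null_mean = -0.146, null_sd = 1.298) {
  if (!is.data.frame(truth) || nrow(truth) == 0) {
    stop("empty truth table: nothing to generate a reference for",
         call. = FALSE)
  }
  if (!is.numeric(concordant_frac) || concordant_frac < 0 ||
      concordant_frac > 1) {
    stop("invalid configuration field 'concordant_frac': must be in [0, 1]",
         call. = FALSE)
  }
  set.seed(seed)
  n <- nrow(truth)
  ref1 <- stats::rnorm(n, null_mean, null_sd)
  ref2 <- stats::rnorm(n, null_mean, null_sd)
  reg_idx <- which(truth$regulated != "null")
  n_conc <- round(length(reg_idx) * concordant_frac)
  if (n_conc > 0) {
    conc <- sample(reg_idx, n_conc)
    sgn <- sign(truth$true_log2_ratio[conc])
    ref1[conc] <- sgn * stats::runif(n_conc, 1, 4)
    ref2[conc] <- sgn * stats::runif(n_conc, 1, 4)
  }
  data.frame(
    protein_id = truth$protein_id,
    log2_kk47_vs_hcv29 = ref1,
    log2_yts1_vs_hcv29 = ref2,
    stringsAsFactors = FALSE
  )
}

#' Write the synthetic dataset to tab-separated files
#'
#' Writes one evidence TSV per replicate plus the truth and annotation
#' tables under `dir`. Annotations can additionally be written in GAF 2.x.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param gaf Also write `annotations.gaf` in GAF 2.x format.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(dataset, dir, gaf = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (r in names(dataset$evidence)) {
    p <- file.path(dir, paste0("evidence_", r, ".tsv"))
    utils::write.table(dataset$evidence[[r]], p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths[paste0("evidence_", r)] <- p
  }
  p <- file.path(dir, "truth.tsv")
  utils::write.table(dataset$truth, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["truth"] <- p
  p <- file.path(dir, "annotations.tsv")
  utils::write.table(dataset$annotations, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["annotations"] <- p
  if (gaf) {
    p <- file.path(dir, "annotations.gaf")
    paths["gaf"] <- write_gaf(dataset$annotations, p)
  }
  invisible(paths)
}

#' Write annotations in GAF 2.x format
#'
#' @param annotations Data frame with `protein_id`, `go_id` and optionally
#'   `aspect` columns.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gaf <- function(annotations, path) {
  aspect <- if ("aspect" %in% names(annotations)) annotations$aspect else "P"
  n <- nrow(annotations)
  gaf <- data.frame(
    db = "SYNTH", id = annotations$protein_id,
    symbol = annotations$protein_id, qualifier = "",
    go_id = annotations$go_id, reference = "SYNTH:0000001",
    evidence = "IEA", with_from = "", aspect = aspect,
    name = "", synonym = "", type = "protein", taxon = "taxon:9606",
    date = "20260101", assigned_by = "SYNTH", extension = "",
    product_id = "",
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.1", con)
  utils::write.table(gaf, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
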