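level_label <- function(level) {
  sub("\\.?0+$", "", sprintf("%.1f", 100 * level))
}

#' Full-run configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Exactly
#' one of `synthetic` (a [synth_config()] or argument list for it) and
#' `inputs` (paths to real evidence/annotation/reference files) must be
#' given.
#'
#' @param synthetic `NULL`, or a [synth_config()] / argument list for one.
#' @param inputs `NULL`, or a list with `evidence` (character vector of
#'   2 evidence TSV paths), `annotations` (GAF or TSV path) and
#'   optionally `bc_reference` (TSV path).
#' @param min_ratio_count Minimum peptide-ratio count for quantitation.
#' @param levels Confidence levels for the z-score tiers.
#' @param filters Enrichment filters, as in [enrich_terms()].
#' @param rule A [concordance_rule()].
#' @param concordant_frac For synthetic runs, the fraction of regulated
#'   proteins made sign-concordant in the generated reference table.
#' @param out_dir Output directory for stage outputs and the report.
#' @param seed Integer master seed, recorded in the report.
#' @return A list of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, inputs = NULL,
                       min_ratio_count = 2,
                       levels = c(0.95, 0.99, 0.999),
                       filters = list(min_count = 2, max_ease = 0.1,
                                      max_p = 0.05, min_fold = 2.5),
                       rule = concordance_rule(),
                       concordant_frac = 0.8,
                       out_dir = "silacemt_run",
                       seed = 1L) {
  if (is.null(synthetic) == is.null(inputs)) {
    stop("configuration error: exactly one of 'synthetic' and 'inputs' ",
         "must be given", call. = FALSE)
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synth_config")) {
    synthetic$seed <- synthetic$seed %||% seed
    synthetic <- do.call(synth_config, synthetic)
  }
  cfg <- list(synthetic = synthetic, inputs = inputs,
              min_ratio_count = min_ratio_count, levels = sort(levels),
              filters = filters, rule = rule,
              concordant_frac = concordant_frac,
              out_dir = out_dir, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from YAML
#'
#' Any field omitted from the YAML file takes the [run_config()] default;
#' the full effective configuration is echoed into the run report.
#'
#' @param path Path to a YAML file whose keys mirror [run_config()]
#'   arguments (`rule` given as a list of [concordance_rule()] arguments).
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$rule)) raw$rule <- do.call(concordance_rule, raw$rule)
  do.call(run_config, raw)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> quantify -> differential regulation
#' -> enrichment -> concordance as one reproducible run. All stage
#' outputs are written as TSV under the configured output directory,
#' together with a JSON report (`report.json`) and a human-readable
#' summary (`report.txt`) that echo the effective configuration and seed.
#' Rerunning with the same configuration and seed reproduces identical
#' outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `quant`, `venn`, `diffreg`, `enrichment`
#'   (up and down), `concordance`, `report` and `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  if (!is.null(config$synthetic)) {
    sim <- run_stage("simulate", {
      ds <- generate_dataset(config$synthetic)
      ds$bc_reference <- generate_bc_reference(
        ds$truth, concordant_frac = config$concordant_frac,
        seed = config$seed + 1L,
        null_mean = config$synthetic$null_mean,
        null_sd = config$synthetic$null_sd)
      ds
    })
    evidence <- sim$evidence
    annotations <- sim$annotations
    bc_reference <- sim$bc_reference
    paths$truth <- write_tsv(sim$truth,
                             file.path(config$out_dir, "truth.tsv"))
  } else {
    sim <- NULL
    evidence <- run_stage("load", lapply(config$inputs$evidence,
                                         parse_evidence))
    annotations <- run_stage("load",
                             read_annotations(config$inputs$annotations))
    bc_reference <- NULL
    if (!is.null(config$inputs$bc_reference)) {
      bc_reference <- run_stage("load", utils::read.delim(
        config$inputs$bc_reference, sep = "\t", stringsAsFactors = FALSE))
    }
  }

  quant_reps <- run_stage("quantify", lapply(evidence, quantify_experiment,
                                             min_ratio_count = config$min_ratio_count))
  if (length(quant_reps) < 2) {
    stop("stage 'quantify' failed: need >= 2 replicate experiments",
         call. = FALSE)
  }
  merged <- run_stage("quantify",
                      merge_replicates(quant_reps[[1]], quant_reps[[2]]))
  paths$quant <- write_tsv(merged$quant,
                           file.path(config$out_dir, "protein_quant.tsv"))

  cutoffs <- confidence_cutoff(config$levels)
  names(cutoffs) <- level_label(config$levels)
  dr <- run_stage("diffreg", differential_table(merged$quant, cutoffs))
  dr_stats <- list(
    fraction_within_2fold = fraction_within_fold(merged$quant$log2_ratio, 2),
    threshold_1 = threshold_classify(merged$quant$log2_ratio, 1)
  )
  paths$diffreg <- write_tsv(dr$table,
                             file.path(config$out_dir, "differential.tsv"))
  paths$tier_summary <- write_tsv(dr$summary,
                                  file.path(config$out_dir,
                                            "tier_summary.tsv"))

  base_tier <- names(cutoffs)[1]
  sig <- dr$table[tier_meets(dr$table$tier, base_tier), , drop = FALSE]
  ann <- run_stage("enrich", annotation_set(annotations))
  enr <- run_stage("enrich", list(
    up = enrich_terms(sig$protein_id[sig$direction == "up"], ann,
                      config$filters),
    down = enrich_terms(sig$protein_id[sig$direction == "down"], ann,
                        config$filters)
  ))
  paths$enrich_up <- write_tsv(enr$up,
                               file.path(config$out_dir, "enrichment_up.tsv"))
  paths$enrich_down <- write_tsv(enr$down,
                                 file.path(config$out_dir,
                                           "enrichment_down.tsv"))

  conc <- NULL
  if (!is.null(bc_reference)) {
    # A single-experiment run fills both EMT slots with the same table.
    conc <- run_stage("concord",
                      concordance(dr$table, dr$table, bc_reference,
                                  config$rule))
    paths$concordance <- write_tsv(conc,
                                   file.path(config$out_dir,
                                             "concordance.tsv"))
  }

  report <- list(
    seed = config$seed,
    config = list(
      min_ratio_count = config$min_ratio_count,
      levels = config$levels, cutoffs = as.list(cutoffs),
      filters = config$filters,
      rule = unclass(config$rule),
      concordant_frac = config$concordant_frac,
      synthetic = if (!is.null(config$synthetic))
        unclass(config$synthetic) else NULL,
      inputs = config$inputs
    ),
    n_quantified_per_replicate = vapply(quant_reps, nrow, integer(1)),
    venn = merged$venn,
    population = list(mean = dr$population$mean, sd = dr$population$sd,
                      n = dr$population$n),
    tier_summary = dr$summary,
    fraction_within_2fold = dr_stats$fraction_within_2fold,
    threshold_1 = dr_stats$threshold_1,
    n_enriched_terms = list(up = sum(enr$up$pass_all),
                            down = sum(enr$down$pass_all)),
    n_concordant = if (!is.null(conc)) sum(conc$rule_satisfied) else NA
  )
  paths$report_json <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, paths$report_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  paths$report_txt <- file.path(config$out_dir, "report.txt")
  writeLines(format_report(report), paths$report_txt)

  invisible(list(simulated = sim, quant = merged$quant, venn = merged$venn,
                 diffreg = dr, enrichment = enr, concordance = conc,
                 report = report, paths = paths))
}

format_report <- function(report) {
  c(
    "SILAC EMT pipeline run",
    sprintf("seed: %d", report$seed),
    sprintf("proteins quantified per replicate: %s",
            paste(report$n_quantified_per_replicate, collapse = ", ")),
    sprintf("replicate Venn: only_a=%d only_b=%d both=%d union=%d",
            report$venn$only_a, report$venn$only_b, report$venn$both,
            report$venn$union),
    sprintf("log2 H/L population: mean=%.4f sd=%.4f n=%d",
            report$population$mean, report$population$sd,
            report$population$n),
    "tier summary (cumulative up, down):",
    sprintf("  %s%%: %d up, %d down", report$tier_summary$tier,
            report$tier_summary$n_up, report$tier_summary$n_down),
    sprintf("fraction varying < 2-fold: %.4f",
            report$fraction_within_2fold),
    sprintf("beyond |log2| > 1: %d up, %d down",
            report$threshold_1$n_up, report$threshold_1$n_down),
    sprintf("enriched terms passing all filters: %d (up), %d (down)",
            report$n_enriched_terms$up, report$n_enriched_terms$down),
    if (!is.na(report$n_concordant))
      sprintf("concordant proteins (EMT vs cancer reference): %d",
              report$n_concordant) else character(0)
  )
}
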