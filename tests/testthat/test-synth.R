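test_that("generator is deterministic and honours row-count contracts", {
  cfg <- synth_config(n_proteins = 50, seed = 7)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$truth), 50)
  expect_equal(length(a$evidence), 2)
  expect_setequal(unique(a$evidence[[1]]$protein_id), a$truth$protein_id)
  expect_false(anyDuplicated(a$truth$protein_id) > 0)

  c <- generate_dataset(synth_config(n_proteins = 50, seed = 8))
  expect_false(identical(a$evidence[[1]], c$evidence[[1]]))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(synth_config(frac_regulated = 1.2), "frac_regulated")
  expect_error(synth_config(null_sd = -1), "null_sd")
  expect_error(synth_config(n_proteins = 0), "n_proteins")
  expect_error(synth_config(channel_dropout_prob = 2),
               "channel_dropout_prob")
  expect_error(synth_config(n_replicates = 0), "n_replicates")
})

test_that("truth ratios follow the configured null and effect model", {
  cfg <- synth_config(n_proteins = 4000, frac_regulated = 0.1,
                      effect_min = 1.5, seed = 21)
  ds <- generate_dataset(cfg)
  nul <- ds$truth[ds$truth$regulated == "null", ]
  reg <- ds$truth[ds$truth$regulated != "null", ]
  # null moments within 4 standard errors of the generator settings
  n0 <- nrow(nul)
  expect_lt(abs(mean(nul$true_log2_ratio) - cfg$null_mean),
            4 * cfg$null_sd / sqrt(n0))
  expect_lt(abs(sd(nul$true_log2_ratio) - cfg$null_sd),
            4 * cfg$null_sd / sqrt(2 * n0))
  # every regulated shift at least effect_min, at most effect_min + 2
  shift <- abs(reg$true_log2_ratio - cfg$null_mean)
  expect_true(all(shift >= cfg$effect_min))
  expect_true(all(shift <= cfg$effect_min + 2))
  expect_true(all(sign(reg$true_log2_ratio - cfg$null_mean) ==
                    ifelse(reg$regulated == "up", 1, -1)))
})

test_that("peptide counts, dropout and intensity channels behave as configured", {
  cfg <- synth_config(n_proteins = 500, channel_dropout_prob = 0.1,
                      seed = 5)
  ds <- generate_dataset(cfg)
  ev <- ds$evidence[[1]]
  k <- table(ev$protein_id)
  expect_true(all(k >= 1 & k <= 15))
  expect_true(all(ev$intensity_H >= 0 & ev$intensity_L >= 0))
  # dropout rate per channel near 10% (3 binomial SDs)
  for (col in c("intensity_H", "intensity_L")) {
    rate <- mean(ev[[col]] == 0)
    expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / nrow(ev)))
  }
  # with no noise/dropout, peptide log2(H/L) equals the truth exactly
  cfg0 <- synth_config(n_proteins = 20, peptide_noise_sd = 0,
                       channel_dropout_prob = 0, replicate_shift_sd = 0,
                       seed = 2)
  ds0 <- generate_dataset(cfg0)
  ev0 <- ds0$evidence[[1]]
  truth <- ds0$truth$true_log2_ratio[match(ev0$protein_id,
                                           ds0$truth$protein_id)]
  expect_equal(log2(ev0$intensity_H / ev0$intensity_L), truth,
               tolerance = 1e-12)
})

test_that("enriched GO terms are over-assigned to regulated proteins", {
  cfg <- synth_config(n_proteins = 2000, frac_regulated = 0.3,
                      n_go_terms = 20, enriched_terms = 3, seed = 13)
  ds <- generate_dataset(cfg)
  enriched <- sprintf("GO:%07d", 1:3)
  ann <- ds$annotations
  reg_ids <- ds$truth$protein_id[ds$truth$regulated != "null"]
  rate_reg <- mean(ann$go_id[ann$protein_id %in% reg_ids] %in% enriched)
  rate_nul <- mean(ann$go_id[!ann$protein_id %in% reg_ids] %in% enriched)
  expect_gt(rate_reg, 2 * rate_nul)
})

test_that("bladder-cancer reference respects concordant_frac boundaries", {
  cfg <- synth_config(n_proteins = 400, frac_regulated = 0.25, seed = 9)
  ds <- generate_dataset(cfg)
  reg <- ds$truth$regulated != "null"

  ref1 <- generate_bc_reference(ds$truth, concordant_frac = 1, seed = 1)
  expect_true(all(sign(ref1$log2_kk47_vs_hcv29[reg]) ==
                    sign(ds$truth$true_log2_ratio[reg])))
  expect_true(all(sign(ref1$log2_yts1_vs_hcv29[reg]) ==
                    sign(ds$truth$true_log2_ratio[reg])))

  # concordant_frac = 0: sign matches at chance level under the
  # (near-symmetric) null; Monte-Carlo band from 40 x n binomial draws
  match_rate <- vapply(101:140, function(s) {
    ref0 <- generate_bc_reference(ds$truth, concordant_frac = 0, seed = s)
    mean(sign(ref0$log2_kk47_vs_hcv29[reg]) ==
           sign(ds$truth$true_log2_ratio[reg]))
  }, numeric(1))
  p0 <- pnorm(0, -0.146, 1.298)  # null mass on each side of zero
  expect_lt(abs(mean(match_rate) - 0.5), abs(0.5 - p0) + 0.05)

  expect_error(generate_bc_reference(ds$truth[0, ], 0.5),
               "empty truth table")
  expect_error(generate_bc_reference(ds$truth, 1.5), "concordant_frac")
})

test_that("datasets round-trip through TSV and GAF files", {
  ds <- generate_dataset(synth_config(n_proteins = 30, seed = 4))
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir, gaf = TRUE)
  ev <- parse_evidence(paths[["evidence_rep1"]])
  expect_equal(nrow(ev), nrow(ds$evidence[[1]]))
  expect_equal(ev$intensity_H, ds$evidence[[1]]$intensity_H,
               tolerance = 1e-6)
  ann <- read_annotations(paths[["gaf"]])
  expect_setequal(paste(ann$protein_id, ann$go_id),
                  paste(ds$annotations$protein_id, ds$annotations$go_id))
  ann2 <- read_annotations(paths[["annotations"]])
  expect_setequal(paste(ann2$protein_id, ann2$go_id, ann2$aspect),
                  paste(ds$annotations$protein_id, ds$annotations$go_id,
                        ds$annotations$aspect))
})
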