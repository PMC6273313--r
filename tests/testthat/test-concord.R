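# Differential-style EMT table built by hand from log2 ratios, classified
# against supplied population moments.
emt_table <- function(ids, log2_ratios, mean = -0.146, sd = 1.298) {
  differential_table(
    data.frame(protein_id = ids, log2_ratio = log2_ratios,
               stringsAsFactors = FALSE),
    population = list(mean = mean, sd = sd)
  )$table
}

test_that("published strong regulators satisfy the default rule", {
  ids <- c("ASSY", "CKAP4", "MID")
  hcv29 <- emt_table(ids, c(3.34, -3.47, 0.10))
  kk47 <- emt_table(ids, c(0.26, -0.08, 0.05), mean = -0.005, sd = 0.209)
  bc <- data.frame(protein_id = ids,
                   log2_kk47_vs_hcv29 = c(3.47, -2.64, 1.0),
                   log2_yts1_vs_hcv29 = c(0.89, -2.12, 1.0),
                   stringsAsFactors = FALSE)
  res <- concordance(hcv29, kk47, bc)
  # ASSY: upregulated in EMT of HCV29 (z = 2.69), cancer ratio positive
  assy <- res[res$protein_id == "ASSY", ]
  expect_true(assy$rule_satisfied)
  expect_equal(assy$direction, "up")
  # CKAP4: downregulated in EMT of HCV29 (z = -2.56), cancer ratio negative
  ckap4 <- res[res$protein_id == "CKAP4", ]
  expect_true(ckap4$rule_satisfied)
  expect_equal(ckap4$direction, "down")
  # a non-significant protein never qualifies
  expect_false(res$rule_satisfied[res$protein_id == "MID"])
  expect_true(is.na(res$direction[res$protein_id == "MID"]))
})

test_that("the rule requires sign agreement with every required column", {
  ids <- "X"
  hcv29 <- emt_table(ids, 4.0)
  kk47 <- emt_table(ids, 0.0, mean = 0, sd = 1)
  bc <- data.frame(protein_id = ids, log2_kk47_vs_hcv29 = 2.0,
                   log2_yts1_vs_hcv29 = -1.0, stringsAsFactors = FALSE)
  expect_true(concordance(hcv29, kk47, bc)$rule_satisfied)
  both <- concordance_rule(agree_columns = c("log2_kk47_vs_hcv29",
                                             "log2_yts1_vs_hcv29"))
  expect_false(concordance(hcv29, kk47, bc, both)$rule_satisfied)
  # dead zone: a reference ratio inside epsilon has no sign
  dz <- concordance_rule(epsilon = 2.5)
  expect_false(concordance(hcv29, kk47, bc, dz)$rule_satisfied)
})

test_that("opposite significant EMT directions are flagged, not satisfied", {
  ids <- "OPP"
  hcv29 <- emt_table(ids, 4.0, mean = 0, sd = 1)
  kk47 <- emt_table(ids, -4.0, mean = 0, sd = 1)
  bc <- data.frame(protein_id = ids, log2_kk47_vs_hcv29 = 3.0,
                   log2_yts1_vs_hcv29 = 3.0, stringsAsFactors = FALSE)
  res <- concordance(hcv29, kk47, bc)
  expect_true(res$opposite_emt)
  expect_false(res$rule_satisfied)
})

test_that("concordance is invariant to row order and flips under negation", {
  set.seed(23)
  n <- 60
  ids <- sprintf("P%02d", 1:n)
  r1 <- rnorm(n, 0, 2)
  r2 <- rnorm(n, 0, 2)
  b1 <- rnorm(n, 0, 2)
  b2 <- rnorm(n, 0, 2)
  hcv29 <- emt_table(ids, r1, mean = 0, sd = 1)
  kk47 <- emt_table(ids, r2, mean = 0, sd = 1)
  bc <- data.frame(protein_id = ids, log2_kk47_vs_hcv29 = b1,
                   log2_yts1_vs_hcv29 = b2, stringsAsFactors = FALSE)
  res <- concordance(hcv29, kk47, bc)

  shuf <- sample(n)
  res_shuf <- concordance(hcv29[shuf, ], kk47[rev(shuf), ], bc[shuf, ])
  expect_equal(res_shuf, res)

  neg <- concordance(emt_table(ids, -r1, mean = 0, sd = 1),
                     emt_table(ids, -r2, mean = 0, sd = 1),
                     data.frame(protein_id = ids,
                                log2_kk47_vs_hcv29 = -b1,
                                log2_yts1_vs_hcv29 = -b2,
                                stringsAsFactors = FALSE))
  expect_equal(neg$rule_satisfied, res$rule_satisfied)
  sat <- res$rule_satisfied
  expect_equal(neg$direction[sat],
               ifelse(res$direction[sat] == "up", "down", "up"))
})

test_that("degenerate inputs are handled explicitly", {
  ids <- c("A", "B")
  hcv29 <- emt_table(ids, c(4, -4), mean = 0, sd = 1)
  kk47 <- emt_table(ids, c(4, -4), mean = 0, sd = 1)
  bc0 <- data.frame(protein_id = character(0),
                    log2_kk47_vs_hcv29 = numeric(0),
                    log2_yts1_vs_hcv29 = numeric(0),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(concordance(hcv29, kk47, bc0)), 0)
  dup <- rbind(hcv29, hcv29[1, ])
  bc <- data.frame(protein_id = ids, log2_kk47_vs_hcv29 = c(1, 1),
                   log2_yts1_vs_hcv29 = c(1, 1), stringsAsFactors = FALSE)
  expect_error(concordance(dup, kk47, bc), "duplicate")
})

test_that("synthetic concordance recovery tracks concordant_frac", {
  cfg <- synth_config(n_proteins = 600, frac_regulated = 0.1,
                      effect_min = 4 * 1.298, seed = 41)
  ds <- generate_dataset(cfg)
  q <- merged_quant(ds)
  dr <- differential_table(q)$table
  reg_ids <- ds$truth$protein_id[ds$truth$regulated != "null"]

  bc1 <- generate_bc_reference(ds$truth, concordant_frac = 1, seed = 2)
  res1 <- concordance(dr, dr, bc1)
  reg_res <- res1[res1$protein_id %in% reg_ids, ]
  expect_gt(mean(reg_res$rule_satisfied), 0.95)

  bc0 <- generate_bc_reference(ds$truth, concordant_frac = 0, seed = 2)
  res0 <- concordance(dr, dr, bc0)
  reg_res0 <- res0[res0$protein_id %in% reg_ids, ]
  # chance level: the null reference is positive/negative roughly half
  # the time, so recovery collapses toward ~0.5
  expect_lt(mean(reg_res0$rule_satisfied), 0.7)
  # with no regulated proteins the significant concordant set is empty
  cfg0 <- synth_config(n_proteins = 200, frac_regulated = 0, seed = 43)
  ds0 <- generate_dataset(cfg0)
  bc <- generate_bc_reference(ds0$truth, concordant_frac = 1, seed = 3)
  expect_equal(nrow(ds0$truth[ds0$truth$regulated != "null", ]), 0)
})
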