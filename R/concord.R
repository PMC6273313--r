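#' Concordance rule between EMT regulation and cancer-cell comparisons
#'
#' Configures how a protein qualifies as concordantly regulated in
#' TGF-beta-induced EMT and in the bladder-cancer cell-line reference.
#' The default requires significance at the 95 percent tier in at least
#' one EMT cell line and sign agreement between that line's EMT log2
#' ratio and the primary cancer ratio (KK47 vs HCV29).
#'
#' @param tier Minimum EMT confidence tier required (`"95"`, `"99"`,
#'   `"99.9"`).
#' @param agree_columns Reference-ratio column(s) that must share the EMT
#'   sign; subset of `c("log2_kk47_vs_hcv29", "log2_yts1_vs_hcv29")`.
#' @param epsilon Dead zone for the sign test: a ratio with absolute
#'   value `<= epsilon` has no sign and can never agree. Default 0
#'   (strict sign test).
#' @return A list of class `concordance_rule`.
#' @export
concordance_rule <- function(tier = "95",
                             agree_columns = "log2_kk47_vs_hcv29",
                             epsilon = 0) {
  tier <- match.arg(tier, c("95", "99", "99.9"))
  stopifnot(length(agree_columns) >= 1, epsilon >= 0)
  structure(list(tier = tier, agree_columns = agree_columns,
                 epsilon = epsilon),
            class = "concordance_rule")
}

# Tier ordering helper: does `tier` meet the `required` confidence level?
tier_meets <- function(tier, required) {
  order <- c(none = 0, "95" = 1, "99" = 2, "99.9" = 3)
  order[tier] >= order[required]
}

sign_dz <- function(x, epsilon) ifelse(abs(x) <= epsilon, 0, sign(x))

#' Concordance of EMT regulation with bladder-cancer cell comparisons
#'
#' Screens for proteins whose regulation direction in TGF-beta-induced
#' EMT (of HCV29 and/or KK47 cells) agrees with their direction in the
#' bladder-cancer cell-line reference ratios. A protein must be present
#' in both EMT tables and the reference; it satisfies the rule when it is
#' significant (per the rule's tier) in at least one EMT cell line and
#' that line's log2 ratio sign-agrees with every required reference
#' column. Proteins significant in both EMT lines with opposite
#' directions are flagged in `opposite_emt` and never satisfy the rule.
#'
#' @param emt_hcv29,emt_kk47 Differential tables (`table` component of
#'   [differential_table()]) for the two EMT experiments, keyed by
#'   `protein_id` (duplicates are an error).
#' @param bc_reference Reference ratio table `protein_id,
#'   log2_kk47_vs_hcv29, log2_yts1_vs_hcv29`.
#' @param rule A [concordance_rule()].
#' @return Data frame `protein_id, emt_hcv29, emt_kk47,
#'   bc_kk47_vs_hcv29, bc_yts1_vs_hcv29, direction, rule_satisfied,
#'   opposite_emt`, sorted by `protein_id`; `direction` is `NA` unless
#'   `rule_satisfied`.
#' @export
concordance <- function(emt_hcv29, emt_kk47, bc_reference,
                        rule = concordance_rule()) {
  stopifnot(inherits(rule, "concordance_rule"))
  for (nm in c("emt_hcv29", "emt_kk47", "bc_reference")) {
    tab <- get(nm)
    if (anyDuplicated(tab$protein_id)) {
      stop("duplicate protein_id in ", nm, call. = FALSE)
    }
  }
  empty <- data.frame(
    protein_id = character(0), emt_hcv29 = numeric(0),
    emt_kk47 = numeric(0), bc_kk47_vs_hcv29 = numeric(0),
    bc_yts1_vs_hcv29 = numeric(0), direction = character(0),
    rule_satisfied = logical(0), opposite_emt = logical(0),
    stringsAsFactors = FALSE
  )
  common <- Reduce(intersect, list(emt_hcv29$protein_id,
                                   emt_kk47$protein_id,
                                   bc_reference$protein_id))
  common <- sort(common)
  if (length(common) == 0) return(empty)
  i1 <- match(common, emt_hcv29$protein_id)
  i2 <- match(common, emt_kk47$protein_id)
  ib <- match(common, bc_reference$protein_id)

  sig1 <- tier_meets(emt_hcv29$tier[i1], rule$tier)
  sig2 <- tier_meets(emt_kk47$tier[i2], rule$tier)
  r1 <- emt_hcv29$log2_ratio[i1]
  r2 <- emt_kk47$log2_ratio[i2]
  bc <- bc_reference[ib, , drop = FALSE]

  bc_signs <- vapply(rule$agree_columns, function(cn) {
    if (!cn %in% names(bc)) {
      stop("reference table has no column '", cn, "'", call. = FALSE)
    }
    sign_dz(bc[[cn]], rule$epsilon)
  }, numeric(length(common)))
  bc_signs <- matrix(bc_signs, nrow = length(common))
  agrees <- function(emt_val) {
    s <- sign_dz(emt_val, rule$epsilon)
    s != 0 & apply(bc_signs == s & bc_signs != 0, 1, all)
  }
  ok1 <- sig1 & agrees(r1)
  ok2 <- sig2 & agrees(r2)
  opposite <- sig1 & sig2 &
    sign_dz(r1, rule$epsilon) * sign_dz(r2, rule$epsilon) < 0
  satisfied <- (ok1 | ok2) & !opposite
  direction <- rep(NA_character_, length(common))
  emt_sign <- ifelse(ok1, sign_dz(r1, rule$epsilon),
                     ifelse(ok2, sign_dz(r2, rule$epsilon), 0))
  direction[satisfied] <- ifelse(emt_sign[satisfied] > 0, "up", "down")

  out <- data.frame(
    protein_id = common,
    emt_hcv29 = r1,
    emt_kk47 = r2,
    bc_kk47_vs_hcv29 = bc$log2_kk47_vs_hcv29,
    bc_yts1_vs_hcv29 = bc$log2_yts1_vs_hcv29,
    direction = direction,
    rule_satisfied = satisfied,
    opposite_emt = opposite,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
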