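check_counts <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N) {
    stop("inconsistent counts: need 0 <= k <= min(n, K), n <= N, K <= N",
         call. = FALSE)
  }
}

#' One-sided Fisher exact p-value for term over-representation
#'
#' Hypergeometric upper tail `P(X >= k)` for `X ~ Hypergeom(N, K, n)`:
#' the probability that a random query list of size `n` drawn from a
#' background of `N` proteins, of which `K` carry the term, overlaps the
#' term in at least `k` proteins. Computed from scratch as a
#' log-binomial-coefficient tail sum.
#'
#' @param k Overlap count (query proteins carrying the term).
#' @param n Query-list size.
#' @param K Background count of proteins carrying the term.
#' @param N Background size.
#' @return Upper-tail probability in (0, 1].
#' @examples
#' fisher_p(4, 4, 5, 10)  # 5/210
#' @export
fisher_p <- function(k, n, K, N) {
  check_counts(k, n, K, N)
  if (k <= 0) return(1)
  i <- k:min(n, K)
  log_denom <- lchoose(N, n)
  min(sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - log_denom)), 1)
}

#' EASE score
#'
#' A conservative variant of the one-sided Fisher exact test: one member
#' is removed from the overlap before taking the hypergeometric upper
#' tail, i.e. `P(X >= k - 1)`. Always at least as large as [fisher_p()];
#' `k <= 1` gives 1.
#'
#' @inheritParams fisher_p
#' @return Upper-tail probability in (0, 1].
#' @examples
#' ease_score(4, 4, 5, 10)  # 55/210
#' @export
ease_score <- function(k, n, K, N) {
  check_counts(k, n, K, N)
  if (k <= 1) return(1)
  # P(X >= k - 1) = P(X >= k) + P(X = k - 1); summing this way keeps
  # ease_p >= fisher_p under floating point
  point <- exp(lchoose(K, k - 1) + lchoose(N - K, n - k + 1) - lchoose(N, n))
  min(fisher_p(k, n, K, N) + point, 1)
}

#' Fold enrichment of a term in a query list
#'
#' `(k / n) / (K / N)`: the term's frequency in the query list relative to
#' its background frequency.
#'
#' @inheritParams fisher_p
#' @return Nonnegative enrichment ratio.
#' @examples
#' fold_enrichment(5, 50, 10, 1000)  # 10
#' @export
fold_enrichment <- function(k, n, K, N) {
  if (n == 0 || K == 0) stop("n and K must be > 0", call. = FALSE)
  check_counts(k, n, K, N)
  (k / n) / (K / N)
}

#' Build an annotation set from a protein-to-term table
#'
#' @param annotations Data frame with `protein_id`, `go_id` and optionally
#'   `aspect` columns (long form, one row per assignment).
#' @param background Character vector of background protein IDs; defaults
#'   to all annotated proteins.
#' @return A list of class `annotation_set` with `protein2terms`,
#'   `term2proteins`, `term_aspect` and `background`.
#' @export
annotation_set <- function(annotations, background = NULL) {
  stopifnot(all(c("protein_id", "go_id") %in% names(annotations)))
  annotations <- unique(annotations[, intersect(
    c("protein_id", "go_id", "aspect"), names(annotations)), drop = FALSE])
  if (is.null(background)) background <- unique(annotations$protein_id)
  extra <- setdiff(annotations$protein_id, background)
  if (length(extra) > 0) {
    stop("annotated protein(s) absent from background: ",
         paste(utils::head(extra, 3), collapse = ", "), call. = FALSE)
  }
  term_aspect <- if ("aspect" %in% names(annotations)) {
    tapply(annotations$aspect, annotations$go_id, function(a) a[1])
  } else NULL
  structure(list(
    protein2terms = split(annotations$go_id, annotations$protein_id),
    term2proteins = split(annotations$protein_id, annotations$go_id),
    term_aspect = term_aspect,
    background = unique(background)
  ), class = "annotation_set")
}

#' GO term over-representation in a protein list
#'
#' For every term overlapping the query list, computes the overlap `k`,
#' one-sided Fisher p ([fisher_p()]), EASE score ([ease_score()]) and
#' fold enrichment ([fold_enrichment()]) against the background, and
#' flags which filters pass. Default filters: overlap count >= 2, EASE
#' score < 0.1, Fisher p < 0.05, fold enrichment > 2.5. Results are
#' sorted by EASE score, ascending.
#'
#' @param query Character vector of protein IDs; proteins outside the
#'   background are dropped with a warning.
#' @param annotations An [annotation_set()], or a data frame accepted by
#'   it.
#' @param filters List with `min_count`, `max_ease`, `max_p`, `min_fold`.
#' @return Data frame with one row per term (`term, aspect, k, n, K, N,
#'   fisher_p, ease_p, fold_enrichment, pass_count, pass_ease, pass_p,
#'   pass_fold, pass_all`).
#' @export
enrich_terms <- function(query, annotations,
                         filters = list(min_count = 2, max_ease = 0.1,
                                        max_p = 0.05, min_fold = 2.5)) {
  if (is.data.frame(annotations)) annotations <- annotation_set(annotations)
  stopifnot(inherits(annotations, "annotation_set"))
  empty <- data.frame(term = character(0), aspect = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), fisher_p = numeric(0),
                      ease_p = numeric(0), fold_enrichment = numeric(0),
                      pass_count = logical(0), pass_ease = logical(0),
                      pass_p = logical(0), pass_fold = logical(0),
                      pass_all = logical(0), stringsAsFactors = FALSE)
  query <- unique(query)
  outside <- setdiff(query, annotations$background)
  if (length(outside) > 0) {
    warning(length(outside), " query protein(s) outside background dropped",
            call. = FALSE)
    query <- setdiff(query, outside)
  }
  if (length(query) == 0) {
    warning("empty query list: no enrichment computed", call. = FALSE)
    return(empty)
  }
  N <- length(annotations$background)
  n <- length(query)
  terms <- unique(unlist(annotations$protein2terms[
    intersect(query, names(annotations$protein2terms))], use.names = FALSE))
  if (length(terms) == 0) return(empty)
  res <- do.call(rbind, lapply(terms, function(tm) {
    hits <- annotations$term2proteins[[tm]]
    k <- length(intersect(hits, query))
    K <- length(unique(hits))
    data.frame(
      term = tm,
      aspect = if (!is.null(annotations$term_aspect))
        unname(annotations$term_aspect[tm]) else NA_character_,
      k = k, n = n, K = K, N = N,
      fisher_p = fisher_p(k, n, K, N),
      ease_p = ease_score(k, n, K, N),
      fold_enrichment = fold_enrichment(k, n, K, N),
      stringsAsFactors = FALSE
    )
  }))
  res$pass_count <- res$k >= filters$min_count
  res$pass_ease <- res$ease_p < filters$max_ease
  res$pass_p <- res$fisher_p < filters$max_p
  res$pass_fold <- res$fold_enrichment > filters$min_fold
  res$pass_all <- res$pass_count & res$pass_ease & res$pass_p & res$pass_fold
  res <- res[order(res$ease_p, res$fisher_p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' GO composition of a protein list within one aspect
#'
#' Percentage of annotation assignments per category within a GO aspect
#' (molecular function `"F"`, biological process `"P"`, or cellular
#' component `"C"`). Denominators are assignments, not proteins — a
#' protein annotated to several categories contributes to each — so
#' percentages sum to 100 within rounding.
#'
#' @param proteins Character vector of protein IDs.
#' @param annotations An [annotation_set()] or compatible data frame with
#'   an `aspect` column.
#' @param aspect One of `"F"`, `"P"`, `"C"`.
#' @return Data frame `category, count, percent`, sorted by count
#'   descending.
#' @export
go_composition <- function(proteins, annotations, aspect = c("F", "P", "C")) {
  aspect <- match.arg(aspect)
  if (is.data.frame(annotations)) annotations <- annotation_set(annotations)
  empty <- data.frame(category = character(0), count = integer(0),
                      percent = numeric(0), stringsAsFactors = FALSE)
  proteins <- unique(proteins)
  if (length(proteins) == 0) return(empty)
  terms <- unlist(annotations$protein2terms[
    intersect(proteins, names(annotations$protein2terms))],
    use.names = FALSE)
  if (is.null(annotations$term_aspect)) {
    stop("annotation set has no aspect information", call. = FALSE)
  }
  terms <- terms[annotations$term_aspect[terms] == aspect]
  if (length(terms) == 0) return(empty)
  tab <- sort(table(terms), decreasing = TRUE)
  data.frame(category = names(tab), count = as.integer(tab),
             percent = round(100 * as.integer(tab) / sum(tab), 2),
             stringsAsFactors = FALSE)
}

#' Read protein-to-GO annotations
#'
#' Reads either a GAF 2.x file (comment lines start with `!`; columns 2, 5
#' and 9 are the object ID, GO ID and aspect) or a two-column TSV
#' `protein_id, go_id` (optional third column `aspect`). The format is
#' detected from the first non-empty line.
#'
#' @param path Path to the annotation file.
#' @return Data frame `protein_id, go_id, aspect` (aspect `NA` when the
#'   TSV has no aspect column).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "!gaf") || startsWith(first, "!")) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- lengths(fields) < 9
    if (any(short)) {
      warning(sum(short), " malformed GAF line(s) dropped", call. = FALSE)
      fields <- fields[!short]
    }
    out <- data.frame(
      protein_id = vapply(fields, `[`, character(1), 2L),
      go_id = vapply(fields, `[`, character(1), 5L),
      aspect = vapply(fields, `[`, character(1), 9L),
      stringsAsFactors = FALSE
    )
  } else {
    out <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    if (!all(c("protein_id", "go_id") %in% names(out))) {
      stop("annotation TSV must have columns protein_id, go_id",
           call. = FALSE)
    }
    if (!"aspect" %in% names(out)) out$aspect <- NA_character_
    out <- out[, c("protein_id", "go_id", "aspect")]
  }
  unique(out)
}
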