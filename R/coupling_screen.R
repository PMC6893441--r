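#' Pearson correlation with a two-sided p-value
#'
#' Pairwise-complete product-moment correlation; the two-sided p-value comes
#' from the t transform t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees
#' of freedom (via \code{stats::cor.test}). Perfect correlation returns
#' p = 0 by convention.
#'
#' @param x,y numeric vectors of equal length; pairs with a missing value
#'   in either vector are removed.
#' @param gene optional identifier used in error messages.
#' @return list with \code{r}, \code{p} and \code{n_used}.
#' @export
pearson_with_p <- function(x, y, gene = NULL) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  who <- if (is.null(gene)) "" else paste0(" for gene '", gene, "'")
  if (n < 3) {
    stop("need at least 3 complete pairs", who, " (got ", n, ")",
         call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation (zero variance)", who, call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  r <- unname(ct$estimate)
  p <- if (abs(r) >= 1) 0 else ct$p.value
  list(r = r, p = p, n_used = n)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Returns, in input order, q_(i) = min over j >= i of m * p_(j) / j (capped
#' at 1); declaring q < alpha reproduces the classic BH rejection set at
#' level alpha.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values, same order as input.
#' @export
bh_fdr <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Bonferroni adjustment with an explicit family size
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @param m family size; must be at least \code{length(pvals)} (default).
#' @return adjusted p-values min(1, m * p), input order preserved.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  pvals <- as.numeric(pvals)
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (m < length(pvals)) {
    stop("family size m must be >= number of p-values", call. = FALSE)
  }
  pmin(1, m * pvals)
}

#' Fisher's exact test for a 2x2 contingency table
#'
#' Two-sided p-value by the probability-mass rule: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (within the conventional
#' 1e-7 relative slack). The odds ratio is the sample odds ratio
#' a*d / (b*c), with \code{Inf} when a zero cell makes the ratio diverge.
#' Cells are read row-wise: \code{rbind(c(a, b), c(c, d))}.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return list with \code{odds_ratio} and \code{p}.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) {
    stop("at least one positive margin required", call. = FALSE)
  }
  m <- a + b       # row 1 total
  n <- c + d       # row 2 total
  k <- a + c       # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  odds_ratio <- (a * d) / (b * c)
  list(odds_ratio = odds_ratio, p = p)
}

#' Cohort-stratified TF-target correlation screen
#'
#' For each gene of a target panel, correlates its expression with the
#' transcription factor's expression separately within each of two cohorts
#' (Pearson, pairwise-complete), applies Benjamini-Hochberg FDR control
#' across the panel within each cohort (optionally pooled across cohorts),
#' flags genes with q below \code{fdr_level}, and compares the per-cohort
#' significant counts with Fisher's exact test on the 2x2 table
#' [significant, not] x [cohort A, cohort B].
#'
#' Panel genes absent from the matrix, or with zero variance within a
#' cohort, are reported in \code{skipped} rather than silently dropped. The
#' Fisher denominators use tested genes by default; set
#' \code{denominator = "panel"} to use the full panel size instead.
#'
#' @param expr genes-by-samples expression matrix.
#' @param ann cohort annotation data frame (\code{sample_id}, \code{cohort});
#'   exactly two cohort labels must occur among annotated samples present in
#'   \code{expr}, each with at least 3 samples.
#' @param tf_gene transcription-factor gene symbol (must be in \code{expr}).
#' @param panel a \code{target_panel}, \code{gene_list} or character vector.
#' @param fdr_level FDR threshold (default 0.01, i.e. "FDR of 1\%").
#' @param fdr_family \code{"per_cohort"} (default) or \code{"pooled"}.
#' @param denominator \code{"tested"} (default) or \code{"panel"}.
#' @return object of class \code{screen_result}: \code{records} (data frame
#'   gene/cohort/r/p/q/significant/n_used), \code{skipped},
#'   \code{counts}, \code{denominators}, \code{fisher},
#'   \code{bh_threshold} (largest rejected raw p per cohort), and settings.
#' @export
run_screen <- function(expr, ann, tf_gene, panel, fdr_level = 0.01,
                       fdr_family = c("per_cohort", "pooled"),
                       denominator = c("tested", "panel")) {
  fdr_family <- match.arg(fdr_family)
  denominator <- match.arg(denominator)
  expr <- validate_expression_matrix(expr)
  ann <- validate_cohort_annotation(ann)
  tf_gene <- canonicalize_symbols(tf_gene)
  stopifnot(fdr_level > 0, fdr_level < 1)
  if (!tf_gene %in% rownames(expr)) {
    stop("TF gene '", tf_gene, "' absent from expression matrix",
         call. = FALSE)
  }
  panel_symbols <- if (inherits(panel, "target_panel")) panel$symbols
    else if (inherits(panel, "gene_list")) panel$symbols
    else canonicalize_symbols(panel)
  if (length(panel_symbols) == 0) stop("empty panel", call. = FALSE)

  ann <- ann[ann$sample_id %in% colnames(expr), , drop = FALSE]
  cohorts <- sort(unique(ann$cohort))
  if (length(cohorts) != 2) {
    stop("exactly two cohort labels required, found: ",
         paste(cohorts, collapse = ", "), call. = FALSE)
  }

  records <- list()
  skipped <- list()
  for (co in cohorts) {
    ids <- ann$sample_id[ann$cohort == co]
    if (length(ids) < 3) {
      stop("cohort '", co, "' has fewer than 3 annotated samples",
           call. = FALSE)
    }
    tf_vals <- expr[tf_gene, ids]
    for (g in panel_symbols) {
      if (!g %in% rownames(expr)) {
        skipped[[length(skipped) + 1]] <-
          data.frame(gene = g, cohort = co,
                     reason = "absent_from_expression")
        next
      }
      res <- tryCatch(pearson_with_p(tf_vals, expr[g, ids], gene = g),
                      error = function(e) conditionMessage(e))
      if (is.character(res)) {
        reason <- if (grepl("zero variance", res)) "zero_variance"
                  else "too_few_complete_pairs"
        skipped[[length(skipped) + 1]] <-
          data.frame(gene = g, cohort = co, reason = reason)
        next
      }
      records[[length(records) + 1]] <-
        data.frame(gene = g, cohort = co, r = res$r, p = res$p,
                   n_used = res$n_used, stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, records)
  if (is.null(rec)) stop("no panel gene could be tested", call. = FALSE)
  skp <- if (length(skipped) > 0) do.call(rbind, skipped) else
    data.frame(gene = character(), cohort = character(),
               reason = character())

  if (fdr_family == "per_cohort") {
    rec$q <- NA_real_
    for (co in cohorts) {
      sel <- rec$cohort == co
      rec$q[sel] <- bh_fdr(rec$p[sel])
    }
  } else {
    rec$q <- bh_fdr(rec$p)
  }
  rec$significant <- rec$q < fdr_level
  rec <- rec[, c("gene", "cohort", "r", "p", "q", "significant", "n_used")]

  counts <- vapply(cohorts, function(co) {
    sum(rec$significant[rec$cohort == co])
  }, 0L)
  tested <- vapply(cohorts, function(co) sum(rec$cohort == co), 0L)
  denoms <- if (denominator == "tested") tested else
    stats::setNames(rep(length(panel_symbols), 2), cohorts)
  bh_threshold <- vapply(cohorts, function(co) {
    p_sig <- rec$p[rec$cohort == co & rec$significant]
    if (length(p_sig) == 0) NA_real_ else max(p_sig)
  }, 0.0)

  fisher <- fisher_exact_2x2(counts[1], denoms[1] - counts[1],
                             counts[2], denoms[2] - counts[2])

  structure(list(records = rec, skipped = skp, cohorts = cohorts,
                 counts = counts, tested = tested, denominators = denoms,
                 fisher = fisher, bh_threshold = bh_threshold,
                 fdr_level = fdr_level, fdr_family = fdr_family,
                 denominator = denominator),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result (FDR %g, %s family):\n", x$fdr_level,
              x$fdr_family))
  for (i in 1:2) {
    cat(sprintf("  %s: %d/%d significant\n", x$cohorts[i], x$counts[i],
                x$denominators[i]))
  }
  cat(sprintf("  Fisher's exact: OR = %.3g, p = %.3g\n",
              x$fisher$odds_ratio, x$fisher$p))
  if (nrow(x$skipped) > 0) {
    cat(sprintf("  skipped: %d gene/cohort pairs\n", nrow(x$skipped)))
  }
  invisible(x)
}

#' Write per-gene screen records to a TSV
#' @param result a \code{screen_result}.
#' @param path output path.
#' @export
write_screen_records <- function(result, path) {
  stopifnot(inherits(result, "screen_result"))
  utils::write.table(result$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Summarise a screen result as a plain list (JSON-ready)
#' @param result a \code{screen_result}.
#' @return list of counts, denominators, Fisher statistics and settings.
#' @export
screen_summary <- function(result) {
  stopifnot(inherits(result, "screen_result"))
  list(cohorts = as.character(result$cohorts),
       count_A = unname(result$counts[1]),
       count_B = unname(result$counts[2]),
       tested_A = unname(result$tested[1]),
       tested_B = unname(result$tested[2]),
       denominator_A = unname(result$denominators[1]),
       denominator_B = unname(result$denominators[2]),
       n_skipped = nrow(result$skipped),
       fisher_p = result$fisher$p,
       odds_ratio = result$fisher$odds_ratio,
       bh_threshold_A = unname(result$bh_threshold[1]),
       bh_threshold_B = unname(result$bh_threshold[2]),
       fdr_level = result$fdr_level,
       fdr_family = result$fdr_family,
       denominator_policy = result$denominator)
}
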