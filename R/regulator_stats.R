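#' Two-sided Mann-Whitney U test
#'
#' U statistic with midrank tie handling. The p-value is exact (full
#' permutation distribution) when both groups have at most 8 observations
#' and no ties are present; otherwise the normal approximation with
#' tie-corrected variance and continuity correction is used.
#'
#' @param x,y numeric vectors (missing values dropped); both non-empty.
#' @return list with \code{U}, \code{p} and \code{method}
#'   (\code{"exact"} or \code{"normal_approx"}).
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 8 && length(y) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal_approx")
}

#' Define a regulator set
#'
#' Role-disjoint groups of receptor, corepressor and (optional) coactivator
#' gene symbols used by \code{\link{compare_regulators}}.
#'
#' @param receptors receptor gene symbols (e.g. NR1H3, NR1H2, ESR1, PGR).
#' @param corepressors corepressor gene symbols (e.g. NCOR1, NCOR2, LCOR).
#' @param coactivators optional coactivator gene symbols.
#' @return object of class \code{regulator_set}.
#' @export
regulator_set <- function(receptors, corepressors,
                          coactivators = character(0)) {
  receptors <- canonicalize_symbols(receptors)
  corepressors <- canonicalize_symbols(corepressors)
  coactivators <- canonicalize_symbols(coactivators)
  all_syms <- c(receptors, corepressors, coactivators)
  dup <- unique(all_syms[duplicated(all_syms)])
  if (length(dup) > 0) {
    stop("regulator roles must be disjoint; shared symbol(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(list(receptors = receptors, corepressors = corepressors,
                 coactivators = coactivators), class = "regulator_set")
}

#' Cross-cohort regulator expression comparison
#'
#' For every regulator gene, compares expression between the two cohorts
#' with a two-tailed Mann-Whitney U test and applies Bonferroni correction
#' over the family of regulators actually tested (override with \code{m}).
#' Regulators absent from the matrix are flagged, not fatal. Cohorts are
#' taken in sorted label order; \code{median_A} refers to the first.
#'
#' @param expr genes-by-samples expression matrix.
#' @param ann cohort annotation (\code{sample_id}, \code{cohort}); exactly
#'   two cohort labels among samples present in \code{expr}.
#' @param regs a \code{regulator_set} or character vector of gene symbols.
#' @param m Bonferroni family size (default: number of regulators tested).
#' @return data frame with one row per regulator: \code{gene}, \code{role},
#'   \code{present}, \code{median_A}, \code{median_B}, \code{U},
#'   \code{p_raw}, \code{p_adj}; cohort labels in the \code{"cohorts"}
#'   attribute.
#' @export
compare_regulators <- function(expr, ann, regs, m = NULL) {
  expr <- validate_expression_matrix(expr)
  ann <- validate_cohort_annotation(ann)
  ann <- ann[ann$sample_id %in% colnames(expr), , drop = FALSE]
  if (nrow(ann) == 0) {
    stop("no overlap between annotation samples and expression columns",
         call. = FALSE)
  }
  cohorts <- sort(unique(ann$cohort))
  if (length(cohorts) != 2) {
    stop("exactly two cohort labels required, found: ",
         paste(cohorts, collapse = ", "), call. = FALSE)
  }
  if (inherits(regs, "regulator_set")) {
    genes <- c(regs$receptors, regs$corepressors, regs$coactivators)
    role <- rep(c("receptor", "corepressor", "coactivator"),
                c(length(regs$receptors), length(regs$corepressors),
                  length(regs$coactivators)))
  } else {
    genes <- canonicalize_symbols(regs)
    role <- rep("regulator", length(genes))
  }
  ids_a <- ann$sample_id[ann$cohort == cohorts[1]]
  ids_b <- ann$sample_id[ann$cohort == cohorts[2]]

  present <- genes %in% rownames(expr)
  rows <- lapply(seq_along(genes), function(i) {
    if (!present[i]) {
      return(data.frame(gene = genes[i], role = role[i], present = FALSE,
                        median_A = NA_real_, median_B = NA_real_,
                        U = NA_real_, p_raw = NA_real_,
                        stringsAsFactors = FALSE))
    }
    xa <- expr[genes[i], ids_a]
    xb <- expr[genes[i], ids_b]
    mw <- mann_whitney_u(xa, xb)
    data.frame(gene = genes[i], role = role[i], present = TRUE,
               median_A = stats::median(xa, na.rm = TRUE),
               median_B = stats::median(xb, na.rm = TRUE),
               U = mw$U, p_raw = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  fam <- if (is.null(m)) sum(present) else m
  out$p_adj <- NA_real_
  if (sum(present) > 0) {
    out$p_adj[present] <- bonferroni(out$p_raw[present], m = fam)
  }
  attr(out, "cohorts") <- cohorts
  out
}

#' Receptor-to-corepressor ratio score
#'
#' Per-sample score = log-expression(receptor) minus the mean
#' log-expression of the given corepressor(s): the log of the linear
#' ratio (geometric-mean corepressor when several are supplied). On
#' log-scale (possibly median-centered) matrices this is the standard
#' reading of "ratio of receptor to corepressor"; a linear-space ratio of
#' centered values would be meaningless since they can be negative. The
#' score is missing wherever any involved gene is missing.
#'
#' @param expr genes-by-samples log-scale expression matrix.
#' @param receptor receptor gene symbol.
#' @param corepressor one or more corepressor gene symbols.
#' @return data frame (\code{sample_id}, \code{score}) with the receptor
#'   and corepressor(s) recorded as attributes.
#' @export
ratio_score <- function(expr, receptor, corepressor) {
  expr <- validate_expression_matrix(expr)
  receptor <- canonicalize_symbols(receptor)
  corepressor <- canonicalize_symbols(corepressor)
  missing_genes <- setdiff(c(receptor, corepressor), rownames(expr))
  if (length(missing_genes) > 0) {
    stop("gene(s) absent from expression matrix: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  cor_mat <- expr[corepressor, , drop = FALSE]
  cor_mean <- colMeans(cor_mat)           # NA if any corepressor missing
  score <- expr[receptor, ] - cor_mean
  out <- data.frame(sample_id = colnames(expr), score = unname(score),
                    stringsAsFactors = FALSE)
  attr(out, "receptor") <- receptor
  attr(out, "corepressor") <- corepressor
  out
}

#' Correlate a ratio score with a target gene, per cohort
#'
#' Pearson correlation (via \code{\link{pearson_with_p}}) of the
#' receptor/corepressor ratio score with the target gene's expression,
#' computed separately within each cohort.
#'
#' @param profile data frame from \code{\link{ratio_score}}.
#' @param expr genes-by-samples expression matrix.
#' @param target target gene symbol (must be present in \code{expr}).
#' @param ann cohort annotation (\code{sample_id}, \code{cohort}).
#' @return data frame with one row per cohort: \code{cohort}, \code{r},
#'   \code{p}, \code{n_used}.
#' @export
ratio_target_correlation <- function(profile, expr, target, ann) {
  expr <- validate_expression_matrix(expr)
  ann <- validate_cohort_annotation(ann)
  target <- canonicalize_symbols(target)
  if (!target %in% rownames(expr)) {
    stop("target gene '", target, "' absent from expression matrix",
         call. = FALSE)
  }
  sc <- stats::setNames(profile$score, profile$sample_id)
  ann <- ann[ann$sample_id %in% colnames(expr) &
               ann$sample_id %in% names(sc), , drop = FALSE]
  cohorts <- sort(unique(ann$cohort))
  rows <- lapply(cohorts, function(co) {
    ids <- ann$sample_id[ann$cohort == co]
    res <- pearson_with_p(sc[ids], expr[target, ids], gene = target)
    data.frame(cohort = co, r = res$r, p = res$p, n_used = res$n_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
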