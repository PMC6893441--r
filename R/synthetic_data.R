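#' Configuration for the two-cohort synthetic expression generator
#'
#' The generator emulates a two-cohort tumour expression extract in which
#' the coupling between a transcription factor (TF) and its target genes is
#' modulated by corepressor abundance: per sample, the TF log-expression x
#' and three corepressor log-expressions z_1..z_3 are Gaussian with
#' cohort-specific means; the repression index is their mean
#' r = mean(z); the coupling weight is the logistic
#' w = 1 / (1 + exp(-kappa * (x - r - theta))); a true target i is
#' y_i = beta_i * w * x + noise while decoys are pure noise. Values sit on
#' a log2-like scale; per-gene median centering applied afterwards mimics
#' array-median-centered extracts without changing any correlation. Cohort
#' A is de-repressed by default (higher TF, much lower corepressors), so
#' its coupling weights saturate near 1 while cohort B sits on the
#' repressed shoulder of the logistic where the corepressor level, not the
#' TF level, controls target output -- mirroring an ER-negative versus
#' Luminal-A contrast with cohort sizes 81 and 234.
#'
#' @param n_A,n_B cohort sizes (defaults 81 and 234).
#' @param n_targets number of true target genes (default 135).
#' @param n_decoys number of uncoupled decoy genes (default 865).
#' @param n_canonical number of targets designated "canonical literature
#'   targets" (default 24); these are the first \code{n_canonical} targets
#'   and are excluded from the simulated binding lists so the panel builder
#'   must re-add them through the canonical-union step.
#' @param mu_tf_A,mu_tf_B TF log-expression means per cohort.
#' @param sigma_tf TF log-expression SD.
#' @param mu_cor_A,mu_cor_B corepressor log-expression means per cohort.
#' @param sigma_cor corepressor log-expression SD.
#' @param beta_range range of per-target coupling magnitudes (uniform draw).
#' @param kappa steepness of the logistic repression modulation.
#' @param theta repression midpoint on the log-ratio scale.
#' @param sigma_y target/decoy noise SD.
#' @param cohort_labels two cohort labels (default \code{"ERneg"},
#'   \code{"ERpos"}; sorted order defines cohort A).
#' @param tf_gene TF gene symbol (default \code{"NR1H3"}).
#' @param corepressor_genes three corepressor symbols (default NCOR1,
#'   NCOR2, LCOR).
#' @param seed RNG seed (Mersenne-Twister); same seed, same output.
#' @param center apply per-gene median centering last, mimicking
#'   array-median-centered extracts (default \code{TRUE}).
#' @return object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_A = 81, n_B = 234,
                             n_targets = 135, n_decoys = 865,
                             n_canonical = 24,
                             mu_tf_A = 2.5, mu_tf_B = 2.0, sigma_tf = 0.5,
                             mu_cor_A = 1.0, mu_cor_B = 4.0,
                             sigma_cor = 1.2,
                             beta_range = c(0.6, 1.4),
                             kappa = 2.5, theta = 0, sigma_y = 1,
                             cohort_labels = c("ERneg", "ERpos"),
                             tf_gene = "NR1H3",
                             corepressor_genes = c("NCOR1", "NCOR2",
                                                   "LCOR"),
                             seed = 1, center = TRUE) {
  stopifnot(n_A >= 1, n_B >= 1, n_targets >= 1, n_decoys >= 0,
            n_canonical >= 0, n_canonical <= n_targets,
            sigma_tf >= 0, sigma_cor >= 0, sigma_y >= 0,
            length(beta_range) == 2, beta_range[1] <= beta_range[2],
            beta_range[1] >= 0, is.finite(kappa), is.finite(theta),
            length(cohort_labels) == 2,
            cohort_labels[1] != cohort_labels[2],
            length(corepressor_genes) == 3)
  structure(list(n_A = as.integer(n_A), n_B = as.integer(n_B),
                 n_targets = as.integer(n_targets),
                 n_decoys = as.integer(n_decoys),
                 n_canonical = as.integer(n_canonical),
                 mu_tf_A = mu_tf_A, mu_tf_B = mu_tf_B,
                 sigma_tf = sigma_tf,
                 mu_cor_A = mu_cor_A, mu_cor_B = mu_cor_B,
                 sigma_cor = sigma_cor,
                 beta_range = as.numeric(beta_range),
                 kappa = kappa, theta = theta, sigma_y = sigma_y,
                 cohort_labels = as.character(cohort_labels),
                 tf_gene = canonicalize_symbols(tf_gene),
                 corepressor_genes =
                   canonicalize_symbols(corepressor_genes),
                 seed = as.integer(seed), center = isTRUE(center)),
            class = "synthetic_config")
}

target_gene_names <- function(n) sprintf("TG%03d", seq_len(n))
decoy_gene_names <- function(n) sprintf("DC%03d", seq_len(n))

#' Simulate a two-cohort expression matrix with modulated TF-target coupling
#'
#' Draws, per sample, the TF value, three corepressor values, the logistic
#' coupling weight, and target/decoy expression as described in
#' \code{\link{synthetic_config}}. The RNG is R's default Mersenne-Twister
#' seeded with \code{cfg$seed}; draws happen in a fixed documented order
#' (target coupling magnitudes; then per cohort: TF, corepressors, target
#' noise, decoy noise), so a seed pins the output exactly. Matrix rows are
#' ordered TF, corepressors, targets (TG...), decoys (DC...).
#'
#' @param cfg a \code{synthetic_config}.
#' @return list with \code{expression} (genes-by-samples matrix),
#'   \code{annotation} (sample_id/cohort data frame) and \code{truth}
#'   (per-gene target flags and coupling magnitudes, canonical subset,
#'   per-sample coupling weights, the config).
#' @export
simulate_cohorts <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  tg <- target_gene_names(cfg$n_targets)
  dc <- decoy_gene_names(cfg$n_decoys)
  genes <- c(cfg$tf_gene, cfg$corepressor_genes, tg, dc)
  beta <- stats::runif(cfg$n_targets, cfg$beta_range[1],
                       cfg$beta_range[2])

  draw_cohort <- function(n, mu_tf, mu_cor) {
    x <- stats::rnorm(n, mu_tf, cfg$sigma_tf)
    z <- matrix(stats::rnorm(3 * n, mu_cor, cfg$sigma_cor), nrow = 3)
    r <- colMeans(z)
    w <- stats::plogis(cfg$kappa * (x - r - cfg$theta))
    y_t <- beta %o% (w * x) +
      matrix(stats::rnorm(cfg$n_targets * n, 0, cfg$sigma_y),
             nrow = cfg$n_targets)
    y_d <- matrix(stats::rnorm(cfg$n_decoys * n, 0, cfg$sigma_y),
                  nrow = cfg$n_decoys, ncol = n)
    list(mat = rbind(x, z, y_t, y_d), w = w)
  }
  a <- draw_cohort(cfg$n_A, cfg$mu_tf_A, cfg$mu_cor_A)
  b <- draw_cohort(cfg$n_B, cfg$mu_tf_B, cfg$mu_cor_B)

  samples <- c(sprintf("%s_%03d", cfg$cohort_labels[1], seq_len(cfg$n_A)),
               sprintf("%s_%03d", cfg$cohort_labels[2], seq_len(cfg$n_B)))
  mat <- cbind(a$mat, b$mat)
  dimnames(mat) <- list(genes, samples)
  if (cfg$center) mat <- median_center(mat)

  ann <- data.frame(
    sample_id = samples,
    cohort = rep(cfg$cohort_labels, c(cfg$n_A, cfg$n_B)),
    stringsAsFactors = FALSE)

  truth <- list(
    is_target = stats::setNames(genes %in% tg, genes),
    beta = stats::setNames(c(rep(NA_real_, 4), beta,
                             rep(0, cfg$n_decoys)), genes),
    canonical = tg[seq_len(cfg$n_canonical)],
    consensus = setdiff(tg, tg[seq_len(cfg$n_canonical)]),
    w = stats::setNames(c(a$w, b$w), samples),
    config = cfg)

  list(expression = mat, annotation = ann, truth = truth)
}

#' Simulate companion ChIP-Seq binding tables and an ortholog map
#'
#' Builds a deterministic binding-score fixture around the ground truth of
#' \code{\link{simulate_cohorts}}, with the geometry of a seven-dataset,
#' five-replicate-group collection (two mouse singleton datasets, two
#' duplicated human groups, one human singleton). Non-canonical ("consensus")
#' targets are planted near the top of exactly two of the five
#' post-averaging lists; additional planted symbols exercise the exclusion
#' bookkeeping: \code{n_no_ortholog} mouse-only symbols appear in both mouse
#' lists but have no ortholog-map entry, and \code{n_not_expressed} symbols
#' appear in two human lists but are withheld from the expression matrix.
#' Remaining list slots are filled with single-list decoy genes, plus a
#' low-scoring tail so top-K selection has something to discard. Mouse list
#' entries use "MM"-prefixed source symbols resolved through the returned
#' ortholog map. Replicated groups emit two tables whose scores average
#' back to the group scores. Canonical targets never appear in any list.
#'
#' @param truth ground-truth list from \code{\link{simulate_cohorts}}.
#' @param n_no_ortholog number of unmapped mouse-only symbols (default 11).
#' @param n_not_expressed number of symbols withheld from the expression
#'   matrix (default 26).
#' @param list_size genes per post-averaging list above the top-K cutoff
#'   (default 100).
#' @param tail_size extra below-cutoff genes per list (default 40).
#' @return list with \code{tables} (seven \code{binding_score_table}s),
#'   \code{orthologs} (data frame) and \code{canonical} (a
#'   \code{gene_list}).
#' @export
simulate_binding_tables <- function(truth, n_no_ortholog = 11,
                                    n_not_expressed = 26,
                                    list_size = 100, tail_size = 40) {
  stopifnot(n_no_ortholog >= 0, n_not_expressed >= 0, list_size >= 1)
  consensus <- truth$consensus
  groups <- data.frame(
    group = c("mouse_untreated", "mouse_gw3965", "crc_2h", "crc_48h",
              "adipocyte"),
    species = c("mouse", "mouse", "human", "human", "human"),
    n_rep = c(1L, 1L, 2L, 2L, 1L),
    stringsAsFactors = FALSE)

  members <- rep(list(character(0)), 5)
  # consensus targets: cycle through the 10 unordered pairs of 5 groups
  pairs <- utils::combn(5, 2)
  for (i in seq_along(consensus)) {
    pr <- pairs[, ((i - 1) %% ncol(pairs)) + 1]
    for (g in pr) members[[g]] <- c(members[[g]], consensus[i])
  }
  # not-expressed symbols: pairs among the three human groups only
  nx <- if (n_not_expressed > 0) sprintf("NX%03d", seq_len(n_not_expressed))
        else character(0)
  hpairs <- utils::combn(3:5, 2)
  for (i in seq_along(nx)) {
    pr <- hpairs[, ((i - 1) %% ncol(hpairs)) + 1]
    for (g in pr) members[[g]] <- c(members[[g]], nx[i])
  }
  # mouse-only unmapped symbols: both mouse lists
  mus <- if (n_no_ortholog > 0) sprintf("MUSG%03d", seq_len(n_no_ortholog))
         else character(0)
  for (g in 1:2) members[[g]] <- c(members[[g]], mus)

  decoys <- names(truth$beta)[startsWith(names(truth$beta), "DC")]
  next_decoy <- 1L
  take_decoys <- function(n) {
    if (n == 0) return(character(0))
    if (next_decoy + n - 1L > length(decoys)) {
      stop("not enough decoy genes to fill binding lists; increase ",
           "n_decoys or lower list_size", call. = FALSE)
    }
    out <- decoys[next_decoy:(next_decoy + n - 1L)]
    next_decoy <<- next_decoy + n
    out
  }

  orth <- list()
  tables <- list()
  for (g in 1:5) {
    core <- sort(unique(members[[g]]))
    if (length(core) > list_size) {
      stop("binding list '", groups$group[g], "' overflows list_size (",
           length(core), " > ", list_size, ")", call. = FALSE)
    }
    fill <- take_decoys(list_size - length(core))
    tail <- take_decoys(tail_size)
    syms <- c(core, fill, tail)
    scores <- as.numeric(length(syms):1)
    if (groups$species[g] == "mouse") {
      mapped <- !syms %in% mus
      src <- ifelse(mapped, paste0("MM", syms), syms)
      orth[[g]] <- data.frame(source_symbol = src[mapped],
                              human_symbol = syms[mapped],
                              stringsAsFactors = FALSE)
      syms <- src
    }
    if (groups$n_rep[g] == 1) {
      tables[[length(tables) + 1]] <- binding_score_table(
        groups$group[g], groups$species[g], groups$group[g], syms, scores)
    } else {
      for (rep_i in seq_len(groups$n_rep[g])) {
        delta <- if (rep_i == 1) 0.5 else -0.5
        tables[[length(tables) + 1]] <- binding_score_table(
          paste0(groups$group[g], "_rep", rep_i), groups$species[g],
          groups$group[g], syms, scores + delta)
      }
    }
  }
  orthologs <- unique(do.call(rbind, orth[!vapply(orth, is.null, TRUE)]))
  list(tables = tables,
       orthologs = orthologs,
       canonical = gene_list(truth$canonical,
                             label = "canonical targets"))
}
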