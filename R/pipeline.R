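#' Pipeline configuration
#'
#' A single serializable source of truth for the end-to-end synthetic
#' analysis: simulate, build the target panel, run the coupling screen,
#' compare regulators, and compute ratio-target correlations. All stage
#' inputs and outputs live under \code{outdir} with fixed file names
#' (\code{expression.tsv}, \code{annotation.tsv}, \code{binding/}
#' with a manifest, \code{orthologs.tsv}, \code{canonical.txt},
#' \code{panel.tsv}, \code{screen.tsv}, \code{regulators.tsv},
#' \code{ratio.tsv}, \code{report.json}), so any stage can be rerun from
#' the persisted intermediates of an earlier run.
#'
#' @param outdir output directory.
#' @param seed RNG seed (overrides the synthetic config's seed).
#' @param synthetic a \code{synthetic_config} (default: package defaults
#'   with \code{seed}).
#' @param panel a \code{panel_config}.
#' @param fdr_level FDR threshold for the screen (default 0.01).
#' @param tf_gene TF gene symbol.
#' @param receptors,corepressors regulator symbols for the cross-cohort
#'   comparison.
#' @param ratio_targets target genes for the ratio-correlation stage.
#' @param quiet suppress progress messages on stderr.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(outdir, seed = 1, synthetic = NULL,
                            panel = panel_config(), fdr_level = 0.01,
                            tf_gene = "NR1H3",
                            receptors = c("NR1H3"),
                            corepressors = c("NCOR1", "NCOR2", "LCOR"),
                            ratio_targets = c("TG001", "TG002"),
                            quiet = FALSE) {
  if (is.null(synthetic)) synthetic <- synthetic_config(seed = seed)
  stopifnot(inherits(synthetic, "synthetic_config"),
            inherits(panel, "panel_config"))
  structure(list(outdir = outdir, seed = as.integer(seed),
                 synthetic = synthetic, panel = panel,
                 fdr_level = fdr_level,
                 tf_gene = canonicalize_symbols(tf_gene),
                 receptors = canonicalize_symbols(receptors),
                 corepressors = canonicalize_symbols(corepressors),
                 ratio_targets = canonicalize_symbols(ratio_targets),
                 quiet = isTRUE(quiet)),
            class = "pipeline_config")
}

pipe_path <- function(cfg, ...) file.path(cfg$outdir, ...)

pipe_log <- function(cfg, ...) {
  if (!cfg$quiet) message("[regulonCoupler] ", ...)
}

require_input <- function(path, what) {
  if (!file.exists(path)) {
    stop(what, " input not found: ", path, call. = FALSE)
  }
  path
}

#' Run the synthetic analysis pipeline
#'
#' Executes the requested stages in dependency order. Later stages read
#' only the files persisted by earlier stages, so
#' \code{run_pipeline(cfg, stages = "screen")} on a directory produced by a
#' full run reproduces the full run's screen output exactly (stage
#' isolation). Progress goes to stderr; results go to files; the combined
#' machine-readable report (counts, statistics, settings, no timestamps)
#' is written to \code{report.json} and returned invisibly.
#'
#' @param cfg a \code{pipeline_config}.
#' @param stages subset of \code{c("simulate", "build-panel", "screen",
#'   "regulators", "ratio")} (default: all, in order).
#' @return the report list, invisibly.
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "build-panel",
                                         "screen", "regulators",
                                         "ratio")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg$seed, stages = stages)

  if ("simulate" %in% stages) {
    pipe_log(cfg, "simulate: cohorts ", cfg$synthetic$n_A, " + ",
             cfg$synthetic$n_B, ", ", cfg$synthetic$n_targets,
             " targets, seed ", cfg$synthetic$seed)
    sim <- simulate_cohorts(cfg$synthetic)
    fix <- simulate_binding_tables(sim$truth)
    write_expression_matrix(sim$expression, pipe_path(cfg, "expression.tsv"))
    write_cohort_annotation(sim$annotation, pipe_path(cfg, "annotation.tsv"))
    write_binding_manifest(fix$tables, pipe_path(cfg, "binding"))
    write_ortholog_map(fix$orthologs, pipe_path(cfg, "orthologs.tsv"))
    write_gene_list(fix$canonical, pipe_path(cfg, "canonical.txt"))
    jsonlite::write_json(
      list(is_target = as.list(sim$truth$is_target),
           beta = as.list(sim$truth$beta),
           canonical = sim$truth$canonical),
      pipe_path(cfg, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    report$simulate <- list(n_genes = nrow(sim$expression),
                            n_samples = ncol(sim$expression),
                            n_binding_tables = length(fix$tables))
  }

  if ("build-panel" %in% stages) {
    pipe_log(cfg, "build-panel: top-", cfg$panel$top_k, ", membership >= ",
             cfg$panel$min_list_membership)
    tables <- read_binding_manifest(
      require_input(pipe_path(cfg, "binding", "manifest.tsv"),
                    "binding manifest"))
    orthologs <- read_ortholog_map(
      require_input(pipe_path(cfg, "orthologs.tsv"), "ortholog map"))
    expr <- read_expression_matrix(
      require_input(pipe_path(cfg, "expression.tsv"), "expression matrix"))
    canonical <- read_gene_list(
      require_input(pipe_path(cfg, "canonical.txt"), "canonical list"))
    averaged <- average_replicates(tables)
    lists <- lapply(averaged, top_k_genes, k = cfg$panel$top_k)
    panel <- build_panel(lists,
                         species = vapply(averaged, `[[`, "", "species"),
                         orthologs = orthologs, expr = expr,
                         canonical = canonical, cfg = cfg$panel)
    write_target_panel(panel, pipe_path(cfg, "panel.tsv"))
    jsonlite::write_json(panel$counts, pipe_path(cfg, "panel_report.json"),
                         auto_unbox = TRUE, digits = NA)
    report$panel <- panel$counts
  }

  if ("screen" %in% stages) {
    pipe_log(cfg, "screen: TF ", cfg$tf_gene, ", FDR ", cfg$fdr_level)
    expr <- read_expression_matrix(
      require_input(pipe_path(cfg, "expression.tsv"), "expression matrix"))
    ann <- read_cohort_annotation(
      require_input(pipe_path(cfg, "annotation.tsv"), "annotation"))
    panel <- read_target_panel(
      require_input(pipe_path(cfg, "panel.tsv"), "target panel"))
    scr <- run_screen(expr, ann, cfg$tf_gene, panel,
                      fdr_level = cfg$fdr_level)
    write_screen_records(scr, pipe_path(cfg, "screen.tsv"))
    jsonlite::write_json(screen_summary(scr),
                         pipe_path(cfg, "screen_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    report$screen <- screen_summary(scr)
  }

  if ("regulators" %in% stages) {
    pipe_log(cfg, "regulators: ",
             length(c(cfg$receptors, cfg$corepressors)), " genes")
    expr <- read_expression_matrix(
      require_input(pipe_path(cfg, "expression.tsv"), "expression matrix"))
    ann <- read_cohort_annotation(
      require_input(pipe_path(cfg, "annotation.tsv"), "annotation"))
    regs <- regulator_set(cfg$receptors, cfg$corepressors)
    cmp <- compare_regulators(expr, ann, regs)
    utils::write.table(cmp, pipe_path(cfg, "regulators.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$regulators <- list(
      n_tested = sum(cmp$present),
      n_adj_significant = sum(cmp$p_adj < 0.05, na.rm = TRUE))
  }

  if ("ratio" %in% stages) {
    pipe_log(cfg, "ratio: ", cfg$tf_gene, " vs ",
             paste(cfg$corepressors, collapse = ","))
    expr <- read_expression_matrix(
      require_input(pipe_path(cfg, "expression.tsv"), "expression matrix"))
    ann <- read_cohort_annotation(
      require_input(pipe_path(cfg, "annotation.tsv"), "annotation"))
    rows <- list()
    for (target in cfg$ratio_targets) {
      for (corep in c(list(cfg$corepressors), as.list(cfg$corepressors))) {
        prof <- ratio_score(expr, cfg$tf_gene, corep)
        rc <- ratio_target_correlation(prof, expr, target, ann)
        rc$target <- target
        rc$corepressor <- paste(corep, collapse = "+")
        rows[[length(rows) + 1]] <- rc
      }
    }
    ratio_tab <- do.call(rbind, rows)
    ratio_tab <- ratio_tab[, c("target", "corepressor", "cohort", "r",
                               "p", "n_used")]
    utils::write.table(ratio_tab, pipe_path(cfg, "ratio.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$ratio <- list(n_rows = nrow(ratio_tab))
  }

  jsonlite::write_json(report, pipe_path(cfg, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  pipe_log(cfg, "done; report at ", pipe_path(cfg, "report.json"))
  invisible(report)
}
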