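#' Panel-construction configuration
#'
#' @param top_k number of top-scoring genes retained from each averaged
#'   binding-score table (default 100).
#' @param min_list_membership minimum number of post-averaging lists a gene
#'   must appear in to enter the consensus panel (default 2; genes seen in
#'   only one list are excluded).
#' @param min_expressed_fraction minimum fraction of samples in which a gene
#'   must be non-missing in the expression matrix to count as "expressed"
#'   (default 0.5); genes absent from the matrix always fail.
#' @return object of class \code{panel_config}.
#' @export
panel_config <- function(top_k = 100, min_list_membership = 2,
                         min_expressed_fraction = 0.5) {
  stopifnot(length(top_k) == 1, top_k >= 1,
            length(min_list_membership) == 1, min_list_membership >= 1,
            length(min_expressed_fraction) == 1,
            min_expressed_fraction >= 0, min_expressed_fraction <= 1)
  structure(list(top_k = as.integer(top_k),
                 min_list_membership = as.integer(min_list_membership),
                 min_expressed_fraction = min_expressed_fraction),
            class = "panel_config")
}

#' Average replicate binding-score tables
#'
#' Tables sharing a \code{replicate_group} are collapsed to one table whose
#' score for each gene is the arithmetic mean over the replicates in which
#' the gene is present (present-only averaging). Groups may not mix species.
#' Singleton groups pass through unchanged. Output order follows the first
#' appearance of each group.
#'
#' @param tables list of \code{binding_score_table} objects.
#' @return list of \code{binding_score_table}, one per replicate group.
#' @export
average_replicates <- function(tables) {
  stopifnot(all(vapply(tables, inherits, TRUE, "binding_score_table")))
  groups <- vapply(tables, function(t) t$replicate_group, "")
  out <- list()
  for (g in unique(groups)) {
    members <- tables[groups == g]
    sp <- unique(vapply(members, function(t) t$species, ""))
    if (length(sp) > 1) {
      stop("replicate group '", g, "' mixes species: ",
           paste(sp, collapse = ", "), call. = FALSE)
    }
    if (length(members) == 1) {
      out[[length(out) + 1]] <- members[[1]]
      next
    }
    all_entries <- do.call(rbind, lapply(members, function(t) t$entries))
    mean_score <- tapply(all_entries$score, all_entries$gene, mean)
    genes <- names(mean_score)[order(names(mean_score))]
    out[[length(out) + 1]] <- binding_score_table(
      dataset_id = g, species = sp, replicate_group = g,
      genes = genes, scores = as.numeric(mean_score[genes]))
  }
  out
}

#' Top-K genes of a binding-score table
#'
#' Returns the \code{min(k, n)} genes with the highest binding scores,
#' sorted by descending score with ties broken by ascending lexicographic
#' symbol order, so the selection is deterministic regardless of input row
#' order.
#'
#' @param table a \code{binding_score_table}.
#' @param k positive integer.
#' @return a \code{gene_list} labelled with the dataset id.
#' @export
top_k_genes <- function(table, k) {
  stopifnot(inherits(table, "binding_score_table"), k >= 1)
  e <- table$entries
  ord <- order(-e$score, e$gene)
  keep <- ord[seq_len(min(as.integer(k), nrow(e)))]
  gene_list(e$gene[keep], label = table$dataset_id)
}

#' Build a consensus TF target panel from top-K binding lists
#'
#' Pipeline order: (1) map every symbol from a non-human list to its human
#' ortholog (unmapped symbols are recorded and then dropped), (2) count in
#' how many lists each human symbol appears and keep symbols reaching
#' \code{min_list_membership}, (3) drop symbols failing the
#' expression-presence rule in \code{expr}, (4) take the deduplicated union
#' with the canonical target list (canonical genes bypass all filters).
#' Bookkeeping counts and per-gene provenance are returned alongside the
#' final symbol list. Consensus symbols are ordered lexicographically,
#' followed by the canonical additions, so identical inputs in any row
#' order yield identical panels.
#'
#' @param lists list of \code{gene_list} objects (or character vectors), one
#'   per post-averaging dataset.
#' @param species character vector, species of each list.
#' @param orthologs ortholog map data frame (\code{source_symbol},
#'   \code{human_symbol}) used for non-human lists; may be empty.
#' @param expr expression matrix used for the presence filter.
#' @param canonical \code{gene_list} (or character vector) of canonical
#'   targets included regardless of filters; may be empty.
#' @param cfg a \code{panel_config}.
#' @return object of class \code{target_panel} with elements
#'   \code{symbols}, \code{provenance} (data frame), \code{counts} (list).
#' @export
build_panel <- function(lists, species, orthologs, expr, canonical,
                        cfg = panel_config()) {
  if (length(lists) == 0) stop("no binding lists supplied", call. = FALSE)
  stopifnot(length(species) == length(lists), inherits(cfg, "panel_config"))
  expr <- validate_expression_matrix(expr)
  if (!is.null(orthologs) && nrow(orthologs) > 0) {
    orthologs <- validate_ortholog_map(orthologs)
    omap <- stats::setNames(orthologs$human_symbol, orthologs$source_symbol)
  } else {
    omap <- character(0)
  }
  species <- tolower(trimws(species))

  labels <- vapply(seq_along(lists), function(i) {
    if (inherits(lists[[i]], "gene_list") && nzchar(lists[[i]]$label))
      lists[[i]]$label else paste0("list", i)
  }, "")

  mapped <- vector("list", length(lists))
  unmapped <- vector("list", length(lists))
  for (i in seq_along(lists)) {
    syms <- if (inherits(lists[[i]], "gene_list")) lists[[i]]$symbols else
      canonicalize_symbols(lists[[i]])
    if (species[i] == "human") {
      mapped[[i]] <- unique(syms)
      unmapped[[i]] <- character(0)
    } else {
      hit <- syms %in% names(omap)
      mapped[[i]] <- unique(unname(omap[syms[hit]]))
      unmapped[[i]] <- unique(syms[!hit])
    }
  }

  membership <- table(unlist(mapped))
  unmapped_membership <- table(unlist(unmapped))
  thr <- cfg$min_list_membership

  multi <- names(membership)[membership >= thr]
  dropped_no_ortholog <-
    names(unmapped_membership)[unmapped_membership >= thr]

  is_expressed <- function(sym) {
    sym %in% rownames(expr) &&
      mean(!is.na(expr[sym, ])) >= cfg$min_expressed_fraction
  }
  expressed_flag <- vapply(multi, is_expressed, TRUE)
  after_filters <- sort(multi[expressed_flag])
  dropped_not_expressed <- sort(multi[!expressed_flag])

  canon_syms <- if (inherits(canonical, "gene_list")) canonical$symbols else
    canonicalize_symbols(canonical)
  canonical_added <- setdiff(canon_syms, after_filters)
  final <- c(after_filters, sort(canonical_added))

  contributing <- function(sym) {
    paste(labels[vapply(mapped, function(m) sym %in% m, TRUE)],
          collapse = ",")
  }
  prov <- data.frame(
    symbol = final,
    source = ifelse(final %in% after_filters & final %in% canon_syms, "both",
                    ifelse(final %in% after_filters, "consensus",
                           "canonical")),
    n_lists = as.integer(ifelse(final %in% names(membership),
                                membership[final], 0L)),
    datasets = vapply(final, contributing, ""),
    in_expression = final %in% rownames(expr),
    stringsAsFactors = FALSE, row.names = NULL)

  counts <- list(
    n_lists_in = length(lists),
    n_multi_list = length(multi) + length(dropped_no_ortholog),
    n_dropped_no_ortholog = length(dropped_no_ortholog),
    n_dropped_not_expressed = length(dropped_not_expressed),
    n_after_filters = length(after_filters),
    n_canonical_added = length(canonical_added),
    n_final = length(final))

  structure(list(symbols = final, provenance = prov, counts = counts,
                 dropped_no_ortholog = sort(dropped_no_ortholog),
                 dropped_not_expressed = dropped_not_expressed,
                 config = cfg),
            class = "target_panel")
}

#' @export
print.target_panel <- function(x, ...) {
  c0 <- x$counts
  cat(sprintf(paste0(
    "target_panel: %d genes\n",
    "  multi-list candidates: %d\n",
    "  dropped (no human ortholog): %d\n",
    "  dropped (not expressed): %d\n",
    "  after filters: %d; canonical added: %d\n"),
    c0$n_final, c0$n_multi_list, c0$n_dropped_no_ortholog,
    c0$n_dropped_not_expressed, c0$n_after_filters, c0$n_canonical_added))
  invisible(x)
}

#' Write a target panel (provenance TSV)
#' @param panel a \code{target_panel}.
#' @param path output path.
#' @export
write_target_panel <- function(panel, path) {
  stopifnot(inherits(panel, "target_panel"))
  utils::write.table(panel$provenance, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a target panel written by \code{write_target_panel}
#' @param path path to the panel TSV.
#' @return a \code{gene_list} of panel symbols (provenance columns retained
#'   as the \code{"provenance"} attribute).
#' @export
read_target_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  gl <- gene_list(df$symbol, label = "target panel")
  attr(gl, "provenance") <- df
  gl
}
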