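#' Canonicalize gene symbols
#'
#' Uppercases and strips surrounding whitespace so joins between expression
#' matrices, binding-score tables and gene lists never fail on case or
#' stray blanks. No alias resolution is attempted; symbol aliasing is an
#' input concern handled through ortholog/alias map files.
#'
#' @param x character vector of gene symbols.
#' @return character vector of canonical symbols.
#' @export
canonicalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Validate a genes-by-samples expression matrix
#'
#' An expression matrix is a plain numeric matrix of log-scale (optionally
#' median-centered) expression values with canonical, unique gene symbols as
#' row names and unique sample identifiers as column names. Missing values
#' are allowed.
#'
#' @param values numeric matrix with dimnames.
#' @return the validated matrix (row names canonicalized), invisibly the
#'   same object.
#' @export
validate_expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix requires gene row names and sample column names",
         call. = FALSE)
  }
  genes <- canonicalize_symbols(rownames(values))
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    stop("duplicate gene symbol(s) in expression matrix: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s) > 0) {
    stop("duplicate sample id(s) in expression matrix: ",
         paste(dup_s, collapse = ", "), call. = FALSE)
  }
  rownames(values) <- genes
  values
}

#' Read an expression matrix from a delimited text file
#'
#' Expects a header row of sample identifiers, a first column of gene
#' symbols, and a numeric body (a configurable token marks missing values).
#' Row and column order are preserved.
#'
#' @param path path to the file.
#' @param sep field delimiter (default tab).
#' @param na_token token representing a missing value (default \code{"NA"}).
#' @return numeric genes-by-samples matrix.
#' @export
read_expression_matrix <- function(path, sep = "\t", na_token = "NA") {
  if (!file.exists(path)) {
    stop("expression matrix file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) {
    stop("expression matrix needs a gene column plus at least one sample: ",
         path, call. = FALSE)
  }
  genes <- canonicalize_symbols(raw[[1]])
  body <- as.matrix(raw[, -1, drop = FALSE])
  is_na <- body == na_token | is.na(body)
  vals <- suppressWarnings(as.numeric(body))
  bad <- which(is.na(vals) & !is_na)
  if (length(bad) > 0) {
    i <- ((bad[1] - 1) %% nrow(body)) + 1
    j <- ((bad[1] - 1) %/% nrow(body)) + 1
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s' in %s",
                 body[bad[1]], genes[i], colnames(body)[j], path),
         call. = FALSE)
  }
  vals[is_na] <- NA_real_
  out <- matrix(vals, nrow = nrow(body),
                dimnames = list(genes, colnames(body)))
  validate_expression_matrix(out)
}

# 17 significant digits: doubles survive the text round trip exactly
fmt17 <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))

#' Write an expression matrix to a delimited text file
#'
#' Values are written with 17 significant digits so a write-then-read
#' round trip reproduces the matrix exactly.
#'
#' @param mat numeric genes-by-samples matrix.
#' @param path output path.
#' @param sep field delimiter.
#' @param na_token token written for missing values.
#' @export
write_expression_matrix <- function(mat, path, sep = "\t", na_token = "NA") {
  mat <- validate_expression_matrix(mat)
  chr <- matrix(fmt17(mat), nrow = nrow(mat), dimnames = dimnames(mat))
  df <- data.frame(gene = rownames(mat), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = na_token)
  invisible(path)
}

#' Per-gene median centering
#'
#' Subtracts from every gene row its median over non-missing entries, the
#' convention used by array-median-centered expression extracts. For rows of
#' even length the median is the mean of the two central order statistics.
#' Idempotent; missing entries are preserved.
#'
#' @param mat numeric genes-by-samples matrix.
#' @return matrix of identical shape with every row median zero.
#' @export
median_center <- function(mat) {
  mat <- validate_expression_matrix(mat)
  med <- apply(mat, 1, stats::median, na.rm = TRUE)
  bad <- rownames(mat)[!is.finite(med)]
  if (length(bad) > 0) {
    stop("cannot median-center all-missing gene row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sweep(mat, 1, med)
}

#' Construct a labelled gene list
#'
#' @param symbols character vector of gene symbols (canonicalized; must be
#'   unique after canonicalization).
#' @param label free-text label (e.g. the dataset the list came from).
#' @return an object of class \code{gene_list}.
#' @export
gene_list <- function(symbols, label = "") {
  symbols <- canonicalize_symbols(symbols)
  symbols <- symbols[nzchar(symbols)]
  dup <- unique(symbols[duplicated(symbols)])
  if (length(dup) > 0) {
    stop("duplicate gene symbol(s) in gene list '", label, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(list(symbols = symbols, label = label), class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("gene_list '%s' with %d symbols\n", x$label, length(x$symbols)))
  invisible(x)
}

#' Read a gene list (one symbol per line)
#'
#' Blank lines and lines starting with \code{#} are ignored.
#'
#' @param path path to the file.
#' @param label label for the list (defaults to the file name).
#' @return a \code{gene_list}.
#' @export
read_gene_list <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("gene list file not found: ", path,
                               call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_list(lines, label = label)
}

#' Write a gene list, one symbol per line
#' @param x a \code{gene_list} or character vector.
#' @param path output path.
#' @export
write_gene_list <- function(x, path) {
  symbols <- if (inherits(x, "gene_list")) x$symbols else
    canonicalize_symbols(x)
  writeLines(symbols, path)
  invisible(path)
}

#' Read a sample-to-cohort annotation table
#'
#' Two tab-separated columns: \code{sample_id} and \code{cohort}. Sample
#' identifiers must be unique.
#'
#' @param path path to the file.
#' @param sep field delimiter.
#' @return data frame with columns \code{sample_id}, \code{cohort}.
#' @export
read_cohort_annotation <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "cohort") %in% names(df))) {
    stop("annotation needs columns 'sample_id' and 'cohort': ", path,
         call. = FALSE)
  }
  validate_cohort_annotation(df[, c("sample_id", "cohort")])
}

#' Validate a cohort annotation data frame
#' @param df data frame with columns \code{sample_id} and \code{cohort}.
#' @return the validated data frame.
#' @export
validate_cohort_annotation <- function(df) {
  df$sample_id <- trimws(df$sample_id)
  df$cohort <- trimws(df$cohort)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0) {
    stop("duplicate sample id(s) in annotation: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(df$cohort))) {
    stop("empty cohort label in annotation", call. = FALSE)
  }
  df
}

#' Write a cohort annotation table
#' @param df data frame with columns \code{sample_id}, \code{cohort}.
#' @param path output path.
#' @export
write_cohort_annotation <- function(df, path) {
  df <- validate_cohort_annotation(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ortholog map (source symbol to human symbol)
#'
#' Two tab-separated columns: \code{source_symbol}, \code{human_symbol}.
#' A source symbol mapping to more than one distinct human symbol is an
#' input error; exact duplicate rows are collapsed. Unmapped source symbols
#' are simply absent from the table.
#'
#' @param path path to the file.
#' @return data frame with columns \code{source_symbol}, \code{human_symbol}.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) stop("ortholog map file not found: ", path,
                               call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "",
                          stringsAsFactors = FALSE)
  if (!all(c("source_symbol", "human_symbol") %in% names(df))) {
    stop("ortholog map needs columns 'source_symbol' and 'human_symbol': ",
         path, call. = FALSE)
  }
  validate_ortholog_map(df[, c("source_symbol", "human_symbol")])
}

#' Validate an ortholog map data frame
#' @param df data frame with columns \code{source_symbol}, \code{human_symbol}.
#' @return validated, deduplicated data frame.
#' @export
validate_ortholog_map <- function(df) {
  df$source_symbol <- canonicalize_symbols(df$source_symbol)
  df$human_symbol <- canonicalize_symbols(df$human_symbol)
  df <- unique(df)
  dup <- unique(df$source_symbol[duplicated(df$source_symbol)])
  if (length(dup) > 0) {
    stop("source symbol(s) mapping to multiple human symbols: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write an ortholog map
#' @param df data frame with columns \code{source_symbol}, \code{human_symbol}.
#' @param path output path.
#' @export
write_ortholog_map <- function(df, path) {
  df <- validate_ortholog_map(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a ChIP-Seq binding-score table
#'
#' One dataset's gene-level binding scores (regulatory-potential style:
#' higher score means stronger binding evidence near the gene), with the
#' species and replicate-group metadata needed for consensus panel building.
#' Datasets sharing a replicate group are averaged before target selection.
#'
#' @param dataset_id dataset identifier.
#' @param species species label, e.g. \code{"human"} or \code{"mouse"}.
#' @param replicate_group replicate-group identifier.
#' @param genes gene symbols (unique after canonicalization).
#' @param scores finite numeric binding scores, one per gene.
#' @return object of class \code{binding_score_table}.
#' @export
binding_score_table <- function(dataset_id, species, replicate_group,
                                genes, scores) {
  genes <- canonicalize_symbols(genes)
  scores <- as.numeric(scores)
  if (length(genes) != length(scores)) {
    stop("genes and scores differ in length for dataset '", dataset_id, "'",
         call. = FALSE)
  }
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    stop("duplicate gene symbol(s) in binding table '", dataset_id, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(scores))) {
    stop("non-finite binding score(s) in dataset '", dataset_id, "'",
         call. = FALSE)
  }
  structure(list(dataset_id = as.character(dataset_id),
                 species = tolower(trimws(species)),
                 replicate_group = as.character(replicate_group),
                 entries = data.frame(gene = genes, score = scores,
                                      stringsAsFactors = FALSE)),
            class = "binding_score_table")
}

#' @export
print.binding_score_table <- function(x, ...) {
  cat(sprintf("binding_score_table '%s' (%s, group '%s'): %d genes\n",
              x$dataset_id, x$species, x$replicate_group, nrow(x$entries)))
  invisible(x)
}

#' Read one binding-score table (gene, score TSV)
#'
#' @param path path to a two-column TSV with header \code{gene}, \code{score}.
#' @param dataset_id dataset identifier.
#' @param species species label.
#' @param replicate_group replicate group identifier.
#' @return a \code{binding_score_table}.
#' @export
read_binding_table <- function(path, dataset_id, species, replicate_group) {
  if (!file.exists(path)) {
    stop("binding score table for dataset '", dataset_id,
         "' not found: ", path, call. = FALSE)
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (!all(c("gene", "score") %in% names(df))) {
    stop("binding table needs columns 'gene' and 'score': ", path,
         call. = FALSE)
  }
  binding_score_table(dataset_id, species, replicate_group,
                      df$gene, df$score)
}

#' Write one binding-score table
#' @param tbl a \code{binding_score_table}.
#' @param path output path.
#' @export
write_binding_table <- function(tbl, path) {
  stopifnot(inherits(tbl, "binding_score_table"))
  out <- data.frame(gene = tbl$entries$gene,
                    score = fmt17(tbl$entries$score),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a binding-score manifest and all referenced tables
#'
#' The manifest is a TSV with columns \code{dataset_id}, \code{species},
#' \code{replicate_group}, \code{path}; relative paths are resolved against
#' the manifest's directory.
#'
#' @param path path to the manifest.
#' @return list of \code{binding_score_table} objects, in manifest order.
#' @export
read_binding_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path,
                               call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "",
                          stringsAsFactors = FALSE)
  need <- c("dataset_id", "species", "replicate_group", "path")
  if (!all(need %in% names(df))) {
    stop("manifest needs columns ", paste(need, collapse = ", "), ": ",
         path, call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  lapply(seq_len(nrow(df)), function(i) {
    p <- df$path[i]
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    read_binding_table(p, df$dataset_id[i], df$species[i],
                       df$replicate_group[i])
  })
}

#' Write binding-score tables plus a manifest describing them
#'
#' @param tables list of \code{binding_score_table} objects.
#' @param dir output directory (created if absent).
#' @param manifest manifest file name within \code{dir}.
#' @return path to the manifest, invisibly.
#' @export
write_binding_manifest <- function(tables, dir, manifest = "manifest.tsv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(tables, function(tbl) {
    fn <- paste0("binding_", tbl$dataset_id, ".tsv")
    write_binding_table(tbl, file.path(dir, fn))
    data.frame(dataset_id = tbl$dataset_id, species = tbl$species,
               replicate_group = tbl$replicate_group, path = fn,
               stringsAsFactors = FALSE)
  })
  mdf <- if (length(rows) == 0) {
    data.frame(dataset_id = character(), species = character(),
               replicate_group = character(), path = character())
  } else {
    do.call(rbind, rows)
  }
  mp <- file.path(dir, manifest)
  utils::write.table(mdf, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mp)
}
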