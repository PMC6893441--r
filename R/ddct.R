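#' Read a qPCR Ct table
#'
#' Tab-separated columns \code{sample_id}, \code{condition}, \code{gene},
#' \code{ct} (threshold cycles, finite and positive).
#'
#' @param path path to the file.
#' @return validated data frame.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("Ct table file not found: ", path,
                               call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "gene", "ct")
  if (!all(need %in% names(df))) {
    stop("Ct table needs columns ", paste(need, collapse = ", "), ": ",
         path, call. = FALSE)
  }
  validate_ct_table(df[, need])
}

#' Validate a Ct table data frame
#' @param df data frame with columns \code{sample_id}, \code{condition},
#'   \code{gene}, \code{ct}.
#' @return the validated data frame (gene symbols canonicalized).
#' @export
validate_ct_table <- function(df) {
  df$gene <- canonicalize_symbols(df$gene)
  df$condition <- trimws(as.character(df$condition))
  df$ct <- as.numeric(df$ct)
  if (any(!is.finite(df$ct)) || any(df$ct <= 0)) {
    stop("Ct values must be finite and positive", call. = FALSE)
  }
  df
}

#' Relative quantification by the delta-delta-Ct method
#'
#' Classic two-step convention: replicate Ct values are averaged (mean Ct)
#' within each (condition, gene) cell before differencing; then
#' delta-Ct = Ct(target) - Ct(housekeeping) per condition,
#' delta-delta-Ct = delta-Ct(treated) - delta-Ct(reference), and
#' fold change = 2^(-delta-delta-Ct), assuming perfect doubling per cycle.
#'
#' @param table Ct data frame (\code{sample_id}, \code{condition},
#'   \code{gene}, \code{ct}).
#' @param target target gene symbol.
#' @param treated treated condition label.
#' @param reference reference condition label (e.g. vehicle control).
#' @param housekeeping housekeeping gene symbol (default \code{"HPRT1"}).
#' @return list with \code{fold}, \code{ddct}, \code{dct_treated} and
#'   \code{dct_reference}.
#' @export
ddct_fold_change <- function(table, target, treated, reference,
                             housekeeping = "HPRT1") {
  table <- validate_ct_table(table)
  target <- canonicalize_symbols(target)
  housekeeping <- canonicalize_symbols(housekeeping)

  mean_ct <- function(condition, gene) {
    v <- table$ct[table$condition == condition & table$gene == gene]
    if (length(v) == 0) {
      stop("no Ct value for condition '", condition, "', gene '", gene,
           "'", call. = FALSE)
    }
    mean(v)
  }
  dct_treated <- mean_ct(treated, target) - mean_ct(treated, housekeeping)
  dct_reference <- mean_ct(reference, target) -
    mean_ct(reference, housekeeping)
  ddct <- dct_treated - dct_reference
  list(fold = 2^(-ddct), ddct = ddct,
       dct_treated = dct_treated, dct_reference = dct_reference)
}
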