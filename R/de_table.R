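#' Read a differential-expression table
#'
#' @param path TSV with header `gene_id  log2fc  p_value`. `log2fc` is the
#'   base-2 log of the mutant/wild-type expression ratio.
#' @return data frame with columns `gene_id`, `log2fc`, `p_value`.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("DE table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_de_table(df)
}

validate_de_table <- function(df) {
  required <- c("gene_id", "log2fc", "p_value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("DE table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$gene_id <- as.character(df$gene_id)
  df$log2fc <- as.numeric(df$log2fc)
  df$p_value <- as.numeric(df$p_value)
  if (nrow(df) > 0L) {
    if (any(!is.finite(df$log2fc))) stop("non-finite log2fc in DE table")
    if (any(is.na(df$p_value) | df$p_value < 0 | df$p_value > 1)) {
      stop("p_value outside [0, 1] in DE table")
    }
    if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in DE table")
  }
  df[, required]
}

#' Select deregulated genes by fold-change and significance thresholds
#'
#' The study's working definition of a deregulated gene: absolute log2 fold
#' change at least `min_abs_log2fc` and p-value at most `max_p`. The default
#' `min_abs_log2fc = 0.8` corresponds to a linear fold change of
#' 2^0.8 = 1.74.
#'
#' @param de_table data frame with `gene_id`, `log2fc`, `p_value`.
#' @param min_abs_log2fc minimum |log2FC| (log2 units), > 0.
#' @param max_p maximum p-value (inclusive boundary).
#' @return a `signed_de_set`: data frame with columns `gene_id` and `sign`
#'   (+1 up, -1 down), with attributes `n_up`, `n_down` and `thresholds`.
#' @export
select_deregulated <- function(de_table, min_abs_log2fc = 0.8, max_p = 0.05) {
  de_table <- validate_de_table(de_table)
  if (!is.numeric(min_abs_log2fc) || min_abs_log2fc <= 0) {
    stop("min_abs_log2fc must be positive")
  }
  if (!is.numeric(max_p) || max_p < 0 || max_p > 1) {
    stop("max_p must lie in [0, 1]")
  }
  keep <- abs(de_table$log2fc) >= min_abs_log2fc & de_table$p_value <= max_p
  members <- de_table[keep, , drop = FALSE]
  out <- data.frame(gene_id = members$gene_id,
                    sign = ifelse(members$log2fc > 0, 1L, -1L),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_up") <- sum(out$sign == 1L)
  attr(out, "n_down") <- sum(out$sign == -1L)
  attr(out, "thresholds") <- c(min_abs_log2fc = min_abs_log2fc, max_p = max_p)
  class(out) <- c("signed_de_set", "data.frame")
  out
}

#' @export
print.signed_de_set <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf(
    "signed_de_set: %d genes (%d up, %d down); |log2FC| >= %.3g, p <= %.3g\n",
    nrow(x), attr(x, "n_up"), attr(x, "n_down"),
    th[["min_abs_log2fc"]], th[["max_p"]]))
  invisible(x)
}

#' Construct the matched near-zero fold-change control gene set
#'
#' Picks `target_size` genes with the smallest |log2FC|, alternating between
#' the positive-fold and negative-fold pools so the two sign counts differ by
#' at most one — "control" genes with fold changes symmetrically distributed
#' about zero, the null cohort of the adjacency chi-square test. The study
#' used 1078 such genes against its 1073 most deregulated genes.
#'
#' @param de_table data frame with `gene_id`, `log2fc`, `p_value`.
#' @param target_size number of control genes wanted.
#' @param excluded_ids gene ids excluded from the pool (typically the
#'   deregulated set).
#' @param mean_tol warn if |mean log2FC| of the chosen set exceeds this
#'   (log2 units).
#' @return character vector of control gene ids (genomically unordered;
#'   deterministic: |log2FC| ties broken by gene_id).
#' @export
build_control_set <- function(de_table, target_size,
                              excluded_ids = character(0), mean_tol = 0.05) {
  de_table <- validate_de_table(de_table)
  stopifnot(is.numeric(target_size), length(target_size) == 1L, target_size >= 1)
  pool <- de_table[!de_table$gene_id %in% excluded_ids, , drop = FALSE]
  # zero-fold genes grouped with the positive pool for determinism
  pos <- pool[pool$log2fc >= 0, , drop = FALSE]
  neg <- pool[pool$log2fc < 0, , drop = FALSE]
  pos <- pos[order(abs(pos$log2fc), pos$gene_id), , drop = FALSE]
  neg <- neg[order(abs(neg$log2fc), neg$gene_id), , drop = FALSE]
  n_pos <- ceiling(target_size / 2)
  n_neg <- floor(target_size / 2)
  if (nrow(pos) < n_pos || nrow(neg) < n_neg) {
    stop(sprintf(
      "insufficient control candidates: need %d positive (have %d) and %d negative (have %d)",
      n_pos, nrow(pos), n_neg, nrow(neg)))
  }
  chosen <- rbind(pos[seq_len(n_pos), ], neg[seq_len(n_neg), ])
  m <- mean(chosen$log2fc)
  if (abs(m) > mean_tol) {
    warning(sprintf("control set mean log2FC = %.4f exceeds tolerance %.3g", m, mean_tol))
  }
  # interleave positive/negative picks so truncation keeps balance
  idx <- order(c(seq_len(n_pos) * 2 - 1, seq_len(n_neg) * 2))
  chosen$gene_id[idx]
}
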