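#' Build a directional gene list
#'
#' A directional gene list records, for one external study (or one cluster of
#' one study), which genes were reported as changed and in which direction.
#' It is the reference side of the cross-study concordance meta-analysis.
#'
#' @param gene_ids character vector of member gene ids.
#' @param signs expected direction per gene: +1, -1, or `NA` (unsigned).
#' @param study_id study label.
#' @param cluster_label optional cluster label within the study.
#' @return a `directional_gene_list`.
#' @export
directional_gene_list <- function(gene_ids, signs, study_id,
                                  cluster_label = NA_character_) {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) == 0L) stop("directional gene list must be non-empty")
  if (length(signs) == 1L) signs <- rep(signs, length(gene_ids))
  stopifnot(length(signs) == length(gene_ids))
  if (anyDuplicated(gene_ids)) stop("duplicate gene_id in directional list")
  ok <- is.na(signs) | signs %in% c(-1, 1)
  if (!all(ok)) stop("signs must be +1, -1 or NA (unsigned)")
  structure(list(study_id = as.character(study_id),
                 cluster_label = as.character(cluster_label),
                 members = stats::setNames(as.integer(signs), gene_ids)),
            class = "directional_gene_list")
}

#' Read directional gene lists from TSV
#'
#' @param path TSV with header `gene_id  sign  study_id  cluster_label`
#'   (`sign` may be empty/NA for unsigned members).
#' @return list of `directional_gene_list`, one per (study_id, cluster_label).
#' @export
read_directional_lists <- function(path) {
  if (!file.exists(path)) stop("directional list file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "sign", "study_id") %in% names(df)))
  if (!"cluster_label" %in% names(df)) df$cluster_label <- NA_character_
  key <- paste(df$study_id, df$cluster_label, sep = "\r")
  lapply(split(df, key), function(d) {
    directional_gene_list(d$gene_id, d$sign, d$study_id[1L], d$cluster_label[1L])
  })
}

concordance_result <- function(n_reference, n_query_up, n_query_down,
                               n_strict = NA_integer_) {
  overall <- 100 * (n_query_up + n_query_down) / n_reference
  strict <- if (is.na(n_strict)) NA_real_ else 100 * n_strict / n_reference
  structure(list(
    n_reference = n_reference,
    n_query_up = n_query_up, n_query_down = n_query_down,
    overall_pct = overall, overall_pct_display = round(overall),
    n_strict = n_strict, strict_pct = strict,
    strict_pct_display = if (is.na(strict)) NA_real_ else round(strict)),
    class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance: %d/%d query-significant (%d up, %d down) = %.1f%% overall",
              x$n_query_up + x$n_query_down, x$n_reference,
              x$n_query_up, x$n_query_down, x$overall_pct))
  if (!is.na(x$n_strict)) {
    cat(sprintf("; %d strict = %.1f%%", x$n_strict, x$strict_pct))
  }
  cat("\n")
  invisible(x)
}

#' Overall concordance of a reference gene list with a query DE table
#'
#' Counts how many reference-list genes are significantly deregulated in the
#' query dataset in either direction. Reference genes absent from the query
#' remain in the denominator (the study's percentages are over the full
#' published list size). The default filter is p <= 0.05 with any nonzero
#' fold change.
#'
#' @param reference a [directional_gene_list()].
#' @param query data frame with `gene_id`, `log2fc`, `p_value`.
#' @param min_abs_log2fc minimum |log2FC| for query significance (default 0:
#'   any nonzero fold).
#' @param max_p maximum query p-value.
#' @param drop_unmeasured if `TRUE`, reference genes absent from the query
#'   are removed from the denominator.
#' @return a `concordance_result`.
#' @export
overall_concordance <- function(reference, query, min_abs_log2fc = 0,
                                max_p = 0.05, drop_unmeasured = FALSE) {
  stopifnot(inherits(reference, "directional_gene_list"))
  query <- validate_de_table(query)
  ids <- names(reference$members)
  n_ref <- length(ids)
  if (drop_unmeasured) n_ref <- sum(ids %in% query$gene_id)
  if (n_ref == 0L) stop("empty reference after removing unmeasured genes")
  q <- query[query$gene_id %in% ids, , drop = FALSE]
  sig <- q$p_value <= max_p & abs(q$log2fc) >= min_abs_log2fc & q$log2fc != 0
  concordance_result(n_ref,
                     n_query_up = sum(sig & q$log2fc > 0),
                     n_query_down = sum(sig & q$log2fc < 0))
}

#' Strict (direction-matching) concordance with a signed query set
#'
#' A reference gene is strictly concordant when it is a member of the query's
#' signed deregulated set with the same sign the reference expects.
#'
#' @param reference a [directional_gene_list()] with signed members.
#' @param query_signed a `signed_de_set` (or any data frame with `gene_id`,
#'   `sign`).
#' @return a `concordance_result` with strict fields populated.
#' @export
strict_concordance <- function(reference, query_signed) {
  stopifnot(inherits(reference, "directional_gene_list"))
  if (anyNA(reference$members)) {
    stop("reference contains unsigned members: use overall_concordance()")
  }
  stopifnot(all(c("gene_id", "sign") %in% names(query_signed)))
  qsign <- stats::setNames(query_signed$sign, query_signed$gene_id)
  ids <- names(reference$members)
  hit <- qsign[ids]
  concordance_result(
    n_reference = length(ids),
    n_query_up = sum(hit == 1L, na.rm = TRUE),
    n_query_down = sum(hit == -1L, na.rm = TRUE),
    n_strict = sum(!is.na(hit) & hit == reference$members))
}

#' Concordance table over several directional gene lists
#'
#' One row per reference list, ordered by (study_id, cluster_label). Strict
#' concordance is computed for fully signed lists from the query genes
#' passing the same significance filter.
#'
#' @param lists list of [directional_gene_list()].
#' @param query data frame with `gene_id`, `log2fc`, `p_value`.
#' @param min_abs_log2fc,max_p query significance filter (see
#'   [overall_concordance()]).
#' @return data frame with one row per list: `study_id`, `cluster_label`,
#'   `n_reference`, `n_query_up`, `n_query_down`, `overall_pct`,
#'   `overall_pct_display`, `n_strict`, `strict_pct`.
#' @export
concordance_matrix <- function(lists, query, min_abs_log2fc = 0, max_p = 0.05) {
  stopifnot(length(lists) >= 1L)
  query <- validate_de_table(query)
  ord <- order(vapply(lists, `[[`, "", "study_id"),
               vapply(lists, `[[`, "", "cluster_label"))
  lists <- lists[ord]
  sig <- query$p_value <= max_p & abs(query$log2fc) >= min_abs_log2fc &
    query$log2fc != 0
  query_signed <- data.frame(
    gene_id = query$gene_id[sig],
    sign = ifelse(query$log2fc[sig] > 0, 1L, -1L),
    stringsAsFactors = FALSE)
  rows <- lapply(lists, function(ref) {
    ov <- overall_concordance(ref, query, min_abs_log2fc, max_p)
    strict <- if (!anyNA(ref$members)) {
      strict_concordance(ref, query_signed)$n_strict
    } else {
      NA_integer_
    }
    data.frame(study_id = ref$study_id, cluster_label = ref$cluster_label,
               n_reference = ov$n_reference,
               n_query_up = ov$n_query_up, n_query_down = ov$n_query_down,
               overall_pct = ov$overall_pct,
               overall_pct_display = ov$overall_pct_display,
               n_strict = strict,
               strict_pct = if (is.na(strict)) NA_real_ else 100 * strict / ov$n_reference,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
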