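#' Build a chromosome-ordered gene catalogue
#'
#' A gene catalogue is the positional substrate of the adjacency analysis: an
#' ordered, strand-aware table of gene records, sorted within each chromosome
#' by (start, end, gene_id). "Immediately adjacent" genes are genes at
#' consecutive ranks in this ordering, with no other annotated gene between
#' them.
#'
#' @param genes data frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand` and optionally `family_id` (paralog/duplicate grouping).
#'   Coordinates are 1-based inclusive; strand is `"+"` or `"-"` (the Unicode
#'   minus sign is accepted and normalised).
#' @return A `gene_catalogue`: the sorted data frame with an additional
#'   integer `rank` column (1-based rank within chromosome).
#' @examples
#' gc <- gene_catalogue(data.frame(
#'   gene_id = c("g2", "g1"), chromosome = "chr1",
#'   start = c(500, 100), end = c(900, 400), strand = c("-", "+")))
#' gc$gene_id  # ordered by start
#' @export
gene_catalogue <- function(genes) {
  required <- c("gene_id", "chromosome", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0L) {
    stop("annotation is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  genes$gene_id <- as.character(genes$gene_id)
  genes$chromosome <- as.character(genes$chromosome)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$strand <- normalise_strand(genes$strand)
  if (!"family_id" %in% names(genes)) {
    genes$family_id <- rep(NA_character_, nrow(genes))
  }
  genes$family_id <- as.character(genes$family_id)
  genes <- genes[, c(required, "family_id")]

  if (nrow(genes) > 0L) {
    if (anyNA(genes$start) || anyNA(genes$end)) {
      stop("non-integer start/end coordinate in annotation")
    }
    bad <- which(genes$start > genes$end)
    if (length(bad) > 0L) {
      stop("start > end for gene(s): ",
           paste(genes$gene_id[bad], collapse = ", "))
    }
    dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
    if (length(dup) > 0L) {
      stop("duplicate gene_id(s) in annotation: ", paste(dup, collapse = ", "))
    }
    ord <- order(genes$chromosome, genes$start, genes$end, genes$gene_id,
                 method = "radix")
    genes <- genes[ord, , drop = FALSE]
    genes$rank <- stats::ave(seq_len(nrow(genes)), genes$chromosome,
                             FUN = seq_along)
  } else {
    genes$rank <- integer(0)
  }
  rownames(genes) <- NULL
  class(genes) <- c("gene_catalogue", "data.frame")
  genes
}

normalise_strand <- function(strand) {
  strand <- as.character(strand)
  strand[strand == "−"] <- "-"  # Unicode minus
  bad <- unique(strand[!strand %in% c("+", "-")])
  if (length(bad) > 0L) {
    stop("unknown strand symbol(s): ", paste(bad, collapse = ", "))
  }
  strand
}

#' @export
print.gene_catalogue <- function(x, ...) {
  cat(sprintf("gene_catalogue: %d genes on %d chromosome(s)\n",
              nrow(x), length(unique(x$chromosome))))
  if (nrow(x) > 0L) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Read a genome gene annotation
#'
#' Ingests gene records from GFF3, BED, or a plain TSV and returns a
#' [gene_catalogue()]. For GFF3 only records of feature type `gene` are used
#' (transcripts/exons are ignored; adjacency is defined on genes). BED input
#' (0-based half-open) is converted to 1-based inclusive coordinates.
#'
#' @param path input file path.
#' @param format one of `"gff3"`, `"bed"`, `"tsv"`. The TSV format has a
#'   header line `gene_id  chromosome  start  end  strand` with an optional
#'   `family_id` column.
#' @return a `gene_catalogue`.
#' @export
read_annotation <- function(path, format = c("tsv", "gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  switch(format,
    tsv = read_annotation_tsv(path),
    gff3 = read_annotation_gff3(path),
    bed = read_annotation_bed(path)
  )
}

read_annotation_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(gene_catalogue(data.frame(
      gene_id = character(0), chromosome = character(0),
      start = integer(0), end = integer(0), strand = character(0))))
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  required <- c("gene_id", "chromosome", "start", "end", "strand")
  if (!all(required %in% header)) {
    stop("TSV annotation header must contain: ",
         paste(required, collapse = ", "))
  }
  rows <- lapply(seq_along(lines)[-1L], function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != length(header)) {
      stop(sprintf("malformed annotation row at line %d of %s (%d fields, expected %d)",
                   i, path, length(fields), length(header)))
    }
    stats::setNames(as.list(fields), header)
  })
  df <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  for (col in c("start", "end")) {
    val <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(val) & !is.na(df[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("malformed annotation row at line %d of %s (non-integer %s)",
                   bad[1L] + 1L, path, col))
    }
    df[[col]] <- val
  }
  gene_catalogue(df)
}

read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df <- df[!is.na(df$type) & df$type == "gene", , drop = FALSE]
  if (nrow(df) == 0L) {
    return(gene_catalogue(data.frame(
      gene_id = character(0), chromosome = character(0),
      start = integer(0), end = integer(0), strand = character(0))))
  }
  ids <- if ("ID" %in% names(df)) df$ID else df$Name
  gene_catalogue(data.frame(
    gene_id = as.character(ids),
    chromosome = as.character(df$seqnames),
    start = df$start, end = df$end,
    strand = as.character(df$strand),
    stringsAsFactors = FALSE))
}

read_annotation_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- as.data.frame(gr)  # GRanges is already 1-based inclusive
  if (nrow(df) == 0L) {
    return(gene_catalogue(data.frame(
      gene_id = character(0), chromosome = character(0),
      start = integer(0), end = integer(0), strand = character(0))))
  }
  gene_catalogue(data.frame(
    gene_id = as.character(df$name),
    chromosome = as.character(df$seqnames),
    start = df$start, end = df$end,
    strand = as.character(df$strand),
    stringsAsFactors = FALSE))
}

#' Write a gene catalogue as canonical TSV
#'
#' The canonical dump round-trips through [read_annotation()] with
#' `format = "tsv"`, preserving gene set, coordinates and strands exactly.
#'
#' @param catalogue a `gene_catalogue`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(catalogue, path) {
  stopifnot(inherits(catalogue, "gene_catalogue"))
  df <- as.data.frame(catalogue)
  df$rank <- NULL
  if (all(is.na(df$family_id))) df$family_id <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Immediate neighbours of a gene in the catalogue order
#'
#' @param catalogue a `gene_catalogue`.
#' @param gene_id gene identifier present in the catalogue.
#' @return list with elements `previous` and `next_` (gene ids, or `NA` at a
#'   chromosome boundary).
#' @export
immediate_neighbours <- function(catalogue, gene_id) {
  stopifnot(inherits(catalogue, "gene_catalogue"))
  i <- match(gene_id, catalogue$gene_id)
  if (is.na(i)) stop("gene_id not in catalogue: ", gene_id)
  chrom <- catalogue$chromosome[i]
  rank <- catalogue$rank[i]
  on_chrom <- catalogue[catalogue$chromosome == chrom, ]
  prev <- if (rank > 1L) on_chrom$gene_id[on_chrom$rank == rank - 1L] else NA_character_
  nxt <- if (rank < nrow(on_chrom)) on_chrom$gene_id[on_chrom$rank == rank + 1L] else NA_character_
  list(previous = prev, next_ = nxt)
}

#' Width of a genomic interval between two coordinates
#'
#' Distance between two flanking coordinates, e.g. the fine-mapping interval
#' between two marker positions.
#'
#' @param coord_a,coord_b positive integer coordinates (bp).
#' @return `abs(coord_b - coord_a)` in bp.
#' @examples
#' interval_width(7213133, 7325482)  # ~112 kbp mapping interval
#' @export
interval_width <- function(coord_a, coord_b) {
  if (!is.numeric(coord_a) || !is.numeric(coord_b) ||
      length(coord_a) != 1L || length(coord_b) != 1L ||
      is.na(coord_a) || is.na(coord_b) || coord_a <= 0 || coord_b <= 0) {
    stop("coordinates must be single positive integers")
  }
  abs(as.numeric(coord_b) - as.numeric(coord_a))
}
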