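# fixture builders shared across test files; everything generated in code

toy_catalogue <- function(n = 6, chromosome = "chr1", strand = NULL,
                          start = NULL, width = 1000, gap = 500) {
  if (is.null(start)) start <- seq(1, by = width + gap, length.out = n)
  if (is.null(strand)) strand <- rep(c("+", "-"), length.out = n)
  gene_catalogue(data.frame(
    gene_id = sprintf("g%02d", seq_len(n)),
    chromosome = chromosome,
    start = start, end = start + width - 1,
    strand = strand, stringsAsFactors = FALSE))
}

# a DE table giving the stated signs to the stated catalogue genes;
# sign 0 means not deregulated (tiny fold, large p)
de_from_signs <- function(catalogue, signs) {
  stopifnot(length(signs) == nrow(catalogue))
  data.frame(
    gene_id = catalogue$gene_id,
    log2fc = ifelse(signs == 0, 0.01, signs * 2),
    p_value = ifelse(signs == 0, 0.9, 0.001),
    stringsAsFactors = FALSE)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent brute-force oracle for set/pair detection: examine every
# consecutive index pair, build concordant edges, merge into runs
enumerate_sets_oracle <- function(catalogue, signs) {
  n <- nrow(catalogue)
  conc <- disc <- logical(max(n - 1, 0))
  for (i in seq_len(max(n - 1, 0))) {
    same_chrom <- catalogue$chromosome[i] == catalogue$chromosome[i + 1]
    if (!same_chrom) next
    if (signs[i] != 0 && signs[i] == signs[i + 1]) conc[i] <- TRUE
    if (signs[i] != 0 && signs[i + 1] != 0 && signs[i] == -signs[i + 1]) disc[i] <- TRUE
  }
  # merge consecutive concordant edges into maximal runs
  runs <- list()
  i <- 1
  while (i <= length(conc)) {
    if (conc[i]) {
      j <- i
      while (j < length(conc) && conc[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- i:(j + 1)  # member indices
      i <- j + 1
    }
    i <- i + 1
  }
  list(n_sets = length(runs),
       members = lapply(runs, function(idx) catalogue$gene_id[idx]),
       n_discordant = sum(disc))
}
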