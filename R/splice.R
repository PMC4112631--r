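#' Build a spliced gene model for splice-mutation consequence prediction
#'
#' Holds the exon/intron structure and sequence of a single protein-coding
#' gene, the substrate for predicting what a splice-donor mutation does to
#' the transcript and protein (intron retention, premature stop,
#' C-terminal truncation).
#'
#' @param gene_id identifier.
#' @param exons character vector of exon sequences (A/C/G/T), 5' to 3'.
#' @param introns character vector of intron sequences, length
#'   `length(exons) - 1`.
#' @param cds_offset number of mature-mRNA nucleotides before the CDS start
#'   (5' UTR length); the CDS must begin with ATG.
#' @param protein_length annotated protein length in residues.
#' @return a `splice_gene_model`.
#' @export
splice_gene_model <- function(gene_id, exons, introns, cds_offset,
                              protein_length) {
  exons <- toupper(as.character(exons))
  introns <- toupper(as.character(introns))
  if (length(exons) < 1L) stop("at least one exon required")
  if (length(introns) != length(exons) - 1L) {
    stop("need exactly one fewer intron than exons")
  }
  seqs <- c(exons, introns)
  if (any(grepl("[^ACGT]", seqs[nzchar(seqs)]))) {
    stop("sequences must be over the alphabet {A, C, G, T}")
  }
  stopifnot(is.numeric(cds_offset), cds_offset >= 0,
            is.numeric(protein_length), protein_length >= 1)
  mature <- paste(exons, collapse = "")
  if (substr(mature, cds_offset + 1L, cds_offset + 3L) != "ATG") {
    stop("CDS must begin with ATG at the stated offset")
  }
  # if the mature CDS contains an in-frame stop, it must terminate the
  # annotated protein exactly
  pep <- translate_nt(substr(mature, cds_offset + 1L, nchar(mature)))
  stop_at <- regexpr("*", pep, fixed = TRUE)
  if (stop_at > 0L && stop_at != protein_length + 1L) {
    stop(sprintf("mature CDS stops at residue %d but annotated length is %d",
                 stop_at - 1L, protein_length))
  }
  structure(list(gene_id = as.character(gene_id), exons = exons,
                 introns = introns, cds_offset = as.integer(cds_offset),
                 protein_length = as.integer(protein_length),
                 mature_length = nchar(mature)),
            class = "splice_gene_model")
}

#' @export
print.splice_gene_model <- function(x, ...) {
  cat(sprintf(
    "splice_gene_model %s: %d exons (mature %d nt), %d introns, CDS offset %d, protein %d aa\n",
    x$gene_id, length(x$exons), x$mature_length, length(x$introns),
    x$cds_offset, x$protein_length))
  invisible(x)
}

translate_nt <- function(seq) {
  n <- 3L * (nchar(seq) %/% 3L)
  if (n == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(seq, 1L, n)),
                                     no.init.codon = TRUE))
}

apply_intron_variant <- function(intron, variant) {
  if (is.null(variant)) return(intron)
  pos <- variant$pos
  if (is.null(pos) || pos < 1L || pos > nchar(intron)) {
    stop("variant position outside intron (length ", nchar(intron), ")")
  }
  if (!is.null(variant$ref)) {
    have <- substr(intron, pos, pos)
    if (have != toupper(variant$ref)) {
      stop(sprintf("variant ref mismatch at intron position %d: have %s, stated %s",
                   pos, have, variant$ref))
    }
  }
  substr(intron, pos, pos) <- toupper(variant$alt)
  intron
}

#' Check the splice-donor consensus of an intron
#'
#' The invariant donor consensus is the GT dinucleotide at intron positions
#' 1-2. An optional single-nucleotide substitution (e.g. the G-to-A donor
#' mutation at intron nucleotide 1) is applied before checking.
#'
#' @param model a [splice_gene_model()].
#' @param intron_index which intron (1-based).
#' @param variant optional list `(pos, alt, ref)` describing a substitution
#'   at a 1-based intron position.
#' @return list `diagnosis` (`"consensus intact"` or
#'   `"consensus abolished"`), `donor_dinucleotide`.
#' @export
validate_donor_site <- function(model, intron_index, variant = NULL) {
  stopifnot(inherits(model, "splice_gene_model"))
  check_intron_index(model, intron_index)
  intron <- apply_intron_variant(model$introns[intron_index], variant)
  dinuc <- substr(intron, 1L, 2L)
  list(diagnosis = if (dinuc == "GT") "consensus intact" else "consensus abolished",
       donor_dinucleotide = dinuc)
}

check_intron_index <- function(model, intron_index) {
  if (!is.numeric(intron_index) || length(intron_index) != 1L ||
      intron_index < 1L || intron_index > length(model$introns)) {
    stop("intron_index must be in 1..", length(model$introns))
  }
  invisible(intron_index)
}

#' Transcript with one intron retained
#'
#' Models the failure to splice one intron: the aberrant mRNA is the mature
#' mRNA with that intron left in place, so its length is the mature length
#' plus the intron length (2212 + 300 = 2512 nt in the study's gene).
#'
#' @param model a [splice_gene_model()].
#' @param intron_index which intron is retained (1-based).
#' @param variant optional substitution applied to the retained intron (see
#'   [validate_donor_site()]).
#' @return list `sequence`, `length`.
#' @export
retained_intron_transcript <- function(model, intron_index, variant = NULL) {
  stopifnot(inherits(model, "splice_gene_model"))
  check_intron_index(model, intron_index)
  intron <- apply_intron_variant(model$introns[intron_index], variant)
  m <- length(model$exons)
  seq <- paste0(
    paste(model$exons[seq_len(intron_index)], collapse = ""),
    intron,
    paste(model$exons[seq(intron_index + 1L, m)], collapse = ""))
  list(sequence = seq, length = nchar(seq))
}

#' Predict the protein consequence of intron retention
#'
#' Translates the intron-retained transcript from the CDS start until the
#' first stop codon and reports: how many residues of the annotated protein
#' are retained (residues encoded entirely by exonic sequence upstream of
#' the retained intron), the novel peptide read from the intron, the stop
#' codon position within the intron (1-based nucleotide of the stop codon's
#' first base), and the residues lost from the C-terminus.
#'
#' @param model a [splice_gene_model()].
#' @param intron_index which intron is retained (1-based).
#' @param variant optional substitution applied to the retained intron (the
#'   donor mutation itself changes the first intron codon, so the predicted
#'   novel peptide depends on it).
#' @return a `truncation_prediction`: list `transcript_length`,
#'   `novel_peptide`, `stop_position_intron`, `residues_retained`,
#'   `residues_lost`.
#' @export
predict_truncation <- function(model, intron_index, variant = NULL) {
  stopifnot(inherits(model, "splice_gene_model"))
  check_intron_index(model, intron_index)
  retained <- retained_intron_transcript(model, intron_index, variant)
  exonic_upstream <- sum(nchar(model$exons[seq_len(intron_index)]))
  if (exonic_upstream <= model$cds_offset) {
    stop("retained intron lies upstream of the CDS start: no coding consequence")
  }
  cds_seq <- substr(retained$sequence, model$cds_offset + 1L, retained$length)
  pep <- translate_nt(cds_seq)
  k <- regexpr("*", pep, fixed = TRUE)
  if (k < 0L) {
    stop("no in-frame stop codon before transcript end (predicted read-through)")
  }
  exonic_cds <- exonic_upstream - model$cds_offset
  residues_retained <- exonic_cds %/% 3L
  if (k - 1L < residues_retained) {
    stop("in-frame stop upstream of the retained intron: inconsistent model")
  }
  novel <- substr(pep, residues_retained + 1L, k - 1L)
  stop_position_intron <- (model$cds_offset + 3L * (k - 1L) + 1L) - exonic_upstream
  structure(list(
    transcript_length = retained$length,
    novel_peptide = novel,
    stop_position_intron = as.integer(stop_position_intron),
    residues_retained = as.integer(residues_retained),
    residues_lost = model$protein_length - as.integer(residues_retained)),
    class = "truncation_prediction")
}

#' Consequence of splicing at an alternative downstream donor
#'
#' Models the hypothesis that a cryptic donor inside the intron is used
#' instead of the annotated one: the first `offset` intron nucleotides stay
#' in the mature mRNA and the remainder of the intron is spliced out. When
#' the offset preserves the reading frame and encodes no stop, the product
#' is the full-length protein with `offset/3` extra residues (a donor 21
#' nucleotides downstream adds 7 residues).
#'
#' @param model a [splice_gene_model()].
#' @param intron_index which intron (1-based).
#' @param offset intron nucleotides retained before the alternative donor
#'   (default 21).
#' @return list `transcript_length`, `protein_length`, `extra_residues`,
#'   `inserted_peptide`.
#' @export
alternative_donor_splice <- function(model, intron_index, offset = 21L) {
  stopifnot(inherits(model, "splice_gene_model"))
  check_intron_index(model, intron_index)
  intron <- model$introns[intron_index]
  if (offset < 1L || offset > nchar(intron)) {
    stop("offset must lie within the intron (length ", nchar(intron), ")")
  }
  m <- length(model$exons)
  seq <- paste0(paste(model$exons[seq_len(intron_index)], collapse = ""),
                substr(intron, 1L, offset),
                paste(model$exons[seq(intron_index + 1L, m)], collapse = ""))
  pep <- translate_nt(substr(seq, model$cds_offset + 1L, nchar(seq)))
  k <- regexpr("*", pep, fixed = TRUE)
  protein_length <- if (k > 0L) as.integer(k) - 1L else nchar(pep)
  exonic_cds <- sum(nchar(model$exons[seq_len(intron_index)])) - model$cds_offset
  residues_before <- exonic_cds %/% 3L
  inserted <- substr(pep, residues_before + 1L,
                     residues_before + offset %/% 3L)
  list(transcript_length = nchar(seq),
       protein_length = protein_length,
       extra_residues = protein_length - model$protein_length,
       inserted_peptide = inserted)
}

#' @export
print.truncation_prediction <- function(x, ...) {
  cat(sprintf(
    "intron retention: %d nt transcript; %d residues retained + novel peptide %s, stop at intron nt %d; %d C-terminal residues lost\n",
    x$transcript_length, x$residues_retained,
    if (nzchar(x$novel_peptide)) x$novel_peptide else "(none)",
    x$stop_position_intron, x$residues_lost))
  invisible(x)
}
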