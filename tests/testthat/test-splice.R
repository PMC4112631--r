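# hand-coded standard genetic code, the independent translation oracle
GENETIC_CODE_ORACLE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

translate_oracle <- function(seq) {
  n <- 3 * (nchar(seq) %/% 3)
  codons <- substring(seq, seq(1, n, 3), seq(3, n, 3))
  paste(GENETIC_CODE_ORACLE[codons], collapse = "")
}

# toy 2-exon gene: CDS = ATG AAA GAG | intron | GGC TAA; intron retention
# appends intron-encoded residues after residue 3 (E)
toy_model <- function(intron = "GTCCATAAAG") {
  splice_gene_model(
    "toy", exons = c("ATGAAAGAG", "GGCTAA"), introns = intron,
    cds_offset = 0, protein_length = 4)
}

test_that("gene model invariants are enforced", {
  expect_error(splice_gene_model("x", c("CCGAAA", "TTT"), "GTAG", 0, 2),
               "ATG")
  expect_error(splice_gene_model("x", c("ATGNNN", "TTT"), "GTAG", 0, 2),
               "alphabet")
  expect_error(splice_gene_model("x", c("ATGAAA", "TTT"), c("GTAG", "GTAG"), 0, 2),
               "fewer intron")
  # mature CDS stop must match the annotated protein length
  expect_error(splice_gene_model("x", c("ATGTAA", "TTTTAA"), "GTAG", 0, 3),
               "annotated length")
})

test_that("donor-site consensus check follows the GT rule", {
  m <- toy_model()
  expect_equal(validate_donor_site(m, 1)$diagnosis, "consensus intact")
  mut <- validate_donor_site(m, 1, variant = list(pos = 1, ref = "G", alt = "A"))
  expect_equal(mut$diagnosis, "consensus abolished")
  expect_equal(mut$donor_dinucleotide, "AT")
  # a variant deeper in the intron leaves the donor intact
  deep <- validate_donor_site(m, 1, variant = list(pos = 5, alt = "G"))
  expect_equal(deep$diagnosis, "consensus intact")
  expect_error(validate_donor_site(m, 1, variant = list(pos = 99, alt = "A")),
               "outside intron")
  expect_error(validate_donor_site(m, 2), "intron_index")
})

test_that("retained-intron transcript length is mature plus intron length", {
  m <- toy_model()
  ret <- retained_intron_transcript(m, 1)
  expect_equal(ret$length, m$mature_length + nchar(m$introns[1]))
  expect_equal(ret$sequence, paste0("ATGAAAGAG", m$introns[1], "GGCTAA"))

  # degenerate zero-length intron: transcript equals the mature mRNA
  m0 <- splice_gene_model("z", c("ATGAAAGAG", "GGCTAA"), "", 0, 4)
  expect_equal(retained_intron_transcript(m0, 1)$sequence, "ATGAAAGAGGGCTAA")

  # toy 2-exon gene with 60 + 30 nt exons and a 9 nt intron
  e1 <- paste0("ATG", strrep("AAA", 19))
  e2 <- paste0(strrep("GAA", 9), "TAA")
  m99 <- splice_gene_model("t", c(e1, e2), "GTCCCCCAG", 0, 29)
  expect_equal(retained_intron_transcript(m99, 1)$length, 99)
})

test_that("truncation prediction matches hand translation of a toy fixture", {
  # intron GTCCATAAAG: in frame after residue 3, reads GTC CAT AAA -> VHK,
  # no stop inside the intron, stop from TAA spanning the downstream exon?
  # Use an intron with an explicit internal stop instead:
  m <- toy_model(intron = "GTCCATTGAG")   # GTC CAT TGA -> V H *
  pred <- predict_truncation(m, 1)
  oracle <- translate_oracle(retained_intron_transcript(m, 1)$sequence)
  stop_at <- as.integer(regexpr("*", oracle, fixed = TRUE))
  expect_equal(pred$residues_retained + nchar(pred$novel_peptide), stop_at - 1)
  expect_equal(pred$novel_peptide, "VH")
  expect_equal(pred$residues_retained, 3L)
  expect_equal(pred$residues_lost, 1L)
  expect_equal(pred$stop_position_intron, 7L)  # TGA starts at intron nt 7
  expect_equal(pred$transcript_length, 15L + 10L)

  # intron beginning with an in-frame stop: empty novel peptide, stop at nt 1
  m2 <- toy_model(intron = "TGACCCCCCG")  # non-canonical donor fixture
  pred2 <- predict_truncation(m2, 1)
  expect_equal(pred2$novel_peptide, "")
  expect_lte(pred2$stop_position_intron, 3L)

  # read-through: no in-frame stop anywhere
  m3 <- splice_gene_model("rt", c("ATGAAA", "GAAGAA"), "GTAAAAAG", 0, 4)
  expect_error(predict_truncation(m3, 1), "read-through")
})

test_that("donor mutation changes the predicted novel peptide", {
  m <- toy_model(intron = "GTCCATTGAG")
  wt <- predict_truncation(m, 1)
  mut <- predict_truncation(m, 1, variant = list(pos = 1, ref = "G", alt = "A"))
  expect_equal(wt$novel_peptide, "VH")   # GTC CAT
  expect_equal(mut$novel_peptide, "IH")  # ATC CAT
  expect_equal(mut$stop_position_intron, wt$stop_position_intron)
})

test_that("alternative downstream donor adds in-frame residues", {
  fx <- make_splice_fixture(seed = 1)
  idx <- attr(fx, "intron_index")
  alt <- alternative_donor_splice(fx, idx, offset = 21)
  expect_equal(alt$transcript_length, fx$mature_length + 21L)
  expect_equal(alt$extra_residues, 7L)       # 21 nt in frame = 7 residues
  expect_equal(alt$protein_length, fx$protein_length + 7L)
  expect_equal(nchar(alt$inserted_peptide), 7L)
  # wild-type intron leader VIIYSYQ, hand-translated
  expect_equal(alt$inserted_peptide,
               translate_oracle(substr(fx$introns[idx], 1, 21)))
  expect_error(alternative_donor_splice(fx, idx, offset = 1000), "within")
})

test_that("length conservation holds for every intron index", {
  fx <- make_splice_fixture(seed = 2)
  for (i in seq_along(fx$introns)) {
    ret <- retained_intron_transcript(fx, i)
    expect_equal(ret$length - fx$mature_length, nchar(fx$introns[i]))
  }
})

test_that("frame consistency links residues to nucleotides consumed", {
  fx <- make_splice_fixture(seed = 1)
  idx <- attr(fx, "intron_index")
  pred <- predict_truncation(fx, idx, attr(fx, "donor_variant"))
  consumed <- 3 * (pred$residues_retained + nchar(pred$novel_peptide)) + 3
  # nucleotides from CDS start to the end of the stop codon
  exonic_upstream <- sum(nchar(fx$exons[seq_len(idx)]))
  stop_end <- exonic_upstream + pred$stop_position_intron + 2
  expect_equal(consumed, stop_end - fx$cds_offset)
  expect_equal(pred$residues_retained + pred$residues_lost, fx$protein_length)
})

test_that("translation agrees with the standard genetic code on all codons", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  got <- vapply(codons, adjacoreg:::translate_nt, character(1))
  expect_equal(unname(got), unname(GENETIC_CODE_ORACLE[codons]))
})

test_that("synthetic splice fixture matches its stored expectation", {
  for (s in c(1, 2, 17)) {
    fx <- make_splice_fixture(seed = s)
    exp <- attr(fx, "expected")
    idx <- attr(fx, "intron_index")
    variant <- attr(fx, "donor_variant")
    # wild-type donor is canonical; the stored variant abolishes it
    expect_equal(validate_donor_site(fx, idx)$diagnosis, "consensus intact")
    expect_equal(validate_donor_site(fx, idx, variant)$diagnosis,
                 "consensus abolished")
    pred <- predict_truncation(fx, idx, variant)
    expect_equal(pred$transcript_length, exp$transcript_length)
    expect_equal(pred$novel_peptide, exp$novel_peptide)
    expect_equal(pred$stop_position_intron, exp$stop_position_intron)
    expect_equal(pred$residues_retained, exp$residues_retained)
    expect_equal(pred$residues_lost, exp$residues_lost)
    # independent check by hand translation of the mutant transcript
    mut_seq <- retained_intron_transcript(fx, idx, variant)$sequence
    pep <- translate_oracle(substr(mut_seq, fx$cds_offset + 1, nchar(mut_seq)))
    stop_at <- regexpr("*", pep, fixed = TRUE)
    expect_equal(substr(pep, exp$residues_retained + 1, stop_at - 1),
                 exp$novel_peptide)
  }
  expect_identical(make_splice_fixture(seed = 5)$exons,
                   make_splice_fixture(seed = 5)$exons)
})
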