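#' Simulation configuration
#'
#' All parameters of the synthetic-data generator. Defaults describe a toy
#' genome of 5 chromosomes x 1000 genes with log-normal gene lengths (mean
#' ~2.2 kb) and intergenic gaps (mean ~2 kb), mirroring a compact plant
#' genome; about 4% of genes carry scattered (non-adjacent) deregulation so
#' the deregulated cohort is dominated by singletons, as in the study's
#' ~1073 of 25673 genes; injected blocks of 2 immediately adjacent,
#' sign-concordant genes at 2 log2 units carry the positional signal.
#'
#' @param n_chromosomes number of chromosomes.
#' @param genes_per_chromosome genes per chromosome.
#' @param gene_length_meanlog,gene_length_sdlog log-normal gene length (bp).
#' @param gap_meanlog,gap_sdlog log-normal intergenic gap (bp).
#' @param strand_prob probability a gene is on the + strand.
#' @param frac_singleton_de fraction of genes given scattered singleton
#'   deregulation (the remainder are null).
#' @param null_sd standard deviation of null-gene log2FC noise.
#' @param n_injected_blocks number of injected adjacent co-regulated blocks.
#' @param block_size genes per block (>= 2).
#' @param block_effect absolute log2FC of injected genes (sign drawn per
#'   block).
#' @param block_p_scale scale of injected p-values (drawn as
#'   `block_p_scale * Beta(1, 20)`).
#' @param n_duplicate_pairs adjacent same-family duplicate pairs with
#'   correlated deregulation.
#' @param seed integer seed driving all generator randomness.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 5L,
                       genes_per_chromosome = 1000L,
                       gene_length_meanlog = log(2200) - 0.125,
                       gene_length_sdlog = 0.5,
                       gap_meanlog = log(2000) - 0.5,
                       gap_sdlog = 1.0,
                       strand_prob = 0.5,
                       frac_singleton_de = 0.04,
                       null_sd = 0.3,
                       n_injected_blocks = 10L,
                       block_size = 2L,
                       block_effect = 2.0,
                       block_p_scale = 1e-3,
                       n_duplicate_pairs = 5L,
                       seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              gene_length_meanlog = gene_length_meanlog,
              gene_length_sdlog = gene_length_sdlog,
              gap_meanlog = gap_meanlog, gap_sdlog = gap_sdlog,
              strand_prob = strand_prob,
              frac_singleton_de = frac_singleton_de,
              null_sd = null_sd,
              n_injected_blocks = as.integer(n_injected_blocks),
              block_size = as.integer(block_size),
              block_effect = block_effect,
              block_p_scale = block_p_scale,
              n_duplicate_pairs = as.integer(n_duplicate_pairs),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_chromosomes >= 0, genes_per_chromosome >= 0,
              strand_prob >= 0, strand_prob <= 1,
              frac_singleton_de >= 0, frac_singleton_de <= 1,
              null_sd >= 0, n_injected_blocks >= 0, block_size >= 2,
              block_effect >= 0, block_p_scale > 0, block_p_scale <= 1,
              n_duplicate_pairs >= 0)
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a chromosome-ordered gene catalogue
#'
#' Non-overlapping genes laid down left to right per chromosome, with
#' log-normal lengths and intergenic gaps and independent Bernoulli strands.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a [gene_catalogue()].
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n_total <- config$n_chromosomes * config$genes_per_chromosome
  if (n_total == 0L) {
    return(gene_catalogue(data.frame(
      gene_id = character(0), chromosome = character(0),
      start = integer(0), end = integer(0), strand = character(0))))
  }
  withr::with_seed(config$seed, {
    rows <- lapply(seq_len(config$n_chromosomes), function(chrom) {
      n <- config$genes_per_chromosome
      len <- pmax(1L, round(stats::rlnorm(n, config$gene_length_meanlog,
                                          config$gene_length_sdlog)))
      gap <- pmax(1L, round(stats::rlnorm(n, config$gap_meanlog,
                                          config$gap_sdlog)))
      start <- cumsum(gap) + c(0L, cumsum(len[-n]))
      data.frame(
        gene_id = sprintf("g%d_%04d", chrom, seq_len(n)),
        chromosome = sprintf("chr%d", chrom),
        start = as.integer(start),
        end = as.integer(start + len - 1L),
        strand = ifelse(stats::runif(n) < config$strand_prob, "+", "-"),
        stringsAsFactors = FALSE)
    })
    gene_catalogue(do.call(rbind, rows))
  })
}

#' Simulate a differential-expression table with injected adjacent blocks
#'
#' Null genes receive zero-centred Gaussian log2FC noise and uniform
#' p-values. Injected blocks occupy consecutive catalogue ranks within one
#' chromosome; all members of a block share the block's sign and receive
#' +/- `block_effect` plus noise and small p-values. Duplicate pairs are
#' adjacent genes sharing a `family_id` with correlated fold changes (they
#' emulate co-regulation caused by duplicated regulatory elements, the cases
#' the adjacency analysis excludes). Singleton deregulated genes are
#' scattered at non-adjacent positions.
#'
#' @param catalogue a [gene_catalogue()] (typically from
#'   [simulate_genome()]).
#' @param config a [sim_config()].
#' @return list with
#'   \describe{
#'     \item{de_table}{data frame `gene_id`, `log2fc`, `p_value`.}
#'     \item{truth}{data frame `gene_id`, `label` (one of `null`,
#'       `injected_up`, `injected_down`, `duplicate`, `singleton_up`,
#'       `singleton_down`), `block` (block index or NA).}
#'     \item{family_map}{data frame `gene_id`, `family_id` for duplicate
#'       pairs.}
#'   }
#' @export
simulate_expression <- function(catalogue, config = sim_config()) {
  stopifnot(inherits(catalogue, "gene_catalogue"), inherits(config, "sim_config"))
  n <- nrow(catalogue)
  need <- config$n_injected_blocks * config$block_size +
    2L * config$n_duplicate_pairs
  if (need > n) {
    stop(sprintf("capacity exceeded: %d genes needed for blocks/duplicates, %d available",
                 need, n))
  }
  withr::with_seed(config$seed + 1L, {
    label <- rep("null", n)
    block <- rep(NA_integer_, n)
    log2fc <- stats::rnorm(n, 0, config$null_sd)
    p_value <- stats::runif(n)

    # candidate consecutive windows entirely within one chromosome
    take_windows <- function(k, size, taken) {
      chosen <- integer(0)
      if (k == 0L) return(chosen)
      last_rank <- stats::ave(catalogue$rank, catalogue$chromosome, FUN = max)
      starts_ok <- which(catalogue$rank + size - 1L <= last_rank)
      starts_ok <- starts_ok[sample.int(length(starts_ok))]  # random order, then greedy
      for (s in starts_ok) {
        idx <- s:(s + size - 1L)
        # keep a one-gene buffer so placed features never touch
        guard <- max(1L, s - 1L):min(n, s + size)
        if (any(taken[guard])) next
        chosen <- c(chosen, s)
        taken[idx] <- TRUE
        if (length(chosen) == k) break
      }
      if (length(chosen) < k) {
        stop("could not place all injected features without overlap")
      }
      attr(chosen, "taken") <- taken
      chosen
    }

    taken <- rep(FALSE, n)
    block_starts <- take_windows(config$n_injected_blocks, config$block_size, taken)
    if (config$n_injected_blocks > 0L) taken <- attr(block_starts, "taken")
    for (b in seq_along(block_starts)) {
      idx <- block_starts[b]:(block_starts[b] + config$block_size - 1L)
      s <- sample(c(1, -1), 1L)
      log2fc[idx] <- s * config$block_effect + stats::rnorm(length(idx), 0, 0.2)
      p_value[idx] <- config$block_p_scale * stats::rbeta(length(idx), 1, 20)
      label[idx] <- if (s > 0) "injected_up" else "injected_down"
      block[idx] <- b
    }

    dup_starts <- take_windows(config$n_duplicate_pairs, 2L, taken)
    if (config$n_duplicate_pairs > 0L) taken <- attr(dup_starts, "taken")
    fam_rows <- list()
    for (d in seq_along(dup_starts)) {
      idx <- dup_starts[d]:(dup_starts[d] + 1L)
      s <- sample(c(1, -1), 1L)
      base <- s * config$block_effect
      log2fc[idx] <- base + stats::rnorm(2L, 0, 0.2)
      p_value[idx] <- config$block_p_scale * stats::rbeta(2L, 1, 20)
      label[idx] <- "duplicate"
      fam_rows[[d]] <- data.frame(gene_id = catalogue$gene_id[idx],
                                  family_id = sprintf("fam%03d", d),
                                  stringsAsFactors = FALSE)
    }

    # scattered singletons: random free positions, kept clear of injected
    # blocks and duplicate pairs but free to land next to one another, so
    # chance concordant and discordant adjacencies arise naturally
    n_singleton <- round(config$frac_singleton_de * n)
    free <- which(!taken)
    free <- free[sample.int(length(free))]
    singles <- integer(0)
    for (s in free) {
      if (length(singles) == n_singleton) break
      guard <- max(1L, s - 1L):min(n, s + 1L)
      if (any(taken[guard])) next
      singles <- c(singles, s)
    }
    if (length(singles) > 0L) {
      sgn <- sample(c(1, -1), length(singles), replace = TRUE)
      log2fc[singles] <- sgn * config$block_effect +
        stats::rnorm(length(singles), 0, 0.2)
      p_value[singles] <- config$block_p_scale *
        stats::rbeta(length(singles), 1, 20)
      label[singles] <- ifelse(sgn > 0, "singleton_up", "singleton_down")
    }

    list(
      de_table = data.frame(gene_id = catalogue$gene_id, log2fc = log2fc,
                            p_value = p_value, stringsAsFactors = FALSE),
      truth = data.frame(gene_id = catalogue$gene_id, label = label,
                         block = block, stringsAsFactors = FALSE),
      family_map = if (length(fam_rows)) do.call(rbind, fam_rows) else
        data.frame(gene_id = character(0), family_id = character(0),
                   stringsAsFactors = FALSE))
  })
}

#' Simulate segregating progeny counts
#'
#' Binomial draw of mutant vs wild-type phenotype counts, e.g. under the
#' 1 mutant : 3 wild type null of a non-complementation cross.
#'
#' @param n_progeny number of scored F1 individuals (> 0).
#' @param mutant_probability per-individual probability of the mutant
#'   phenotype (0.25 under non-complementation).
#' @param seed integer seed.
#' @return named integer vector `c(mutant, wild_type)`.
#' @export
simulate_segregation <- function(n_progeny, mutant_probability = 0.25, seed = 1) {
  if (!is.numeric(n_progeny) || n_progeny <= 0) stop("n_progeny must be > 0")
  if (mutant_probability < 0 || mutant_probability > 1) {
    stop("mutant_probability must lie in [0, 1]")
  }
  m <- withr::with_seed(seed, stats::rbinom(1L, n_progeny, mutant_probability))
  c(mutant = m, wild_type = as.integer(n_progeny) - m)
}

# codons by residue, used to engineer fixture sequences
.codon_for <- c(I = "ATT", Y = "TAT", S = "TCT", Q = "CAA", V = "GTT",
                M = "ATG", A = "GCT", L = "CTT", G = "GGT", K = "AAA",
                E = "GAA", D = "GAT", F = "TTT", P = "CCT", T = "ACT",
                N = "AAT", H = "CAT", R = "CGT", W = "TGG", C = "TGT")

#' Synthetic splice fixture mirroring a donor-site mutation scenario
#'
#' Generates an 8-exon gene with the geometry of the study's TOP6B gene:
#' a 2212 nt mature mRNA encoding a 670-residue protein (100 nt 5' UTR),
#' whose 300 nt intron 7 sits exactly after the codon of Met198. The
#' wild-type intron 7 starts with the canonical GT donor; the stored donor
#' variant (G to A at intron nucleotide 1) abolishes it, and the retained
#' mutant intron encodes the novel peptide IIIYSYQV followed by a TGA stop
#' whose first base is intron nucleotide 25. The expected
#' [predict_truncation()] outcome is computed at generation time and stored
#' in the `expected` attribute. All sequences are synthetic; only the
#' geometry mirrors the real gene. Seeds change the filler codons, never
#' the expected outcome.
#'
#' @param seed integer seed for filler sequence.
#' @return a [splice_gene_model()] with attributes `expected` (list
#'   `transcript_length`, `novel_peptide`, `stop_position_intron`,
#'   `residues_retained`, `residues_lost`) and `donor_variant` (the list to
#'   pass as `variant`), plus `intron_index`.
#' @export
make_splice_fixture <- function(seed = 1) {
  protein_length <- 670L
  utr5 <- 100L
  mature_len <- 2212L
  intron_idx <- 7L
  cds_len <- 3L * (protein_length + 1L)        # 2013 nt incl. stop
  utr3 <- mature_len - utr5 - cds_len          # 99 nt

  withr::with_seed(seed, {
    non_stop <- setdiff(unname(.codon_for), c("TAA", "TAG", "TGA"))
    codons <- sample(non_stop, protein_length, replace = TRUE)
    codons[1L] <- "ATG"
    codons[198L] <- "ATG"                      # Met198, last retained residue
    cds <- paste0(paste(codons, collapse = ""), "TAA")
    mature <- paste0(random_nt(utr5), cds, random_nt(utr3))

    # exon boundaries: exons 1..7 cover the first utr5 + 594 nt so intron 7
    # falls exactly after the codon of residue 198 (5'UTR 100 + 198*3 = 694)
    cut7 <- utr5 + 198L * 3L
    cuts <- c(100L, 200L, 300L, 400L, 500L, 600L, cut7, mature_len)
    exon_bounds <- cbind(c(1L, cuts[-8L] + 1L), cuts)
    exons <- apply(exon_bounds, 1L, function(b) substr(mature, b[1L], b[2L]))

    # mutant intron 7 reads IIIYSYQV then TGA at nt 25; wild type starts GT
    mut_lead <- paste0(paste(.codon_for[c("I", "I", "I", "Y", "S", "Y", "Q", "V")],
                             collapse = ""), "TGA")
    wt_lead <- sub("^A", "G", mut_lead)        # GTT... : canonical GT donor
    intron7 <- paste0(wt_lead, random_nt(300L - nchar(wt_lead) - 2L), "AG")
    introns <- vapply(seq_len(7L), function(i) {
      if (i == intron_idx) intron7 else
        paste0("GT", random_nt(sample(60:120, 1L)), "AG")
    }, character(1))

    model <- splice_gene_model("synthetic_top6b_like", exons, introns,
                               cds_offset = utr5,
                               protein_length = protein_length)
    attr(model, "intron_index") <- intron_idx
    attr(model, "donor_variant") <- list(pos = 1L, ref = "G", alt = "A")
    attr(model, "expected") <- list(
      transcript_length = mature_len + 300L,
      novel_peptide = "IIIYSYQV",
      stop_position_intron = 25L,
      residues_retained = 198L,
      residues_lost = protein_length - 198L)
    model
  })
}

random_nt <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
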