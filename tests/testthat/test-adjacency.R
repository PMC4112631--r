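test_that("maximal same-sign runs and discordant pairs are detected", {
  gc <- toy_catalogue(6)
  # signs (+ + none - - +) -> one up set {g1,g2}, one down set {g4,g5},
  # one discordant pair (g5,g6)
  de <- select_deregulated(de_from_signs(gc, c(1, 1, 0, -1, -1, 1)))
  found <- find_coregulated_sets(gc, de)
  expect_equal(nrow(found$sets), 2L)
  expect_equal(found$sets$members, c("g01,g02", "g04,g05"))
  expect_equal(found$sets$direction, c(1L, -1L))
  expect_equal(nrow(found$discordant), 1L)
  expect_equal(found$discordant$gene_a, "g05")
  expect_equal(found$discordant$gene_b, "g06")

  # three consecutive same-sign genes form one set of three, not two pairs
  gc3 <- toy_catalogue(3)
  found3 <- find_coregulated_sets(gc3, select_deregulated(de_from_signs(gc3, c(1, 1, 1))))
  expect_equal(nrow(found3$sets), 1L)
  expect_equal(found3$sets$n_genes, 3L)

  # vacuous input
  found0 <- find_coregulated_sets(gc, select_deregulated(de_from_signs(gc, rep(0, 6))))
  expect_equal(nrow(found0$sets), 0L)
  expect_equal(nrow(found0$discordant), 0L)

  missing <- data.frame(gene_id = "zz", sign = 1L)
  expect_error(find_coregulated_sets(gc, missing), "absent from catalogue")
})

test_that("runs never span a chromosome boundary", {
  gc <- gene_catalogue(data.frame(
    gene_id = c("a1", "a2", "b1", "b2"),
    chromosome = c("c1", "c1", "c2", "c2"),
    start = c(1L, 100L, 1L, 100L), end = c(50L, 150L, 50L, 150L),
    strand = "+", stringsAsFactors = FALSE))
  de <- select_deregulated(de_from_signs(gc, c(1, 1, 1, 1)))
  found <- find_coregulated_sets(gc, de)
  expect_equal(nrow(found$sets), 2L)  # one run per chromosome, not one of 4
  expect_equal(found$sets$n_genes, c(2L, 2L))
})

test_that("detection matches exhaustive enumeration on small catalogues", {
  # exhaustive over every sign assignment of a 5-gene chromosome
  gc5 <- toy_catalogue(5)
  grid <- expand.grid(rep(list(c(-1, 0, 1)), 5))
  for (r in seq_len(nrow(grid))) {
    signs <- as.numeric(grid[r, ])
    de <- select_deregulated(de_from_signs(gc5, signs))
    found <- find_coregulated_sets(gc5, de)
    oracle <- enumerate_sets_oracle(gc5, signs)
    expect_equal(nrow(found$sets), oracle$n_sets)
    expect_equal(nrow(found$discordant), oracle$n_discordant)
    if (oracle$n_sets > 0) {
      expect_equal(strsplit(found$sets$members, ","), oracle$members)
    }
  }
  # random assignments on 12-gene two-chromosome catalogues
  set.seed(99)
  for (rep_i in 1:50) {
    gc12 <- gene_catalogue(data.frame(
      gene_id = sprintf("g%02d", 1:12),
      chromosome = rep(c("c1", "c2"), each = 6),
      start = rep(seq(1, by = 1000, length.out = 6), 2),
      end = rep(seq(900, by = 1000, length.out = 6), 2),
      strand = sample(c("+", "-"), 12, replace = TRUE),
      stringsAsFactors = FALSE))
    signs <- sample(c(-1, 0, 1), 12, replace = TRUE)
    de <- select_deregulated(de_from_signs(gc12, signs))
    found <- find_coregulated_sets(gc12, de)
    oracle <- enumerate_sets_oracle(gc12, signs)
    expect_equal(nrow(found$sets), oracle$n_sets)
    expect_equal(nrow(found$discordant), oracle$n_discordant)
  }
})

test_that("within-set pair count equals the sum of set sizes minus one", {
  set.seed(4)
  for (i in 1:20) {
    gc <- toy_catalogue(30)
    signs <- sample(c(-1, 0, 1), 30, replace = TRUE, prob = c(0.3, 0.4, 0.3))
    found <- find_coregulated_sets(gc, select_deregulated(de_from_signs(gc, signs)))
    if (nrow(found$sets) == 0) next
    n_pairs_direct <- sum(found$sets$n_genes - 1L)
    # recount from the edge definition
    edge <- signs[-30] != 0 & signs[-30] == signs[-1]
    expect_equal(n_pairs_direct, sum(edge))
    # sets do not overlap: each gene in at most one set
    members <- unlist(strsplit(found$sets$members, ","))
    expect_equal(anyDuplicated(members), 0L)
  }
})

test_that("duplicate-family adjacent pairs are excluded and counted", {
  pairs <- data.frame(gene_a = c("a", "c", "e"), gene_b = c("b", "d", "f"),
                      stringsAsFactors = FALSE)
  expect_equal(exclude_duplicates(pairs, NULL),
               list(retained = pairs, n_excluded = 0L))
  fam <- c(a = "f1", b = "f1", c = "f2")
  res <- exclude_duplicates(pairs, fam)
  expect_equal(res$n_excluded, 1L)
  expect_equal(res$retained$gene_a, c("c", "e"))

  # inside detection only the duplicate EDGE is discounted: the run loses
  # the g01-g02 adjacency but g02 still genuinely co-regulates with g03
  gc <- toy_catalogue(4)
  de <- select_deregulated(de_from_signs(gc, c(1, 1, 1, 1)))
  fam_map <- data.frame(gene_id = c("g01", "g02"), family_id = "famA",
                        stringsAsFactors = FALSE)
  found <- find_coregulated_sets(gc, de, fam_map)
  expect_equal(found$n_duplicate_excluded, 1L)
  expect_equal(found$sets$members, "g02,g03,g04")

  # an isolated duplicate pair disappears entirely
  gc2 <- toy_catalogue(4)
  de2 <- select_deregulated(de_from_signs(gc2, c(1, 1, 0, 0)))
  found2 <- find_coregulated_sets(gc2, de2, fam_map)
  expect_equal(found2$n_duplicate_excluded, 1L)
  expect_equal(nrow(found2$sets), 0L)
})

test_that("strand composition counts opposite-strand within-set pairs", {
  gc <- toy_catalogue(4, strand = c("+", "+", "+", "+"))
  de <- select_deregulated(de_from_signs(gc, c(1, 1, 1, 1)))
  expect_equal(strand_composition(find_coregulated_sets(gc, de)$sets), 0)

  # strands + - + -: one 4-gene run has 3 pairs, all opposite; plus a
  # separate 2-gene run with equal strands gives 2/4 opposite
  gc2 <- gene_catalogue(data.frame(
    gene_id = sprintf("g%d", 1:6),
    chromosome = c(rep("c1", 4), "c2", "c2"),
    start = c(1, 100, 200, 300, 1, 100) * 10,
    end = c(1, 100, 200, 300, 1, 100) * 10 + 50,
    strand = c("+", "-", "+", "+", "-", "-"),
    stringsAsFactors = FALSE))
  de2 <- select_deregulated(de_from_signs(gc2, rep(1, 6)))
  sets2 <- find_coregulated_sets(gc2, de2)$sets
  expect_equal(strand_composition(sets2), 0.5)  # 2 of 4 pairs opposite

  expect_true(is.na(strand_composition(sets2[0, ])))
})

test_that("span statistics use inclusive distal-end distances", {
  gc <- gene_catalogue(data.frame(
    gene_id = c("a", "b"), chromosome = "c1",
    start = c(1L, 600L), end = c(400L, 1000L), strand = "+",
    stringsAsFactors = FALSE))
  sets <- find_coregulated_sets(gc, select_deregulated(de_from_signs(gc, c(1, 1))))$sets
  expect_equal(span_statistics(sets)$mean_span_bp, 1000)
  expect_equal(span_statistics(sets, exclusive_gap = TRUE)$mean_span_bp, 998)

  two <- data.frame(span_bp = c(4000, 12000))
  expect_equal(span_statistics(two)$mean_span_bp, 8000)
  expect_error(span_statistics(sets[0, ]), "undefined")
})

test_that("adjacency chi-square matches a hand-coded 2x2 Pearson oracle", {
  chi_hand <- function(a, n1, b, n2) {
    tab <- matrix(c(a, n1 - a, b, n2 - b), 2, byrow = TRUE)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
  }
  got <- adjacency_chi2(102, 1073, 4, 1078)
  expect_equal(got$chi2_stat, chi_hand(102, 1073, 4, 1078))
  expect_equal(got$chi2_p,
               pchisq(chi_hand(102, 1073, 4, 1078), 1, lower.tail = FALSE))
  # cohort proportions at the study's scale are significant beyond 1e-21
  expect_lt(got$chi2_p, 1e-21)

  eq <- adjacency_chi2(10, 100, 10, 100)
  expect_equal(eq$chi2_stat, 0)
  expect_equal(eq$chi2_p, 1)
  expect_error(adjacency_chi2(0, 100, 0, 100), "zero margin")
  expect_error(adjacency_chi2(-1, 100, 0, 100), "non-negative")
  expect_error(adjacency_chi2(101, 100, 0, 100), "exceed")
})

test_that("binomial sign null reproduces the printed enrichment arithmetic", {
  # direct arithmetic oracle with p = 559/1073
  p <- 559 / 1073
  p_conc <- p^2 + (1 - p)^2
  expected <- 14 * p_conc / (2 * p * (1 - p))
  got <- binomial_sign_null(27, 24, 14, 559, 514)
  expect_equal(got$expected_concordant, expected)
  expect_equal(round(got$expected_concordant, 2), 14.05)
  expect_equal(got$enrichment_ratio, 51 / expected)
  expect_equal(round(got$enrichment_ratio, 1), 3.6)
  expect_gt(got$enrichment_ratio, 3)
  expect_equal(got$binomial_p,
               pbinom(50, 65, p_conc, lower.tail = FALSE))

  # symmetric null: p = q = 0.5 and equal counts give ratio 1
  sym <- binomial_sign_null(5, 5, 10, 300, 300)
  expect_equal(sym$expected_concordant, 10)
  expect_equal(sym$enrichment_ratio, 1)

  # zero discordant pairs: expectation undefined, ratio unbounded marker
  nodisc <- binomial_sign_null(5, 5, 0, 300, 300)
  expect_true(is.na(nodisc$expected_concordant))
  expect_true(is.infinite(nodisc$enrichment_ratio))
  expect_true(nodisc$binomial_p >= 0 && nodisc$binomial_p <= 1)
})

test_that("permutation null is deterministic and saturates under injection", {
  cfg <- sim_config(n_chromosomes = 2, genes_per_chromosome = 250,
                    n_injected_blocks = 8, n_duplicate_pairs = 0, seed = 21)
  gc <- simulate_genome(cfg)
  sim <- simulate_expression(gc, cfg)
  a <- permutation_null(gc, sim$de_table, n_perm = 199, seed = 5)
  b <- permutation_null(gc, sim$de_table, n_perm = 199, seed = 5)
  expect_identical(a, b)
  # strong injected clustering reaches the minimum attainable p
  expect_equal(a$empirical_p, 1 / 200)
  expect_error(permutation_null(gc, sim$de_table, n_perm = 50), "at least 99")
})

test_that("full adjacency report is internally consistent", {
  cfg <- sim_config(n_chromosomes = 2, genes_per_chromosome = 400, seed = 31)
  gc <- simulate_genome(cfg)
  sim <- simulate_expression(gc, cfg)
  rep <- run_adjacency_analysis(gc, sim$de_table, family_map = sim$family_map)
  expect_equal(rep$n_up_sets + rep$n_down_sets, nrow(rep$sets))
  expect_equal(rep$n_discordant_pairs, nrow(rep$discordant))
  expect_equal(rep$n_de_in_sets,
               length(unique(unlist(strsplit(rep$sets$members, ",")))))
  expect_true(rep$chi2_p >= 0 && rep$chi2_p <= 1)
  expect_true(rep$binomial_p >= 0 && rep$binomial_p <= 1)
  expect_gte(rep$enrichment_ratio, 0)
  expect_true(rep$opposite_strand_fraction >= 0 &&
                rep$opposite_strand_fraction <= 1)

  # empty DE set: zeroed report with undefined test fields flagged as NA
  null_de <- sim$de_table
  null_de$p_value <- 1
  empty <- run_adjacency_analysis(gc, null_de)
  expect_equal(empty$n_up_sets + empty$n_down_sets, 0L)
  expect_true(is.na(empty$chi2_p))
  expect_true(is.na(empty$binomial_p))
})
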