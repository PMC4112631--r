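#' Run the full adjacency + concordance pipeline from a config
#'
#' Orchestrates annotation ingest, deregulation thresholding, adjacency
#' detection with both analytic nulls and the permutation null, and
#' (optionally) the cross-study concordance table, writing machine-readable
#' reports with a provenance block (input checksums, parameters, seed,
#' package version).
#'
#' @param config a list (or path to a YAML file) with fields:
#'   `annotation` (path), `annotation_format` (`tsv`/`gff3`/`bed`),
#'   `de` (path to DE TSV), optional `families` (TSV `gene_id`, `family_id`),
#'   optional `reference_lists` (TSV for [read_directional_lists()]),
#'   `min_abs_log2fc` (default 0.8), `max_p` (default 0.05),
#'   `control_size` (default `"auto"`), `n_perm` (default 0 = skip
#'   permutation), `seed` (default 1), `out_dir`.
#' @return (invisibly) list with `report` (the `adjacency_report`),
#'   `concordance` (data frame or NULL), and `files` written.
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  defaults <- list(annotation_format = "tsv", min_abs_log2fc = 0.8,
                   max_p = 0.05, control_size = "auto", n_perm = 0L,
                   seed = 1L, families = NULL, reference_lists = NULL)
  config <- utils::modifyList(defaults, config)
  for (field in c("annotation", "de", "out_dir")) {
    if (is.null(config[[field]])) stop("pipeline config missing field: ", field)
  }
  log_lines <- character(0)
  say <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, msg)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  in_files <- c(annotation = config$annotation, de = config$de,
                families = config$families,
                reference_lists = config$reference_lists)
  in_files <- in_files[!vapply(in_files, is.null, logical(1))]
  for (f in in_files) if (!file.exists(f)) {
    stop("pipeline stage 'inputs' failed: missing file ", f)
  }
  provenance <- list(
    package = "adjacoreg",
    version = as.character(utils::packageVersion("adjacoreg")),
    seed = config$seed,
    parameters = config[c("annotation_format", "min_abs_log2fc", "max_p",
                          "control_size", "n_perm")],
    input_md5 = as.list(tools::md5sum(unlist(in_files))))

  say("annotation", sprintf("reading %s (%s)", config$annotation,
                            config$annotation_format))
  catalogue <- stage("annotation",
                     read_annotation(config$annotation, config$annotation_format))
  say("annotation", sprintf("%d genes", nrow(catalogue)))

  say("de", sprintf("reading %s", config$de))
  de_table <- stage("de", read_de_table(config$de))
  family_map <- NULL
  if (!is.null(config$families)) {
    family_map <- stage("families",
                        utils::read.delim(config$families,
                                          stringsAsFactors = FALSE))
  }

  say("adjacency", sprintf("|log2FC| >= %g, p <= %g, control %s",
                           config$min_abs_log2fc, config$max_p,
                           config$control_size))
  report <- stage("adjacency",
                  run_adjacency_analysis(catalogue, de_table,
                                         config$min_abs_log2fc, config$max_p,
                                         family_map, config$control_size))
  perm <- NULL
  if (config$n_perm >= 99) {
    say("permutation", sprintf("%d permutations, seed %d", config$n_perm,
                               config$seed))
    perm <- stage("permutation",
                  permutation_null(catalogue, de_table, config$min_abs_log2fc,
                                   config$max_p, config$n_perm, config$seed))
  }

  concordance <- NULL
  if (!is.null(config$reference_lists)) {
    say("concordance", sprintf("reading %s", config$reference_lists))
    lists <- stage("concordance", read_directional_lists(config$reference_lists))
    concordance <- stage("concordance",
                         concordance_matrix(lists, de_table,
                                            max_p = config$max_p))
  }

  files <- character(0)
  adjacency_json <- file.path(config$out_dir, "adjacency.json")
  payload <- report[setdiff(names(report), c("sets", "discordant"))]
  payload$permutation <- perm
  payload$provenance <- provenance
  jsonlite::write_json(payload, adjacency_json, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  files <- c(files, adjacency_json)

  sets_tsv <- file.path(config$out_dir, "coregulated_sets.tsv")
  utils::write.table(report$sets, sets_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, sets_tsv)

  if (!is.null(concordance)) {
    conc_tsv <- file.path(config$out_dir, "concordance.tsv")
    utils::write.table(concordance, conc_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, conc_tsv)
  }
  say("done", sprintf("%d report file(s) written to %s", length(files),
                      config$out_dir))
  log_file <- file.path(config$out_dir, "pipeline.log")
  writeLines(log_lines, log_file)
  files <- c(files, log_file)
  invisible(list(report = report, permutation = perm,
                 concordance = concordance, files = files))
}

# reference/query fixtures realizing printed cross-study cluster counts
concordance_inputs_from_counts <- function(n_reference, n_up, n_down,
                                           prefix = "ref") {
  ids <- sprintf("%s%04d", prefix, seq_len(n_reference))
  query <- data.frame(
    gene_id = ids,
    log2fc = c(rep(1, n_up), rep(-1, n_down),
               rep(0.01, n_reference - n_up - n_down)),
    p_value = c(rep(0.001, n_up + n_down),
                rep(0.9, n_reference - n_up - n_down)),
    stringsAsFactors = FALSE)
  list(reference = directional_gene_list(ids, -1, "external", "cluster"),
       query = query)
}

#' Recompute the study's printed desk-scale statistics
#'
#' Re-derives every quantity of the source study that is recomputable from
#' printed numbers alone, using the package's own functions: the segregation
#' chi-square p-values, the starch group means/SEMs and end-of-day fold
#' effects, the binomial sign-model enrichment from the printed adjacency
#' counts, the splice-consequence arithmetic on the synthetic fixture
#' mirroring the TOP6B gene geometry, the fine-mapping interval width, and
#' the cross-study concordance percentages from printed cluster counts.
#'
#' @param verbose print the pass/fail table.
#' @return data frame with columns `check`, `expected`, `computed`, `pass`.
#' @export
reproduce_study_statistics <- function(verbose = TRUE) {
  rows <- list()
  add <- function(check, expected, computed, pass) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, expected = as.character(expected),
      computed = as.character(computed), pass = pass,
      stringsAsFactors = FALSE)
  }
  near <- function(x, y, tol) abs(x - y) <= tol

  seg1 <- segregation_chi2(c(9, 39), c(1, 3))
  add("segregation chi2 p, 48 F1 progeny (9 mutant / 39 wt vs 1:3)",
      0.32, round(seg1$p, 2), round(seg1$p, 2) == 0.32)
  seg2 <- segregation_chi2(c(47, 148), c(1, 3))
  add("segregation chi2 p, 195 F1 progeny (47 mutant / 148 wt vs 1:3)",
      0.77, round(seg2$p, 2), round(seg2$p, 2) == 0.77)
  add("expected counts under 1:3 for 195 progeny",
      "48.75, 146.25", paste(seg2$expected, collapse = ", "),
      all(seg2$expected == c(48.75, 146.25)))

  wt <- group_summary(c(3.89, 6.09, 5.14))
  mu <- group_summary(c(15.94, 17.18, 9.88))
  add("wild-type leaf starch mean (end of day, mg/g FW)",
      5.04, round(wt$mean, 2), round(wt$mean, 2) == 5.04)
  add("wild-type leaf starch SEM", 0.64, round(wt$sem, 2),
      round(wt$sem, 2) == 0.64)
  add("mutant leaf starch mean", 14.33, round(mu$mean, 2),
      round(mu$mean, 2) == 14.33)
  add("mutant leaf starch SEM", 2.25, round(mu$sem, 3),
      near(mu$sem, 2.25, 0.011))
  add("hlq-1 end-of-day starch fold effect", 4.1,
      fold_effect(15.94, 3.89), fold_effect(15.94, 3.89) == 4.1)
  add("hlq-3 end-of-day starch fold effect", 1.9,
      fold_effect(9.88, 5.14), fold_effect(9.88, 5.14) == 1.9)

  add("linear fold change at log2FC threshold 0.8", 1.74,
      round(2^0.8, 2), round(2^0.8, 2) == 1.74)

  bin <- binomial_sign_null(27, 24, 14, 559, 514)
  add("adjacency enrichment over binomial sign null", "> 3",
      round(bin$enrichment_ratio, 2), bin$enrichment_ratio > 3)
  add("expected concordant adjacent cases under sign null", "~14.05",
      round(bin$expected_concordant, 2),
      near(bin$expected_concordant, 14.05, 0.02))

  fx <- make_splice_fixture(seed = 1)
  pred <- predict_truncation(fx, attr(fx, "intron_index"),
                             attr(fx, "donor_variant"))
  add("intron-retained transcript length (nt)", 2512,
      pred$transcript_length, pred$transcript_length == 2512)
  add("C-terminal residues lost from 670 aa protein", 472,
      pred$residues_lost, pred$residues_lost == 472)
  add("novel peptide read from retained mutant intron", "IIIYSYQV",
      pred$novel_peptide, pred$novel_peptide == "IIIYSYQV")
  add("premature stop position within intron (nt)", 25,
      pred$stop_position_intron, pred$stop_position_intron == 25)
  donor <- validate_donor_site(fx, attr(fx, "intron_index"),
                               attr(fx, "donor_variant"))
  add("G-to-A at intron nt 1 abolishes donor consensus",
      "consensus abolished", donor$diagnosis,
      donor$diagnosis == "consensus abolished")

  add("fine-mapping interval width chr3:7213133..7325482 (bp)",
      "112349 (~112 kbp)", interval_width(7213133, 7325482),
      interval_width(7213133, 7325482) == 112349)

  c4 <- concordance_inputs_from_counts(113, 22, 12)
  ov4 <- overall_concordance(c4$reference, c4$query)
  add("overall concordance, 113-gene singlet-oxygen cluster (%)", 30,
      ov4$overall_pct_display, ov4$overall_pct_display == 30)
  c68 <- concordance_inputs_from_counts(199, 90, 5)
  ov68 <- overall_concordance(c68$reference, c68$query)
  add("overall concordance, 199-gene TopoVI-repressed clusters (%)", 48,
      ov68$overall_pct_display, ov68$overall_pct_display == 48)
  ref255 <- directional_gene_list(sprintf("d%04d", 1:255), -1, "caa39", "down")
  query314 <- data.frame(
    gene_id = c(sprintf("d%04d", 1:13), sprintf("x%04d", 1:301)),
    sign = -1L, stringsAsFactors = FALSE)
  st <- strict_concordance(ref255, query314)
  add("strict concordance, 255 down-regulated genes vs 314-gene list (%)",
      5, st$strict_pct_display, st$strict_pct_display == 5)

  out <- do.call(rbind, rows)
  if (verbose) {
    status <- ifelse(out$pass, "PASS", "FAIL")
    cat(sprintf("%-62s %-18s %-12s %s\n", "check", "expected", "computed",
                "status"))
    for (i in seq_len(nrow(out))) {
      cat(sprintf("%-62s %-18s %-12s %s\n", out$check[i], out$expected[i],
                  out$computed[i], status[i]))
    }
  }
  invisible(out)
}
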