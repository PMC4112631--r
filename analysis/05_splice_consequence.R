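#!/usr/bin/env Rscript
# Splice-donor mutation consequence prediction on the synthetic gene model
# that mirrors the TOP6B gene geometry (2212 nt mature mRNA, 670 aa
# protein, 300 nt intron 7 after Met198).

library(adjacoreg)
dir.create("results/splice", recursive = TRUE, showWarnings = FALSE)

model <- make_splice_fixture(seed = 101)
idx <- attr(model, "intron_index")
variant <- attr(model, "donor_variant")
print(model)

cat("wild-type donor:", validate_donor_site(model, idx)$diagnosis, "\n")
cat("after G>A at intron nt 1:",
    validate_donor_site(model, idx, variant)$diagnosis, "\n")

pred <- predict_truncation(model, idx, variant)
print(pred)

jsonlite::write_json(
  list(gene_id = model$gene_id, intron_index = idx, variant = variant,
       prediction = unclass(pred)),
  "results/splice/truncation_prediction.json",
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("prediction written to results/splice/truncation_prediction.json\n")
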