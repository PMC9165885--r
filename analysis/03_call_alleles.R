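#!/usr/bin/env Rscript
# Step 3: call blood-group diplotypes for the simulated cohort.
#
# Projects each sample's VCF records onto the gene CDSs, re-bases them
# against the baseline table, enumerates consistent diplotypes, and
# scores the resolved calls against the simulation truth table.

library(bgtyper)

cfg <- demo_simulation_config(seed = 41L, n_samples = 250L, dropout_rate = 0.18)
bundle <- build_synthetic_reference(cfg)
res <- run_call("results/cohort.vcf", bundle, out_prefix = "results/cohort")

truth <- read.delim("results/cohort_truth.tsv", stringsAsFactors = FALSE)
truth_key <- setNames(
  vapply(seq_len(nrow(truth)), function(i)
    paste(sort(c(truth$allele1[i], truth$allele2[i])), collapse = "/"), ""),
  paste(truth$sample_id, truth$gene_symbol))

cat(sprintf("Excluded %d zero-variant samples; called %d sample-gene pairs\n",
            length(res$excluded), nrow(res$calls)))
print(table(res$calls$status))
resolved <- res$calls[res$calls$status == "resolved", ]
ok <- resolved$candidates ==
  truth_key[paste(resolved$sample_id, resolved$gene_symbol)]
cat(sprintf("Resolved calls matching truth: %d / %d (%.2f%%)\n",
            sum(ok), nrow(resolved), 100 * mean(ok)))
cat("Mean projected variants per included sample, by gene:\n")
print(res$gene_summary, row.names = FALSE)
cat("Wrote results/cohort_calls.tsv, results/cohort_excluded.txt, results/cohort_gene_summary.tsv\n")
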