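test_that("synthetic references plant exactly the configured baseline", {
  al <- data.frame(allele_name = c("X*01", "X*02"), changes = c("-", "50A>G"),
                   freq = c(0.5, 0.5), phenotype = "", stringsAsFactors = FALSE)
  for (strand in c("+", "-")) {
    cfg <- simulation_config(seed = 9L, n_samples = 2L, genes = list(
      sim_gene("XG1", 120L, strand = strand, n_segments = 2L,
               baseline_changes = "50A>G", alleles = al)))
    bun <- build_synthetic_reference(cfg)
    cds <- extract_cds(bun$genome, bun$models$XG1)
    d <- diff_cds(bun$conventionals$XG1$cds, cds)
    expect_identical(vapply(d, function(c) c$hgvs_c, ""), "50A>G")
  }
  # empty baseline: genome CDS equals the conventional CDS
  cfg0 <- simulation_config(seed = 9L, n_samples = 2L, genes = list(
    sim_gene("XG1", 120L, alleles = al)))
  bun0 <- build_synthetic_reference(cfg0)
  expect_identical(extract_cds(bun0$genome, bun0$models$XG1),
                   bun0$conventionals$XG1$cds)
})

test_that("pinned bases and change refs shape the conventional CDS", {
  cfg <- fy_config(seed = 3L, n_samples = 2L)
  bun <- build_synthetic_reference(cfg)
  conv <- bun$conventionals$ACKR1$cds
  expect_identical(substr(conv, 124, 126), "GAC")  # Asp codon at 42
  expect_identical(substr(conv, 199, 199), "C")    # ref of 199C>T
  expect_identical(substr(conv, 1, 3), "ATG")
})

test_that("baseline-homozygous samples emit no records; conventional carriers restore", {
  al1 <- data.frame(allele_name = c("FY*02", "FY*01"),
                    changes = c("-", "125A>G"), freq = c(0, 1),
                    phenotype = "", stringsAsFactors = FALSE)
  cfg <- simulation_config(seed = 21L, n_samples = 6L, genes = list(
    sim_gene("ACKR1", 210L, baseline_changes = "125A>G", alleles = al1)))
  bun <- build_synthetic_reference(cfg)
  sim <- simulate_cohort(cfg, bun)
  expect_false(any(grepl("^chr_ACKR1\t", sim$vcf_lines)))
  expect_true(all(sim$truth$allele1 == "FY*01"))

  al2 <- al1; al2$freq <- c(1, 0)
  cfg2 <- simulation_config(seed = 21L, n_samples = 6L, genes = list(
    sim_gene("ACKR1", 210L, baseline_changes = "125A>G", alleles = al2)))
  bun2 <- build_synthetic_reference(cfg2)
  sim2 <- simulate_cohort(cfg2, bun2)
  recs <- grep("^chr_ACKR1\t", sim2$vcf_lines, value = TRUE)
  expect_length(recs, 1L)
  gts <- strsplit(recs, "\t")[[1]][-(1:9)]
  expect_true(all(gts == "1/1"))  # every sample hom for the restoring allele
})

test_that("identical seed and config give byte-identical outputs", {
  cfg <- fy_config(seed = 12L, n_samples = 25L, dropout_rate = 0.2,
                   neutral_rate = 0.02)
  bun <- build_synthetic_reference(cfg)
  s1 <- simulate_cohort(cfg, bun)
  s2 <- simulate_cohort(cfg, bun)
  expect_identical(s1$vcf_lines, s2$vcf_lines)
  expect_identical(s1$truth, s2$truth)
})

test_that("empirical truth frequencies track the configured ones", {
  cfg <- fy_config(seed = 8L, n_samples = 205L)
  bun <- build_synthetic_reference(cfg)
  sim <- simulate_cohort(cfg, bun)
  tf <- truth_frequencies(sim$truth, include_dropout = TRUE)
  f <- tf$frequency[tf$allele_name == "FY*01"]
  # 99.9% binomial bound around the configured 0.93 over 410 draws
  bound <- stats::qnorm(1 - 0.001 / 2) * sqrt(0.93 * 0.07 / 410)
  expect_lt(abs(f - 0.93), bound)
})

test_that("neutral extra variants are synonymous and flow through as unexplained", {
  cfg <- fy_config(seed = 14L, n_samples = 12L, neutral_rate = 0.05)
  bun <- build_synthetic_reference(cfg)
  sim <- simulate_cohort(cfg, bun)
  vcf <- tempfile(fileext = ".vcf")
  writeLines(sim$vcf_lines, vcf)
  res <- run_call(vcf, bun, keep_zero_variant_samples = TRUE)
  # calls either resolve exactly or surface the neutral load as novel/ND,
  # never a wrong confident call
  truth_key <- setNames(diplotype_key(sim$truth$allele1, sim$truth$allele2),
                        sim$truth$sample_id)
  resolved <- res$calls[res$calls$status == "resolved", ]
  expect_identical(resolved$candidates,
                   unname(truth_key[resolved$sample_id]))
  genome_cds <- extract_cds(bun$genome, bun$models$ACKR1)
  others <- res$calls[res$calls$status != "resolved", ]
  if (nrow(others)) {
    un <- unlist(strsplit(others$unexplained[others$unexplained != ""], ";"))
    un <- setdiff(un, c("125A>G", "199C>T"))
    for (h in un) {
      eff <- predict_effects(genome_cds, h)
      expect_true(all(eff$synonymous))
    }
  }
})
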