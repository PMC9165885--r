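test_that("positional diff finds substitutions and merges adjacent ones", {
  expect_length(diff_cds("ATGAAA", "ATGAAA"), 0L)
  d <- diff_cds("ATGGCA", "ATGGAA")
  expect_length(d, 1L)
  expect_identical(d[[1]]$hgvs_c, "5C>A")
  d <- diff_cds("ATGACGT", "ATGGTGT")
  expect_length(d, 1L)
  expect_identical(d[[1]]$hgvs_c, "4_5delACinsGT")
  # a single matching base between mismatches keeps changes separate
  d <- diff_cds("ATGACGTAC", "ATGGCGAAC")
  expect_identical(vapply(d, function(c) c$hgvs_c, ""), c("4A>G", "7T>A"))
})

test_that("diff/apply round trip holds for random substitution sets", {
  set.seed(101)
  for (i in 1:40) {
    cds <- random_cds_string(3 * sample(10:30, 1))
    changes <- random_change_set(cds, n_sub = sample(0:5, 1))
    mutated <- apply_changes(cds, changes)
    d <- diff_cds(cds, mutated)  # internally asserts re-application
    expect_identical(apply_changes(cds, d), mutated)
    # isolated substitutions are recovered one-for-one at their positions
    expect_setequal(vapply(d, function(c) c$hgvs_c, ""),
                    vapply(changes, function(c) c$hgvs_c, ""))
  }
})

test_that("diff/apply round trip holds when lengths differ (alignment path)", {
  set.seed(202)
  for (i in 1:15) {
    cds <- random_cds_string(3 * sample(15:25, 1))
    changes <- random_change_set(cds, n_sub = 2, n_indel = 1)
    mutated <- apply_changes(cds, changes)
    d <- diff_cds(cds, mutated)
    expect_identical(apply_changes(cds, d), mutated)
  }
})

test_that("combined-codon and synonymous effects are predicted", {
  # codon 24 = GGT (Gly); the pair 71G>A + 72T>G makes GAG (Glu)
  cds <- paste0(strrep("ATG", 23), "GGT", strrep("GCA", 6))
  eff <- predict_effects(cds, "71G>A;72T>G")
  expect_identical(nrow(eff), 1L)
  expect_identical(eff$hgvs_p, "Gly24Glu")
  expect_false(eff$synonymous)
  # same effect when the pair arrives merged as a delins
  eff2 <- predict_effects(cds, "71_72delGTinsAG")
  expect_identical(eff2$hgvs_p, "Gly24Glu")

  # codon 31 = ACC (Thr); 93C>T makes ACT, still Thr
  cds <- paste0(strrep("ATG", 30), "ACC", strrep("GCA", 3))
  eff <- predict_effects(cds, "93C>T")
  expect_identical(eff$hgvs_p, "Thr31Thr")
  expect_true(eff$synonymous)

  expect_identical(nrow(predict_effects("ATGAAA", list())), 0L)
})

test_that("effects are invariant to change-list order", {
  cds <- paste0("ATG", strrep("GAC", 10), strrep("TTC", 5))
  a <- predict_effects(cds, "5A>T;20A>C;33C>A")
  b <- predict_effects(cds, "33C>A;5A>T;20A>C")
  expect_identical(a, b)
})

test_that("frame-breaking changes yield a frameshift marker only", {
  cds <- paste0("ATG", strrep("GAC", 9))
  eff <- predict_effects(cds, "8delA")
  expect_identical(nrow(eff), 1L)
  expect_true(eff$frameshift)
  expect_match(eff$hgvs_p, "fs$")
  # frame-preserving deletion reports a single combined in-frame effect
  eff <- predict_effects(cds, "7_9delGAC")
  expect_identical(nrow(eff), 1L)
  expect_false(eff$frameshift)
})

test_that("baseline table assigns alleles by exact change-set match", {
  defs <- data.frame(
    gene_symbol = c("ACKR1", "ACKR1"), allele_name = c("FY*02", "FY*01"),
    defining_changes = c("-", "125A>G"), phenotype = c("Fy(b+)", "Fy(a+)"),
    source = "ISBT", stringsAsFactors = FALSE)
  # conventional CDS with codon 42 = GAC; genome copy carries 125A>G (GGC)
  conv <- paste0("ATG", strrep("CTT", 40), "GAC", strrep("TTC", 8))
  genome_cds <- apply_changes(conv, "125A>G")
  genome <- genome_ref(list(c1 = genome_cds))
  models <- list(ACKR1 = gene_model("ACKR1", "c1", "+",
                                    rbind(c(1, nchar(conv)))))
  convs <- list(ACKR1 = suppressWarnings(
    conventional_reference("ACKR1", "FY*02", conv, "Fy(b+)")))
  bl <- build_baseline_table(genome, models, convs, defs)
  expect_identical(bl$hgvs_c, "125A>G")
  expect_identical(bl$hgvs_p, "Asp42Gly")
  expect_identical(bl$predicted_allele, "FY*01")

  # identical CDS: no changes, predicted allele = conventional name
  genome2 <- genome_ref(list(c1 = conv))
  bl2 <- build_baseline_table(genome2, models, convs, defs)
  expect_identical(bl2$hgvs_c, "-")
  expect_identical(bl2$predicted_allele, "FY*02")

  # diff set matching no definition is ND
  genome3 <- genome_ref(list(c1 = apply_changes(conv, "5T>A")))
  bl3 <- build_baseline_table(genome3, models, convs, defs)
  expect_identical(bl3$predicted_allele, "ND")
})
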