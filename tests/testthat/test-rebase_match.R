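fy_defs <- data.frame(
  gene_symbol = "ACKR1",
  allele_name = c("FY*02", "FY*01"),
  defining_changes = c("-", "125A>G"),
  phenotype = c("Fy(b+)", "Fy(a+)"), source = "ISBT",
  stringsAsFactors = FALSE)

no_variants <- data.frame(hgvs_c = character(), dosage = integer(),
                          stringsAsFactors = FALSE)

test_that("re-basing treats absence of a call at a baseline site as non-conventional", {
  baseline <- list(parse_hgvs_c("125A>G"))
  st <- rebase(baseline, no_variants, ploidy = 2L)
  expect_identical(st$hgvs_c, "125A>G")
  expect_identical(st$dosage, 2L)

  # het call restoring the conventional base leaves one non-conventional copy
  sv <- data.frame(hgvs_c = "125G>A", dosage = 1L, stringsAsFactors = FALSE)
  st <- rebase(baseline, sv, ploidy = 2L)
  expect_identical(st$dosage, 1L)

  # hom restore: nothing left relative to the conventional allele
  sv$dosage <- 2L
  expect_identical(nrow(rebase(baseline, sv, ploidy = 2L)), 0L)

  # non-baseline site passes through
  sv2 <- data.frame(hgvs_c = "838A>G", dosage = 1L, stringsAsFactors = FALSE)
  st <- rebase(list(), sv2, ploidy = 2L)
  expect_identical(st$hgvs_c, "838A>G")
  expect_identical(st$dosage, 1L)
})

test_that("a third allele at a baseline site is emitted and flagged", {
  baseline <- list(parse_hgvs_c("125A>G"))
  sv <- data.frame(hgvs_c = "125G>T", dosage = 1L, stringsAsFactors = FALSE)
  st <- rebase(baseline, sv, ploidy = 2L)
  expect_setequal(st$hgvs_c, c("125A>G", "125A>T"))
  expect_identical(st$dosage[st$hgvs_c == "125A>T"], 1L)
  expect_true(st$third_allele[st$hgvs_c == "125A>T"])
  expect_identical(st$dosage[st$hgvs_c == "125A>G"], 1L)
})

test_that("adjacent sample SNVs restore a merged baseline delins", {
  baseline <- list(parse_hgvs_c("71_72delGTinsAG"))
  sv <- data.frame(hgvs_c = c("71A>G", "72G>T"), dosage = 2L,
                   stringsAsFactors = FALSE)
  expect_identical(nrow(rebase(baseline, sv, ploidy = 2L)), 0L)
})

test_that("diplotype enumeration reproduces the published single-gene calls", {
  st <- data.frame(hgvs_c = "125A>G", dosage = 2L, stringsAsFactors = FALSE)
  res <- enumerate_diplotypes(st, fy_defs)
  expect_identical(res$status, "resolved")
  expect_identical(res$candidates, "FY*01/FY*01")

  jk_defs <- data.frame(gene_symbol = "SLC14A1",
                        allele_name = c("JK*02", "JK*01"),
                        defining_changes = c("-", "838A>G"),
                        phenotype = "", source = "ISBT",
                        stringsAsFactors = FALSE)
  res <- enumerate_diplotypes(no_variants, jk_defs)
  expect_identical(res$status, "resolved")
  expect_identical(res$candidates, "JK*02/JK*02")

  rh_defs <- data.frame(gene_symbol = "RHD",
                        allele_name = c("RHD*01", "RHD*DAU0"),
                        defining_changes = c("-", "1136C>T"),
                        phenotype = "", source = "ISBT",
                        stringsAsFactors = FALSE)
  st <- data.frame(hgvs_c = "1136C>T", dosage = 2L, stringsAsFactors = FALSE)
  res <- enumerate_diplotypes(st, rh_defs)
  expect_identical(res$candidates, "RHD*DAU0/RHD*DAU0")
})

test_that("two het sites across two alleles are ambiguous without phase", {
  # the ABO situation: (A,B) and (AB,conventional) both explain the data
  defs <- data.frame(
    gene_symbol = "ABO",
    allele_name = c("CONV", "A1", "B1", "AB"),
    defining_changes = c("-", "100C>T", "200G>A", "100C>T;200G>A"),
    phenotype = "", source = "ISBT", stringsAsFactors = FALSE)
  st <- data.frame(hgvs_c = c("100C>T", "200G>A"), dosage = 1L,
                   stringsAsFactors = FALSE)
  res <- enumerate_diplotypes(st, defs)
  expect_identical(res$status, "ambiguous")
  expect_setequal(res$candidates, c("A1/B1", "AB/CONV"))
})

test_that("novel placeholder and hypervariable statuses cover unmatched genotypes", {
  st <- data.frame(hgvs_c = c("125A>G", "300C>T"), dosage = c(2L, 1L),
                   stringsAsFactors = FALSE)
  res <- enumerate_diplotypes(st, fy_defs)
  expect_identical(res$status, "ambiguous")
  expect_identical(res$candidates, "FY*01/novel")
  # the novel haplotype carries the unmatched site plus one 125A>G copy
  expect_setequal(res$unexplained, c("125A>G", "300C>T"))
  expect_true("300C>T" %in% res$unexplained)

  # many unexplained sites with no exact pair: hypervariable ND
  st_many <- data.frame(hgvs_c = sprintf("%dC>T", seq(102, 132, by = 3)),
                        dosage = 1L, stringsAsFactors = FALSE)
  res <- enumerate_diplotypes(st_many, fy_defs, hypervariable_threshold = 6L)
  expect_identical(res$status, "nd_hypervariable")

  # impossible dosage with no novel rescue
  st_bad <- data.frame(hgvs_c = c("300C>T"), dosage = 2L,
                       stringsAsFactors = FALSE)
  res <- enumerate_diplotypes(st_bad, fy_defs)
  expect_identical(res$status, "nd_no_match")
})

test_that("haploid calls match single alleles", {
  res <- enumerate_diplotypes(
    data.frame(hgvs_c = "125A>G", dosage = 1L, stringsAsFactors = FALSE),
    fy_defs, ploidy = 1L)
  expect_identical(res$status, "resolved")
  expect_identical(res$candidates, "FY*01")
})

test_that("enumeration agrees with the brute-force assignment oracle", {
  sites <- c("10A>G", "20C>T", "30G>A")
  set.seed(77)
  for (rep in 1:60) {
    n_extra <- sample(0:5, 1)
    subsets <- list(character())
    pool <- unlist(lapply(1:3, function(k)
      utils::combn(sites, k, simplify = FALSE)), recursive = FALSE)
    subsets <- c(subsets, sample(pool, n_extra))
    subsets <- unique(subsets)
    defs <- data.frame(
      gene_symbol = "G",
      allele_name = paste0("AL", seq_along(subsets)),
      defining_changes = vapply(subsets, function(s)
        if (!length(s)) "-" else paste(s, collapse = ";"), ""),
      phenotype = "", source = "ISBT", stringsAsFactors = FALSE)
    dos <- sample(0:2, 3, replace = TRUE)
    st <- data.frame(hgvs_c = sites[dos > 0], dosage = dos[dos > 0],
                     stringsAsFactors = FALSE)
    res <- enumerate_diplotypes(st, defs)
    expected <- oracle_diplotypes(st, defs)
    if (length(expected)) {
      expect_identical(sort(res$candidates), expected)
      expect_identical(res$status,
                       if (length(expected) == 1L) "resolved" else "ambiguous")
    } else {
      expect_true(res$status %in% c("nd_no_match", "ambiguous"))
      if (res$status == "ambiguous")  # only the novel-placeholder rescue
        expect_match(res$candidates, "/novel$")
    }
  }
})

test_that("cohort calling excludes zero-variant samples and scores truth", {
  cfg <- fy_config(seed = 5L, n_samples = 40L)
  bun <- build_synthetic_reference(cfg)
  sim <- simulate_cohort(cfg, bun)
  vcf <- tempfile(fileext = ".vcf")
  writeLines(sim$vcf_lines, vcf)
  bl <- run_baseline(bun)
  res <- run_call(vcf, bun, baseline = bl, keep_zero_variant_samples = TRUE)
  truth_key <- setNames(diplotype_key(sim$truth$allele1, sim$truth$allele2),
                        sim$truth$sample_id)
  expect_true(all(res$calls$status == "resolved"))
  expect_identical(res$calls$candidates,
                   unname(truth_key[res$calls$sample_id]))

  # with the default exclusion, zero-variant samples drop out of the calls
  res2 <- run_call(vcf, bun, baseline = bl)
  expect_identical(sort(unique(c(res2$calls$sample_id, res2$excluded))),
                   sort(unique(sim$truth$sample_id)))
  expect_false(any(res2$excluded %in% res2$calls$sample_id))
})
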