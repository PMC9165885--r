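write_vcf_lines <- function(path, records, samples = "S1") {
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"),
             records)
  writeLines(lines, path)
  path
}

test_that("VCF loading keeps CDS records and splits multi-allelics", {
  g <- genome_ref(list(chr1 = "ATGAAGGGTTTCCCAAA"))
  models <- list(G1 = gene_model("G1", "chr1", "+", rbind(c(1, 6), c(10, 12))))
  vcf <- tempfile(fileext = ".vcf")
  write_vcf_lines(vcf, c(
    "chr1\t4\t.\tA\tG\t.\tPASS\t.\tGT\t0/1",
    "chr1\t8\t.\tG\tC\t.\tPASS\t.\tGT\t1/1",        # intronic
    "chr1\t11\t.\tT\tG,A\t.\tPASS\t.\tGT\t1/2"))    # multi-allelic
  res <- load_vcf(vcf, models, genome = g)
  expect_identical(res$n_outside, 1L)
  expect_identical(nrow(res$variants), 3L)
  ma <- res$variants[res$variants$pos == 11, ]
  expect_setequal(ma$alt, c("G", "A"))
  expect_identical(ma$dosage, c(1L, 1L))
})

test_that("REF mismatches against the genome are warned about", {
  g <- genome_ref(list(chr1 = "ATGAAGGGTTTCCCAAA"))
  models <- list(G1 = gene_model("G1", "chr1", "+", rbind(c(1, 6))))
  vcf <- tempfile(fileext = ".vcf")
  write_vcf_lines(vcf, "chr1\t4\t.\tC\tG\t.\tPASS\t.\tGT\t0/1")
  expect_warning(load_vcf(vcf, models, genome = g), "REF mismatch")
})

test_that("a header-only VCF yields samples but no variants", {
  models <- list(G1 = gene_model("G1", "chr1", "+", rbind(c(1, 6))))
  vcf <- tempfile(fileext = ".vcf")
  write_vcf_lines(vcf, character(), samples = c("S1", "S2"))
  res <- load_vcf(vcf, models)
  expect_identical(nrow(res$variants), 0L)
  expect_identical(res$samples, c("S1", "S2"))
})

test_that("projection maps position, strand and boundary cases", {
  m_plus <- gene_model("G1", "chr1", "+", rbind(c(3, 8)))
  pr <- project(m_plus, "chr1", 7, "C", "T")
  expect_identical(pr$change$hgvs_c, "5C>T")

  m_minus <- gene_model("G1", "chr1", "-", rbind(c(3, 8)))
  pr <- project(m_minus, "chr1", 4, "G", "A")
  expect_identical(pr$change$hgvs_c, "5C>T")

  expect_null(project(m_plus, "chr1", 1, "A", "G"))
  expect_null(project(m_plus, "chr2", 5, "A", "G"))

  m_split <- gene_model("G1", "chr1", "+", rbind(c(1, 6), c(10, 12)))
  expect_warning(pr <- project(m_split, "chr1", 5, "AGGGT", "A"), "boundary")
  expect_null(pr)
})

test_that("projected changes are consistent with the extracted CDS", {
  set.seed(303)
  for (seed in 1:20) {
    rm <- random_gene_model(seed + 400)
    cds <- extract_cds(rm$genome, rm$model)
    cpos <- sample(rm$model$cds_length, 1)
    gpos <- cdna_to_genomic(rm$model, cpos)
    gbase <- substr(rm$genome$sequences$chrT, gpos, gpos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), gbase), 1)
    pr <- project(rm$model, "chrT", gpos, gbase, alt)
    expect_identical(pr$change$start, cpos)
    # the change's ref base must equal the CDS base at that position,
    # and applying it must place the strand-oriented alt there
    expect_identical(pr$change$ref, substr(cds, cpos, cpos))
    mutated <- apply_changes(cds, list(pr$change))
    expected_alt <- if (rm$model$strand == "-") revcomp(alt) else alt
    expect_identical(substr(mutated, cpos, cpos), expected_alt)
  }
})

test_that("minus-strand projection equals plus-strand on the mirrored model", {
  for (seed in 30:37) {
    rm <- random_gene_model(seed, strand = "-")
    contig <- rm$genome$sequences$chrT
    L <- nchar(contig)
    mirrored <- genome_ref(list(chrT = revcomp(contig)))
    segs <- rm$model$cds_segments
    segs_m <- cbind(L - segs[, 2] + 1L, L - segs[, 1] + 1L)
    model_m <- gene_model("TESTG", "chrT", "+", segs_m[order(segs_m[, 1]), ,
                                                       drop = FALSE])
    cpos <- sample(rm$model$cds_length, 1)
    gpos <- cdna_to_genomic(rm$model, cpos)
    gbase <- substr(contig, gpos, gpos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), gbase), 1)
    pr1 <- project(rm$model, "chrT", gpos, gbase, alt)
    gpos_m <- L - gpos + 1L
    pr2 <- project(model_m, "chrT", gpos_m, revcomp(gbase), revcomp(alt))
    expect_identical(pr1$change$hgvs_c, pr2$change$hgvs_c)
  }
})
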