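#' @title Workflow wrappers and the demonstration reference bundle
#'
#' @description Thin wrappers tying the modules into the two-part
#'   workflow: (1) baseline analysis of the reference genome against the
#'   conventional alleles, (2) per-sample variant projection, re-basing
#'   and diplotype calling, followed by cohort frequency comparison. The
#'   demonstration bundle is a fully synthetic genome whose nine divergent
#'   gene analogues reproduce the published baseline change sets
#'   (ACKR1 125A>G/Asp42Gly, RHD 1136C>T/Thr379Met, the GYPA combined-
#'   codon pair 71G>A+72T>G, ...) with deterministic construction.
#' @name workflow
NULL

#' Demonstration simulation config (study-scale synthetic cohort)
#'
#' Twelve gene analogues: the nine genes where the reference genome
#' diverges from its conventional allele, plus three non-divergent ones.
#' Cohort defaults mirror the study design: 250 samples of which a
#' dropout fraction of 0.18 yield no variants (the data-quality failures
#' excluded before analysis), and hypervariable genes carry incidental
#' synonymous variant load. Allele truth frequencies follow the study's
#' reported cohort frequencies where available (Duffy, Dombrock),
#' otherwise values realistic for an East-Asian cohort.
#'
#' @param seed RNG seed
#' @param n_samples cohort size
#' @param dropout_rate fraction of samples yielding an empty VCF
#' @return [simulation_config()]
#' @export
demo_simulation_config <- function(seed = 41L, n_samples = 250L,
                                   dropout_rate = 0.18) {
  al <- function(names, changes, freq, phen = rep("", length(names)))
    data.frame(allele_name = names, changes = changes, freq = freq,
               phenotype = phen, stringsAsFactors = FALSE)
  genes <- list(
    sim_gene("GYPA", 150L, strand = "-", n_segments = 2L,
             baseline_changes = c("38C>A", "59C>T", "71G>A", "72T>G", "93C>T"),
             pin = c("37" = "G", "39" = "A", "58" = "T", "60" = "A",
                     "70" = "G", "91" = "A", "92" = "C"),
             alleles = al("GYPA*01", "-", 1, "M+")),
    sim_gene("RHD", 1254L, n_segments = 3L,
             baseline_changes = "1136C>T",
             pin = c("1135" = "A", "1137" = "G"),
             alleles = al(c("RHD*01", "RHD*DAU0"), c("-", "1136C>T"),
                          c(0, 1), c("D+", "DAU0"))),
    sim_gene("RHCE", 150L,
             baseline_changes = "48G>C",
             pin = c("46" = "T", "47" = "G"),
             alleles = al(c("RHCE*01", "RHCE*01.01"), c("-", "48G>C"),
                          c(0, 1), c("c+e+", "weak e"))),
    sim_gene("FUT3", 360L, strand = "-", n_segments = 2L,
             baseline_changes = c("202T>C", "314C>T"),
             pin = c("203" = "G", "204" = "G", "313" = "A", "315" = "G"),
             alleles = al("FUT3*01", "-", 1, "Le(a-b-)"),
             extra_neutral_variant_rate = 0.10),
    sim_gene("ACKR1", 210L,
             baseline_changes = "125A>G",
             pin = c("124" = "G", "126" = "C"),
             alleles = al(c("FY*02", "FY*01", "FY*01.1000G"),
                          c("-", "125A>G", "125A>G;199C>T"),
                          c(0.0391, 0.9302, 0.0307),
                          c("Fy(b+)", "Fy(a+)", "Fy(a+)"))),
    sim_gene("SLC14A1", 858L, n_segments = 2L,
             baseline_changes = "838A>G",
             pin = c("839" = "A", "840" = "C"),
             alleles = al(c("JK*02", "JK*01"), c("-", "838A>G"),
                          c(0.53, 0.47), c("Jk(b+)", "Jk(a+)"))),
    sim_gene("ART4", 816L, strand = "-",
             baseline_changes = c("378C>T", "624T>C", "793A>G"),
             pin = c("376" = "T", "377" = "A", "622" = "C", "623" = "T",
                     "794" = "A", "795" = "T"),
             alleles = al(c("DO*01", "DO*02"),
                          c("-", "378C>T;624T>C;793A>G"),
                          c(0.0335, 0.9665), c("Do(a+)", "Do(b+)"))),
    sim_gene("CR1", 5916L, n_segments = 4L,
             baseline_changes = c("180G>A", "4828T>A", "5905G>A"),
             pin = c("178" = "C", "179" = "C", "4829" = "C", "4830" = "A",
                     "5906" = "C", "5907" = "T"),
             alleles = al("KN*01", "-", 1, "KN:1"),
             extra_neutral_variant_rate = 0.004),
    sim_gene("GCNT2", 828L,
             baseline_changes = "816G>C",
             pin = c("814" = "G", "815" = "A"),
             alleles = al(c("GCNT2*01", "GCNT2*02"), c("-", "816G>C"),
                          c(0.5, 0.5), c("I+", "I+")),
             extra_neutral_variant_rate = 0.04),
    sim_gene("BCAM", 240L,
             alleles = al(c("LU*02", "LU*01"), c("-", "230G>A"),
                          c(1, 0), c("Lu(b+)", "Lu(a+)"))),
    sim_gene("KEL", 600L, strand = "-",
             alleles = al(c("KEL*02", "KEL*01.01"), c("-", "578C>T"),
                          c(1, 0), c("k+", "K+"))),
    sim_gene("ICAM4", 90L,
             alleles = al("LW*05", "-", 1, "LW(a+)")))
  simulation_config(seed = seed, n_samples = n_samples, genes = genes,
                    dropout_rate = dropout_rate)
}

#' Build the demonstration reference bundle
#'
#' Deterministic: the same config always yields the same genome, models
#' and conventional CDSs.
#'
#' @param config a [simulation_config()]; defaults to
#'   [demo_simulation_config()]
#' @return see [build_synthetic_reference()]
#' @export
demo_reference_bundle <- function(config = demo_simulation_config()) {
  build_synthetic_reference(config)
}

#' Baseline command: genome vs conventional alleles
#'
#' @param bundle reference bundle (genome, models, conventionals,
#'   allele_defs) — from [build_synthetic_reference()] or assembled from
#'   files via the readers
#' @param out_tsv optional path for the Table-1-style TSV
#' @return the baseline table (invisibly written if `out_tsv` given)
#' @export
run_baseline <- function(bundle, out_tsv = NULL) {
  bl <- build_baseline_table(bundle$genome, bundle$models,
                             bundle$conventionals, bundle$allele_defs)
  if (!is.null(out_tsv)) write_baseline_table(bl, out_tsv)
  bl
}

#' Call command: VCF -> per-sample diplotype calls
#'
#' @param vcf_path VCF file (single- or multi-sample)
#' @param bundle reference bundle
#' @param baseline baseline table (computed from the bundle when NULL)
#' @param out_prefix optional path prefix; writes `<prefix>_calls.tsv`,
#'   `<prefix>_excluded.txt`, `<prefix>_gene_summary.tsv`
#' @param ... passed to [call_cohort()]
#' @return [call_cohort()] result
#' @export
run_call <- function(vcf_path, bundle, baseline = NULL, out_prefix = NULL, ...) {
  if (is.null(baseline)) baseline <- run_baseline(bundle)
  vcf <- load_vcf(vcf_path, bundle$models, genome = bundle$genome)
  res <- call_cohort(vcf, baseline, bundle$allele_defs, bundle$models, ...)
  ord <- order(res$calls$sample_id, res$calls$gene_symbol)
  res$calls <- res$calls[ord, , drop = FALSE]
  if (!is.null(out_prefix)) {
    utils::write.table(res$calls, paste0(out_prefix, "_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(res$excluded, paste0(out_prefix, "_excluded.txt"))
    utils::write.table(res$gene_summary, paste0(out_prefix, "_gene_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' Compare command: study counts vs external frequency sources
#'
#' @param study study count table ([count_alleles()] or
#'   [counts_from_percent()])
#' @param sources external sources ([read_frequency_sources()])
#' @param out_prefix optional; writes `<prefix>_comparisons.tsv` and
#'   `<prefix>_grid.tsv`
#' @param ... passed to [compare_all()]
#' @return list(comparisons, grid)
#' @export
run_compare <- function(study, sources, out_prefix = NULL, ...) {
  comparisons <- compare_all(study, sources, ...)
  grid <- render_comparison_grid(study, comparisons)
  if (!is.null(out_prefix)) {
    utils::write.table(comparisons, paste0(out_prefix, "_comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(grid, paste0(out_prefix, "_grid.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(comparisons = comparisons, grid = grid)
}

#' Path to a shipped reference fixture
#'
#' @param name fixture file name under `extdata/`
#' @return absolute path
#' @export
bgtyper_fixture <- function(name) {
  p <- system.file("extdata", name, package = "bgtyper")
  if (!nzchar(p)) stop("fixture not found: ", name)
  p
}
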