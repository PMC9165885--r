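#' @title Synthetic references and cohorts with truth tables
#'
#' @description The cohort this pipeline was designed around is
#'   access-restricted, so every stage is exercised instead on fully
#'   synthetic data: random conventional CDSs with planted baseline
#'   differences embedded in a synthetic genome, and diploid cohorts drawn
#'   from configured allele frequencies under Hardy-Weinberg independence,
#'   written as ordinary multi-sample VCFs against that genome. A truth
#'   table accompanies every cohort so calls can be scored exactly.
#'   Sample-level dropout (a sample yielding no variants at all) emulates
#'   the data-quality failures seen in low-coverage WGS cohorts; neutral
#'   synonymous third-position variants emulate the incidental variant
#'   load of hypervariable genes.
#' @name synthetic_data
NULL

#' Per-gene specification for the simulator
#'
#' @param gene_symbol gene name
#' @param cds_length CDS length, multiple of 3
#' @param strand "+" or "-"
#' @param n_segments number of CDS segments (introns are synthesized
#'   between them)
#' @param baseline_changes character vector of HGVS cDNA substitutions to
#'   plant in the synthetic genome relative to the conventional CDS
#' @param alleles data.frame: allele_name, changes (semicolon-joined HGVS
#'   substitutions relative to the conventional CDS, "-" for the
#'   conventional allele), freq (truth frequencies summing to 1),
#'   optionally phenotype
#' @param extra_neutral_variant_rate per-site probability of an incidental
#'   synonymous third-position het variant (0 = off)
#' @param pin named character vector (cDNA position -> base) fixing
#'   additional conventional-CDS bases, so planted changes land in codons
#'   with a chosen amino-acid context
#' @return list of class `sim_gene`
#' @export
sim_gene <- function(gene_symbol, cds_length, strand = "+", n_segments = 1L,
                     baseline_changes = character(),
                     alleles = data.frame(allele_name = paste0(gene_symbol, "*01"),
                                          changes = "-", freq = 1),
                     extra_neutral_variant_rate = 0, pin = character()) {
  stopifnot(cds_length %% 3 == 0, cds_length >= 3)
  if (abs(sum(alleles$freq) - 1) > 1e-9)
    stop(gene_symbol, ": allele frequencies must sum to 1")
  if (is.null(alleles$phenotype)) alleles$phenotype <- ""
  all_changes <- c(lapply(baseline_changes, parse_hgvs_c),
                   unlist(lapply(alleles$changes, parse_hgvs_list),
                          recursive = FALSE))
  for (ch in all_changes) {
    if (ch$kind != "substitution")
      stop(gene_symbol, ": the simulator plants substitutions only")
    if (ch$end > cds_length)
      stop(gene_symbol, ": change ", ch$hgvs_c, " beyond CDS length ", cds_length)
  }
  structure(list(gene_symbol = gene_symbol, cds_length = as.integer(cds_length),
                 strand = strand, n_segments = as.integer(n_segments),
                 baseline_changes = baseline_changes, alleles = alleles,
                 extra_neutral_variant_rate = extra_neutral_variant_rate,
                 pin = pin),
            class = "sim_gene")
}

#' Simulation configuration
#'
#' @param seed integer RNG seed; identical seed + config give byte-identical
#'   outputs
#' @param n_samples cohort size
#' @param genes list of [sim_gene()] specs
#' @param dropout_rate probability that a sample yields an empty VCF
#'   (a data-quality failure excluded at the cohort level)
#' @return list of class `sim_config`
#' @export
simulation_config <- function(seed, n_samples, genes, dropout_rate = 0) {
  stopifnot(n_samples >= 1, dropout_rate >= 0, dropout_rate <= 1)
  names(genes) <- vapply(genes, function(g) g$gene_symbol, "")
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 genes = genes, dropout_rate = dropout_rate),
            class = "sim_config")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_cds <- function(len, constraints) {
  # constraints: named (position) vector of required bases
  n_codons <- len %/% 3L
  bases <- character(len)
  for (ci in seq_len(n_codons)) {
    pos <- (3L * ci - 2L):(3L * ci)
    repeat {
      codon <- if (ci == 1L) c("A", "T", "G") else
        sample(c("A", "C", "G", "T"), 3L, replace = TRUE)
      fixed <- as.character(pos) %in% names(constraints)
      codon[fixed] <- constraints[as.character(pos[fixed])]
      if (!paste(codon, collapse = "") %in% STOP_CODONS) break
      if (all(fixed)) break  # fully constrained; accept as given
    }
    bases[pos] <- codon
  }
  paste(bases, collapse = "")
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Build a synthetic reference bundle from a simulation config
#'
#' Per gene: generates a random conventional CDS (seeded) honouring the
#' reference bases of every configured change, embeds it in a contig with
#' flanking and intronic sequence, then applies the baseline changes to
#' produce the genome's copy — so the genome differs from the conventional
#' allele exactly at the planted sites.
#'
#' @param config [simulation_config()]
#' @return list: genome (`genome_ref`), models, conventionals,
#'   allele_defs (data.frame), expected_baseline (named list of
#'   `nt_change` lists), config
#' @export
build_synthetic_reference <- function(config) {
  set.seed(config$seed)
  sequences <- list(); models <- list(); conventionals <- list()
  defs <- list(); expected <- list()
  intron_len <- 50L; flank <- 30L
  for (g in config$genes) {
    all_changes <- c(lapply(g$baseline_changes, parse_hgvs_c),
                     unlist(lapply(g$alleles$changes, parse_hgvs_list),
                            recursive = FALSE))
    constraints <- g$pin
    for (ch in all_changes) {
      key <- as.character(ch$start)
      if (key %in% names(constraints) && constraints[key] != ch$ref)
        stop(g$gene_symbol, ": conflicting reference bases at cDNA ", ch$start)
      constraints[key] <- ch$ref
    }
    conv_cds <- random_cds(g$cds_length, constraints)
    genome_cds <- apply_changes(conv_cds, parse_hgvs_list(g$baseline_changes))

    # split into segments and lay out a plus-strand cassette
    cuts <- unique(round(seq(0, g$cds_length, length.out = g$n_segments + 1L)))
    seg_len <- diff(cuts)
    layout <- random_seq(flank)
    segs <- matrix(0L, nrow = length(seg_len), ncol = 2L)
    off <- 0L
    for (i in seq_along(seg_len)) {
      segs[i, 1] <- nchar(layout) + 1L
      layout <- paste0(layout, substr(genome_cds, off + 1L, off + seg_len[i]))
      segs[i, 2] <- nchar(layout)
      off <- off + seg_len[i]
      if (i < length(seg_len)) layout <- paste0(layout, random_seq(intron_len))
    }
    layout <- paste0(layout, random_seq(flank))
    if (g$strand == "-") {
      L <- nchar(layout)
      layout <- revcomp(layout)
      segs <- cbind(L - segs[, 2] + 1L, L - segs[, 1] + 1L)
      segs <- segs[order(segs[, 1]), , drop = FALSE]
    }
    contig <- paste0("chr_", g$gene_symbol)
    sequences[[contig]] <- layout
    models[[g$gene_symbol]] <- gene_model(g$gene_symbol, contig, g$strand, segs)
    conv_name <- g$alleles$allele_name[
      vapply(g$alleles$changes, function(s) !length(parse_hgvs_list(s)), TRUE)]
    if (length(conv_name) != 1L)
      stop(g$gene_symbol, ": exactly one allele must have an empty change set")
    conventionals[[g$gene_symbol]] <- suppressWarnings(
      conventional_reference(g$gene_symbol, conv_name, conv_cds,
                             phenotype = g$alleles$phenotype[
                               g$alleles$allele_name == conv_name]))
    defs[[g$gene_symbol]] <- data.frame(
      gene_symbol = g$gene_symbol, allele_name = g$alleles$allele_name,
      defining_changes = ifelse(g$alleles$changes == "", "-", g$alleles$changes),
      phenotype = g$alleles$phenotype, source = "synthetic",
      stringsAsFactors = FALSE)
    expected[[g$gene_symbol]] <- parse_hgvs_list(g$baseline_changes)
  }
  list(genome = genome_ref(sequences), models = models,
       conventionals = conventionals,
       allele_defs = validate_allele_definitions(do.call(rbind, defs)),
       expected_baseline = expected, config = config)
}

neutral_sites <- function(g, genome_cds, blocked) {
  # third codon positions where some substitution of the genome base is
  # synonymous and the site is free of configured changes
  third <- seq.int(3L, g$cds_length, by = 3L)
  setdiff(third, blocked)
}

synonymous_alt <- function(genome_cds, pos) {
  ci <- (pos - 1L) %/% 3L + 1L
  codon <- substr(genome_cds, 3L * ci - 2L, 3L * ci)
  base <- substr(genome_cds, pos, pos)
  within <- pos - (3L * ci - 3L)
  aa <- Biostrings::GENETIC_CODE[[codon]]
  for (b in sample(setdiff(c("A", "C", "G", "T"), base))) {
    alt_codon <- codon
    substr(alt_codon, within, within) <- b
    if (!alt_codon %in% STOP_CODONS &&
        Biostrings::GENETIC_CODE[[alt_codon]] == aa) return(b)
  }
  NA_character_
}

#' Simulate a diploid cohort against a synthetic reference bundle
#'
#' Per sample and gene, two allele names are drawn independently from the
#' configured truth frequencies (Hardy-Weinberg). Each haplotype's change
#' set is superimposed on the conventional CDS; genotypes are then written
#' relative to the synthetic GENOME, so a sample homozygous for the
#' baseline-implied allele produces no record at baseline sites, and a
#' conventional-allele carrier produces a record restoring the
#' conventional base. Incidental synonymous variants and sample dropout
#' are added per the config. Records are sorted by contig and position and
#' REF is always the genome base.
#'
#' @param config [simulation_config()]
#' @param bundle output of [build_synthetic_reference()]
#' @param vcf_path where to write the multi-sample VCF (default: not
#'   written, lines returned)
#' @return list: truth (data.frame sample_id, gene_symbol, allele1,
#'   allele2, dropout), vcf_lines (character), vcf_path (if written),
#'   truth_freq (configured per-gene frequency map)
#' @export
simulate_cohort <- function(config, bundle, vcf_path = NULL) {
  set.seed(config$seed + 10007L)
  samples <- sprintf("S%04d", seq_len(config$n_samples))
  dropout <- stats::runif(config$n_samples) < config$dropout_rate

  truth <- list()
  # records[[contig]][[pos]] = list(ref=, alts=character(), gt=named int pairs)
  rec <- new.env(parent = emptyenv())

  add_allele_copy <- function(contig, gpos, ref_top, alt_top, sample, hap) {
    key <- paste0(contig, ":", gpos)
    r <- rec[[key]]
    if (is.null(r))
      r <- list(contig = contig, pos = gpos, ref = ref_top,
                alts = character(),
                hap1 = integer(0), hap2 = integer(0))
    if (!alt_top %in% r$alts) r$alts <- c(r$alts, alt_top)
    ai <- match(alt_top, r$alts)
    if (hap == 1L) r$hap1[[sample]] <- ai else r$hap2[[sample]] <- ai
    rec[[key]] <- r
  }

  for (gi in seq_along(config$genes)) {
    g <- config$genes[[gi]]
    model <- bundle$models[[g$gene_symbol]]
    conv <- bundle$conventionals[[g$gene_symbol]]$cds
    genome_cds <- apply_changes(conv, parse_hgvs_list(g$baseline_changes))
    contig <- model$contig
    hap_sets <- lapply(g$alleles$changes, parse_hgvs_list)
    names(hap_sets) <- g$alleles$allele_name
    blocked <- unique(c(
      vapply(parse_hgvs_list(g$baseline_changes), function(c) c$start, integer(1)),
      unlist(lapply(hap_sets, function(s)
        vapply(s, function(c) c$start, integer(1))))))
    free3 <- neutral_sites(g, genome_cds, blocked)

    base_at <- function(cds, p) substr(cds, p, p)
    top_strand <- function(b) if (model$strand == "-") revcomp(b) else b

    for (si in seq_along(samples)) {
      pair <- sample(g$alleles$allele_name, 2L, replace = TRUE,
                     prob = g$alleles$freq)
      truth[[length(truth) + 1L]] <- data.frame(
        sample_id = samples[si], gene_symbol = g$gene_symbol,
        allele1 = pair[1], allele2 = pair[2], dropout = dropout[si],
        stringsAsFactors = FALSE)
      if (dropout[si]) next
      for (hap in 1:2) {
        hap_cds <- apply_changes(conv, hap_sets[[pair[hap]]])
        sites <- unique(c(blocked))
        for (p in sites) {
          hb <- base_at(hap_cds, p); gb <- base_at(genome_cds, p)
          if (hb != gb)
            add_allele_copy(contig, cdna_to_genomic(model, p),
                            top_strand(gb), top_strand(hb), samples[si], hap)
        }
      }
      if (g$extra_neutral_variant_rate > 0 && length(free3)) {
        hit <- free3[stats::runif(length(free3)) < g$extra_neutral_variant_rate]
        for (p in hit) {
          alt <- synonymous_alt(genome_cds, p)
          if (is.na(alt)) next
          add_allele_copy(contig, cdna_to_genomic(model, p),
                          top_strand(base_at(genome_cds, p)), top_strand(alt),
                          samples[si], sample(1:2, 1L))
        }
      }
    }
  }

  truth <- do.call(rbind, truth)
  keys <- ls(rec)
  lines <- c("##fileformat=VCFv4.2",
             paste0("##contig=<ID=", names(bundle$genome$sequences), ",length=",
                    nchar(unlist(bundle$genome$sequences)), ">"),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  if (length(keys)) {
    recs <- lapply(keys, function(k) rec[[k]])
    ord <- order(vapply(recs, function(r) r$contig, ""),
                 vapply(recs, function(r) r$pos, integer(1)))
    for (r in recs[ord]) {
      gt <- vapply(samples, function(s) {
        a1 <- if (s %in% names(r$hap1)) r$hap1[[s]] else 0L
        a2 <- if (s %in% names(r$hap2)) r$hap2[[s]] else 0L
        paste0(a1, "/", a2)
      }, "")
      lines <- c(lines, paste(c(r$contig, r$pos, ".", r$ref,
                                paste(r$alts, collapse = ","), ".", "PASS",
                                ".", "GT", gt), collapse = "\t"))
    }
  }
  if (!is.null(vcf_path)) writeLines(lines, vcf_path)
  truth_freq <- lapply(config$genes, function(g)
    stats::setNames(g$alleles$freq, g$alleles$allele_name))
  list(truth = truth, vcf_lines = lines, vcf_path = vcf_path,
       truth_freq = truth_freq)
}

#' Empirical truth frequencies of a simulated cohort
#'
#' @param truth truth table from [simulate_cohort()]
#' @param include_dropout count dropout samples too (default FALSE, to
#'   match the cohort-level exclusion of zero-variant samples)
#' @return data.frame gene_symbol, allele_name, count, n_alleles, frequency
#' @export
truth_frequencies <- function(truth, include_dropout = FALSE) {
  tt <- if (include_dropout) truth else truth[!truth$dropout, , drop = FALSE]
  rows <- list()
  for (g in unique(tt$gene_symbol)) {
    al <- c(tt$allele1[tt$gene_symbol == g], tt$allele2[tt$gene_symbol == g])
    tab <- table(al)
    for (a in names(tab))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_symbol = g, allele_name = a, count = as.integer(tab[[a]]),
        n_alleles = length(al), frequency = tab[[a]] / length(al),
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write an allele-definition table as TSV
#'
#' @param defs allele-definition data.frame
#' @param path output path
#' @export
write_allele_definitions <- function(defs, path) {
  utils::write.table(defs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
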