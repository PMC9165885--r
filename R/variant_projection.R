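#' @title Projecting VCF variants into cDNA space
#'
#' @description The pipeline consumes VCF — any caller can feed it — and
#'   restricts records to the CDS of the target genes, splitting
#'   multi-allelic records and mapping each retained variant onto the
#'   spliced, strand-oriented CDS so it can be expressed in HGVS cDNA
#'   notation. Genotypes are treated as unphased dosages throughout: the
#'   data this design targets cannot distinguish the two haplotypes.
#' @name variant_projection
NULL

parse_gt_dosage <- function(gt, alt_index) {
  # unphased dosage of allele `alt_index` in a GT string; phase bars are
  # ignored; "." alleles drop out of the dosage (and of the ploidy)
  alleles <- strsplit(gsub("\\|", "/", gt), "/")[[1]]
  alleles <- alleles[alleles != "."]
  list(dosage = sum(alleles == as.character(alt_index)),
       ploidy = length(alleles))
}

#' Load per-sample variants from a VCF, restricted to gene CDS
#'
#' Only records whose position overlaps a CDS segment of some gene model
#' are retained; multi-allelic records are split into one record per alt
#' allele. Records without a usable GT are skipped with a warning. When a
#' genome is supplied, REF fields are checked against it (warning on
#' mismatch).
#'
#' @param path VCF 4.x file (plain or bgzipped), single- or multi-sample
#' @param models named list of `gene_model`
#' @param genome optional `genome_ref` for REF consistency checks
#' @return list with `variants`: data.frame (sample_id, contig, pos, ref,
#'   alt, dosage, ploidy), dosage >= 1 rows only; `n_outside`: count of
#'   records dropped by the coding-region filter; `samples`: all sample
#'   names seen in the VCF
#' @export
load_vcf <- function(path, models, genome = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- data.frame(sample_id = character(), contig = character(),
                      pos = integer(), ref = character(), alt = character(),
                      dosage = integer(), ploidy = integer(),
                      stringsAsFactors = FALSE)
  gt_mat <- tryCatch(vcfR::extract.gt(v, element = "GT"),
                     error = function(e) NULL)
  samples <- colnames(v@gt)[-1]
  if (nrow(v@fix) == 0L)
    return(list(variants = empty, n_outside = 0L, samples = samples %||% character()))
  fix <- as.data.frame(v@fix[, 1:8, drop = FALSE], stringsAsFactors = FALSE)
  pos <- as.integer(fix$POS)

  in_cds <- rep(FALSE, length(pos))
  for (m in models) {
    hit <- fix$CHROM == m$contig &
      Reduce(`|`, lapply(seq_len(nrow(m$cds_segments)), function(i)
        pos >= m$cds_segments[i, 1] & pos <= m$cds_segments[i, 2]))
    in_cds <- in_cds | hit
  }
  n_outside <- sum(!in_cds)

  if (!is.null(genome)) {
    for (i in which(in_cds)) {
      ctg <- genome$sequences[[fix$CHROM[i]]]
      if (!is.null(ctg)) {
        have <- substr(ctg, pos[i], pos[i] + nchar(fix$REF[i]) - 1L)
        if (have != fix$REF[i])
          warning("REF mismatch at ", fix$CHROM[i], ":", pos[i],
                  " (VCF ", fix$REF[i], ", genome ", have, ")")
      }
    }
  }

  rows <- list()
  for (i in which(in_cds)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (s in samples) {
      gt <- if (!is.null(gt_mat)) gt_mat[i, s] else NA_character_
      if (is.na(gt) || !nzchar(gt)) next
      for (k in seq_along(alts)) {
        if (alts[k] %in% c(".", "*")) next
        d <- parse_gt_dosage(gt, k)
        if (d$dosage >= 1L)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = s, contig = fix$CHROM[i], pos = pos[i],
            ref = fix$REF[i], alt = alts[k],
            dosage = d$dosage, ploidy = d$ploidy,
            stringsAsFactors = FALSE)
      }
    }
  }
  variants <- if (length(rows)) do.call(rbind, rows) else empty
  list(variants = variants, n_outside = n_outside, samples = samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Project a genomic variant onto a gene's cDNA
#'
#' Maps the variant's position through the gene model; for strand "-"
#' genes the ref/alt bases are reverse complemented and multi-base changes
#' re-anchored so the HGVS string reads in CDS orientation. Variants that
#' span a CDS/intron boundary are rejected with a "boundary" warning;
#' variants entirely outside the CDS return NULL.
#'
#' @param model `gene_model`
#' @param contig,pos,ref,alt the genomic variant (VCF conventions: for
#'   indels, pos anchors the first REF base)
#' @return list(gene_symbol, change = `nt_change`) or NULL
#' @export
project <- function(model, contig, pos, ref, alt) {
  if (contig != model$contig) return(NULL)
  ref <- toupper(ref); alt <- toupper(alt)

  # strip the shared prefix base of VCF-style indel anchoring
  if (nchar(ref) != nchar(alt) && nchar(ref) >= 1L && nchar(alt) >= 1L &&
      substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    pos <- pos + 1L
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
  }

  if (nchar(ref) == 0L) {                       # pure insertion after pos-1
    c_before <- genomic_to_cdna(model, pos - 1L)
    c_after <- genomic_to_cdna(model, pos)
    if (is.na(c_before) && is.na(c_after)) return(NULL)
    if (is.na(c_before) || is.na(c_after) || abs(c_after - c_before) != 1L) {
      warning(model$gene_symbol, ": insertion at ", contig, ":", pos,
              " spans a CDS boundary; rejected")
      return(NULL)
    }
    ins <- if (model$strand == "-") revcomp(alt) else alt
    start <- min(c_before, c_after)
    return(list(gene_symbol = model$gene_symbol,
                change = nt_change("insertion", start, start + 1L, alt = ins)))
  }

  gpos <- seq.int(pos, pos + nchar(ref) - 1L)
  cpos <- genomic_to_cdna(model, gpos)
  if (all(is.na(cpos))) return(NULL)
  if (any(is.na(cpos)) || (length(cpos) > 1L && any(abs(diff(cpos)) != 1L))) {
    warning(model$gene_symbol, ": variant at ", contig, ":", pos,
            " spans a CDS/intron boundary; rejected")
    return(NULL)
  }
  if (model$strand == "-") {
    ref <- revcomp(ref)
    alt <- if (nchar(alt)) revcomp(alt) else alt
  }
  start <- min(cpos); end <- max(cpos)
  change <- if (nchar(alt) == 0L) {
    nt_change("deletion", start, end, ref = ref)
  } else if (nchar(ref) == 1L && nchar(alt) == 1L) {
    nt_change("substitution", start, ref = ref, alt = alt)
  } else {
    nt_change("delins", start, end, ref = ref, alt = alt)
  }
  list(gene_symbol = model$gene_symbol, change = change)
}

#' Project all of a sample's variants for the modelled genes
#'
#' @param models named list of `gene_model`
#' @param variants data.frame as produced by [load_vcf()] (one sample's rows)
#' @return data.frame: gene_symbol, hgvs_c, dosage (alt copies), ploidy
#' @export
project_sample <- function(models, variants) {
  rows <- list()
  if (nrow(variants)) for (i in seq_len(nrow(variants))) {
    for (m in models) {
      pr <- project(m, variants$contig[i], variants$pos[i],
                    variants$ref[i], variants$alt[i])
      if (!is.null(pr))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_symbol = pr$gene_symbol, hgvs_c = pr$change$hgvs_c,
          dosage = variants$dosage[i], ploidy = variants$ploidy[i],
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(gene_symbol = character(), hgvs_c = character(),
                  dosage = integer(), ploidy = integer(),
                  stringsAsFactors = FALSE)
}
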