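#' Reference genome container
#'
#' A minimal in-memory genome: a named list of uppercase nucleotide
#' strings, one per contig. Real data is read with [read_genome_fasta()];
#' tests and the simulator build small synthetic genomes directly.
#'
#' @param sequences named character vector or list, contig -> sequence
#' @return object of class `genome_ref`
#' @export
genome_ref <- function(sequences) {
  sequences <- as.list(sequences)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("contig names must be present and unique")
  sequences <- lapply(sequences, toupper)
  ok <- vapply(sequences, function(s) nzchar(s) && !grepl("[^ACGTN]", s), TRUE)
  if (!all(ok))
    stop("sequences must be non-empty over the A/C/G/T/N alphabet: ",
         paste(names(sequences)[!ok], collapse = ", "))
  structure(list(sequences = sequences), class = "genome_ref")
}

#' Read a genome from FASTA
#'
#' @param path multi-record FASTA (folded or unfolded)
#' @return `genome_ref`
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  genome_ref(stats::setNames(as.character(ss), nm))
}

#' Write a genome to FASTA
#'
#' @param genome `genome_ref`
#' @param path output path
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome$sequences))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Gene model: one transcript's CDS segments on a contig
#'
#' Segments are 1-based inclusive genomic intervals, sorted ascending and
#' non-overlapping; the spliced CDS read in transcription order (reverse
#' complemented for strand "-") must have length a multiple of 3. UTRs are
#' not modelled: analysis is restricted to coding regions.
#'
#' @param gene_symbol e.g. "ACKR1"
#' @param contig contig name
#' @param strand "+" or "-"
#' @param cds_segments two-column matrix (start, end) or list of c(start, end)
#' @param transcript_id transcript identifier recording which splicing
#'   pattern was chosen for the gene
#' @return object of class `gene_model`
#' @export
gene_model <- function(gene_symbol, contig, strand, cds_segments,
                       transcript_id = paste0(gene_symbol, ".tx1")) {
  if (is.list(cds_segments))
    cds_segments <- do.call(rbind, cds_segments)
  cds_segments <- matrix(as.integer(cds_segments), ncol = 2L,
                         dimnames = list(NULL, c("start", "end")))
  stopifnot(strand %in% c("+", "-"), nrow(cds_segments) >= 1L,
            all(cds_segments[, 1] <= cds_segments[, 2]))
  ord <- order(cds_segments[, 1])
  cds_segments <- cds_segments[ord, , drop = FALSE]
  if (nrow(cds_segments) > 1L &&
      any(cds_segments[-1L, 1] <= cds_segments[-nrow(cds_segments), 2]))
    stop(gene_symbol, ": CDS segments overlap")
  len <- sum(cds_segments[, 2] - cds_segments[, 1] + 1L)
  if (len %% 3L != 0L)
    stop(gene_symbol, ": total CDS length ", len, " is not a multiple of 3")
  structure(list(gene_symbol = gene_symbol, transcript_id = transcript_id,
                 contig = contig, strand = strand,
                 cds_segments = cds_segments, cds_length = len),
            class = "gene_model")
}

# genomic positions of CDS bases in transcription (cDNA) order
cds_positions <- function(model) {
  pos <- unlist(lapply(seq_len(nrow(model$cds_segments)), function(i)
    seq.int(model$cds_segments[i, 1], model$cds_segments[i, 2])))
  if (model$strand == "-") rev(pos) else pos
}

#' Extract the spliced CDS of a gene from a genome
#'
#' Concatenates the CDS segments in transcription order; for strand "-",
#' the reverse complement of the descending-ordered concatenation. N bases
#' are retained with a warning since downstream diffs at those sites are
#' unreliable.
#'
#' @param genome `genome_ref`
#' @param model `gene_model`
#' @return nucleotide string of length `model$cds_length`
#' @export
extract_cds <- function(genome, model) {
  seq <- genome$sequences[[model$contig]]
  if (is.null(seq))
    stop("contig ", model$contig, " not in genome")
  if (any(model$cds_segments[, 2] > nchar(seq)) || any(model$cds_segments[, 1] < 1L))
    stop(model$gene_symbol, ": CDS segment out of contig bounds")
  parts <- vapply(seq_len(nrow(model$cds_segments)), function(i)
    substr(seq, model$cds_segments[i, 1], model$cds_segments[i, 2]), "")
  cds <- paste(parts, collapse = "")
  if (model$strand == "-") cds <- revcomp(cds)
  if (grepl("N", cds, fixed = TRUE))
    warning(model$gene_symbol, ": CDS contains N bases; diffs at those sites are unreliable")
  cds
}

#' Map a genomic position to a cDNA (CDS) position
#'
#' @param model `gene_model`
#' @param genomic_pos 1-based genomic position
#' @return 1-based position on the spliced, strand-oriented CDS, or NA when
#'   the position falls outside every CDS segment
#' @export
genomic_to_cdna <- function(model, genomic_pos) {
  match(as.integer(genomic_pos), cds_positions(model))
}

#' Map a cDNA (CDS) position back to the genome
#'
#' Inverse of [genomic_to_cdna()] over CDS positions.
#'
#' @param model `gene_model`
#' @param cdna_pos 1-based CDS position
#' @return 1-based genomic position
#' @export
cdna_to_genomic <- function(model, cdna_pos) {
  cdna_pos <- as.integer(cdna_pos)
  if (any(cdna_pos < 1L | cdna_pos > model$cds_length))
    stop("cDNA position out of range 1..", model$cds_length)
  cds_positions(model)[cdna_pos]
}

#' Conventional ISBT reference allele of a gene
#'
#' The conventional reference allele is the ISBT-designated baseline
#' against which all other alleles' defining changes are expressed (e.g.
#' FY*02 for ACKR1). Its CDS need not equal the reference genome's copy.
#'
#' @param gene_symbol gene name
#' @param allele_name ISBT allele string, e.g. "FY*02"
#' @param cds nucleotide string, length a multiple of 3
#' @param phenotype phenotype string, e.g. "Fy(b+)"
#' @return object of class `conventional_reference`
#' @export
conventional_reference <- function(gene_symbol, allele_name, cds, phenotype = "") {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L)
    stop(gene_symbol, ": conventional CDS length not a multiple of 3")
  if (substr(cds, 1L, 3L) != "ATG")
    warning(gene_symbol, ": conventional CDS does not start with ATG")
  structure(list(gene_symbol = gene_symbol, allele_name = allele_name,
                 cds = cds, phenotype = phenotype),
            class = "conventional_reference")
}

#' Read gene models from a TSV
#'
#' Columns: gene_symbol, transcript_id, contig, strand, cds_segments
#' (comma-separated "start-end" pairs, 1-based inclusive).
#'
#' @param path TSV path
#' @return named list of `gene_model`
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_symbol", "transcript_id", "contig", "strand", "cds_segments")
  if (!all(need %in% names(df)))
    stop("gene-model TSV must have columns: ", paste(need, collapse = ", "))
  models <- lapply(seq_len(nrow(df)), function(i) {
    segs <- strsplit(strsplit(df$cds_segments[i], ",")[[1]], "-")
    segs <- do.call(rbind, lapply(segs, as.integer))
    gene_model(df$gene_symbol[i], df$contig[i], df$strand[i], segs,
               transcript_id = df$transcript_id[i])
  })
  stats::setNames(models, df$gene_symbol)
}

#' Write gene models to a TSV
#'
#' @param models list of `gene_model`
#' @param path output path
#' @export
write_gene_models <- function(models, path) {
  df <- do.call(rbind, lapply(models, function(m) data.frame(
    gene_symbol = m$gene_symbol, transcript_id = m$transcript_id,
    contig = m$contig, strand = m$strand,
    cds_segments = paste(paste0(m$cds_segments[, 1], "-", m$cds_segments[, 2]),
                         collapse = ","),
    stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
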