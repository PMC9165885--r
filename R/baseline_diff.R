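#' @title Baseline differences between conventional alleles and a genome
#'
#' @description The reference genome's copy of a blood-group gene is not,
#'   in general, the conventional ISBT reference allele: for nine of the 41
#'   genes analysed here the genome carries the non-conventional state at
#'   one or more cDNA sites. Variant callers report against the genome, so
#'   every downstream allele call must first know this baseline difference
#'   set. This module computes it per gene and predicts protein effects.
#' @name baseline_diff
NULL

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", "*" = "Ter", X = "Xaa")

translate_cds <- function(cds) {
  n <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"  # codons containing N
  unname(aa)
}

check_alphabet <- function(x, what) {
  if (grepl("[^ACGTN]", x))
    stop(what, " contains characters outside A/C/G/T/N")
  invisible(x)
}

# classify one run of aligned difference into an nt_change;
# conv_start = conventional position of the first consumed base in the run
classify_run <- function(ref, alt, conv_start, conv_before) {
  if (!nzchar(ref)) {
    if (conv_before < 1L)
      stop("insertion before the first CDS base is not representable")
    nt_change("insertion", conv_before, conv_before + 1L, alt = alt)
  } else if (!nzchar(alt)) {
    nt_change("deletion", conv_start, conv_start + nchar(ref) - 1L, ref = ref)
  } else if (nchar(ref) == 1L && nchar(alt) == 1L) {
    nt_change("substitution", conv_start, ref = ref, alt = alt)
  } else {
    nt_change("delins", conv_start, conv_start + nchar(ref) - 1L,
              ref = ref, alt = alt)
  }
}

diff_aligned <- function(pat, sub) {
  p <- strsplit(pat, "")[[1]]
  s <- strsplit(sub, "")[[1]]
  changes <- list()
  conv_pos <- 0L           # last consumed conventional position
  i <- 1L
  while (i <= length(p)) {
    if (p[i] == s[i]) { conv_pos <- conv_pos + 1L; i <- i + 1L; next }
    j <- i
    while (j <= length(p) && p[j] != s[j]) j <- j + 1L
    ref <- paste(p[i:(j - 1L)][p[i:(j - 1L)] != "-"], collapse = "")
    alt <- paste(s[i:(j - 1L)][s[i:(j - 1L)] != "-"], collapse = "")
    changes[[length(changes) + 1L]] <-
      classify_run(ref, alt, conv_pos + 1L, conv_pos)
    conv_pos <- conv_pos + nchar(ref)
    i <- j
  }
  changes
}

#' Diff two coding sequences at the cDNA level
#'
#' Equal-length sequences are compared positionally; runs of adjacent
#' differing positions merge into one delins change (the conventional
#' "201_202delACinsGT" rendering). Unequal lengths are first globally aligned
#' (Needleman-Wunsch; match +1, mismatch -1, gap open -4, gap extend -1)
#' and the alignment walked the same way. The returned change list applied
#' to `conventional_cds` reproduces `target_cds` exactly (asserted).
#'
#' @param conventional_cds conventional reference CDS
#' @param target_cds the sequence to express relative to it
#' @return list of `nt_change`, sorted by start
#' @export
diff_cds <- function(conventional_cds, target_cds) {
  conventional_cds <- toupper(conventional_cds)
  target_cds <- toupper(target_cds)
  stopifnot(nzchar(conventional_cds), nzchar(target_cds))
  check_alphabet(conventional_cds, "conventional CDS")
  check_alphabet(target_cds, "target CDS")
  if (nchar(conventional_cds) == nchar(target_cds)) {
    changes <- diff_aligned(conventional_cds, target_cds)
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(gsub("N", "A", conventional_cds)),
      Biostrings::DNAString(gsub("N", "A", target_cds)),
      type = "global", substitutionMatrix = mat,
      gapOpening = 4, gapExtension = 1)
    pat <- as.character(Biostrings::alignedPattern(aln))
    sub <- as.character(Biostrings::alignedSubject(aln))
    # restore any N masked for alignment
    pat <- restore_gapped(pat, conventional_cds)
    sub <- restore_gapped(sub, target_cds)
    changes <- diff_aligned(pat, sub)
  }
  stopifnot(identical(apply_changes(conventional_cds, changes), target_cds))
  changes
}

restore_gapped <- function(aligned, original) {
  a <- strsplit(aligned, "")[[1]]
  a[a != "-"] <- strsplit(original, "")[[1]]
  paste(a, collapse = "")
}

#' Predict amino-acid effects of a cDNA change set
#'
#' All changes are applied jointly and both sequences translated with the
#' standard genetic code; one effect is emitted per codon touched by any
#' change, so two substitutions in one codon (e.g. 71G>A + 72T>G) yield a
#' single combined effect (Gly24Glu), as do frame-preserving delins within
#' a codon. Synonymous effects are flagged, not dropped, so callers can
#' suppress them in reports. A change set whose net length shift breaks
#' the reading frame is reported as a single frameshift marker with no
#' per-codon calls.
#'
#' @param conventional_cds conventional reference CDS
#' @param changes list of `nt_change` (or semicolon-joined HGVS string)
#' @return data.frame with columns codon_index, ref_aa, alt_aa, hgvs_p,
#'   synonymous, frameshift
#' @export
predict_effects <- function(conventional_cds, changes) {
  if (is.character(changes)) changes <- parse_hgvs_list(changes)
  empty <- data.frame(codon_index = integer(), ref_aa = character(),
                      alt_aa = character(), hgvs_p = character(),
                      synonymous = logical(), frameshift = logical(),
                      stringsAsFactors = FALSE)
  if (!length(changes)) return(empty)
  ends <- vapply(changes, function(c) c$end, integer(1))
  if (any(ends > nchar(conventional_cds)))
    stop("change extends past CDS end")
  delta <- sum(vapply(changes, function(c) nchar(c$alt) - nchar(c$ref), numeric(1)))
  first_codon <- (min(vapply(changes, function(c) c$start, integer(1))) - 1L) %/% 3L + 1L
  ref_aa_all <- translate_cds(conventional_cds)
  if (delta %% 3L != 0L) {
    aa <- AA3[[ref_aa_all[first_codon]]]
    return(data.frame(codon_index = first_codon, ref_aa = aa, alt_aa = "fs",
                      hgvs_p = paste0(aa, first_codon, "fs"),
                      synonymous = FALSE, frameshift = TRUE,
                      stringsAsFactors = FALSE))
  }
  mutant <- apply_changes(conventional_cds, changes)
  alt_aa_all <- translate_cds(mutant)
  if (delta != 0L) {
    # in-frame indel: one combined effect over the differing codon window,
    # found by trimming the common codon prefix and suffix
    n1 <- length(ref_aa_all); n2 <- length(alt_aa_all)
    i <- 1L
    while (i <= min(n1, n2) && ref_aa_all[i] == alt_aa_all[i]) i <- i + 1L
    k <- 0L
    while (k < min(n1, n2) - i + 1L &&
           ref_aa_all[n1 - k] == alt_aa_all[n2 - k]) k <- k + 1L
    j <- n1 - k
    repl <- if (i <= n2 - k) alt_aa_all[i:(n2 - k)] else character()
    i <- min(i, n1)
    repl_str <- if (length(repl)) paste(AA3[repl], collapse = "") else "del"
    hgvs_p <- paste0(AA3[[ref_aa_all[i]]], i,
                     if (j > i) paste0("_", AA3[[ref_aa_all[max(j, i)]]], j),
                     if (length(repl)) "delins" else "", repl_str)
    return(data.frame(codon_index = i, ref_aa = AA3[[ref_aa_all[i]]],
                      alt_aa = repl_str, hgvs_p = hgvs_p,
                      synonymous = FALSE, frameshift = FALSE,
                      stringsAsFactors = FALSE))
  }
  touched <- sort(unique(unlist(lapply(changes, function(c)
    ((c$start - 1L) %/% 3L + 1L):((c$end - 1L) %/% 3L + 1L)))))
  out <- lapply(touched, function(ci) {
    ra <- AA3[[ref_aa_all[ci]]]; aa <- AA3[[alt_aa_all[ci]]]
    data.frame(codon_index = ci, ref_aa = ra, alt_aa = aa,
               hgvs_p = paste0(ra, ci, aa),
               synonymous = ra == aa, frameshift = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

match_allele <- function(changes, defs_gene, conventional_name) {
  obs <- sort(vapply(changes, function(c) c$hgvs_c, ""))
  if (!length(obs)) return(conventional_name)
  for (i in seq_len(nrow(defs_gene))) {
    def <- sort(vapply(parse_hgvs_list(defs_gene$defining_changes[i]),
                       function(c) c$hgvs_c, ""))
    if (length(def) == length(obs) && all(def == obs))
      return(defs_gene$allele_name[i])
  }
  "ND"
}

#' Build the per-gene baseline table (genome vs conventional alleles)
#'
#' For each gene: extract the genome CDS through the gene model, diff it
#' against the conventional reference CDS, predict amino-acid effects, and
#' assign the genome's allele by exact set match against the definition
#' table ("ND" when no definition matches).
#'
#' @param genome `genome_ref`
#' @param models named list of `gene_model`
#' @param conventionals named list of `conventional_reference`
#' @param allele_defs allele-definition data.frame (see
#'   [read_allele_definitions()])
#' @return data.frame (one row per gene) with columns gene_symbol,
#'   conventional_allele, hgvs_c, hgvs_p, predicted_allele; the parsed
#'   change lists are kept in attribute "changes" for re-basing
#' @export
build_baseline_table <- function(genome, models, conventionals, allele_defs) {
  genes <- names(models)
  missing <- setdiff(genes, names(conventionals))
  if (length(missing))
    stop("no conventional reference for gene(s): ", paste(missing, collapse = ", "))
  change_lists <- list()
  rows <- lapply(genes, function(g) {
    cds_g <- extract_cds(genome, models[[g]])
    conv <- conventionals[[g]]
    changes <- diff_cds(conv$cds, cds_g)
    change_lists[[g]] <<- changes
    eff <- predict_effects(conv$cds, changes)
    nonsyn <- eff[!eff$synonymous, , drop = FALSE]
    defs_g <- allele_defs[allele_defs$gene_symbol == g, , drop = FALSE]
    data.frame(
      gene_symbol = g,
      conventional_allele = conv$allele_name,
      hgvs_c = hgvs_string(changes),
      hgvs_p = if (nrow(nonsyn)) paste(nonsyn$hgvs_p, collapse = ";") else "-",
      predicted_allele = match_allele(changes, defs_g, conv$allele_name),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "changes") <- change_lists
  out
}

#' Read an allele-definition table
#'
#' TSV columns: gene_symbol, allele_name, defining_changes (semicolon-
#' joined HGVS cDNA changes relative to the conventional CDS; "-" for the
#' conventional allele itself), phenotype, source (ISBT / dbRBC /
#' 1000G-only).
#'
#' @param path TSV path
#' @return data.frame
#' @export
read_allele_definitions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_symbol", "allele_name", "defining_changes", "phenotype", "source")
  if (!all(need %in% names(df)))
    stop("allele-definition TSV must have columns: ", paste(need, collapse = ", "))
  validate_allele_definitions(df)
}

validate_allele_definitions <- function(df) {
  for (g in unique(df$gene_symbol)) {
    sets <- vapply(df$defining_changes[df$gene_symbol == g], function(s)
      paste(sort(vapply(parse_hgvs_list(s), function(c) c$hgvs_c, "")),
            collapse = ";"), "")
    if (anyDuplicated(sets))
      stop("duplicate defining-change sets within gene ", g)
  }
  df
}

#' Write a baseline table as TSV
#'
#' @param baseline output of [build_baseline_table()]
#' @param path output path
#' @export
write_baseline_table <- function(baseline, path) {
  utils::write.table(baseline, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
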