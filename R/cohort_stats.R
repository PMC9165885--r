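#' @title Cohort allele frequencies and cross-population comparison
#'
#' @description Resolved diplotype calls are counted into per-gene allele
#'   frequency tables and compared against external population sources
#'   (multiplex-genotyped national registry data; 1000 Genomes-derived
#'   database columns) with 2x2 chi-square or Fisher tests, reporting the
#'   conventional significance tiers p<0.05 / p<0.01 / p<0.001. External
#'   sources publish percentages plus cohort sizes, so integer allele
#'   counts are reconstructed before testing.
#' @name cohort_stats
NULL

#' Count alleles across resolved calls
#'
#' Only `resolved` calls contribute: each diploid call adds two allele
#' observations, a haploid call one. Per-gene totals reflect only the
#' contributing samples, so a gene with ambiguous or ND calls has a
#' smaller denominator.
#'
#' @param calls data.frame of calls (sample_id, gene_symbol, status,
#'   candidates) as produced by [call_cohort()]
#' @return data.frame: gene_symbol, allele_name, count, n_alleles,
#'   frequency (proportion) and freq_percent
#' @export
count_alleles <- function(calls) {
  res <- calls[calls$status == "resolved", , drop = FALSE]
  rows <- list()
  for (g in unique(res$gene_symbol)) {
    cand <- res$candidates[res$gene_symbol == g]
    alleles <- unlist(strsplit(cand, "/", fixed = TRUE))
    tab <- table(alleles)
    n <- sum(tab)
    for (a in names(tab))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_symbol = g, allele_name = a, count = as.integer(tab[[a]]),
        n_alleles = n, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_symbol = character(), allele_name = character(),
               count = integer(), n_alleles = integer(),
               stringsAsFactors = FALSE)
  out$frequency <- ifelse(out$n_alleles > 0, out$count / out$n_alleles, NA_real_)
  out$freq_percent <- 100 * out$frequency
  stopifnot(all(abs(tapply(out$frequency, out$gene_symbol, sum) - 1) < 1e-9))
  out
}

#' Reconstruct an integer allele count from a printed percentage
#'
#' Rounds percent/100 x n to the nearest integer (half away from zero)
#' and warns when the re-rendered percentage disagrees with the printed
#' one by more than 0.005, which signals that the published denominator
#' differed from the nominal one.
#'
#' @param freq_percent printed frequency in percent
#' @param n_alleles total allele count of the source
#' @return integer count
#' @export
reconstruct_counts <- function(freq_percent, n_alleles) {
  stopifnot(n_alleles > 0)
  x <- freq_percent / 100 * n_alleles
  count <- as.integer(sign(x) * floor(abs(x) + 0.5))
  back <- count / n_alleles * 100
  if (abs(back - freq_percent) > 0.005)
    warning(sprintf(
      "count %d/%d re-renders as %.4f%%, printed %.4f%%: denominator mismatch",
      count, n_alleles, back, freq_percent))
  count
}

tier_of <- function(p) {
  if (p < 0.001) "p<0.001" else if (p < 0.01) "p<0.01"
  else if (p < 0.05) "p<0.05" else "ns"
}

#' Compare one allele's frequency between two cohorts
#'
#' Builds the 2x2 table (allele vs all-other, study vs source) and applies
#' Pearson's chi-square without continuity correction, switching to
#' Fisher's exact (two-sided) when any expected cell count is below 5.
#' Zero-margin tables (the allele absent, or fixed, in both cohorts) get
#' p = 1 with a warning.
#'
#' @param study_count,study_n allele count and total alleles in the study
#' @param other_count,other_n allele count and total alleles in the source
#' @param continuity apply Yates continuity correction (default FALSE)
#' @return list: p_value, tier, test_used, table
#' @export
compare_counts <- function(study_count, study_n, other_count, other_n,
                           continuity = FALSE) {
  stopifnot(study_count <= study_n, other_count <= other_n)
  tab <- matrix(c(study_count, study_n - study_count,
                  other_count, other_n - other_count),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("study", "source"), c("allele", "other")))
  if (any(colSums(tab) == 0L)) {
    warning("zero-margin 2x2 table; p set to 1")
    return(list(p_value = 1, tier = "ns", test_used = "chi-square", table = tab))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    p <- stats::fisher.test(tab)$p.value
    test <- "fisher"
  } else {
    p <- stats::chisq.test(tab, correct = continuity)$p.value
    test <- "chi-square"
  }
  list(p_value = p, tier = tier_of(p), test_used = test, table = tab)
}

#' Read external frequency sources from TSV
#'
#' Columns: source, n_individuals, gene_symbol, allele_name, freq_percent.
#' `n_individuals` is the number of genotyped people; allele totals are
#' twice that.
#'
#' @param path TSV path
#' @return data.frame
#' @export
read_frequency_sources <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("source", "n_individuals", "gene_symbol", "allele_name", "freq_percent")
  if (!all(need %in% names(df)))
    stop("frequency TSV must have columns: ", paste(need, collapse = ", "))
  if (any(df$freq_percent < 0 | df$freq_percent > 100))
    stop("freq_percent outside [0, 100]")
  df
}

#' Build a study count table from printed percentages
#'
#' Used when only a published frequency column is available (percent plus
#' cohort size) rather than raw calls.
#'
#' @param freqs data.frame (gene_symbol, allele_name, freq_percent)
#' @param n_individuals cohort size; allele total is 2 x this
#' @return data.frame in the shape of [count_alleles()] output
#' @export
counts_from_percent <- function(freqs, n_individuals) {
  n <- 2L * n_individuals
  counts <- vapply(freqs$freq_percent, function(f)
    suppressWarnings(reconstruct_counts(f, n)), integer(1))
  data.frame(gene_symbol = freqs$gene_symbol,
             allele_name = freqs$allele_name,
             count = counts, n_alleles = n,
             frequency = counts / n, freq_percent = 100 * counts / n,
             stringsAsFactors = FALSE)
}

#' Compare a study frequency table against every external source
#'
#' One comparison per (gene, allele, source) present in either table;
#' alleles absent from one side are compared against count 0 with a
#' warning. External counts are reconstructed from percentages with
#' allele totals of 2 x n_individuals.
#'
#' @param study count table ([count_alleles()] or [counts_from_percent()])
#' @param sources external source data.frame ([read_frequency_sources()])
#' @param continuity passed to [compare_counts()]
#' @param bonferroni apply Bonferroni correction across all comparisons
#'   before assigning tiers (default FALSE, matching per-comparison
#'   reporting)
#' @return data.frame: gene_symbol, allele_name, source, study_count,
#'   study_n, source_count, source_n, p_value, tier, test_used
#' @export
compare_all <- function(study, sources, continuity = FALSE, bonferroni = FALSE) {
  rows <- list()
  for (src in unique(sources$source)) {
    sdf <- sources[sources$source == src, , drop = FALSE]
    src_n <- 2L * sdf$n_individuals[1]
    genes <- union(unique(study$gene_symbol), unique(sdf$gene_symbol))
    for (g in genes) {
      st_g <- study[study$gene_symbol == g, , drop = FALSE]
      so_g <- sdf[sdf$gene_symbol == g, , drop = FALSE]
      if (!nrow(so_g)) next    # gene absent from this source (NA column)
      alleles <- union(st_g$allele_name, so_g$allele_name)
      for (a in alleles) {
        in_st <- a %in% st_g$allele_name
        in_so <- a %in% so_g$allele_name
        if (!in_st || !in_so)
          warning("allele ", a, " (", g, ") absent from ",
                  if (in_so) "study" else src, "; compared against count 0")
        st_count <- if (in_st) st_g$count[st_g$allele_name == a] else 0L
        st_n <- if (nrow(st_g)) st_g$n_alleles[1] else 0L
        if (st_n == 0L) next
        so_count <- if (in_so)
          suppressWarnings(reconstruct_counts(
            so_g$freq_percent[so_g$allele_name == a], src_n)) else 0L
        cmp <- suppressWarnings(compare_counts(st_count, st_n, so_count, src_n,
                                               continuity = continuity))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_symbol = g, allele_name = a, source = src,
          study_count = st_count, study_n = st_n,
          source_count = so_count, source_n = src_n,
          p_value = cmp$p_value, tier = cmp$tier, test_used = cmp$test_used,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_symbol = character(), allele_name = character(),
               source = character(), study_count = integer(),
               study_n = integer(), source_count = integer(),
               source_n = integer(), p_value = numeric(), tier = character(),
               test_used = character(), stringsAsFactors = FALSE)
  if (bonferroni && nrow(out)) {
    out$p_value <- pmin(1, out$p_value * nrow(out))
    out$tier <- vapply(out$p_value, tier_of, "")
  }
  out
}

#' Render comparisons as a frequency grid with tier markers
#'
#' One row per (gene, allele); one column per source showing the source
#' percentage suffixed with the marker a/b/c for p<0.05 / p<0.01 /
#' p<0.001 against the study.
#'
#' @param study study count table
#' @param comparisons output of [compare_all()]
#' @return data.frame grid
#' @export
render_comparison_grid <- function(study, comparisons) {
  marker <- c(ns = "", `p<0.05` = "a", `p<0.01` = "b", `p<0.001` = "c")
  key <- unique(comparisons[, c("gene_symbol", "allele_name")])
  out <- data.frame(gene_symbol = key$gene_symbol,
                    allele_name = key$allele_name,
                    stringsAsFactors = FALSE)
  idx <- match(paste(key$gene_symbol, key$allele_name),
               paste(study$gene_symbol, study$allele_name))
  out$study <- ifelse(is.na(idx), "0.00%",
                      sprintf("%.2f%%", study$freq_percent[idx]))
  for (src in unique(comparisons$source)) {
    cc <- comparisons[comparisons$source == src, , drop = FALSE]
    j <- match(paste(key$gene_symbol, key$allele_name),
               paste(cc$gene_symbol, cc$allele_name))
    out[[src]] <- ifelse(is.na(j), "NA",
      sprintf("%.2f%%%s", 100 * cc$source_count[j] / cc$source_n[j],
              marker[cc$tier[j]]))
  }
  out
}
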