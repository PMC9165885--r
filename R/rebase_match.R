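#' @title Re-basing and diplotype enumeration
#'
#' @description Variant callers report against the reference genome, but
#'   blood-group alleles are defined against each gene's conventional ISBT
#'   reference allele. Where the genome itself carries the
#'   non-conventional state (the baseline diff), a sample with NO variant
#'   call at that site carries the non-conventional base on every
#'   haplotype — absence of evidence is a genotype. `rebase()` converts
#'   sample variants into per-site non-conventional dosages;
#'   `enumerate_diplotypes()` finds every unordered allele pair consistent
#'   with those dosages, surfacing unphased ambiguity (the ABO problem)
#'   rather than guessing.
#' @name rebase_match
NULL

#' Re-base a sample's cDNA variants onto the conventional reference
#'
#' The site universe is the union of baseline-change positions and the
#' sample's variant positions. At a baseline site the non-conventional
#' dosage is `ploidy - (copies of the alt that restores the conventional
#' base)`; no call there means dosage = ploidy. At a non-baseline site the
#' alt dosage passes through. A sample alt at a baseline site matching
#' neither the conventional nor the genome base is emitted as a distinct,
#' flagged third-allele state.
#'
#' @param baseline_changes list of `nt_change` separating the genome from
#'   the conventional allele for this gene (may be empty)
#' @param sample_variants data.frame (hgvs_c, dosage) of this gene's
#'   projected variants, expressed relative to the genome
#' @param ploidy 1 or 2
#' @return data.frame: hgvs_c (relative to the conventional CDS), dosage
#'   (non-conventional copies, 1..ploidy), third_allele flag
#' @export
rebase <- function(baseline_changes, sample_variants, ploidy = 2L) {
  stopifnot(ploidy %in% c(1L, 2L))
  out <- list()
  baseline_changes <- decompose_changes(baseline_changes)
  # decompose multi-base substitutions so adjacent SNV calls and merged
  # delins forms meet in the same per-site space
  sv <- sample_variants
  if (nrow(sv)) {
    dec <- lapply(seq_len(nrow(sv)), function(i) {
      parts <- decompose_change(parse_hgvs_c(sv$hgvs_c[i]))
      data.frame(hgvs_c = vapply(parts, function(c) c$hgvs_c, ""),
                 dosage = sv$dosage[i], stringsAsFactors = FALSE)
    })
    sv <- do.call(rbind, dec)
  }
  sv_changes <- lapply(sv$hgvs_c, parse_hgvs_c)
  sv_used <- rep(FALSE, nrow(sv))

  for (b in baseline_changes) {
    # genome carries b$alt where the conventional allele has b$ref
    hits <- which(vapply(sv_changes, function(c)
      c$start == b$start && c$end == b$end, TRUE) & !sv_used)
    restored <- 0L
    for (i in hits) {
      c <- sv_changes[[i]]
      if (c$ref != b$alt) next            # not anchored on the genome state
      sv_used[i] <- TRUE
      if (c$alt == b$ref) {               # restores the conventional base
        restored <- restored + sv$dosage[i]
      } else {                            # third allele at a baseline site
        third <- nt_change(if (nchar(b$ref) == 1L && nchar(c$alt) == 1L)
                             "substitution" else "delins",
                           b$start, b$end, ref = b$ref, alt = c$alt)
        out[[length(out) + 1L]] <- data.frame(
          hgvs_c = third$hgvs_c, dosage = sv$dosage[i], third_allele = TRUE,
          stringsAsFactors = FALSE)
        restored <- restored + 0L
        # those alt copies occupy haplotypes that are non-conventional but
        # not baseline-state either; subtract them from the baseline dosage
        # below via `other`
      }
    }
    other <- sum(vapply(which(sv_used & vapply(sv_changes, function(c)
      c$start == b$start && c$end == b$end, TRUE)), function(i)
        if (sv_changes[[i]]$alt != b$ref) sv$dosage[i] else 0L, integer(1)))
    dosage <- ploidy - restored - other
    if (dosage < 0L)
      stop("baseline site ", b$hgvs_c, ": restored copies exceed ploidy")
    if (dosage > 0L)
      out[[length(out) + 1L]] <- data.frame(
        hgvs_c = b$hgvs_c, dosage = dosage, third_allele = FALSE,
        stringsAsFactors = FALSE)
  }

  for (i in which(!sv_used)) {
    if (sv$dosage[i] > 0L)
      out[[length(out) + 1L]] <- data.frame(
        hgvs_c = sv$hgvs_c[i], dosage = min(sv$dosage[i], ploidy),
        third_allele = FALSE, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(hgvs_c = character(), dosage = integer(),
                      third_allele = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(vapply(res$hgvs_c, function(h) parse_hgvs_c(h)$start, integer(1))), ,
      drop = FALSE]
}

def_change_sets <- function(defs) {
  lapply(defs$defining_changes, function(s) {
    parts <- decompose_changes(parse_hgvs_list(s))
    sort(vapply(parts, function(c) c$hgvs_c, ""))
  })
}

#' Enumerate allele pairs consistent with observed site dosages
#'
#' For diploid calls every unordered pair of defined alleles is tested:
#' a pair is consistent iff at every site in the union of both alleles'
#' defining changes and the observed states, the two alleles' indicator
#' sum equals the observed non-conventional dosage. Exactly one
#' consistent pair with nothing unexplained is `resolved`; several are
#' `ambiguous` (the unphased-data ABO situation). When no pair fits and
#' the observed change count exceeds `hypervariable_threshold` the call is
#' `nd_hypervariable`; otherwise one novel placeholder haplotype may
#' absorb the unexplained changes alongside a single defined allele
#' (`ambiguous`, absorbed changes reported), else `nd_no_match`.
#'
#' @param states data.frame from [rebase()] (hgvs_c, dosage)
#' @param defs allele-definition data.frame for ONE gene; must include the
#'   conventional allele (empty defining set)
#' @param ploidy 1 or 2
#' @param hypervariable_threshold observed-site count above which an
#'   unmatched gene is declared hypervariable (default 6)
#' @return list of class `call_result`: candidates (character vector,
#'   "X/Y" for diploid), status, unexplained (character vector of hgvs_c)
#' @export
enumerate_diplotypes <- function(states, defs, ploidy = 2L,
                                 hypervariable_threshold = 6L) {
  if (!nrow(defs)) stop("empty allele-definition table")
  sets <- def_change_sets(defs)
  if (!any(lengths(sets) == 0L))
    stop("definition table lacks the conventional allele (empty change set)")
  nm <- defs$allele_name
  sites <- sort(unique(c(unlist(sets), states$hgvs_c)))
  obs <- stats::setNames(rep(0L, length(sites)), sites)
  obs[states$hgvs_c] <- states$dosage
  ind <- matrix(0L, nrow = length(sites), ncol = length(nm))
  for (j in seq_along(sets)) ind[sites %in% sets[[j]], j] <- 1L

  result <- function(candidates, status, unexplained = character()) {
    structure(list(candidates = candidates, status = status,
                   unexplained = unexplained), class = "call_result")
  }

  if (ploidy == 1L) {
    hit <- which(vapply(seq_along(nm), function(i)
      all(ind[, i] == obs), TRUE))
    if (length(hit) == 1L) return(result(nm[hit], "resolved"))
    if (length(hit) > 1L) return(result(sort(nm[hit]), "ambiguous"))
    if (nrow(states) > hypervariable_threshold)
      return(result(character(), "nd_hypervariable", states$hgvs_c))
    if (all(obs <= 1L))
      return(result("novel", "ambiguous", names(obs)[obs == 1L]))
    return(result(character(), "nd_no_match", states$hgvs_c))
  }

  pairs <- list()
  for (i in seq_along(nm)) for (j in i:length(nm)) {
    if (all(ind[, i] + ind[, j] == obs))
      pairs[[length(pairs) + 1L]] <- sort(c(nm[i], nm[j]))
  }
  if (length(pairs)) {
    cand <- sort(vapply(pairs, paste, "", collapse = "/"))
    return(result(cand, if (length(cand) == 1L) "resolved" else "ambiguous"))
  }
  if (nrow(states) > hypervariable_threshold)
    return(result(character(), "nd_hypervariable", states$hgvs_c))
  # novel retry: one haplotype is a defined allele, the other a novel
  # placeholder absorbing whatever dosage remains
  viable <- list()
  for (i in seq_along(nm)) {
    rem <- obs - ind[, i]
    if (all(rem %in% c(0L, 1L)))
      viable[[length(viable) + 1L]] <-
        list(name = nm[i], absorbed = names(obs)[rem == 1L])
  }
  if (length(viable) == 1L)
    return(result(paste0(viable[[1]]$name, "/novel"), "ambiguous",
                  viable[[1]]$absorbed))
  result(character(), "nd_no_match", states$hgvs_c)
}

#' Call blood-group diplotypes for a whole cohort
#'
#' Per sample and gene: project genomic variants to cDNA, re-base against
#' the baseline table, and enumerate consistent diplotypes. Samples with
#' zero variants across ALL genes are treated as data-quality failures and
#' excluded (they would otherwise trivially resolve to the baseline-
#' implied homozygote everywhere); `keep_zero_variant_samples = TRUE`
#' keeps them.
#'
#' @param vcf_data output of [load_vcf()] (or a compatible list)
#' @param baseline output of [build_baseline_table()]
#' @param defs allele-definition data.frame (all genes)
#' @param models named list of `gene_model`
#' @param hypervariable_threshold see [enumerate_diplotypes()]
#' @param keep_zero_variant_samples keep samples whose VCF has no variants
#' @param sample_sex optional named vector ("M"/"F") for X-linked ploidy;
#'   X-linked genes default to diploid with a warning when absent
#' @param x_genes gene symbols treated as X-linked for male samples
#' @return list: `calls` data.frame (sample_id, gene_symbol, status,
#'   candidates, unexplained), `excluded` character vector of zero-variant
#'   samples, `gene_summary` data.frame (gene_symbol, mean_variants)
#' @export
call_cohort <- function(vcf_data, baseline, defs, models,
                        hypervariable_threshold = 6L,
                        keep_zero_variant_samples = FALSE,
                        sample_sex = NULL,
                        x_genes = c("XG", "XK", "GATA1")) {
  variants <- vcf_data$variants
  samples <- vcf_data$samples
  n_var <- table(factor(variants$sample_id, levels = samples))
  excluded <- names(n_var)[n_var == 0L]
  included <- if (keep_zero_variant_samples) samples
              else setdiff(samples, excluded)
  base_changes <- attr(baseline, "changes")

  calls <- list()
  var_counts <- matrix(0L, nrow = length(included), ncol = length(models),
                       dimnames = list(included, names(models)))
  for (s in included) {
    proj <- project_sample(models, variants[variants$sample_id == s, , drop = FALSE])
    for (g in names(models)) {
      ploidy <- 2L
      if (g %in% x_genes) {
        if (!is.null(sample_sex) && !is.na(sample_sex[s])) {
          ploidy <- if (sample_sex[s] == "M") 1L else 2L
        } else {
          warning("no sex for sample ", s, "; treating X-linked ", g,
                  " as diploid")
        }
      }
      pv <- proj[proj$gene_symbol == g, , drop = FALSE]
      var_counts[s, g] <- nrow(pv)
      states <- rebase(base_changes[[g]] %||% list(), pv, ploidy = ploidy)
      res <- enumerate_diplotypes(
        states, defs[defs$gene_symbol == g, , drop = FALSE],
        ploidy = ploidy, hypervariable_threshold = hypervariable_threshold)
      calls[[length(calls) + 1L]] <- data.frame(
        sample_id = s, gene_symbol = g, status = res$status,
        candidates = paste(res$candidates, collapse = ";"),
        unexplained = paste(res$unexplained, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(sample_id = character(), gene_symbol = character(),
               status = character(), candidates = character(),
               unexplained = character(), stringsAsFactors = FALSE)
  gene_summary <- data.frame(
    gene_symbol = names(models),
    mean_variants = if (nrow(var_counts)) colMeans(var_counts) else NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
  list(calls = calls, excluded = excluded, gene_summary = gene_summary)
}
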