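# Independent oracles and small generators used across the suite.

# Brute-force diplotype oracle: enumerate every assignment of each observed
# change copy to haplotype 1/2, then check whether both resulting haplotype
# change sets equal some defined allele. Independent of the pair-testing
# logic in enumerate_diplotypes().
oracle_diplotypes <- function(states, defs) {
  sets <- lapply(defs$defining_changes, function(s) {
    parts <- bgtyper::parse_hgvs_list(s)
    sort(vapply(parts, function(c) c$hgvs_c, ""))
  })
  names(sets) <- defs$allele_name
  site_opts <- lapply(seq_len(nrow(states)), function(i) {
    d <- states$dosage[i]
    if (d == 0) list(c(0L, 0L))
    else if (d == 1) list(c(1L, 0L), c(0L, 1L))
    else list(c(1L, 1L))
  })
  combos <- list(list())
  for (opts in site_opts) {
    combos <- unlist(lapply(combos, function(cm)
      lapply(opts, function(o) c(cm, list(o)))), recursive = FALSE)
  }
  found <- character()
  match_name <- function(hap_set) {
    hap_set <- sort(hap_set)
    hits <- names(sets)[vapply(sets, function(s)
      length(s) == length(hap_set) && all(s == hap_set), TRUE)]
    if (length(hits)) hits[1] else NA_character_
  }
  for (cm in combos) {
    h1 <- states$hgvs_c[vapply(cm, `[`, 0L, 1) == 1L]
    h2 <- states$hgvs_c[vapply(cm, `[`, 0L, 2) == 1L]
    n1 <- match_name(h1); n2 <- match_name(h2)
    if (!is.na(n1) && !is.na(n2))
      found <- c(found, paste(sort(c(n1, n2)), collapse = "/"))
  }
  sort(unique(found))
}

# Pearson chi-square on a 2x2 allele table, from the closed-form statistic
chisq_p_manual <- function(a, n1, b, n2) {
  tab <- as.numeric(c(a, n1 - a, b, n2 - b))
  N <- as.numeric(n1 + n2)
  n1 <- as.numeric(n1); n2 <- as.numeric(n2)
  stat <- N * (tab[1] * tab[4] - tab[2] * tab[3])^2 /
    (n1 * n2 * (tab[1] + tab[3]) * (tab[2] + tab[4]))
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration,
# probabilities computed directly from binomial coefficients
fisher_p_enum <- function(a, n1, b, n2) {
  k <- a + b                                  # allele-column margin
  lo <- max(0L, k - n2); hi <- min(n1, k)
  probs <- vapply(lo:hi, function(x)
    choose(n1, x) * choose(n2, k - x) / choose(n1 + n2, k), numeric(1))
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random single-gene model embedded in a random contig
random_gene_model <- function(seed, n_segments = sample(1:3, 1),
                              strand = sample(c("+", "-"), 1)) {
  set.seed(seed)
  seg_len <- sample(seq(6, 30, by = 3), n_segments, replace = TRUE)
  while (sum(seg_len) %% 3 != 0)
    seg_len[1] <- seg_len[1] + 1
  gaps <- sample(5:20, n_segments, replace = TRUE)
  segs <- matrix(0L, n_segments, 2)
  pos <- 0L
  for (i in seq_len(n_segments)) {
    segs[i, 1] <- pos + gaps[i]
    segs[i, 2] <- segs[i, 1] + seg_len[i] - 1L
    pos <- segs[i, 2]
  }
  contig_len <- max(segs) + sample(5:20, 1)
  contig <- paste(sample(c("A", "C", "G", "T"), contig_len, replace = TRUE),
                  collapse = "")
  genome <- bgtyper::genome_ref(list(chrT = contig))
  model <- bgtyper::gene_model("TESTG", "chrT", strand, segs)
  list(genome = genome, model = model)
}

random_cds_string <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Random change set over a CDS: isolated substitutions plus optional indels
random_change_set <- function(cds, n_sub = 3, n_indel = 0) {
  len <- nchar(cds)
  changes <- list()
  used <- integer()
  tries <- 0
  while (length(changes) < n_sub && tries < 200) {
    tries <- tries + 1
    p <- sample(len, 1)
    if (any(abs(p - used) <= 1)) next
    ref <- substr(cds, p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    changes[[length(changes) + 1L]] <- bgtyper::nt_change(
      "substitution", p, ref = ref, alt = alt)
    used <- c(used, p)
  }
  if (n_indel > 0) {
    for (i in seq_len(n_indel)) {
      p <- sample(2:(len - 4), 1)
      if (any(abs(p - used) <= 3)) next
      if (stats::runif(1) < 0.5) {
        w <- sample(1:3, 1)
        changes[[length(changes) + 1L]] <- bgtyper::nt_change(
          "deletion", p, p + w - 1L, ref = substr(cds, p, p + w - 1L))
      } else {
        ins <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1),
                            replace = TRUE), collapse = "")
        changes[[length(changes) + 1L]] <- bgtyper::nt_change(
          "insertion", p, p + 1L, alt = ins)
      }
      used <- c(used, (p - 1):(p + 3))
    }
  }
  changes
}

# FY-like single-gene simulation config used in end-to-end checks
fy_config <- function(seed, n_samples = 205L, dropout_rate = 0,
                      neutral_rate = 0) {
  al <- data.frame(
    allele_name = c("FY*02", "FY*01", "FY*01.1000G"),
    changes = c("-", "125A>G", "125A>G;199C>T"),
    freq = c(0.04, 0.93, 0.03), phenotype = "",
    stringsAsFactors = FALSE)
  bgtyper::simulation_config(
    seed = seed, n_samples = n_samples, dropout_rate = dropout_rate,
    genes = list(bgtyper::sim_gene(
      "ACKR1", 210L, strand = "-", n_segments = 2L,
      baseline_changes = "125A>G", pin = c("124" = "G", "126" = "C"),
      alleles = al, extra_neutral_variant_rate = neutral_rate)))
}

diplotype_key <- function(a, b) {
  vapply(seq_along(a), function(i)
    paste(sort(c(a[i], b[i])), collapse = "/"), "")
}
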