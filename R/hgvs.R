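#' @title cDNA-level nucleotide changes in HGVS-style notation
#'
#' @description A nucleotide change records one difference between a
#'   conventional reference CDS and another sequence, at cDNA coordinates
#'   (1-based on the spliced CDS). Four kinds are supported: substitution
#'   ("125A>G"), deletion ("125delA", "125_127delACG"), insertion
#'   ("125_126insAGT") and delins ("201_202delACinsGT"). The string
#'   rendering round-trips through [parse_hgvs_c()].
#' @name hgvs
NULL

#' Construct a nucleotide change
#'
#' @param kind one of "substitution", "deletion", "insertion", "delins"
#' @param start,end 1-based cDNA positions (end = start for single-base
#'   changes; for insertions, the flanking positions start/start+1)
#' @param ref reference (conventional) bases at start..end ("" for insertion)
#' @param alt replacement bases ("" for deletion)
#' @return a list of class `nt_change` with fields kind, start, end, ref,
#'   alt and the canonical `hgvs_c` rendering
#' @export
nt_change <- function(kind, start, end = start, ref = "", alt = "") {
  kind <- match.arg(kind, c("substitution", "deletion", "insertion", "delins"))
  stopifnot(start >= 1L, end >= start)
  ref <- toupper(ref); alt <- toupper(alt)
  if (kind == "substitution" && (nchar(ref) != 1L || nchar(alt) != 1L))
    stop("substitution requires single ref and alt bases")
  if (kind == "delins" && (nchar(ref) == 0L || nchar(alt) == 0L))
    stop("delins requires non-empty ref and alt")
  if (kind == "delins" && nchar(ref) == 1L && nchar(alt) == 1L)
    stop("single-base delins is a substitution")
  if (kind == "deletion" && nchar(ref) != end - start + 1L)
    stop("deletion ref length must match the deleted span")
  if (kind == "insertion" && (nchar(alt) == 0L || end != start + 1L))
    stop("insertion needs alt bases and flanking positions start, start+1")
  chg <- list(kind = kind, start = as.integer(start), end = as.integer(end),
              ref = ref, alt = alt)
  chg$hgvs_c <- format_hgvs_c(chg)
  class(chg) <- "nt_change"
  chg
}

#' Render a change as its canonical HGVS-style cDNA string
#'
#' @param chg an `nt_change` (or bare list with the same fields)
#' @return character scalar such as "125A>G"
#' @export
format_hgvs_c <- function(chg) {
  span <- if (chg$end > chg$start) paste0(chg$start, "_", chg$end)
          else as.character(chg$start)
  switch(chg$kind,
    substitution = paste0(chg$start, chg$ref, ">", chg$alt),
    deletion     = paste0(span, "del", chg$ref),
    insertion    = paste0(chg$start, "_", chg$end, "ins", chg$alt),
    delins       = paste0(span, "del", chg$ref, "ins", chg$alt))
}

#' Parse an HGVS-style cDNA change string
#'
#' Accepts the renderings produced by [format_hgvs_c()]; a leading "c."
#' prefix is tolerated and stripped.
#'
#' @param x character scalar, e.g. "125A>G" or "216_217delCCinsTA"
#' @return an `nt_change`
#' @export
parse_hgvs_c <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  s <- sub("^c\\.", "", trimws(x))
  m <- regmatches(s, regexec("^([0-9]+)([ACGTN])>([ACGTN])$", s))[[1]]
  if (length(m)) {
    return(nt_change("substitution", as.integer(m[2]), ref = m[3], alt = m[4]))
  }
  m <- regmatches(s, regexec("^([0-9]+)(?:_([0-9]+))?del([ACGTN]+)ins([ACGTN]+)$", s))[[1]]
  if (length(m)) {
    start <- as.integer(m[2])
    end <- if (nzchar(m[3])) as.integer(m[3]) else start
    return(nt_change("delins", start, end, ref = m[4], alt = m[5]))
  }
  m <- regmatches(s, regexec("^([0-9]+)_([0-9]+)ins([ACGTN]+)$", s))[[1]]
  if (length(m)) {
    return(nt_change("insertion", as.integer(m[2]), as.integer(m[3]), alt = m[4]))
  }
  m <- regmatches(s, regexec("^([0-9]+)(?:_([0-9]+))?del([ACGTN]+)$", s))[[1]]
  if (length(m)) {
    start <- as.integer(m[2])
    end <- if (nzchar(m[3])) as.integer(m[3]) else start
    return(nt_change("deletion", start, end, ref = m[4]))
  }
  stop("cannot parse HGVS cDNA change: ", x)
}

#' Parse a semicolon-joined list of HGVS cDNA changes
#'
#' @param x character scalar ("" or "-" mean no changes) or character vector
#' @return list of `nt_change`, sorted by start position
#' @export
parse_hgvs_list <- function(x) {
  if (length(x) == 0L) return(list())
  if (length(x) == 1L && (is.na(x) || x %in% c("", "-"))) return(list())
  parts <- if (length(x) > 1L) x else strsplit(x, ";")[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  chgs <- lapply(parts, parse_hgvs_c)
  chgs[order(vapply(chgs, function(c) c$start, integer(1)))]
}

#' Apply a set of changes to a CDS
#'
#' Changes are expressed on the input (conventional) coordinates and must
#' not overlap; they are applied jointly right-to-left so earlier positions
#' are unaffected by length changes.
#'
#' @param cds nucleotide string (conventional CDS)
#' @param changes list of `nt_change`, or a semicolon-joined HGVS string
#' @return the mutated sequence
#' @export
apply_changes <- function(cds, changes) {
  if (is.character(changes)) changes <- parse_hgvs_list(changes)
  if (!length(changes)) return(cds)
  starts <- vapply(changes, function(c) c$start, integer(1))
  ends <- vapply(changes, function(c) c$end, integer(1))
  ord <- order(starts)
  if (any(starts[ord][-1] <= ends[ord][-length(ord)] &
          vapply(changes[ord], function(c) c$kind, "")[-1] != "insertion"))
    stop("overlapping changes cannot be applied jointly")
  out <- cds
  for (chg in changes[order(starts, decreasing = TRUE)]) {
    if (chg$end > nchar(cds) && chg$kind != "insertion")
      stop("change ", chg$hgvs_c, " extends past CDS end (length ", nchar(cds), ")")
    if (chg$kind == "insertion") {
      out <- paste0(substr(out, 1L, chg$start), chg$alt,
                    substr(out, chg$start + 1L, nchar(out)))
    } else {
      have <- substr(out, chg$start, chg$end)
      if (have != chg$ref)
        stop("change ", chg$hgvs_c, ": sequence has ", have, " not ", chg$ref)
      out <- paste0(substr(out, 1L, chg$start - 1L), chg$alt,
                    substr(out, chg$end + 1L, nchar(out)))
    }
  }
  out
}

#' Reverse complement of a nucleotide string
#'
#' @param x nucleotide string over A/C/G/T/N
#' @return reverse complement string
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), "", USE.NAMES = FALSE))
}

#' Decompose an equal-length change into per-base substitutions
#'
#' Multi-base substitutions (delins with equal ref/alt length, as produced
#' by merging adjacent mismatches) are split into one substitution per
#' differing position. Length-changing variants are returned unchanged.
#' Site matching during re-basing and diplotype enumeration works on this
#' decomposed representation so that a sample's adjacent SNV calls match a
#' merged baseline delins and vice versa.
#'
#' @param chg an `nt_change`
#' @return list of `nt_change`
#' @export
decompose_change <- function(chg) {
  if (chg$kind == "substitution") return(list(chg))
  if (chg$kind == "delins" && nchar(chg$ref) == nchar(chg$alt)) {
    r <- strsplit(chg$ref, "")[[1]]
    a <- strsplit(chg$alt, "")[[1]]
    keep <- which(r != a)
    return(lapply(keep, function(i)
      nt_change("substitution", chg$start + i - 1L, ref = r[i], alt = a[i])))
  }
  list(chg)
}

decompose_changes <- function(changes) {
  unlist(lapply(changes, decompose_change), recursive = FALSE)
}

hgvs_string <- function(changes) {
  if (!length(changes)) return("-")
  paste(vapply(changes, function(c) c$hgvs_c, ""), collapse = ";")
}
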