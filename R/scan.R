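#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet matchPattern reverseComplement pairwiseAlignment
#'   nmatch pattern subject
#' @importFrom IRanges start end width
NULL

# coerce character / DNAString / DNAStringSet to a named DNAStringSet
as_dna_set <- function(seq) {
  if (is(seq, "DNAStringSet")) {
    ss <- seq
  } else if (is(seq, "DNAString")) {
    ss <- DNAStringSet(seq)
  } else if (is.character(seq)) {
    ss <- DNAStringSet(toupper(seq))
  } else stop("unsupported sequence type: ", class(seq)[1])
  if (length(ss) && (is.null(names(ss)) || any(!nzchar(names(ss)))))
    names(ss) <- paste0("seq", seq_along(ss))
  ss
}

empty_sites <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             strand = character(0), mod_pos = integer(0),
             mod_pos_rev = integer(0), motif = character(0),
             stringsAsFactors = FALSE)
}

# matches of a degenerate pattern on the + strand of one contig
plus_matches <- function(subject_dna, pattern_seq) {
  if (nchar(pattern_seq) > length(subject_dna)) return(integer(0))
  m <- matchPattern(DNAString(pattern_seq), subject_dna,
                    fixed = c(pattern = FALSE, subject = TRUE))
  start(m)
}

#' Find motif sites in a sequence
#'
#' Scans a sequence (or a set of contigs) for all occurrences of a
#' degenerate motif on both strands: matches of the motif itself on the
#' plus strand, plus matches of its reverse complement (which are sites of
#' the motif on the minus strand). Overlapping matches are all reported.
#' For palindromic motifs the plus- and minus-strand matches of a duplex
#' locus coincide; by default they are collapsed to a single site (strand
#' `"+"`), with the minus-strand modified-base coordinate retained in
#' `mod_pos_rev`. An `N` in the subject sequence never matches a specified
#' motif position.
#'
#' All coordinates are 1-based and refer to the plus strand; `mod_pos` is
#' the plus-strand coordinate of the base expected to carry the
#' modification for the site's strand.
#'
#' @param seq character string, `DNAString`, or (named) `DNAStringSet`.
#' @param m a `methyl_motif`.
#' @param collapse_palindromes collapse duplex-palindromic loci to one site.
#' @param circular treat each contig as circular: additionally scan a
#'   wrap-around window of `length(motif) - 1` bases across the origin.
#' @return data.frame with columns contig, start, end, strand, mod_pos,
#'   mod_pos_rev, motif; sorted by (contig, start, strand).
#' @examples
#' find_sites("GGATCC", motif("GATC", 2, "m6A"))
#' @export
find_sites <- function(seq, m, collapse_palindromes = TRUE,
                       circular = FALSE) {
  ss <- as_dna_set(seq)
  len <- nchar(m$sequence)
  pal <- is_palindromic(m)
  rc_seq <- reverse_complement_motif(m)$sequence
  out <- vector("list", length(ss))
  for (i in seq_along(ss)) {
    contig <- names(ss)[i]
    subj <- ss[[i]]
    L <- length(subj)
    scan_subj <- subj
    if (circular && L > len - 1L)
      scan_subj <- Biostrings::xscat(subj, Biostrings::subseq(subj, 1L, len - 1L))
    p_starts <- plus_matches(scan_subj, m$sequence)
    m_starts <- if (pal && collapse_palindromes) integer(0)
    else plus_matches(scan_subj, rc_seq)
    if (circular) {
      p_starts <- p_starts[p_starts <= L]
      m_starts <- m_starts[m_starts <= L]
    }
    wrap <- function(x) if (circular) ((x - 1L) %% L) + 1L else x
    rows <- list()
    if (length(p_starts)) {
      rows[[1]] <- data.frame(
        contig = contig, start = p_starts, end = p_starts + len - 1L,
        strand = "+",
        mod_pos = wrap(p_starts + m$modified_position - 1L),
        mod_pos_rev = if (pal && collapse_palindromes)
          wrap(p_starts + len - m$modified_position) else NA_integer_,
        motif = m$sequence, stringsAsFactors = FALSE)
    }
    if (length(m_starts)) {
      # motif lies on the minus strand; its modified position counts from
      # the plus-strand end of the interval
      rows[[2]] <- data.frame(
        contig = contig, start = m_starts, end = m_starts + len - 1L,
        strand = "-",
        mod_pos = wrap(m_starts + len - m$modified_position),
        mod_pos_rev = NA_integer_,
        motif = m$sequence, stringsAsFactors = FALSE)
    }
    out[[i]] <- if (length(rows)) do.call(rbind, rows) else empty_sites()
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Count motif sites per motif across a sequence set
#'
#' @param seq FASTA path, character vector, `DNAString` or `DNAStringSet`.
#' @param motifs a `methyl_motif` or list of them.
#' @param collapse_palindromes,circular see [find_sites()].
#' @return data.frame with columns motif, modified_position, mod_type,
#'   n_sites.
#' @export
count_sites <- function(seq, motifs, collapse_palindromes = TRUE,
                        circular = FALSE) {
  if (is.character(seq) && length(seq) == 1L && file.exists(seq))
    seq <- readDNAStringSet(seq)
  ss <- as_dna_set(seq)
  if (length(ss) == 0L || sum(IRanges::width(ss)) == 0L)
    stop("empty sequence input")
  if (inherits(motifs, "methyl_motif")) motifs <- list(motifs)
  data.frame(
    motif = vapply(motifs, function(m) m$sequence, ""),
    modified_position = vapply(motifs, function(m) m$modified_position, 1L),
    mod_type = vapply(motifs, function(m) m$mod_type, ""),
    n_sites = vapply(motifs, function(m)
      nrow(find_sites(ss, m, collapse_palindromes, circular)), 1L),
    stringsAsFactors = FALSE
  )
}

# type compatibility between a motif's modification type and a call's
compatible_type <- function(call_type, motif_type) {
  call_type == motif_type | call_type == "unknown" | motif_type == "unknown" |
    call_type == "modified_base"
}

#' Per-motif detection rate against modification calls
#'
#' The detection rate of a motif is the fraction of its sites whose expected
#' modified base (on the site's strand) carries a modification call of a
#' compatible type with modification QV at or above `qv_min`. For collapsed
#' palindromic sites a qualifying call on either strand's modified base
#' counts the locus as detected. Also reports the mean modification QV of
#' the matched calls.
#'
#' @param sites data.frame from [find_sites()].
#' @param calls data.frame of modification calls (see [calls_df()]).
#' @param qv_min minimum modification QV for a call to qualify (default 30,
#'   the conventional caller cut-off).
#' @param mod_type modification type expected at the sites; defaults to the
#'   type stored with the calls being unconstrained (`"unknown"`).
#' @return list with `fraction` (NA when there are no sites), `mean_qv`,
#'   `n_sites`, `n_detected`.
#' @export
detection_rate <- function(sites, calls, qv_min = 30, mod_type = "unknown") {
  n_sites <- nrow(sites)
  if (n_sites == 0L)
    return(list(fraction = NA_real_, mean_qv = NA_real_,
                n_sites = 0L, n_detected = 0L))
  calls <- calls[calls$qv >= qv_min &
                   compatible_type(calls$mod_type, mod_type), , drop = FALSE]
  key <- function(contig, strand, pos) paste(contig, strand, pos, sep = "\r")
  call_qv <- tapply(calls$qv, key(calls$contig, calls$strand, calls$position),
                    max)
  fwd_qv <- unname(call_qv[key(sites$contig, sites$strand, sites$mod_pos)])
  rev_qv <- rep(NA_real_, n_sites)
  has_rev <- !is.na(sites$mod_pos_rev)
  if (any(has_rev))
    rev_qv[has_rev] <- unname(call_qv[key(sites$contig[has_rev], "-",
                                          sites$mod_pos_rev[has_rev])])
  qv_hit <- pmax(fwd_qv, rev_qv, na.rm = TRUE)
  qv_hit[is.na(fwd_qv) & is.na(rev_qv)] <- NA_real_
  detected <- !is.na(qv_hit)
  list(fraction = mean(detected),
       mean_qv = if (any(detected)) mean(qv_hit[detected]) else NA_real_,
       n_sites = n_sites,
       n_detected = sum(detected))
}
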