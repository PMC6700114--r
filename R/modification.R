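#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols
#' @importFrom rtracklayer import export
NULL

#' Construct/validate a modification-call table
#'
#' A modification call is one base position reported as methylated by a
#' base-modification caller: contig, 1-based plus-strand coordinate of the
#' base, the strand the modified base lies on, the modification type, a
#' Phred-like modification QV, and the read coverage at the position.
#'
#' @param contig,position,strand,mod_type,qv,coverage vectors (recycled).
#' @return data.frame of class `mod_calls`.
#' @export
calls_df <- function(contig = character(0), position = integer(0),
                     strand = character(0), mod_type = character(0),
                     qv = numeric(0), coverage = integer(0)) {
  df <- data.frame(contig = as.character(contig),
                   position = as.integer(position),
                   strand = as.character(strand),
                   mod_type = as.character(mod_type),
                   qv = as.numeric(qv),
                   coverage = as.integer(coverage),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    stopifnot(all(df$strand %in% c("+", "-")),
              all(df$qv >= 0), all(df$coverage >= 1))
    bad <- !df$mod_type %in% c(MOD_TYPES, "modified_base")
    if (any(bad)) stop("unknown mod_type: ",
                       paste(unique(df$mod_type[bad]), collapse = ", "))
  }
  class(df) <- c("mod_calls", "data.frame")
  df
}

#' Read modification calls (CSV or GFF3)
#'
#' CSV: headered columns contig, position (1-based), strand, mod_type, qv,
#' coverage. GFF3 (the dialect emitted by base-modification callers): the
#' feature type holds the modification type, the score column the
#' modification QV, and a `coverage` attribute the read depth.
#'
#' @param path file path; format chosen by extension (`.gff`/`.gff3` vs
#'   anything else = CSV) unless `format` is given.
#' @param format `"auto"`, `"csv"` or `"gff"`.
#' @return a `mod_calls` data.frame.
#' @export
read_calls <- function(path, format = c("auto", "csv", "gff")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff"
    else "csv"
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    return(calls_df(df$contig, df$position, df$strand, df$mod_type,
                    df$qv, df$coverage))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  cov <- S4Vectors::mcols(gr)$coverage
  if (is.null(cov)) cov <- rep(1L, length(gr))
  calls_df(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr),
           as.character(GenomicRanges::strand(gr)),
           as.character(S4Vectors::mcols(gr)$type),
           S4Vectors::mcols(gr)$score,
           as.integer(cov))
}

#' Write modification calls (CSV or GFF3)
#' @param calls a `mod_calls` data.frame.
#' @param path output path; format by extension unless `format` given.
#' @param format `"auto"`, `"csv"` or `"gff"`.
#' @export
write_calls <- function(calls, path, format = c("auto", "csv", "gff")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff"
    else "csv"
  if (format == "csv") {
    write.csv(as.data.frame(calls), path, row.names = FALSE, quote = FALSE)
  } else {
    gr <- GenomicRanges::GRanges(
      calls$contig, IRanges::IRanges(calls$position, calls$position),
      strand = calls$strand)
    S4Vectors::mcols(gr)$type <- calls$mod_type
    S4Vectors::mcols(gr)$score <- calls$qv
    S4Vectors::mcols(gr)$source <- "motifcassette"
    S4Vectors::mcols(gr)$coverage <- calls$coverage
    rtracklayer::export(gr, path, format = "gff3")
  }
  invisible(path)
}

#' Summarise detection of a motif list against modification calls
#'
#' The central per-methyltransferase report: for every motif, how many
#' sites the sequence carries, how many of those sites are detected as
#' modified (a qualifying call at the expected base), the detection
#' fraction, and the mean modification QV of the matched calls. Rows are
#' sorted by descending detection fraction, then descending site count.
#'
#' @param seq sequence (FASTA path, character, `DNAString(Set)`).
#' @param motifs list of `methyl_motif`.
#' @param calls a `mod_calls` data.frame.
#' @param qv_min minimum modification QV (default 30).
#' @param collapse_palindromes,circular see [find_sites()].
#' @return data.frame with columns motif, modified_position, mod_type,
#'   fraction_detected, mean_qv, n_sites, n_detected.
#' @export
summarize_motifs <- function(seq, motifs, calls, qv_min = 30,
                             collapse_palindromes = TRUE, circular = FALSE) {
  if (is.character(seq) && length(seq) == 1L && file.exists(seq))
    seq <- readDNAStringSet(seq)
  ss <- as_dna_set(seq)
  if (inherits(motifs, "methyl_motif")) motifs <- list(motifs)
  rows <- lapply(motifs, function(m) {
    sites <- find_sites(ss, m, collapse_palindromes, circular)
    dr <- detection_rate(sites, calls, qv_min, m$mod_type)
    data.frame(motif = m$sequence, modified_position = m$modified_position,
               mod_type = m$mod_type,
               fraction_detected = if (dr$n_sites > 0L) dr$fraction else NA_real_,
               mean_qv = dr$mean_qv, n_sites = dr$n_sites,
               n_detected = dr$n_detected, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.na(out$fraction_detected), -1,
                           out$fraction_detected), -out$n_sites), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a motif summary as CSV
#' @param summary data.frame from [summarize_motifs()].
#' @param path output path.
#' @export
write_motif_summary <- function(summary, path) {
  write.csv(summary, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# smallest IUPAC code covering >= min_fraction of the column's base mass;
# ties among equal-cardinality codes broken by larger coverage, then
# alphabetically. Returns "N" when nothing below N qualifies.
column_code <- function(freq, min_fraction) {
  codes <- names(IUPAC_SETS)
  card <- lengths(IUPAC_SETS)
  cover <- vapply(codes, function(code)
    sum(freq[IUPAC_SETS[[code]]]), 0)
  ok <- cover >= min_fraction
  if (!any(ok)) return("N")
  ord <- order(card[ok], -cover[ok], codes[ok])
  codes[ok][ord][1]
}

#' Discover a recognition motif from modification calls
#'
#' A simplified de novo motif finder working from calls alone: the +/- k
#' sequence context around every qualifying call is collected (contexts of
#' minus-strand calls are reverse complemented so the modified base sits at
#' a fixed index), a per-position base-frequency profile is built, each
#' position is assigned the smallest IUPAC code covering at least
#' `min_fraction` of its base mass, flanking N are trimmed, and the
#' candidate is then greedily refined: edge positions are trimmed while the
#' score — the fraction of the motif's genome-wide sites that are detected
#' by the calls — improves, and ambiguous positions beyond
#' `max_degeneracy` are collapsed to their majority base when that does not
#' cost score. Background positions see near-uniform base usage, which no
#' code below N covers at the default `min_fraction`, so they fall away as
#' N; positions under selection retain their (possibly degenerate)
#' consensus. A composite signal — calls planted at the sites of two
#' motifs differing at one position — yields the degenerate union motif.
#'
#' @param seq sequence the calls refer to.
#' @param calls a `mod_calls` data.frame.
#' @param k context half-width (default 10).
#' @param min_fraction minimum base-mass coverage per position (default 0.9).
#' @param qv_min minimum modification QV for a call to be used (default 30).
#' @param max_degeneracy ambiguous (non-N) positions tolerated without score
#'   justification (default 2).
#' @return list of class `refined_motif`: `motif` (a `methyl_motif`, or NULL
#'   when no signal), `score`, `n_calls`; or a no-motif result when no call
#'   qualifies or no position rises above background.
#' @export
refine_motif <- function(seq, calls, k = 10L, min_fraction = 0.9,
                         qv_min = 30, max_degeneracy = 2L) {
  ss <- as_dna_set(seq)
  calls <- calls[calls$qv >= qv_min, , drop = FALSE]
  no_motif <- structure(list(motif = NULL, score = NA_real_,
                             n_calls = nrow(calls)),
                        class = "refined_motif")
  if (nrow(calls) == 0L) return(no_motif)
  contexts <- character(0)
  for (i in seq_along(ss)) {
    contig <- names(ss)[i]
    sub <- calls[calls$contig == contig, , drop = FALSE]
    if (!nrow(sub)) next
    L <- length(ss[[i]])
    keep <- sub$position > k & sub$position <= L - k
    sub <- sub[keep, , drop = FALSE]
    if (!nrow(sub)) next
    win <- Biostrings::extractAt(
      ss[[i]], IRanges::IRanges(sub$position - k, sub$position + k))
    win <- as.character(win)
    minus <- sub$strand == "-"
    if (any(minus))
      win[minus] <- as.character(reverseComplement(DNAStringSet(win[minus])))
    contexts <- c(contexts, win)
  }
  if (!length(contexts)) return(no_motif)
  mat <- do.call(rbind, strsplit(contexts, "", fixed = TRUE))
  codes <- apply(mat, 2, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    if (!length(col)) return("N")
    freq <- table(factor(col, levels = c("A", "C", "G", "T"))) / length(col)
    column_code(setNames(as.numeric(freq), names(freq)), min_fraction)
  })
  center <- k + 1L
  spec_idx <- which(codes != "N")
  if (!length(spec_idx)) return(no_motif)
  first <- min(spec_idx, center); last <- max(spec_idx, center)
  mod_types <- table(calls$mod_type)
  mod_type <- names(mod_types)[which.max(mod_types)]
  if (mod_type == "modified_base") mod_type <- "unknown"
  make_motif <- function(from, to, code_vec) {
    seq_str <- paste(code_vec[from:to], collapse = "")
    pos <- center - from + 1L
    # center must stay compatible with the call type
    tryCatch(motif(seq_str, pos, mod_type), error = function(e) NULL)
  }
  # call keys used for recall: qualifying calls the motif's sites explain
  call_keys <- unique(paste(calls$contig, calls$strand, calls$position,
                            sep = "\r"))
  score_motif <- function(m) {
    if (is.null(m)) return(list(frac = -Inf, f = -Inf))
    sites <- find_sites(ss, m)
    if (!nrow(sites)) return(list(frac = -Inf, f = -Inf))
    dr <- detection_rate(sites, calls, qv_min, m$mod_type)
    site_keys <- c(paste(sites$contig, sites$strand, sites$mod_pos,
                         sep = "\r"),
                   paste(sites$contig, "-", sites$mod_pos_rev,
                         sep = "\r")[!is.na(sites$mod_pos_rev)])
    recall <- mean(call_keys %in% site_keys)
    prec <- dr$fraction
    f <- if (prec + recall > 0) 2 * prec * recall / (prec + recall) else 0
    list(frac = dr$fraction, f = f)
  }
  cur <- make_motif(first, last, codes)
  if (is.null(cur)) return(no_motif)
  cur_score <- score_motif(cur)
  cur_range <- c(first, last)
  repeat {
    improved <- FALSE
    # trim one position from either end (keep the modified base inside and
    # at least two positions); a trim that does not cost combined score is
    # taken — prefer the simpler motif on a tie
    for (side in c("left", "right")) {
      from <- cur_range[1]; to <- cur_range[2]
      if (side == "left") from <- from + 1L else to <- to - 1L
      if (from > center || to < center || to - from < 1L) next
      cand <- make_motif(from, to, codes)
      s <- score_motif(cand)
      if (!is.null(cand) && s$f >= cur_score$f - 1e-9) {
        cur <- cand; cur_score <- s; cur_range <- c(from, to)
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  # collapse excess degeneracy unless it pays for itself in score
  chars <- strsplit(cur$sequence, "", fixed = TRUE)[[1]]
  amb <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(amb) > max_degeneracy) {
    counts <- apply(mat[, seq(cur_range[1], cur_range[2]), drop = FALSE], 2,
                    function(col) table(factor(col, levels = c("A", "C",
                                                               "G", "T"))))
    excess <- amb[order(-vapply(amb, function(j)
      max(counts[, j]) / sum(counts[, j]), 0))]
    excess <- tail(excess, length(amb) - max_degeneracy)
    for (j in excess) {
      trial <- chars
      trial[j] <- rownames(counts)[which.max(counts[, j])]
      cand <- tryCatch(motif(paste(trial, collapse = ""),
                             cur$modified_position, cur$mod_type),
                       error = function(e) NULL)
      s <- score_motif(cand)
      if (!is.null(cand) && s$f >= cur_score$f - 1e-9) {
        cur <- cand; cur_score <- s; chars <- trial
      }
    }
  }
  structure(list(motif = cur, score = cur_score$frac,
                 n_calls = nrow(calls)),
            class = "refined_motif")
}

#' @export
print.refined_motif <- function(x, ...) {
  if (is.null(x$motif)) {
    cat("<refined_motif> no motif (", x$n_calls, " qualifying calls)\n",
        sep = "")
  } else {
    cat(sprintf("<refined_motif> %s  modified position %d (%s)  score %.3f  from %d calls\n",
                x$motif$sequence, x$motif$modified_position,
                x$motif$mod_type, x$score, x$n_calls))
  }
  invisible(x)
}

#' Link a detected motif to the best-matching design motif
#'
#' Relates a de novo detected motif to each motif of the cassette design
#' using [relate_motifs()] and returns the best match, ranking relations
#' identical > detected-subset-of-design > design-subset-of-detected >
#' overlapping; disjoint design motifs are never linked. Ties are broken by
#' the larger number of shared specified positions.
#'
#' @param detected a `methyl_motif`.
#' @param design_motifs non-empty list of `methyl_motif`.
#' @return list with `design_motif` (NULL when nothing overlaps),
#'   `relation`, `shared_specified`.
#' @export
assign_to_design <- function(detected, design_motifs) {
  stopifnot(length(design_motifs) >= 1L)
  rank <- c(identical = 4, a_subset_of_b = 3, b_subset_of_a = 2,
            overlapping = 1, disjoint = 0)
  best <- NULL; best_key <- c(-1, -1)
  for (d in design_motifs) {
    rel <- relate_motifs(detected, d)
    key <- c(rank[[as.character(rel)]], attr(rel, "shared_specified"))
    if (key[1] > best_key[1] ||
        (key[1] == best_key[1] && key[2] > best_key[2])) {
      best <- list(design_motif = d, relation = as.character(rel),
                   shared_specified = attr(rel, "shared_specified"))
      best_key <- key
    }
  }
  if (best$relation == "disjoint")
    return(list(design_motif = NULL, relation = "no_link",
                shared_specified = 0L))
  best
}
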