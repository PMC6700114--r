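# read sequences from FASTA/FASTQ (gz accepted) into a named DNAStringSet
read_seqs <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", x, ignore.case = TRUE))
      "fastq" else "fasta"
    ss <- readDNAStringSet(x, format = fmt)
    # FASTA headers: keep the id up to the first whitespace
    names(ss) <- sub("\\s.*$", "", names(ss))
    return(ss)
  }
  as_dna_set(x)
}

# vectorized local alignment of many reads against one reference; returns
# per-read identity (matches / alignment length), aligned fraction of the
# reference, SW score, and aligned read bases
align_stats <- function(reads, ref) {
  if (length(reads) == 0L)
    return(data.frame(identity = numeric(0), aligned_fraction = numeric(0),
                      score = numeric(0), aligned_bases = numeric(0)))
  aln <- pairwiseAlignment(reads, DNAString(ref), type = "local")
  ref_w <- IRanges::width(Biostrings::subject(aln))
  data.frame(identity = Biostrings::pid(aln, type = "PID1") / 100,
             aligned_fraction = ref_w / nchar(ref),
             score = Biostrings::score(aln),
             aligned_bases = IRanges::width(Biostrings::pattern(aln)))
}

# better of forward / reverse-complement alignment for each read
align_both <- function(reads, ref) {
  fwd <- align_stats(reads, ref)
  rev <- align_stats(reverseComplement(reads), ref)
  take_rev <- rev$score > fwd$score
  out <- fwd
  out[take_rev, ] <- rev[take_rev, ]
  out$orientation <- ifelse(take_rev, "-", "+")
  out
}

#' Select reads containing the motif cassette
#'
#' First sorting step for a pooled-plasmid sequencing run: a read is kept
#' iff a local alignment of the cassette reference against the read (in
#' either orientation) reaches `min_identity` over at least
#' `min_aligned_fraction` of the cassette length. Kept reads are
#' reverse-complemented to the cassette-forward orientation so downstream
#' gene alignment sees a canonical strand.
#'
#' @param reads FASTA/FASTQ path, character vector, or `DNAStringSet`.
#' @param cassette_ref cassette reference sequence (string or
#'   `motif_cassette`); must be at least 50 bp.
#' @param min_identity minimum alignment identity (default 0.85).
#' @param min_aligned_fraction minimum fraction of the cassette covered by
#'   the alignment (default 0.8).
#' @return list with `kept` (canonicalised `DNAStringSet`), `stats`
#'   (per-read data.frame: read_id, cassette_identity, aligned_fraction,
#'   orientation, kept), `unassigned_no_cassette` (read ids).
#' @export
select_by_cassette <- function(reads, cassette_ref, min_identity = 0.85,
                               min_aligned_fraction = 0.8) {
  if (inherits(cassette_ref, "motif_cassette"))
    cassette_ref <- cassette_ref$sequence
  if (is.character(cassette_ref) && length(cassette_ref) == 1L &&
      file.exists(cassette_ref))
    cassette_ref <- as.character(read_seqs(cassette_ref)[[1]])
  cassette_ref <- toupper(as.character(cassette_ref))
  if (nchar(cassette_ref) < 50L)
    stop("cassette reference must be at least 50 bp")
  rs <- read_seqs(reads)
  st <- align_both(rs, cassette_ref)
  kept_mask <- st$identity >= min_identity &
    st$aligned_fraction >= min_aligned_fraction
  kept <- rs[kept_mask]
  flip <- st$orientation[kept_mask] == "-"
  if (any(flip)) kept[flip] <- reverseComplement(kept[flip])
  stats <- data.frame(read_id = names(rs),
                      cassette_identity = st$identity,
                      cassette_aligned_fraction = st$aligned_fraction,
                      orientation = st$orientation,
                      kept = kept_mask, stringsAsFactors = FALSE)
  list(kept = kept, stats = stats,
       unassigned_no_cassette = names(rs)[!kept_mask])
}

#' Group cassette-containing reads by methyltransferase gene
#'
#' Second sorting step: every kept read is locally aligned against every
#' gene reference (both orientations) and assigned to the best-scoring gene
#' that passes the identity and aligned-fraction thresholds. When the top
#' two gene scores are within `tie_margin` (relative), the read is left
#' `unassigned_ambiguous`. The gene reference set should include the
#' negative-control insert so control reads form their own group instead of
#' contaminating gene groups.
#'
#' @param kept_reads canonicalised `DNAStringSet` from
#'   [select_by_cassette()].
#' @param gene_refs named `DNAStringSet`/character vector/FASTA path of
#'   gene references; names must be unique.
#' @param min_identity minimum gene alignment identity (default 0.85).
#' @param min_aligned_fraction minimum fraction of the gene covered
#'   (default 0.9).
#' @param tie_margin relative score margin below which the top two genes
#'   tie (default 0.02).
#' @return data.frame of class `bin_assignments`: read_id, group,
#'   gene_identity, gene_aligned_fraction, aligned_bases.
#' @export
group_by_gene <- function(kept_reads, gene_refs, min_identity = 0.85,
                          min_aligned_fraction = 0.9, tie_margin = 0.02) {
  refs <- read_seqs(gene_refs)
  if (anyDuplicated(names(refs)))
    stop("duplicate gene reference names")
  n <- length(kept_reads)
  gene_names <- names(refs)
  if (n == 0L)
    return(structure(data.frame(read_id = character(0), group = character(0),
                                gene_identity = numeric(0),
                                gene_aligned_fraction = numeric(0),
                                aligned_bases = numeric(0),
                                stringsAsFactors = FALSE),
                     class = c("bin_assignments", "data.frame")))
  per_gene <- lapply(gene_names, function(g)
    align_both(kept_reads, as.character(refs[[g]])))
  scores <- vapply(per_gene, function(s) s$score, numeric(n))
  scores <- matrix(scores, nrow = n)
  best_idx <- max.col(scores, ties.method = "first")
  best <- scores[cbind(seq_len(n), best_idx)]
  second <- vapply(seq_len(n), function(i)
    if (ncol(scores) > 1L) max(scores[i, -best_idx[i]]) else -Inf, 0)
  bs <- do.call(rbind, lapply(seq_len(n), function(i)
    per_gene[[best_idx[i]]][i, ]))
  passes <- bs$identity >= min_identity &
    bs$aligned_fraction >= min_aligned_fraction
  ambiguous <- is.finite(second) & best > 0 &
    (best - second) / pmax(best, 1e-9) < tie_margin
  group <- ifelse(!passes, "unassigned_ambiguous",
                  ifelse(ambiguous, "unassigned_ambiguous",
                         gene_names[best_idx]))
  # a read failing thresholds outright is distinct from a tie only in label
  group[!passes] <- "unassigned_ambiguous"
  structure(data.frame(read_id = names(kept_reads), group = group,
                       gene_identity = bs$identity,
                       gene_aligned_fraction = bs$aligned_fraction,
                       aligned_bases = bs$aligned_bases,
                       stringsAsFactors = FALSE),
            class = c("bin_assignments", "data.frame"))
}

#' Two-step read sorting: cassette selection, then gene grouping
#'
#' @inheritParams select_by_cassette
#' @inheritParams group_by_gene
#' @param min_read_length drop reads shorter than this before sorting
#'   (default 0, no filter).
#' @param min_cassette_identity,min_cassette_aligned_fraction thresholds
#'   for the cassette step.
#' @return list with `assignments` (a `bin_assignments` data.frame covering
#'   every input read, unassigned categories included), `kept_reads`
#'   (canonicalised), `cassette_stats`.
#' @export
sort_reads <- function(reads, cassette_ref, gene_refs,
                       min_cassette_identity = 0.85,
                       min_cassette_aligned_fraction = 0.8,
                       min_identity = 0.85, min_aligned_fraction = 0.9,
                       tie_margin = 0.02, min_read_length = 0L) {
  rs <- read_seqs(reads)
  if (min_read_length > 0L)
    rs <- rs[IRanges::width(rs) >= min_read_length]
  sel <- select_by_cassette(rs, cassette_ref, min_cassette_identity,
                            min_cassette_aligned_fraction)
  grouped <- group_by_gene(sel$kept, gene_refs, min_identity,
                           min_aligned_fraction, tie_margin)
  n0 <- length(sel$unassigned_no_cassette)
  no_cas <- data.frame(read_id = sel$unassigned_no_cassette,
                       group = rep("unassigned_no_cassette", n0),
                       gene_identity = rep(NA_real_, n0),
                       gene_aligned_fraction = rep(NA_real_, n0),
                       aligned_bases = rep(NA_real_, n0),
                       stringsAsFactors = FALSE)
  assignments <- rbind(as.data.frame(grouped), no_cas)
  ci <- sel$stats$cassette_identity[match(assignments$read_id,
                                          sel$stats$read_id)]
  assignments$cassette_identity <- ci
  class(assignments) <- c("bin_assignments", "data.frame")
  list(assignments = assignments, kept_reads = sel$kept,
       cassette_stats = sel$stats)
}

#' @export
print.bin_assignments <- function(x, ...) {
  cat("<bin_assignments>", nrow(x), "reads\n")
  print(table(x$group))
  invisible(x)
}

#' Write per-group read files and a summary CSV
#'
#' One FASTA per non-empty group plus `group_summary.csv` with read counts,
#' mean identities and estimated fold coverage (aligned read bases over
#' reference length) per group. Empty groups keep their summary row with
#' count 0; the group files partition the input reads.
#'
#' @param assignments a `bin_assignments` data.frame (from [sort_reads()]).
#' @param reads the reads the assignments refer to (any [read_seqs()]
#'   input); canonicalised reads from [sort_reads()] work too.
#' @param gene_refs gene references (for coverage denominators); optional.
#' @param out_dir output directory.
#' @return invisibly, the summary data.frame.
#' @export
report_groups <- function(assignments, reads, gene_refs = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rs <- read_seqs(reads)
  ref_len <- if (!is.null(gene_refs)) {
    refs <- read_seqs(gene_refs)
    setNames(IRanges::width(refs), names(refs))
  } else NULL
  groups <- unique(c(assignments$group,
                     if (!is.null(ref_len)) names(ref_len)))
  rows <- lapply(groups, function(g) {
    sub <- assignments[assignments$group == g, , drop = FALSE]
    ids <- intersect(sub$read_id, names(rs))
    if (length(ids) > 0L) {
      fp <- file.path(out_dir, paste0("group_", gsub("[^A-Za-z0-9_.-]", "_", g),
                                      ".fasta"))
      writeXStringSet(rs[ids], fp)
    }
    cov <- if (!is.null(ref_len) && g %in% names(ref_len) && nrow(sub) > 0L)
      sum(sub$aligned_bases, na.rm = TRUE) / ref_len[[g]] else NA_real_
    data.frame(group = g, n_reads = nrow(sub),
               mean_gene_identity = if (nrow(sub))
                 mean(sub$gene_identity, na.rm = TRUE) else NA_real_,
               est_coverage = cov, stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  write.csv(summary, file.path(out_dir, "group_summary.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(summary)
}
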