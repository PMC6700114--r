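#' @import methods
#' @importFrom stats rbinom rnorm runif setNames complete.cases median
#' @importFrom utils read.csv write.csv head tail
NULL

# IUPAC nucleotide code -> base set (standard 15-letter alphabet)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  M = "K", R = "Y", W = "W", S = "S", Y = "R", K = "M",
  V = "B", H = "D", D = "H", B = "V", N = "N"
)

MOD_TYPES <- c("m6A", "m4C", "m5C", "unknown")

# smallest IUPAC code whose set equals a base set; base_set over A,C,G,T
iupac_code_for <- function(base_set) {
  base_set <- sort(unique(base_set))
  for (code in names(IUPAC_SETS)) {
    if (identical(sort(IUPAC_SETS[[code]]), base_set)) return(code)
  }
  stop("no IUPAC code for base set: ", paste(base_set, collapse = ""))
}

#' Construct a degenerate methylation motif
#'
#' A `methyl_motif` couples a recognition sequence written in the 15-letter
#' IUPAC nucleotide alphabet with the position of the methylated base
#' (1-based) and the modification type (m6A, m4C, m5C, or unknown).
#' Bacterial methyltransferases deposit N6-methyladenine (m6A),
#' N4-methylcytosine (m4C) or C5-methylcytosine (m5C) at a fixed position of
#' their recognition sequence, so the triple (sequence, position, type) is
#' the unit the rest of the package works with.
#'
#' @param sequence motif string over the IUPAC alphabet
#'   (A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N); case-insensitive, stored uppercase.
#' @param modified_position 1-based index of the methylated base within
#'   `sequence`.
#' @param mod_type one of `"m6A"`, `"m4C"`, `"m5C"`, `"unknown"`.
#' @param opposite_strand logical; marks a motif whose modification call
#'   refers to the base on the opposite strand (used when reverse
#'   complementing, see [reverse_complement_motif()]).
#' @return an object of class `methyl_motif`.
#' @examples
#' motif("GATGNNNNNNTGC", 2, "m6A")
#' motif("gatc", 2, "m6A")  # uppercased
#' @export
motif <- function(sequence, modified_position, mod_type = "unknown",
                  opposite_strand = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0)
  seq_up <- toupper(sequence)
  chars <- strsplit(seq_up, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad))
    stop(sprintf("invalid IUPAC character '%s' at position %d of '%s'",
                 chars[bad[1]], bad[1], seq_up))
  if (all(chars == "N"))
    stop("motif must contain at least one non-N position")
  modified_position <- as.integer(modified_position)
  if (is.na(modified_position) || modified_position < 1L ||
      modified_position > length(chars))
    stop("modified_position must lie within the motif (1..", length(chars), ")")
  mod_type <- match.arg(mod_type, MOD_TYPES)
  base_set <- IUPAC_SETS[[chars[modified_position]]]
  # with opposite_strand the type refers to the complementary base
  need <- if (isTRUE(opposite_strand)) c(A = "T", C = "G") else c(A = "A", C = "C")
  if (mod_type == "m6A" && !need[["A"]] %in% base_set)
    stop("m6A requires an A-compatible base at the modified position")
  if (mod_type %in% c("m4C", "m5C") && !need[["C"]] %in% base_set)
    stop(mod_type, " requires a C-compatible base at the modified position")
  structure(
    list(sequence = seq_up, modified_position = modified_position,
         mod_type = mod_type, opposite_strand = isTRUE(opposite_strand)),
    class = "methyl_motif"
  )
}

#' Parse a motif from its textual representation
#'
#' Convenience wrapper around [motif()] mirroring the `MOTIF:POS:TYPE` token
#' accepted on the command line, e.g. `"GATC:2:m6A"`.
#'
#' @param token a string `MOTIF:POS:TYPE` (TYPE optional, defaults unknown).
#' @return a `methyl_motif`.
#' @export
parse_motif_token <- function(token) {
  parts <- strsplit(token, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2L)
    stop("motif token must be MOTIF:POS[:TYPE], got '", token, "'")
  motif(parts[1], as.integer(parts[2]),
        if (length(parts) >= 3L) parts[3] else "unknown")
}

#' @export
print.methyl_motif <- function(x, ...) {
  cat(sprintf("<methyl_motif> %s  modified %s%d (%s)%s\n",
              x$sequence,
              substr(x$sequence, x$modified_position, x$modified_position),
              x$modified_position, x$mod_type,
              if (x$opposite_strand) " [opposite strand]" else ""))
  invisible(x)
}

#' @method format methyl_motif
#' @export
format.methyl_motif <- function(x, ...) {
  sprintf("%s%d%s", x$sequence, x$modified_position, x$mod_type)
}

#' Read a motif list from CSV
#'
#' Expects a headered CSV with columns `motif`, `modified_position`,
#' `mod_type` — the format produced by methylome analyses summarising a
#' strain's methylation motifs.
#'
#' @param path CSV file path.
#' @return a list of `methyl_motif` objects.
#' @export
read_motifs <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("motif", "modified_position", "mod_type")
  if (!all(need %in% names(df)))
    stop("motif CSV needs columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    motif(df$motif[i], df$modified_position[i], df$mod_type[i]))
}

#' Write a motif list to CSV
#' @param motifs list of `methyl_motif`.
#' @param path output CSV path.
#' @export
write_motifs <- function(motifs, path) {
  df <- data.frame(
    motif = vapply(motifs, function(m) m$sequence, ""),
    modified_position = vapply(motifs, function(m) m$modified_position, 1L),
    mod_type = vapply(motifs, function(m) m$mod_type, ""),
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# maximal runs of a character class; returns data.frame(start, end, len)
char_runs <- function(chars, is_member) {
  r <- rle(is_member)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             len = r$lengths[keep])
}

#' Classify a motif as bipartite (spacer) or simple
#'
#' Type I restriction-modification enzymes recognise bipartite motifs: two
#' fully specified half-sites separated by a run of 2-10 unspecified (N)
#' bases. Such motifs are classed `"spacer"`; everything else (typical for
#' Type II and Type III enzymes) is `"simple"`. The class decides how many
#' copies of the motif a designed cassette carries (see [cassette_spec()]).
#'
#' A run of a single N does not make a motif bipartite, and a run longer
#' than 10 N is rejected with a warning and classed simple.
#'
#' @param m a `methyl_motif`.
#' @return `"spacer"` or `"simple"`.
#' @examples
#' classify_motif(motif("GAGNNNNNGAT", 2, "m6A"))  # spacer
#' classify_motif(motif("CAAAAAR", 6, "m6A"))      # simple
#' @export
classify_motif <- function(m) {
  chars <- strsplit(m$sequence, "", fixed = TRUE)[[1]]
  runs <- char_runs(chars, chars == "N")
  if (nrow(runs) == 0L) return("simple")
  # internal runs only (flanks must be non-empty)
  internal <- runs[runs$start > 1L & runs$end < length(chars), , drop = FALSE]
  if (any(internal$len > 10L))
    warning("N-run longer than 10 in '", m$sequence,
            "'; treating motif as simple")
  for (i in seq_len(nrow(internal))) {
    run <- internal[i, ]
    if (run$len < 2L || run$len > 10L) next
    left <- chars[seq_len(run$start - 1L)]
    right <- chars[seq.int(run$end + 1L, length(chars))]
    if (!any(left == "N") && !any(right == "N")) return("spacer")
  }
  "simple"
}

# positions of the spacer N-run (integer vector, empty if simple)
spacer_positions <- function(m) {
  if (classify_motif(m) != "spacer") return(integer(0))
  chars <- strsplit(m$sequence, "", fixed = TRUE)[[1]]
  runs <- char_runs(chars, chars == "N")
  internal <- runs[runs$start > 1L & runs$end < length(chars) &
                     runs$len >= 2L & runs$len <= 10L, , drop = FALSE]
  unlist(lapply(seq_len(nrow(internal)), function(i)
    seq.int(internal$start[i], internal$end[i])))
}

#' Count the concrete sequence variants a degenerate motif denotes
#'
#' The product over positions of the cardinality of each position's IUPAC
#' set. `N` counts as 4 only when `enumerate_N = TRUE`; by default N
#' positions are treated as unspecified filler (spacer) and contribute a
#' factor of 1.
#'
#' @param m a `methyl_motif`.
#' @param enumerate_N logical; treat N as an enumerable 4-base ambiguity.
#' @return integer (may be large for long degenerate motifs).
#' @examples
#' variant_count(motif("ATGNNTTA", 1, "m6A"), enumerate_N = TRUE)  # 16
#' variant_count(motif("GAWTC", 2, "m6A"))                          # 2
#' @export
variant_count <- function(m, enumerate_N = FALSE) {
  chars <- strsplit(m$sequence, "", fixed = TRUE)[[1]]
  card <- vapply(chars, function(ch) length(IUPAC_SETS[[ch]]), 1L)
  if (!enumerate_N) card[chars == "N"] <- 1L
  prod(card)
}

#' Expand a degenerate motif into its concrete variants
#'
#' Enumerates every concrete sequence the motif denotes. Positions inside a
#' spacer N-run are retained as `N` (they are filler between the two
#' half-sites, not specificity positions) unless `enumerate_N = TRUE`, in
#' which case all N positions are enumerated too. Variants are returned in
#' lexicographic order.
#'
#' @param m a `methyl_motif`.
#' @param enumerate_N logical; also enumerate N positions.
#' @param max_variants guard against combinatorial explosion.
#' @return character vector of variant sequences.
#' @examples
#' expand_motif(motif("SATC", 2, "m6A"))  # "CATC" "GATC"
#' @export
expand_motif <- function(m, enumerate_N = FALSE, max_variants = 65536L) {
  chars <- strsplit(m$sequence, "", fixed = TRUE)[[1]]
  sets <- lapply(chars, function(ch) IUPAC_SETS[[ch]])
  if (!enumerate_N) sets[chars == "N"] <- list("N")
  n <- prod(vapply(sets, length, 1L))
  if (n > max_variants)
    stop("motif expands to ", n, " variants (> max_variants)")
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  variants <- apply(grid[, rev(seq_along(sets)), drop = FALSE], 1, paste0,
                    collapse = "")
  sort(unique(variants))
}

#' Reverse complement of a degenerate motif
#'
#' IUPAC-aware reverse complement. The modified position is remapped to
#' `length - position + 1` and the motif is flagged `opposite_strand`,
#' recording that the modification type now refers to the base on the other
#' strand (complementary Type I motif pairs are conventionally listed in
#' both orientations). Applying the operation twice returns the original
#' motif.
#'
#' @param m a `methyl_motif`.
#' @return a `methyl_motif`.
#' @examples
#' reverse_complement_motif(motif("GAGNNNNNGAT", 2, "m6A"))  # ATCNNNNNCTC
#' @export
reverse_complement_motif <- function(m) {
  chars <- strsplit(m$sequence, "", fixed = TRUE)[[1]]
  rc <- paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
  motif(rc, nchar(m$sequence) - m$modified_position + 1L, m$mod_type,
        opposite_strand = !m$opposite_strand)
}

# is the motif its own IUPAC reverse complement?
is_palindromic <- function(m) {
  chars <- strsplit(m$sequence, "", fixed = TRUE)[[1]]
  rc <- paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
  identical(rc, m$sequence)
}

# position-wise IUPAC sets for a motif sequence string
seq_sets <- function(s) {
  lapply(strsplit(s, "", fixed = TRUE)[[1]], function(ch) IUPAC_SETS[[ch]])
}

# best ungapped alignment offset of b relative to a, maximising the number
# of overlapping positions where both motifs are specified (non-N);
# ties broken by the smallest |offset|, then by the negative offset first.
best_offset <- function(a_seq, b_seq) {
  na <- nchar(a_seq); nb <- nchar(b_seq)
  a_spec <- strsplit(a_seq, "", fixed = TRUE)[[1]] != "N"
  b_spec <- strsplit(b_seq, "", fixed = TRUE)[[1]] != "N"
  offsets <- seq.int(-(nb - 1L), na - 1L)
  shared <- vapply(offsets, function(off) {
    ia <- seq_len(na)
    ib <- ia - off
    ok <- ib >= 1L & ib <= nb
    sum(a_spec[ia[ok]] & b_spec[ib[ok]])
  }, 1L)
  best <- max(shared)
  cand <- offsets[shared == best]
  cand <- cand[order(abs(cand), cand)]
  list(offset = cand[1], shared = best)
}

# pad both motif strings with N to a common window given b's offset
pad_common <- function(a_seq, b_seq, offset) {
  na <- nchar(a_seq); nb <- nchar(b_seq)
  start <- min(1L, 1L + offset)
  end <- max(na, nb + offset)
  w <- end - start + 1L
  pad <- function(s, from) {
    paste0(strrep("N", from - start), s,
           strrep("N", end - (from + nchar(s) - 1L)))
  }
  c(pad(a_seq, 1L), pad(b_seq, 1L + offset))
}

#' Set-theoretic relation between two degenerate motifs
#'
#' Aligns the two motifs by ungapped sliding (offset maximising the number
#' of positions specified in both; ties broken toward the smallest offset),
#' pads them with N to a common window, and compares the concrete-sequence
#' sets they denote position-by-position. Because both sets are Cartesian
#' products of per-position base sets, subset/disjointness can be decided
#' position-wise.
#'
#' @param a,b `methyl_motif` objects.
#' @return one of `"identical"`, `"a_subset_of_b"`, `"b_subset_of_a"`,
#'   `"overlapping"`, `"disjoint"`, with attributes `offset` and
#'   `shared_specified`.
#' @examples
#' relate_motifs(motif("GATC", 2, "m6A"), motif("SATC", 2, "m6A"))
#' @export
relate_motifs <- function(a, b) {
  al <- best_offset(a$sequence, b$sequence)
  padded <- pad_common(a$sequence, b$sequence, al$offset)
  sa <- seq_sets(padded[1]); sb <- seq_sets(padded[2])
  sub_ab <- all(mapply(function(x, y) all(x %in% y), sa, sb))
  sub_ba <- all(mapply(function(x, y) all(y %in% x), sa, sb))
  disj <- any(mapply(function(x, y) length(intersect(x, y)) == 0L, sa, sb))
  rel <- if (sub_ab && sub_ba) "identical"
  else if (sub_ab) "a_subset_of_b"
  else if (sub_ba) "b_subset_of_a"
  else if (disj) "disjoint"
  else "overlapping"
  structure(rel, offset = al$offset, shared_specified = al$shared)
}

#' Does a set of motifs jointly cover exactly another motif?
#'
#' `TRUE` iff the union of the concrete-sequence sets of `parts` equals the
#' concrete-sequence set of `whole`. Used to recognise composite motifs: a
#' degenerate motif called on a genome may really be the union of two
#' independent motifs methylated by different enzymes (e.g. SATC = GATC +
#' CATC).
#'
#' @param parts list of `methyl_motif`, all the same length as `whole`.
#' @param whole a `methyl_motif`.
#' @return logical.
#' @examples
#' union_equals(list(motif("GATC", 2, "m6A"), motif("CATC", 2, "m6A")),
#'              motif("SATC", 2, "m6A"))
#' @export
union_equals <- function(parts, whole) {
  if (inherits(parts, "methyl_motif")) parts <- list(parts)
  lens <- vapply(parts, function(p) nchar(p$sequence), 1L)
  if (any(lens != nchar(whole$sequence)))
    stop("all motifs must have the same length")
  # enumerate with spacer N retained when N patterns agree, else fully
  n_pat <- function(s) gsub("[^N]", "x", s)
  same_N <- all(vapply(parts, function(p)
    identical(n_pat(p$sequence), n_pat(whole$sequence)), TRUE))
  ex <- function(m) expand_motif(m, enumerate_N = !same_N)
  union_set <- sort(unique(unlist(lapply(parts, ex))))
  identical(union_set, ex(whole))
}
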