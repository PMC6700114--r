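# Independent oracles for property tests. These are deliberately naive and
# share no code with the package internals: their own IUPAC table, their own
# position-by-position matcher.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)
ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", M = "K", R = "Y",
                 W = "W", S = "S", Y = "R", K = "M", V = "B", H = "D",
                 D = "H", B = "V", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(unname(ORACLE_COMP[strsplit(s, "", fixed = TRUE)[[1]]])),
        collapse = "")
}

# all + strand match start positions of a degenerate pattern in a concrete
# subject; subject N matches only pattern N. Position-by-position over all
# offsets (naive by construction, vectorised only over offsets).
oracle_match_starts <- function(subject, pattern) {
  sub <- strsplit(subject, "", fixed = TRUE)[[1]]
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  L <- length(sub); k <- length(pat)
  if (k > L) return(integer(0))
  ok <- rep(TRUE, L - k + 1L)
  offs <- seq_len(L - k + 1L)
  for (j in seq_len(k)) {
    sb <- sub[offs + j - 1L]
    ok <- ok & ifelse(sb == "N", pat[j] == "N",
                      sb %in% ORACLE_IUPAC[[pat[j]]])
  }
  offs[ok]
}

# both-strand site count with palindromic loci counted once
oracle_count_sites <- function(subject, pattern) {
  rc <- oracle_revcomp(pattern)
  fwd <- oracle_match_starts(subject, pattern)
  if (rc == pattern) return(length(fwd))
  length(fwd) + length(oracle_match_starts(subject, rc))
}

# full enumeration of the concrete set a degenerate motif denotes
oracle_enumerate <- function(pattern) {
  sets <- lapply(strsplit(pattern, "", fixed = TRUE)[[1]],
                 function(ch) ORACLE_IUPAC[[ch]])
  grid <- expand.grid(sets, stringsAsFactors = FALSE)
  sort(unique(apply(grid, 1, paste0, collapse = "")))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random IUPAC motif string (no N), biased toward mostly-concrete motifs
random_iupac <- function(len, n_ambiguous = 1L) {
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (n_ambiguous > 0L) {
    idx <- sample(len, min(n_ambiguous, len))
    chars[idx] <- sample(c("M", "R", "W", "S", "Y", "K", "V", "H", "D", "B"),
                         length(idx), replace = TRUE)
  }
  paste(chars, collapse = "")
}

# a valid methyl_motif around a random string: pick a position whose set
# contains A or C and a matching type
random_motif <- function(len, n_ambiguous = 1L) {
  repeat {
    s <- random_iupac(len, n_ambiguous)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    ok <- which(vapply(chars, function(ch)
      any(c("A", "C") %in% ORACLE_IUPAC[[ch]]), TRUE))
    if (length(ok)) {
      p <- if (length(ok) == 1L) ok else sample(ok, 1L)
      ty <- if ("A" %in% ORACLE_IUPAC[[chars[p]]]) "m6A" else "m4C"
      return(motif(s, p, ty))
    }
  }
}

# small helper: default two-motif design used in several cassette tests
design_motifs_default <- function() {
  list(motif("GAGNNNNNGAT", 2, "m6A"), motif("AACCA", 5, "m6A"))
}
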