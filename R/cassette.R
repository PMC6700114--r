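# run code with a private, seeded RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Cassette design parameters
#'
#' Bundles the copy rules and rendering policies used by
#' [design_cassette()]. Bipartite (spacer-class) motifs get more copies than
#' simple motifs because their unspecified spacer makes each instance a
#' weaker observation of the half-sites; the defaults (12 vs 10) are the
#' copy numbers used for synthesised strain cassettes.
#'
#' Degenerate motifs are de-ambiguated under one of two modes:
#' `"distribute_L"` (default) keeps the class copy number L fixed and
#' spreads it over the motif's concrete variants — L distinct random
#' variants when there are more variants than copies, otherwise
#' `floor(L/V)` copies of every variant with the remainder assigned to
#' randomly chosen variants; `"per_variant_K"` instead places exactly `K`
#' copies of every variant.
#'
#' @param copies_spacer copies per bipartite (N-spacer) motif; default 12.
#' @param copies_simple copies per simple motif; default 10.
#' @param deambiguation_mode `"distribute_L"` or `"per_variant_K"`.
#' @param K copies per concrete variant in `per_variant_K` mode.
#' @param seed integer seed; the design is a pure function of the spec.
#' @param separator_policy `"random_base"` (default; synthesisable output)
#'   or `"literal_n"` (separators and spacer fillers left as N for review).
#' @param junction_guard rescan the rendered cassette and re-randomise
#'   fillers until no junction-created extra sites remain (default TRUE).
#' @param max_arrange_tries,max_guard_tries bounded retry counts.
#' @return an object of class `cassette_spec`.
#' @export
cassette_spec <- function(copies_spacer = 12L, copies_simple = 10L,
                          deambiguation_mode = c("distribute_L",
                                                 "per_variant_K"),
                          K = 1L, seed = 1L,
                          separator_policy = c("random_base", "literal_n"),
                          junction_guard = TRUE,
                          max_arrange_tries = 1000L,
                          max_guard_tries = 50L) {
  deambiguation_mode <- match.arg(deambiguation_mode)
  separator_policy <- match.arg(separator_policy)
  stopifnot(copies_spacer >= 1L, copies_simple >= 1L, K >= 1L)
  structure(list(copies_spacer = as.integer(copies_spacer),
                 copies_simple = as.integer(copies_simple),
                 deambiguation_mode = deambiguation_mode,
                 K = as.integer(K), seed = as.integer(seed),
                 separator_policy = separator_policy,
                 junction_guard = isTRUE(junction_guard),
                 max_arrange_tries = as.integer(max_arrange_tries),
                 max_guard_tries = as.integer(max_guard_tries)),
            class = "cassette_spec")
}

#' Allocate concrete variant copies for one motif
#'
#' Applies the de-ambiguation rules configured in `spec` to one motif and
#' returns the multiset of concrete variant sequences (spacer N retained)
#' that the cassette will carry for it. Uses the RNG stream of the caller;
#' [design_cassette()] seeds it from the spec.
#'
#' @param m a `methyl_motif`.
#' @param spec a `cassette_spec`.
#' @return character vector of variant sequences (with multiplicity).
#' @export
allocate_copies <- function(m, spec) {
  variants <- expand_motif(m)
  V <- length(variants)
  if (spec$deambiguation_mode == "per_variant_K")
    return(rep(variants, each = spec$K))
  L <- if (classify_motif(m) == "spacer") spec$copies_spacer
  else spec$copies_simple
  if (V >= L) {
    sort(sample(variants, L))
  } else {
    extra <- if (L %% V > 0L) sample(variants, L %% V) else character(0)
    sort(c(rep(variants, L %/% V), extra))
  }
}

# deterministic fallback: interleave by descending multiplicity
interleave_by_count <- function(ids) {
  groups <- split(seq_along(ids), ids)
  groups <- groups[order(-lengths(groups))]
  n <- length(ids)
  slots <- c(seq(1L, n, by = 2L), seq(2L, n, by = 2L))
  order_idx <- integer(n)
  order_idx[slots] <- unlist(groups)
  order_idx
}

#' Arrange allocated instances with no identical neighbours
#'
#' Produces a seeded random permutation of the allocated instances in which
#' no two consecutive instances carry the same concrete sequence, mirroring
#' the design rule that copies of the same motif are never placed directly
#' adjacent. Random shuffles are retried up to a bound, then a deterministic
#' interleaving by descending multiplicity is used. When the multiset makes
#' the constraint infeasible (one sequence holds more than half the slots)
#' the arrangement is emitted with a warning.
#'
#' @param alloc data.frame with columns `parent` (motif index), `variant`,
#'   and optionally `filled` (the spacer-filled concrete sequence, used for
#'   the adjacency check when present).
#' @param spec a `cassette_spec`.
#' @param warn warn when the constraint is infeasible (default TRUE).
#' @return `alloc` reordered.
#' @export
arrange_instances <- function(alloc, spec, warn = TRUE) {
  key <- if (!is.null(alloc$filled)) alloc$filled else alloc$variant
  n <- nrow(alloc)
  if (n <= 1L) return(alloc)
  ok <- function(v) all(v[-1] != v[-n])
  max_count <- max(table(key))
  feasible <- max_count <= (n + 1L) %/% 2L
  for (i in seq_len(spec$max_arrange_tries)) {
    perm <- sample.int(n)
    if (ok(key[perm])) return(alloc[perm, , drop = FALSE])
  }
  perm <- interleave_by_count(key)
  if (warn && (!ok(key[perm]) || !feasible))
    warning("no arrangement without identical adjacent instances exists; ",
            "emitting best-effort arrangement")
  alloc[perm, , drop = FALSE]
}

random_bases <- function(n) {
  if (n == 0L) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

fill_variant <- function(variant, policy) {
  if (policy == "literal_n") return(variant)
  chars <- strsplit(variant, "", fixed = TRUE)[[1]]
  nn <- chars == "N"
  chars[nn] <- random_bases(sum(nn))
  paste(chars, collapse = "")
}

render_once <- function(arranged, spec) {
  filled <- arranged$filled
  n <- length(filled)
  seps <- if (spec$separator_policy == "literal_n") rep("N", max(n - 1L, 0L))
  else random_bases(max(n - 1L, 0L))
  widths <- nchar(filled)
  starts <- cumsum(c(1L, head(widths, -1L) + 1L))
  pieces <- character(2L * n - 1L)
  pieces[seq(1L, 2L * n - 1L, by = 2L)] <- filled
  if (n > 1L) pieces[seq(2L, 2L * n - 2L, by = 2L)] <- seps
  seq <- paste(pieces, collapse = "")
  # filler mask: separator positions plus spacer-N positions of instances
  total <- nchar(seq)
  filler <- rep(FALSE, total)
  if (n > 1L) filler[starts[-1L] - 1L] <- TRUE
  for (i in seq_len(n)) {
    vn <- strsplit(arranged$variant[i], "", fixed = TRUE)[[1]] == "N"
    filler[starts[i] + which(vn) - 1L] <- TRUE
  }
  list(sequence = seq, filled = filled, start = starts,
       end = starts + widths - 1L, filler = filler)
}

# (motif, start, strand) keys of the sites determined by the design itself:
# per-instance variant-level matches lifted to cassette coordinates
designed_site_keys <- function(arranged, starts, motifs) {
  keys <- character(0)
  for (i in seq_along(starts)) {
    for (m in motifs) {
      s <- find_sites(arranged$variant[i], m)
      if (nrow(s))
        keys <- c(keys, paste(m$sequence, starts[i] + s$start - 1L,
                              s$strand, sep = "\r"))
    }
  }
  keys
}

#' Design a strain-specific motif cassette
#'
#' Builds a synthetic DNA segment containing every motif of a methylome in
#' prescribed copy numbers: 12 instances of each bipartite (N-spacer) motif
#' and 10 of each simple motif by default, degenerate motifs de-ambiguated
#' into concrete variants, all instances randomly ordered with no identical
#' neighbours and separated by exactly one separator base. Spacer N
#' positions and separators are filled with seeded random bases (policy
#' `random_base`) so the output is synthesisable. With the junction guard
#' on (default), the rendered sequence is rescanned for every design motif
#' and fillers are re-randomised until the scan finds exactly the designed
#' number of sites — no extra sites created across junctions or by filler
#' bases — so detection-rate denominators computed from the cassette are
#' exact.
#'
#' The design is a pure function of the motif list and the spec (including
#' its seed): identical inputs give byte-identical cassettes.
#'
#' @param motifs list of `methyl_motif` (or a single one).
#' @param spec a `cassette_spec`.
#' @return object of class `motif_cassette`: list with `sequence`,
#'   `instances` (data.frame parent/variant/filled/start/end), `spec`,
#'   `motifs`.
#' @examples
#' m <- list(motif("GAGNNNNNGAT", 2, "m6A"), motif("AACCA", 5, "m6A"))
#' cas <- design_cassette(m, cassette_spec(seed = 7))
#' cas
#' @export
design_cassette <- function(motifs, spec = cassette_spec()) {
  if (inherits(motifs, "methyl_motif")) motifs <- list(motifs)
  stopifnot(length(motifs) >= 1L)
  with_seed(spec$seed, {
    alloc <- do.call(rbind, lapply(seq_along(motifs), function(i)
      data.frame(parent = i, variant = allocate_copies(motifs[[i]], spec),
                 stringsAsFactors = FALSE)))
    alloc$filled <- vapply(alloc$variant, fill_variant, "",
                           policy = spec$separator_policy, USE.NAMES = FALSE)
    arranged <- arrange_instances(alloc, spec)
    r <- render_once(arranged, spec)
    if (spec$junction_guard) {
      designed_keys <- designed_site_keys(arranged, r$start, motifs)
      chars <- strsplit(r$sequence, "", fixed = TRUE)[[1]]
      for (try in seq_len(max(spec$max_guard_tries, 1L))) {
        seq_now <- paste(chars, collapse = "")
        extras <- empty_sites()
        for (m in motifs) {
          s <- find_sites(seq_now, m)
          if (!nrow(s)) next
          key <- paste(m$sequence, s$start, s$strand, sep = "\r")
          extras <- rbind(extras, s[!key %in% designed_keys, , drop = FALSE])
        }
        if (nrow(extras) == 0L) { r$sequence <- seq_now; break }
        # re-randomise only the fillers inside the artifact sites
        redraw <- unique(unlist(lapply(seq_len(nrow(extras)), function(j)
          seq.int(extras$start[j], extras$end[j]))))
        redraw <- redraw[r$filler[redraw]]
        if (length(redraw) == 0L || spec$separator_policy == "literal_n" ||
            try == spec$max_guard_tries)
          stop("junction guard failed after ", try,
               " rendering attempts; try a different seed")
        chars[redraw] <- random_bases(length(redraw))
      }
    }
    instances <- data.frame(
      parent = vapply(arranged$parent, function(i)
        motifs[[i]]$sequence, ""),
      variant = arranged$variant,
      # guard repair may have redrawn spacer fills: take the final sequence
      filled = substring(r$sequence, r$start, r$end),
      start = r$start, end = r$end, strand = "+",
      stringsAsFactors = FALSE)
    rownames(instances) <- NULL
    structure(list(sequence = r$sequence, instances = instances,
                   spec = spec, motifs = motifs),
              class = "motif_cassette")
  })
}

#' @export
print.motif_cassette <- function(x, ...) {
  cat(sprintf("<motif_cassette> %d bp, %d instances of %d motifs (seed %d)\n",
              nchar(x$sequence), nrow(x$instances), length(x$motifs),
              x$spec$seed))
  tab <- table(x$instances$parent)
  for (nm in names(tab))
    cat(sprintf("  %-20s %3d copies\n", nm, tab[[nm]]))
  invisible(x)
}

# ---- GenBank / FASTA output -------------------------------------------------

wrap_origin <- function(seq) {
  n <- nchar(seq)
  lines <- character(0)
  for (off in seq(1L, n, by = 60L)) {
    chunk <- substr(seq, off, min(off + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, by = 10L),
                           nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", off,
                              paste(tolower(tens), collapse = " ")))
  }
  lines
}

#' Write a cassette as annotated GenBank and FASTA files
#'
#' Each motif instance becomes a `misc_feature` with qualifiers recording
#' the parent motif, the concrete variant, the rendered (filled) sequence
#' and the modified position. Re-parsing the GenBank file with
#' [read_cassette_genbank()] recovers all instance coordinates.
#'
#' @param cassette a `motif_cassette`.
#' @param out_dir output directory (created if needed).
#' @param name base file name (default `"cassette"`).
#' @return invisibly, the paths written (genbank, fasta).
#' @export
write_cassette <- function(cassette, out_dir, name = "cassette") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gb <- file.path(out_dir, paste0(name, ".gb"))
  fa <- file.path(out_dir, paste0(name, ".fasta"))
  motif_by_seq <- setNames(cassette$motifs,
                           vapply(cassette$motifs, function(m) m$sequence, ""))
  lines <- c(
    sprintf("LOCUS       %s %d bp    DNA     linear   SYN",
            name, nchar(cassette$sequence)),
    "DEFINITION  synthetic methylation motif cassette.",
    "FEATURES             Location/Qualifiers")
  for (i in seq_len(nrow(cassette$instances))) {
    ins <- cassette$instances[i, ]
    pm <- motif_by_seq[[ins$parent]]
    lines <- c(lines,
               sprintf("     misc_feature    %d..%d", ins$start, ins$end),
               sprintf("                     /label=\"%s\"", ins$parent),
               sprintf("                     /note=\"variant=%s;filled=%s;modified_position=%d;mod_type=%s\"",
                       ins$variant, ins$filled, pm$modified_position,
                       pm$mod_type))
  }
  lines <- c(lines, "ORIGIN", wrap_origin(cassette$sequence), "//")
  writeLines(lines, gb)
  ss <- DNAStringSet(cassette$sequence)
  names(ss) <- name
  writeXStringSet(ss, fa)
  invisible(c(genbank = gb, fasta = fa))
}

#' Design and write a batch of independently seeded cassettes
#'
#' @param motifs list of `methyl_motif`.
#' @param spec a `cassette_spec`; cassette `i` uses seed `spec$seed + i - 1`.
#' @param count number of cassettes.
#' @param out_dir output directory.
#' @param name base name; files are suffixed `_1`, `_2`, ...
#' @return invisibly, a list of the written path pairs.
#' @export
write_cassettes <- function(motifs, spec = cassette_spec(), count = 1L,
                            out_dir = ".", name = "cassette") {
  paths <- vector("list", count)
  for (i in seq_len(count)) {
    spec_i <- spec
    spec_i$seed <- spec$seed + i - 1L
    cas <- design_cassette(motifs, spec_i)
    paths[[i]] <- write_cassette(cas, out_dir, sprintf("%s_%d", name, i))
  }
  invisible(paths)
}

#' Parse a cassette GenBank file written by [write_cassette()]
#'
#' @param path GenBank file path.
#' @return list with `sequence` (uppercase) and `instances` data.frame
#'   (parent, variant, filled, start, end, modified_position, mod_type).
#' @export
read_cassette_genbank <- function(path) {
  lines <- readLines(path)
  feat_idx <- grep("^     misc_feature", lines)
  instances <- lapply(feat_idx, function(i) {
    loc <- regmatches(lines[i],
                      regexec("(\\d+)\\.\\.(\\d+)", lines[i]))[[1]]
    label <- sub('.*/label="([^"]*)".*', "\\1", lines[i + 1L])
    note <- sub('.*/note="([^"]*)".*', "\\1", lines[i + 2L])
    kv <- strsplit(strsplit(note, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    data.frame(parent = label, variant = vals[["variant"]],
               filled = vals[["filled"]],
               start = as.integer(loc[2]), end = as.integer(loc[3]),
               modified_position = as.integer(vals[["modified_position"]]),
               mod_type = vals[["mod_type"]], stringsAsFactors = FALSE)
  })
  origin <- grep("^ORIGIN", lines)
  endrec <- grep("^//", lines)
  seq_lines <- lines[(origin + 1L):(endrec - 1L)]
  seq <- toupper(gsub("[ 0-9]", "", paste(seq_lines, collapse = "")))
  list(sequence = seq, instances = do.call(rbind, instances))
}
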