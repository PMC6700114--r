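#' Simulation parameters for synthetic methylome data
#'
#' Bundles everything the synthetic-data generators need: sequence
#' composition, which motifs are methylated and how detectable they are,
#' the modification-QV distributions of true and false calls, and the
#' long-read error/length model. The defaults emulate a well-behaved
#' single-molecule run on a bacterial construct: near-complete per-site
#' detection (p_detect 0.99), a small per-base false-call rate (1e-4),
#' true-call QVs well above the conventional QV-30 cut-off (mean 60, sd 20)
#' and false-call QVs mostly below it (mean 15, sd 5), ~2 per cent read
#' error split 60/20/20 between substitutions, insertions and deletions,
#' and log-normal read lengths.
#'
#' @param seed integer seed; every generator is a pure function of it.
#' @param genome_length simulated sequence length in bp.
#' @param gc_content fraction of G+C.
#' @param active_motifs list of `methyl_motif` that are methylated.
#' @param p_detect per-site detection probability; scalar or one value per
#'   active motif.
#' @param fp_rate per-base false-call probability (per strand).
#' @param qv_true,qv_false c(mean, sd) of modification QV for true and
#'   false calls (truncated at 0).
#' @param qv_report_min the caller's internal reporting threshold: true
#'   calls are drawn from the QV distribution conditioned above it, so that
#'   `p_detect` is the probability of a *reported* (qualifying) call and the
#'   measured detection rate at the default cut-off matches `p_detect`.
#' @param m5c_multiplier multiplier applied to p_detect of m5C motifs,
#'   emulating the weaker single-molecule m5C signal (default 0.5).
#' @param coverage_mean mean read depth reported with each call.
#' @param read_error_rate per-base read error rate.
#' @param read_log_mean,read_log_sd log-normal read length parameters.
#' @param read_min,read_max truncation bounds on read length (bp).
#' @param reads_per_plasmid reads simulated per plasmid.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 50000L, gc_content = 0.5,
                       active_motifs = list(), p_detect = 0.99,
                       fp_rate = 1e-4, qv_true = c(60, 20),
                       qv_false = c(15, 5), qv_report_min = 30,
                       m5c_multiplier = 0.5,
                       coverage_mean = 100L, read_error_rate = 0.02,
                       read_log_mean = log(1500), read_log_sd = 0.4,
                       read_min = 300L, read_max = 30000L,
                       reads_per_plasmid = 200L) {
  stopifnot(genome_length >= 1L, gc_content >= 0, gc_content <= 1,
            all(p_detect >= 0), all(p_detect <= 1),
            fp_rate >= 0, fp_rate <= 1,
            read_error_rate >= 0, read_error_rate <= 1,
            reads_per_plasmid >= 1L)
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 gc_content = gc_content, active_motifs = active_motifs,
                 p_detect = p_detect, fp_rate = fp_rate,
                 qv_true = qv_true, qv_false = qv_false,
                 qv_report_min = qv_report_min,
                 m5c_multiplier = m5c_multiplier,
                 coverage_mean = as.integer(coverage_mean),
                 read_error_rate = read_error_rate,
                 read_log_mean = read_log_mean, read_log_sd = read_log_sd,
                 read_min = as.integer(read_min),
                 read_max = as.integer(read_max),
                 reads_per_plasmid = as.integer(reads_per_plasmid)),
            class = "sim_config")
}

#' Simulate an i.i.d. random DNA sequence
#'
#' Bases drawn independently with P(G) = P(C) = gc/2 and
#' P(A) = P(T) = (1-gc)/2; deterministic per seed.
#'
#' @param length sequence length (>= 1).
#' @param gc_content fraction of G+C.
#' @param seed integer seed.
#' @return a character string over ACGT.
#' @export
simulate_sequence <- function(length, gc_content = 0.5, seed = 1L) {
  stopifnot(length >= 1L)
  with_seed(seed, {
    p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
           G = gc_content / 2, T = (1 - gc_content) / 2)
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  })
}

# regenerate a random segment until it contains no site of any mask motif
masked_segment <- function(length, gc_content, mask_motifs, seed,
                           max_tries = 200L) {
  if (length == 0L) return("")
  for (i in seq_len(max_tries)) {
    s <- simulate_sequence(length, gc_content, seed + i - 1L)
    if (is.null(mask_motifs) ||
        all(vapply(mask_motifs, function(m)
          nrow(find_sites(s, m)) == 0L, TRUE)))
      return(s)
  }
  stop("could not generate a motif-free segment in ", max_tries, " tries")
}

#' Simulate an annotated plasmid carrying a gene and a motif cassette
#'
#' Concatenates backbone-1 + gene + cassette + backbone-2 with feature
#' coordinates recorded; position 1 is the designated linearisation point,
#' mirroring a plasmid cut once before full-length library construction.
#' When `mask_motifs` is given, the backbone segments are regenerated until
#' neither they nor the part junctions carry any site of those motifs, so
#' the plasmid-wide site count of each masked motif equals its count within
#' the gene plus the cassette.
#'
#' @param backbone_length total backbone length (split evenly around the
#'   insert); 0 gives gene+cassette only.
#' @param gene_seq gene sequence (string).
#' @param cassette a `motif_cassette` or a plain sequence string.
#' @param seed integer seed for backbone generation.
#' @param gc_content backbone GC content.
#' @param mask_motifs optional list of `methyl_motif` the backbone must not
#'   contain.
#' @return list with `sequence` and `features` (data.frame name/start/end).
#' @export
simulate_plasmid <- function(backbone_length, gene_seq, cassette, seed = 1L,
                             gc_content = 0.5, mask_motifs = NULL) {
  cas_seq <- if (inherits(cassette, "motif_cassette")) cassette$sequence
  else toupper(as.character(cassette))
  gene_seq <- toupper(as.character(gene_seq))
  b1_len <- backbone_length %/% 2L
  b2_len <- backbone_length - b1_len
  inner_counts <- if (is.null(mask_motifs)) NULL
  else vapply(mask_motifs, function(m)
    nrow(find_sites(gene_seq, m)) + nrow(find_sites(cas_seq, m)), 1L)
  for (round in seq_len(50L)) {
    off <- (round - 1L) * 2000L
    b1 <- masked_segment(b1_len, gc_content, mask_motifs, seed + off)
    b2 <- masked_segment(b2_len, gc_content, mask_motifs,
                         seed + 1000L + off)
    parts <- c(backbone_1 = b1, gene = gene_seq, cassette = cas_seq,
               backbone_2 = b2)
    plasmid <- paste(parts, collapse = "")
    if (is.null(mask_motifs)) break
    # junctions between parts must not create additional sites either
    whole <- vapply(mask_motifs, function(m)
      nrow(find_sites(plasmid, m)), 1L)
    if (all(whole == inner_counts)) break
    if (round == 50L)
      stop("could not assemble a plasmid whose backbone and junctions are ",
           "free of the masked motifs; try a different seed")
  }
  widths <- nchar(parts)
  starts <- cumsum(c(1L, head(widths, -1L)))
  feats <- data.frame(name = names(parts), start = starts,
                      end = starts + widths - 1L,
                      stringsAsFactors = FALSE)
  feats <- feats[widths > 0L, , drop = FALSE]
  rownames(feats) <- NULL
  list(sequence = plasmid, features = feats)
}

# apply substitution/insertion/deletion errors to one sequence
mutate_read <- function(s, error_rate) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  hit <- which(runif(n) < error_rate)
  if (!length(hit)) return(s)
  kind <- sample(c("sub", "ins", "del"), length(hit), replace = TRUE,
                 prob = c(0.6, 0.2, 0.2))
  out <- chars
  for (j in seq_along(hit)) {
    i <- hit[j]
    if (kind[j] == "sub") {
      out[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    } else if (kind[j] == "ins") {
      out[i] <- paste0(chars[i], sample(c("A", "C", "G", "T"), 1L))
    } else {
      out[i] <- ""
    }
  }
  paste(out, collapse = "")
}

#' Simulate noisy long reads from a pool of plasmids
#'
#' Per plasmid, `reads_per_plasmid` reads with uniform start, truncated
#' log-normal length (clipped at the linear molecule's end), random strand,
#' and substitution/insertion/deletion errors at `read_error_rate` (split
#' 60/20/20). The true source plasmid and interval are returned alongside
#' the reads so binning accuracy can be scored exactly.
#'
#' @param plasmids named list of plasmid records (from
#'   [simulate_plasmid()]) or named character vector of sequences.
#' @param cfg a `sim_config`.
#' @param seed seed (defaults to `cfg$seed`).
#' @return list with `reads` (named `DNAStringSet`) and `truth`
#'   (data.frame read_id/plasmid/start/end/strand).
#' @export
simulate_reads <- function(plasmids, cfg = sim_config(), seed = cfg$seed) {
  seqs <- vapply(plasmids, function(p)
    if (is.list(p)) p$sequence else as.character(p), "")
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  with_seed(seed, {
    all_reads <- character(0); truth <- list()
    for (nm in names(seqs)) {
      L <- nchar(seqs[[nm]])
      for (i in seq_len(cfg$reads_per_plasmid)) {
        len <- 0L
        while (len < cfg$read_min || len > cfg$read_max)
          len <- round(stats::rlnorm(1, cfg$read_log_mean, cfg$read_log_sd))
        start <- sample.int(max(L - min(len, L) + 1L, 1L), 1L)
        end <- min(start + len - 1L, L)
        frag <- substr(seqs[[nm]], start, end)
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-")
          frag <- as.character(reverseComplement(DNAString(frag)))
        read <- mutate_read(frag, cfg$read_error_rate)
        id <- sprintf("%s_read%04d", nm, i)
        all_reads[[id]] <- read
        truth[[id]] <- data.frame(read_id = id, plasmid = nm,
                                  start = start, end = end, strand = strand,
                                  stringsAsFactors = FALSE)
      }
    }
    reads <- DNAStringSet(all_reads)
    list(reads = reads, truth = do.call(rbind, unname(truth)))
  })
}

#' Simulate base-modification calls for a sequence
#'
#' For every site of every active motif (found with [find_sites()]), a call
#' is emitted at the expected modified base with probability `p_detect`
#' (per-locus; collapsed palindromic loci emit correlated calls on both
#' strands), QV drawn from the true-call distribution. Additionally, every
#' A and C base on each strand emits a false call with probability
#' `fp_rate`, with QV from the false-call distribution and a modification
#' type consistent with the base. QVs are truncated at 0. m5C motifs have
#' their detection probability scaled by `m5c_multiplier`.
#'
#' @param seq sequence (character, `DNAString(Set)`).
#' @param cfg a `sim_config`; `active_motifs` must be set.
#' @param seed seed (defaults to `cfg$seed`).
#' @return a `mod_calls` data.frame.
#' @export
simulate_calls <- function(seq, cfg = sim_config(), seed = cfg$seed) {
  ss <- as_dna_set(seq)
  motifs <- cfg$active_motifs
  p <- rep_len(cfg$p_detect, length(motifs))
  # N(mean, sd) conditioned >= floor, by inverse-CDF sampling
  rqv_true <- function(n) {
    lo <- stats::pnorm(cfg$qv_report_min, cfg$qv_true[1], cfg$qv_true[2])
    stats::qnorm(runif(n, lo, 1), cfg$qv_true[1], cfg$qv_true[2])
  }
  with_seed(seed, {
    rows <- list()
    for (mi in seq_along(motifs)) {
      m <- motifs[[mi]]
      p_m <- p[mi] * if (m$mod_type == "m5C") cfg$m5c_multiplier else 1
      sites <- find_sites(ss, m)
      if (!nrow(sites)) next
      det <- runif(nrow(sites)) < p_m
      sites <- sites[det, , drop = FALSE]
      if (!nrow(sites)) next
      qv <- rqv_true(nrow(sites))
      cov <- pmax(stats::rpois(nrow(sites), cfg$coverage_mean), 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        contig = sites$contig, position = sites$mod_pos,
        strand = sites$strand, mod_type = m$mod_type, qv = qv,
        coverage = cov, stringsAsFactors = FALSE)
      pal <- !is.na(sites$mod_pos_rev)
      if (any(pal)) {
        qv2 <- rqv_true(sum(pal))
        rows[[length(rows) + 1L]] <- data.frame(
          contig = sites$contig[pal], position = sites$mod_pos_rev[pal],
          strand = "-", mod_type = m$mod_type, qv = qv2,
          coverage = pmax(stats::rpois(sum(pal), cfg$coverage_mean), 1L),
          stringsAsFactors = FALSE)
      }
    }
    # false positives: any A/C base on either strand
    if (cfg$fp_rate > 0) {
      for (i in seq_along(ss)) {
        chars <- strsplit(as.character(ss[[i]]), "", fixed = TRUE)[[1]]
        for (strand in c("+", "-")) {
          base <- if (strand == "+") chars
          else unname(IUPAC_COMPLEMENT[chars])
          cand <- which(base %in% c("A", "C"))
          fp <- cand[runif(length(cand)) < cfg$fp_rate]
          if (!length(fp)) next
          types <- ifelse(base[fp] == "A", "m6A",
                          sample(c("m4C", "m5C"), length(fp),
                                 replace = TRUE))
          rows[[length(rows) + 1L]] <- data.frame(
            contig = names(ss)[i], position = fp, strand = strand,
            mod_type = types,
            qv = pmax(rnorm(length(fp), cfg$qv_false[1], cfg$qv_false[2]), 0),
            coverage = pmax(stats::rpois(length(fp), cfg$coverage_mean), 1L),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (!length(rows)) return(calls_df())
    df <- do.call(rbind, rows)
    df <- df[order(df$contig, df$position, df$strand), , drop = FALSE]
    calls_df(df$contig, df$position, df$strand, df$mod_type, df$qv,
             df$coverage)
  })
}
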