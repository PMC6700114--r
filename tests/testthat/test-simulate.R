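test_that("sequence simulation is seeded, composition-correct and validated", {
  expect_identical(simulate_sequence(1000, 0.5, seed = 3),
                   simulate_sequence(1000, 0.5, seed = 3))
  expect_false(identical(simulate_sequence(1000, 0.5, seed = 3),
                         simulate_sequence(1000, 0.5, seed = 4)))
  s <- simulate_sequence(100000, 0.56, seed = 5)
  gc <- mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.56), 3 * sqrt(0.56 * 0.44 / 100000))
  expect_true(simulate_sequence(1, 0.0, seed = 6) %in% c("A", "T"))
  expect_error(simulate_sequence(0))
})

test_that("plasmid assembly records features and honours backbone masking", {
  motifs <- design_motifs_default()
  cas <- design_cassette(motifs, cassette_spec(seed = 21))
  gene <- simulate_sequence(300, 0.5, seed = 22)
  p <- simulate_plasmid(600, gene, cas, seed = 23)
  # features reparse to the exact input parts
  f <- p$features
  get_part <- function(nm) substr(p$sequence, f$start[f$name == nm],
                                  f$end[f$name == nm])
  expect_equal(get_part("gene"), gene)
  expect_equal(get_part("cassette"), cas$sequence)
  expect_equal(nchar(p$sequence), 600 + 300 + nchar(cas$sequence))
  # plasmid-wide counts are at least the designed counts
  expect_gte(nrow(find_sites(p$sequence, motifs[[2]])), 10)
  # with backbone masking, plasmid counts are exactly gene + cassette counts
  pm <- simulate_plasmid(600, gene, cas, seed = 23, mask_motifs = motifs)
  for (m in motifs)
    expect_equal(nrow(find_sites(pm$sequence, m)),
                 nrow(find_sites(gene, m)) + nrow(find_sites(cas$sequence, m)))
  # empty backbone gives gene+cassette only
  p0 <- simulate_plasmid(0, gene, cas, seed = 24)
  expect_equal(nchar(p0$sequence), 300 + nchar(cas$sequence))
  expect_equal(p0$features$name, c("gene", "cassette"))
})

test_that("error-free reads are exact substrings and labels are faithful", {
  motifs <- design_motifs_default()
  cas <- design_cassette(motifs, cassette_spec(seed = 31))
  p <- simulate_plasmid(500, simulate_sequence(300, 0.5, seed = 32), cas,
                        seed = 33)
  cfg <- sim_config(reads_per_plasmid = 25, read_error_rate = 0,
                    read_log_mean = log(600), read_log_sd = 0.3,
                    read_min = 300, read_max = 2000)
  sim <- simulate_reads(list(p1 = p), cfg, seed = 34)
  expect_length(sim$reads, 25)
  expect_equal(sim$truth$read_id, names(sim$reads))
  for (i in seq_along(sim$reads)) {
    tr <- sim$truth[i, ]
    frag <- substr(p$sequence, tr$start, tr$end)
    if (tr$strand == "-")
      frag <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(frag)))
    expect_identical(as.character(sim$reads[[i]]), frag)
  }
})

test_that("read lengths follow the configured truncated log-normal", {
  cfg <- sim_config(reads_per_plasmid = 1000, read_error_rate = 0,
                    read_log_mean = log(1000), read_log_sd = 0.25,
                    read_min = 400, read_max = 4000)
  long_seq <- simulate_sequence(20000, 0.5, seed = 41)
  sim <- simulate_reads(list(p = long_seq), cfg, seed = 42)
  mean_len <- mean(Biostrings::width(sim$reads))
  # mean of the log-normal: exp(mu + sigma^2/2)
  expect_lt(abs(mean_len - exp(log(1000) + 0.25^2 / 2)) /
              exp(log(1000) + 0.25^2 / 2), 0.10)
})

test_that("modification calls land exactly on motif sites when noise is off", {
  seq <- simulate_sequence(20000, 0.5, seed = 51)
  # non-palindromic motif: exactly one call per site
  m <- motif("GCCRAG", 5, "m6A")
  cfg <- sim_config(active_motifs = list(m), p_detect = 1, fp_rate = 0)
  calls <- simulate_calls(seq, cfg, seed = 52)
  sites <- find_sites(seq, m)
  expect_equal(nrow(calls), nrow(sites))
  expect_setequal(paste(calls$position, calls$strand),
                  paste(sites$mod_pos, sites$strand))
  expect_true(all(calls$mod_type == "m6A"))
  expect_true(all(calls$qv >= 30))
  # p_detect = 0 leaves only false positives
  cfg0 <- sim_config(active_motifs = list(m), p_detect = 0, fp_rate = 1e-3)
  fp <- simulate_calls(seq, cfg0, seed = 53)
  expect_gt(nrow(fp), 0)
  expect_false(any(paste(fp$position, fp$strand) %in%
                     paste(sites$mod_pos, sites$strand)))
  # determinism
  expect_identical(simulate_calls(seq, cfg, seed = 52), calls)
})

test_that("palindromic loci emit correlated calls on both strands", {
  seq <- simulate_sequence(20000, 0.5, seed = 61)
  m <- motif("GATC", 2, "m6A")
  cfg <- sim_config(active_motifs = list(m), p_detect = 1, fp_rate = 0)
  calls <- simulate_calls(seq, cfg, seed = 62)
  sites <- find_sites(seq, m)
  # one call per strand per collapsed locus
  expect_equal(nrow(calls), 2 * nrow(sites))
  expect_equal(sum(calls$strand == "+"), nrow(sites))
})

test_that("m5C motifs get the reduced detection multiplier", {
  seq <- simulate_sequence(50000, 0.5, seed = 71)
  m <- motif("CCWGG", 1, "m5C")
  cfg <- sim_config(active_motifs = list(m), p_detect = 1, fp_rate = 0,
                    m5c_multiplier = 0.5)
  calls <- simulate_calls(seq, cfg, seed = 72)
  sites <- find_sites(seq, m)
  dr <- detection_rate(sites, calls, 30, "m5C")
  ci <- 2.58 * sqrt(0.5 * 0.5 / nrow(sites))
  expect_lt(abs(dr$fraction - 0.5), ci + 1e-9)
})

test_that("end-to-end closure: designed motifs are recovered from simulated calls", {
  motifs <- list(motif("GAGNNNNNGAT", 2, "m6A"), motif("AACCA", 5, "m6A"))
  cas <- design_cassette(motifs, cassette_spec(seed = 81))
  gene <- simulate_sequence(300, 0.5, seed = 82)
  p <- simulate_plasmid(600, gene, cas, seed = 83, mask_motifs = motifs)
  cfg <- sim_config(active_motifs = motifs, p_detect = 1, fp_rate = 0)
  calls <- simulate_calls(setNames(p$sequence, "plasmid1"), cfg, seed = 84)
  s <- summarize_motifs(setNames(p$sequence, "plasmid1"), motifs, calls)
  expect_equal(s$fraction_detected, c(1, 1))
  # masked backbone/junctions: sites are those of the gene plus the cassette
  expect_gte(s$n_sites[s$motif == "GAGNNNNNGAT"], 12)
  expect_gte(s$n_sites[s$motif == "AACCA"], 10)
})
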