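test_that("copy allocation follows the class copy numbers and de-ambiguation rules", {
  spec <- cassette_spec(seed = 1)
  withr::with_seed(1, {
    # single variant, simple class: L copies of the same sequence
    expect_equal(allocate_copies(motif("AACCA", 5, "m6A"), spec),
                 rep("AACCA", 10))
    # spacer class gets 12
    expect_equal(allocate_copies(motif("GAGNNNNNGAT", 2, "m6A"), spec),
                 rep("GAGNNNNNGAT", 12))
    # two variants under L=10: floor(10/2) = 5 each
    expect_equal(as.vector(table(allocate_copies(motif("SATC", 2, "m6A"),
                                                 spec))),
                 c(5, 5))
    # V=4 under L=10: 2 each plus 2 extras
    tab <- table(allocate_copies(motif("WSTC", 4, "m4C"), spec))
    expect_length(tab, 4)
    expect_equal(sum(tab), 10)
    expect_true(all(tab %in% c(2, 3)))
    # more variants (27) than copies: L distinct variants
    a <- allocate_copies(motif("HVDTC", 1, "m6A"), spec)
    expect_length(a, 10)
    expect_false(anyDuplicated(a) > 0)
  })
  # per-variant mode: K copies of every variant
  speck <- cassette_spec(deambiguation_mode = "per_variant_K", K = 3)
  withr::with_seed(1, {
    expect_equal(as.vector(table(allocate_copies(motif("SATC", 2, "m6A"),
                                                 speck))),
                 c(3, 3))
  })
})

test_that("arrangement avoids identical neighbours whenever feasible", {
  spec <- cassette_spec(seed = 4)
  alloc <- data.frame(parent = c(1, 1, 2, 2),
                      variant = c("AAAA", "AAAA", "CCCC", "CCCC"),
                      stringsAsFactors = FALSE)
  withr::with_seed(5, {
    for (i in 1:20) {
      arr <- arrange_instances(alloc, spec)
      v <- arr$variant
      expect_true(all(v[-1] != v[-length(v)]))
      expect_equal(sort(v), sort(alloc$variant))
    }
  })
  # single repeated sequence: emitted with a warning, not an error
  alloc1 <- data.frame(parent = 1, variant = rep("AACCA", 4),
                       stringsAsFactors = FALSE)
  withr::with_seed(5, expect_warning(arrange_instances(alloc1, spec),
                                     "adjacent"))
})

test_that("designed cassettes carry the exact copy numbers, verified by scanning", {
  motifs <- design_motifs_default()
  cas <- design_cassette(motifs, cassette_spec(seed = 7))
  expect_equal(nrow(find_sites(cas$sequence, motifs[[1]])), 12)
  expect_equal(nrow(find_sites(cas$sequence, motifs[[2]])), 10)
  expect_equal(nrow(cas$instances), 22)
  # instances are non-overlapping, separated by exactly one base
  ins <- cas$instances[order(cas$instances$start), ]
  expect_true(all(diff(ins$start) == (ins$end[-nrow(ins)] -
                                        ins$start[-nrow(ins)] + 2L)))
  # each filled instance matches its parent motif at specified positions
  for (i in seq_len(nrow(ins)))
    expect_equal(nrow(find_sites(ins$filled[i],
                                 motif(ins$parent[i], 1, "unknown"))) >= 1,
                 TRUE)
})

test_that("junction guard keeps scan counts equal to design counts for degenerate sets", {
  motifs <- list(motif("GAGNNNNNGAT", 2, "m6A"), motif("AACCA", 5, "m6A"),
                 motif("SATC", 2, "m6A"))
  for (s in c(2, 9, 17)) {
    cas <- design_cassette(motifs, cassette_spec(seed = s))
    # SATC allocation 5 GATC + 5 CATC; GATC instances match SATC on both
    # strands (GATC is palindromic, SATC is not), hence 15 sites
    expect_equal(nrow(find_sites(cas$sequence, motifs[[1]])), 12)
    expect_equal(nrow(find_sites(cas$sequence, motifs[[2]])), 10)
    expect_equal(nrow(find_sites(cas$sequence, motifs[[3]])), 15)
  }
})

test_that("identical spec gives byte-identical output; different seeds differ", {
  motifs <- design_motifs_default()
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  write_cassette(design_cassette(motifs, cassette_spec(seed = 3)), d1)
  write_cassette(design_cassette(motifs, cassette_spec(seed = 3)), d2)
  write_cassette(design_cassette(motifs, cassette_spec(seed = 4)), d3)
  f1 <- readLines(file.path(d1, "cassette.fasta"))
  expect_identical(f1, readLines(file.path(d2, "cassette.fasta")))
  expect_false(identical(f1, readLines(file.path(d3, "cassette.fasta"))))
})

test_that("literal_n policy keeps separators and spacers as N", {
  # two copies of a single variant cannot avoid self-adjacency
  expect_warning(
    cas <- design_cassette(list(motif("GATC", 2, "m6A")),
                           cassette_spec(seed = 1, copies_simple = 2,
                                         separator_policy = "literal_n",
                                         junction_guard = FALSE)),
    "adjacent")
  expect_equal(cas$sequence, "GATCNGATC")
  expect_equal(nchar(cas$sequence), 2 * 4 + 1)
})

test_that("GenBank output round-trips instances and sequence", {
  motifs <- design_motifs_default()
  cas <- design_cassette(motifs, cassette_spec(seed = 12))
  out <- tempfile()
  paths <- write_cassette(cas, out, "c1")
  expect_true(all(file.exists(paths)))
  back <- read_cassette_genbank(paths["genbank"])
  expect_equal(back$sequence, cas$sequence)
  expect_equal(back$instances$start, cas$instances$start)
  expect_equal(back$instances$end, cas$instances$end)
  expect_equal(back$instances$parent, cas$instances$parent)
  expect_equal(back$instances$filled, cas$instances$filled)
  expect_equal(nrow(back$instances), 22)
  # FASTA agrees with the GenBank ORIGIN
  fa <- as.character(Biostrings::readDNAStringSet(paths["fasta"])[[1]])
  expect_equal(fa, cas$sequence)
})

test_that("write_cassettes emits the requested number of file pairs", {
  out <- tempfile()
  write_cassettes(design_motifs_default(), cassette_spec(seed = 5),
                  count = 3, out_dir = out)
  expect_length(list.files(out, pattern = "\\.gb$"), 3)
  expect_length(list.files(out, pattern = "\\.fasta$"), 3)
  # independently seeded cassettes differ
  s1 <- read_cassette_genbank(file.path(out, "cassette_1.gb"))$sequence
  s2 <- read_cassette_genbank(file.path(out, "cassette_2.gb"))$sequence
  expect_false(identical(s1, s2))
})
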