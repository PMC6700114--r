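test_that("motif parsing validates alphabet, position and type", {
  m <- motif("GATGNNNNNNTGC", 2, "m6A")
  expect_s3_class(m, "methyl_motif")
  expect_equal(m$sequence, "GATGNNNNNNTGC")

  expect_equal(motif("gatc", 2, "m6A")$sequence, "GATC")

  expect_error(motif("GAXTC", 2, "m6A"), "position 3")
  expect_error(motif("GGTC", 2, "m6A"), "m6A requires")
  expect_error(motif("GATC", 3, "m4C"), "m4C requires")
  expect_error(motif("GATC", 0, "m6A"), "modified_position")
  expect_error(motif("GATC", 5, "m6A"), "modified_position")
  expect_error(motif("NNNN", 1, "unknown"), "non-N")
  expect_equal(parse_motif_token("GATC:2:m6A")$mod_type, "m6A")
  expect_error(parse_motif_token("GATC"), "MOTIF:POS")
})

test_that("spacer/simple classification follows the 2-10 N rule", {
  expect_equal(classify_motif(motif("GAGNNNNNGAT", 2, "m6A")), "spacer")
  expect_equal(classify_motif(motif("GATGNNNNNNTGC", 2, "m6A")), "spacer")
  expect_equal(classify_motif(motif("CAAAAAR", 6, "m6A")), "simple")
  # a single internal N is below the rule's lower bound
  expect_equal(classify_motif(motif("GANTC", 2, "m6A")), "simple")
  # exactly 2 and exactly 10 N qualify; 11 is rejected with a warning
  expect_equal(classify_motif(motif("GANNTC", 2, "m6A")), "spacer")
  expect_equal(classify_motif(
    motif(paste0("GAG", strrep("N", 10), "GAT"), 2, "m6A")), "spacer")
  expect_warning(
    cls <- classify_motif(motif(paste0("GAG", strrep("N", 11), "GAT"),
                                2, "m6A")),
    "longer than 10")
  expect_equal(cls, "simple")
  # leading/trailing N runs are not spacers
  expect_equal(classify_motif(motif("NNGATC", 4, "m6A")), "simple")
})

test_that("expansion and variant counting follow the IUPAC table", {
  expect_equal(expand_motif(motif("SATC", 2, "m6A")), c("CATC", "GATC"))
  expect_equal(expand_motif(motif("GATC", 2, "m6A")), "GATC")
  expect_equal(variant_count(motif("ATGNNTTA", 1, "m6A"),
                             enumerate_N = TRUE), 16)
  expect_length(expand_motif(motif("ATGNNTTA", 1, "m6A"),
                             enumerate_N = TRUE), 16)
  expect_equal(variant_count(motif("GAWTC", 2, "m6A")), 2)
  expect_equal(variant_count(motif("AACCA", 5, "m6A")), 1)
  # spacer N retained unless enumerated
  expect_equal(expand_motif(motif("GANNTC", 2, "m6A")), "GANNTC")

  # |variants| equals the product of per-position cardinalities
  set.seed(101)
  for (i in 1:25) {
    m <- random_motif(sample(4:8, 1), n_ambiguous = sample(0:2, 1))
    expect_length(expand_motif(m), variant_count(m))
    expect_setequal(expand_motif(m), oracle_enumerate(m$sequence))
  }
})

test_that("reverse complement remaps the modified position and is an involution", {
  rc <- reverse_complement_motif(motif("GAGNNNNNGAT", 2, "m6A"))
  expect_equal(rc$sequence, "ATCNNNNNCTC")
  expect_equal(rc$modified_position, 10)
  expect_true(rc$opposite_strand)

  expect_equal(reverse_complement_motif(motif("GAWTC", 2, "m6A"))$sequence,
               "GAWTC")
  expect_equal(reverse_complement_motif(motif("GATC", 2, "m6A"))$sequence,
               "GATC")

  set.seed(7)
  for (i in 1:50) {
    m <- random_motif(sample(3:12, 1), n_ambiguous = sample(0:3, 1))
    expect_equal(reverse_complement_motif(reverse_complement_motif(m)), m)
  }
})

test_that("expand/collapse round trip recovers spacer-free motifs", {
  collapse_variants <- function(vars) {
    cols <- do.call(rbind, strsplit(vars, "", fixed = TRUE))
    paste(apply(cols, 2, function(col) {
      bs <- sort(unique(col))
      names(Filter(function(x) identical(sort(x), bs), ORACLE_IUPAC))[1]
    }), collapse = "")
  }
  set.seed(11)
  for (i in 1:20) {
    m <- random_motif(sample(4:7, 1), n_ambiguous = sample(0:2, 1))
    expect_equal(collapse_variants(expand_motif(m)), m$sequence)
  }
})

test_that("motif relations agree with brute-force set comparison", {
  expect_equal(as.character(relate_motifs(motif("GATC", 2, "m6A"),
                                          motif("SATC", 2, "m6A"))),
               "a_subset_of_b")
  expect_equal(as.character(relate_motifs(motif("SATC", 2, "m6A"),
                                          motif("GATC", 2, "m6A"))),
               "b_subset_of_a")
  expect_equal(as.character(relate_motifs(motif("GAWTC", 2, "m6A"),
                                          motif("GASTC", 2, "m6A"))),
               "disjoint")
  expect_equal(as.character(relate_motifs(motif("GATC", 2, "m6A"),
                                          motif("GATC", 2, "m6A"))),
               "identical")
  expect_equal(as.character(relate_motifs(motif("RATC", 2, "m6A"),
                                          motif("SATC", 2, "m6A"))),
               "overlapping")

  # brute force over enumerated sets for same-length motif pairs
  set.seed(23)
  for (i in 1:40) {
    len <- sample(3:6, 1)
    a <- random_motif(len, sample(0:2, 1))
    b <- random_motif(len, sample(0:2, 1))
    rel <- as.character(relate_motifs(a, b))
    # oracle only valid at offset 0; skip pairs the aligner shifted
    if (attr(relate_motifs(a, b), "offset") != 0) next
    sa <- oracle_enumerate(a$sequence); sb <- oracle_enumerate(b$sequence)
    expected <- if (setequal(sa, sb)) "identical"
    else if (all(sa %in% sb)) "a_subset_of_b"
    else if (all(sb %in% sa)) "b_subset_of_a"
    else if (length(intersect(sa, sb)) == 0) "disjoint"
    else "overlapping"
    expect_equal(rel, expected,
                 info = paste(a$sequence, "vs", b$sequence))
  }
})

test_that("union_equals recognises composite motifs", {
  expect_true(union_equals(list(motif("GATC", 2, "m6A"),
                                motif("CATC", 2, "m6A")),
                           motif("SATC", 2, "m6A")))
  expect_true(union_equals(list(motif("GATC", 2, "m6A")),
                           motif("GATC", 2, "m6A")))
  expect_false(union_equals(list(motif("GATC", 2, "m6A")),
                            motif("SATC", 2, "m6A")))
  expect_error(union_equals(list(motif("GATC", 2, "m6A")),
                            motif("GGATC", 3, "m6A")), "same length")
})

test_that("motif CSV round trip preserves the motif list", {
  motifs <- list(motif("SATC", 2, "m6A"), motif("GAGNNNNNGAT", 2, "m6A"),
                 motif("CCWGG", 1, "m5C"))
  path <- tempfile(fileext = ".csv")
  write_motifs(motifs, path)
  back <- read_motifs(path)
  expect_equal(back, motifs)
})
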