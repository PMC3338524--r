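test_that("well-formed FASTA + annotations round-trip through read_alignment", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "grp.fasta")
  ann <- file.path(dir, "grp.tsv")
  writeLines(c(">s1", "ACDEFGHIKL", ">s2", "ACDEFGHIK-", ">s3", "AC-EFGHIKL"), fa)
  writeLines(c("seq_id\tspecies\tcategory",
               "s1\tspA\tJ", "s2\tspB\tJ", "s3\tspC\tJ"), ann)
  g <- read_alignment(fa, ann)
  expect_s3_class(g, "alignment_group")
  expect_equal(dim(g$seq), c(3L, 10L))
  expect_equal(rownames(g$seq), c("s1", "s2", "s3"))  # file order preserved
  expect_equal(unname(g$species["s2"]), "spB")

  # write + re-read preserves sequences, ids and order byte-for-byte
  out <- file.path(dir, "copy.fasta")
  write_alignment(g, out)
  g2 <- read_alignment(out, ann, group_id = g$group_id)
  expect_identical(g2$seq, g$seq)
  expect_identical(readLines(out),
                   c(">s1", "ACDEFGHIKL", ">s2", "ACDEFGHIK-", ">s3", "AC-EFGHIKL"))
})

test_that("ragged alignments, missing annotations and bad letters are rejected", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "bad.fasta")
  ann <- file.path(dir, "ann.tsv")
  writeLines(c("seq_id\tspecies\tcategory", "s1\tspA\tJ", "s2\tspB\tJ"), ann)

  writeLines(c(">s1", "ACDEFGHIKL", ">s2", "ACDEFGHIK"), fa)
  expect_error(read_alignment(fa, ann), "ragged")

  writeLines(c(">s1", "ACDEFGHIKL", ">s2", "ACDEFGHIKB"), fa)
  expect_error(read_alignment(fa, ann), "alphabet")
  # permissive mode maps ambiguity letters to gaps instead
  g <- read_alignment(fa, ann, mode = "permissive")
  expect_equal(unname(g$seq["s2", 10L]), "-")

  writeLines(c(">s1", "ACDEFGHIKL", ">s3", "ACDEFGHIKL"), fa)
  expect_error(read_alignment(fa, ann), "annotation")
})

test_that("filter_group applies the size, single-tag and excluded-category rules", {
  mk <- function(n, tags) {
    seqs <- stats::setNames(rep("ACDEF", n), paste0("s", seq_len(n)))
    alignment_group(seqs,
                    species = stats::setNames(paste0("sp", seq_len(n)), names(seqs)),
                    category = stats::setNames(tags, names(seqs)))
  }
  r <- filter_group(mk(9, rep("J", 9)))
  expect_true(r$passed)
  expect_equal(r$modal_tag_frequency, 1)
  expect_equal(r$n_distinct_tags, 1L)

  r <- filter_group(mk(20, c(rep("E", 19), "G")))
  expect_false(r$passed)
  expect_equal(r$failure_reasons, "multi-tag")
  expect_equal(r$modal_tag, "E")
  expect_equal(r$modal_tag_frequency, 0.95)

  r <- filter_group(mk(12, rep("R", 12)))
  expect_false(r$passed)
  expect_equal(r$failure_reasons, "excluded-category")

  r <- filter_group(mk(8, rep("J", 8)))
  expect_false(r$passed)
  expect_equal(r$failure_reasons, "too-few-sequences")

  # multi-letter tags count as multi-tag even when every sequence agrees
  r <- filter_group(mk(9, rep("EG", 9)))
  expect_false(r$passed)
  expect_true("multi-tag" %in% r$failure_reasons)
})

test_that("filter_group is invariant under sequence permutation", {
  set.seed(7)
  n <- 12
  seqs <- stats::setNames(rep("ACDEF", n), paste0("s", seq_len(n)))
  tags <- sample(c(rep("E", 9), rep("G", 3)))
  g1 <- alignment_group(seqs,
                        species = stats::setNames(paste0("sp", 1:n), names(seqs)),
                        category = stats::setNames(tags, names(seqs)))
  perm <- sample(n)
  g2 <- alignment_group(seqs[perm],
                        species = g1$species[perm], category = g1$category[perm])
  r1 <- filter_group(g1); r2 <- filter_group(g2)
  expect_equal(r1[c("n_sequences", "n_distinct_tags", "modal_tag",
                    "modal_tag_frequency", "passed")],
               r2[c("n_sequences", "n_distinct_tags", "modal_tag",
                    "modal_tag_frequency", "passed")])
  # and modal frequency 1 <=> a single distinct tag
  expect_equal(r1$modal_tag_frequency == 1, r1$n_distinct_tags == 1L)
})

test_that("gap_profile averages per-sequence gaps and rounds half to even", {
  mk <- function(seqs) toy_group(seqs)
  g <- mk(c(s1 = "ACDEF", s2 = "ACDEF"))
  gp <- gap_profile(g)
  expect_equal(gp$mean, 0)
  expect_equal(gp$simulated_length, 5L)

  g <- mk(c(s1 = "AC--EFGHIK", s2 = "A--DEFGHIK",
            s3 = "ACD--FGHIK", s4 = "ACDE--GHIK"))
  gp <- gap_profile(g)
  expect_equal(unname(gp$per_sequence), rep(2, 4))
  expect_equal(gp$simulated_length, 8L)

  g <- mk(c(s1 = "AC-DE", s2 = "A--DE"))
  gp <- gap_profile(g)
  expect_equal(gp$mean, 1.5)
  expect_equal(gp$simulated_length, 3L)  # round(1.5) = 2, half to even

  g <- mk(c(s1 = "ACD-", s2 = "ACDE"))
  expect_equal(gap_profile(g)$simulated_length, 4L)  # round(0.5) = 0
})
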