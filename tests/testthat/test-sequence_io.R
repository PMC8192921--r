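write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("read_fasta parses minimal, wrapped, and lower-case records", {
  path <- write_tmp_fasta(c(">x", "ACGT"))
  seqs <- read_fasta(path)
  expect_length(seqs, 1L)
  expect_equal(seqs[[1]]$id, "x")
  expect_equal(seqs[[1]]$bases, "ACGT")

  path2 <- write_tmp_fasta(c(">a desc text", "acgt", "ACGT", ">b", "GG", "GG"))
  seqs2 <- read_fasta(path2)
  expect_equal(vapply(seqs2, `[[`, "", "id"), c("a", "b"))
  expect_equal(seqs2[[1]]$bases, "ACGTACGT")  # case fold + line wrap
  expect_equal(seqs2[[2]]$bases, "GGGG")
})

test_that("ambiguity policies behave as documented", {
  path <- write_tmp_fasta(c(">y", "acgtn"))
  expect_error(read_fasta(path, policy = "strict"), "y")
  stripped <- read_fasta(path, policy = "strip")
  expect_equal(stripped[[1]]$bases, "ACGT")
  expect_equal(attr(stripped, "stripped"), c(y = 1L))

  path2 <- write_tmp_fasta(c(">z", "ACN", ">ok", "ACGTACGT"))
  expect_error(read_fasta(path2, policy = "strict"), "z")
  kept <- read_fasta(path2, policy = "fail-record")
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$id, "ok")
  expect_equal(attr(kept, "failed"), "z")
})

test_that("read_fasta errors on missing/empty files and too-short records", {
  expect_error(read_fasta(file.path(tempdir(), "nope.fasta")), "not found")
  empty <- write_tmp_fasta(character(0))
  expect_error(read_fasta(empty), "no records")
  short <- write_tmp_fasta(c(">s", "ACNG"))
  expect_error(read_fasta(short, policy = "strip"), "at least 4")
})

test_that("FASTA write/read round-trips ids and bases exactly", {
  set.seed(99)
  seqs <- lapply(1:5, function(i) {
    nt_sequence(random_bases(sample(4:200, 1)), id = sprintf("rec_%d", i))
  })
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, path, width = 17L)
  back <- read_fasta(path)
  expect_equal(vapply(back, `[[`, "", "id"), vapply(seqs, `[[`, "", "id"))
  expect_equal(vapply(back, `[[`, "", "bases"), vapply(seqs, `[[`, "", "bases"))
})

test_that("encode_sequence substitutes elementwise and is invertible", {
  expect_equal(encode_sequence("ACGT")$values, c(1, 2, 3, 4))
  expect_equal(encode_sequence("AAAA")$values, c(1, 1, 1, 1))
  expect_equal(encode_sequence("TGCA")$values, c(4, 3, 2, 1))
  custom <- c(A = 2, C = 4, G = 6, T = 8)
  enc <- encode_sequence("GATTACA", custom)
  expect_equal(enc$values, c(6, 2, 8, 8, 2, 4, 2))
  expect_equal(decode_sequence(enc), "GATTACA")
  set.seed(1)
  for (n in c(4, 17, 300)) {
    s <- random_bases(n)
    enc <- encode_sequence(s)
    expect_length(enc$values, n)
    expect_equal(decode_sequence(enc), s)
  }
  expect_error(encode_sequence("ACGT", c(A = 1, C = 2, G = 3)), "cover")
  expect_error(encode_sequence("ACGT", c(A = 1, C = 1, G = 3, T = 4)), "injective")
  expect_error(encode_sequence("ACGT", c(A = 0, C = 2, G = 3, T = 4)), "nonzero")
})

test_that("nt_sequence validates alphabet and minimum length", {
  expect_error(nt_sequence("ACG"), "at least 4")
  expect_error(nt_sequence("ACGN", id = "bad"), "bad")
  expect_equal(nt_sequence("acgt")$bases, "ACGT")
})

test_that("labeled_dataset enforces parallel labels and binary coding", {
  expect_error(labeled_dataset(c("ACGT", "GGTT"), c(1)), "equal length")
  expect_error(labeled_dataset(c("ACGT"), 2), "0 or 1")
  d <- labeled_dataset(c(a = "ACGT", b = "GGTT"), c(1, 0))
  expect_equal(d$sequences[[1]]$id, "a")
})

test_that("two-file and label-table loading agree", {
  set.seed(7)
  pos <- lapply(1:3, function(i) nt_sequence(random_bases(30), sprintf("p%d", i)))
  neg <- lapply(1:4, function(i) nt_sequence(random_bases(30), sprintf("n%d", i)))
  pf <- withr::local_tempfile(fileext = ".fasta")
  nf <- withr::local_tempfile(fileext = ".fasta")
  all_f <- withr::local_tempfile(fileext = ".fasta")
  lab_f <- withr::local_tempfile(fileext = ".tsv")
  write_fasta(pos, pf); write_fasta(neg, nf); write_fasta(c(pos, neg), all_f)
  writeLines(sprintf("%s\t%d", c(sprintf("p%d", 1:3), sprintf("n%d", 1:4)),
                     c(1, 1, 1, 0, 0, 0, 0)), lab_f)
  d1 <- read_two_class_fasta(pf, nf)
  d2 <- read_labeled_fasta(all_f, lab_f)
  expect_equal(d1$labels, d2$labels)
  expect_equal(vapply(d1$sequences, `[[`, "", "bases"),
               vapply(d2$sequences, `[[`, "", "bases"))
  expect_no_error(read_labeled_fasta(pf, lab_f))
  badlab <- withr::local_tempfile(fileext = ".tsv")
  writeLines("p1\t1", badlab)
  expect_error(read_labeled_fasta(nf, badlab), "no label")
})

test_that("synthetic generator is seed-reproducible and validates inputs", {
  d1 <- generate_synthetic_dataset(5, 5, 50, 1, seed = 7)
  d2 <- generate_synthetic_dataset(5, 5, 50, 1, seed = 7)
  expect_identical(d1, d2)
  d3 <- generate_synthetic_dataset(5, 5, 50, 1, seed = 8)
  expect_false(identical(vapply(d1$sequences, `[[`, "", "bases"),
                         vapply(d3$sequences, `[[`, "", "bases")))
  expect_equal(d1$labels, c(rep(1L, 5), rep(0L, 5)))
  expect_error(generate_synthetic_dataset(5, 5, 50, 1.2), "separation")
  expect_error(generate_synthetic_dataset(5, 5, 10, 1), ">= 20")
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_synthetic_dataset(3, 3, 30, 0.5, seed = 9))
  expect_identical(runif(1), before)
})

test_that("separation = 0 gives statistically indistinguishable GC content", {
  d <- generate_synthetic_dataset(500, 500, 100, 0, seed = 21)
  gc <- vapply(d$sequences, function(s) {
    fv <- frequency_vector(s)
    (fv[["C"]] + fv[["G"]]) / s$n
  }, numeric(1))
  g_pos <- gc[d$labels == 1L]
  g_neg <- gc[d$labels == 0L]
  se <- sqrt(var(g_pos) / length(g_pos) + var(g_neg) / length(g_neg))
  expect_lt(abs(mean(g_pos) - mean(g_neg)), 3 * se)
})

test_that("separation shifts composition in the documented direction", {
  d <- generate_synthetic_dataset(200, 200, 100, 0.6, seed = 22)
  gc <- vapply(d$sequences, function(s) {
    fv <- frequency_vector(s)
    (fv[["C"]] + fv[["G"]]) / s$n
  }, numeric(1))
  expect_gt(mean(gc[d$labels == 1L]), 0.7)
  expect_lt(mean(gc[d$labels == 0L]), 0.3)
})
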