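test_that("one-hot encoding maps bases to the stated channel vectors", {
  expect_equal(as.vector(one_hot_encode("A")), c(1, 0, 0, 0))
  expect_equal(as.vector(one_hot_encode("T")), c(0, 1, 0, 0))
  expect_equal(as.vector(one_hot_encode("C")), c(0, 0, 1, 0))
  expect_equal(as.vector(one_hot_encode("G")), c(0, 0, 0, 1))
  M <- one_hot_encode("ACGT")
  expect_equal(dim(M), c(4L, 4L))
  expect_true(all(rowSums(M) == 1))
  expect_true(all(rowSums(M == 1) == 1))
  expect_true(attr(M, "is_hard"))
})

test_that("encoding and decoding are mutually inverse on hard sequences", {
  set.seed(42)
  for (i in 1:25) {
    s <- random_hard_seq(sample(5:40, 1))
    expect_identical(one_hot_decode(one_hot_encode(s)), s)
  }
  X <- encode_batch(c(a = "GATC", b = "TTAA"))
  expect_identical(decode_batch(X), c("GATC", "TTAA"))
})

test_that("N handling follows the policy", {
  expect_error(one_hot_encode("ACNT"), "invalid alphabet")
  M <- one_hot_encode("ACNT", n_policy = "uniform")
  expect_equal(M[3, ], c(A = 0.25, T = 0.25, C = 0.25, G = 0.25))
  expect_false(attr(M, "is_hard"))
  expect_error(one_hot_encode("ACXT", "uniform"), "invalid alphabet")
})

test_that("decoding resolves ties by channel order or errors on request", {
  soft <- matrix(0.25, 2, 4)
  expect_identical(one_hot_decode(soft), "AA")
  expect_error(one_hot_decode(soft, tie_break = "error"), "tie")
  expect_identical(one_hot_decode(matrix(c(0.7, 0.1, 0.1, 0.1), 1)), "A")
})

test_that("every one-hot row sums to 1 for soft generator output", {
  gan <- tiny_gan()
  F <- generator_forward(gan$gen, sample_latent(6, 8, seed = 1))
  rows <- promogan:::flat_to_blc(F, 4L)
  expect_true(max(abs(rowSums(rows) - 1)) < 1e-6)
})

test_that("FASTA round-trips, uppercases, and tolerates empty files", {
  path <- tempfile(fileext = ".fa")
  seqs <- c(s1 = "ACGTACGTAA", s2 = "TTTTACGTGG", s3 = paste(rep("ACGT", 40), collapse = ""))
  write_fasta(seqs, path)
  back <- read_fasta(path)
  expect_identical(back, seqs)
  # lowercase on disk reads back uppercased
  writeLines(c(">x", "acgtn"), path)
  expect_identical(unname(read_fasta(path)), "ACGTN")
  file.create(path2 <- tempfile(fileext = ".fa"))
  expect_length(read_fasta(path2), 0L)
})

test_that("PWM reader validates, renormalizes, and detects orientation", {
  path <- tempfile()
  writeLines(c("# mymotif", rep("0.25 0.25 0.25 0.25", 3)), path)
  p <- read_pwm(path)
  expect_s3_class(p, "pwm")
  expect_equal(nrow(p), 3L)
  expect_true(all(p == 0.25))
  expect_identical(attr(p, "name"), "mymotif")

  writeLines("2 0 0 0", path)
  expect_error(read_pwm(path), "1e-3")

  writeLines("0.5004 0.4996 0 0", path)
  p2 <- read_pwm(path)
  expect_equal(sum(p2[1, ]), 1, tolerance = 1e-12)

  # transposed 4 x Len dialect: auto-detected via the axis of size 4
  writeLines(c("1 0 0", "0 1 0", "0 0 1", "0 0 0"), path)
  p3 <- read_pwm(path)
  expect_equal(dim(p3), c(3L, 4L))
  expect_equal(pwm_consensus(p3), "ATC")

  # 4 x 4 is ambiguous without explicit orientation
  writeLines(rep("0.25 0.25 0.25 0.25", 4), path)
  expect_error(read_pwm(path), "ambiguous")
  expect_s3_class(read_pwm(path, orientation = "positions_by_base"), "pwm")

  writeLines("0.5 0.5 0 0 0", path)
  expect_error(read_pwm(path))
})

test_that("pwm round-trips through its file format", {
  p <- consensus_pwm("TGACGT", max_prob = 0.9)
  path <- tempfile()
  write_pwm(p, path)
  p2 <- read_pwm(path)
  expect_equal(unclass(p2), unclass(p), ignore_attr = TRUE, tolerance = 1e-9)
  expect_identical(attr(p2, "name"), "TGACGT")
})

test_that("simulate_dataset is bit-reproducible under a fixed seed", {
  a <- simulate_dataset(100, 50, seed = 1)
  b <- simulate_dataset(100, 50, seed = 1)
  expect_identical(a, b)
  c <- simulate_dataset(100, 50, seed = 2)
  expect_false(identical(a$sequences, c$sequences))
})

test_that("embedded motifs are recoverable by scanning at embed prob 1", {
  # 20-mer consensus: instances with up to two sampling mutations still
  # score above 0.9, so virtually every embedded sequence is recoverable
  p <- consensus_pwm("TGACGTCAGTTGACCATGCA", max_prob = 0.97)
  sim <- simulate_dataset(200, 50, motif = p, motif_embed_prob = 1, seed = 7)
  expect_true(all(sim$embedded))
  hits <- vapply(sim$sequences, function(s) {
    brute_motif_score(one_hot_encode(s), p)$normalized > 0.9
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("background-only simulation matches its composition", {
  bg <- c(0.4, 0.3, 0.2, 0.1)
  sim <- simulate_dataset(500, 60, background = bg, motif = NULL,
                          motif_embed_prob = 0, seed = 11)
  expect_false(any(sim$embedded))
  counts <- table(factor(strsplit(paste(sim$sequences, collapse = ""), "")[[1]],
                         levels = DNA_BASES))
  n <- sum(counts)
  # each base frequency within 3 standard errors of its target
  for (b in 1:4) {
    se <- sqrt(bg[b] * (1 - bg[b]) / n)
    expect_lt(abs(counts[b] / n - bg[b]), 3 * se + 1e-12)
  }
  # 4-mer composition consistent with an i.i.d. background (chi-square)
  sim2 <- simulate_dataset(5000, 24, background = bg, motif_embed_prob = 0,
                           seed = 12)
  kmers <- unlist(lapply(sim2$sequences, function(s) {
    substring(s, seq(1, 21, by = 4), seq(4, 24, by = 4))  # disjoint windows
  }))
  all4 <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES, DNA_BASES), 1,
                paste, collapse = "")
  probs <- apply(expand.grid(bg, bg, bg, bg), 1, prod)
  obs <- table(factor(kmers, levels = all4))
  # rare 4-mers have smallish expected counts; the approximation is still
  # adequate for a p > 0.001 consistency check
  pval <- suppressWarnings(
    stats::chisq.test(as.numeric(obs), p = probs / sum(probs))$p.value
  )
  expect_gt(pval, 0.001)
})

test_that("class-motif simulation balances labels and embeds consensi", {
  sim <- simulate_dataset(400, 60, class_motifs = sigma_class_motifs(),
                          mutation_rate = 0, seed = 5)
  tab <- table(sim$labels)
  expect_equal(length(tab), 4L)
  expect_lte(diff(range(tab)), 1)
  cm <- sigma_class_motifs()
  for (i in which(sim$labels != "none")[1:40]) {
    expect_true(grepl(cm[[as.character(sim$labels[i])]], sim$sequences[i],
                      fixed = TRUE))
  }
  expect_error(simulate_dataset(10, 8, class_motifs = sigma_class_motifs()),
               "longer than sequence")
})

test_that("label tables round-trip", {
  sim <- simulate_dataset(20, 40, class_motifs = sigma_class_motifs(), seed = 1)
  path <- tempfile()
  write_labels(sim$labels, path, ids = names(sim$sequences))
  back <- read_labels(path)
  expect_identical(unname(back), as.character(sim$labels))
  expect_identical(names(back), names(sim$sequences))
})
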