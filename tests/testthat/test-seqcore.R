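test_that("window enumeration yields all contiguous 9mers left to right", {
  w <- extract_windows("ACDEFGHIKLM")
  expect_equal(w$offsets, 0:2)
  expect_equal(w$windows, c("ACDEFGHIK", "CDEFGHIKL", "DEFGHIKLM"))

  p9 <- rand_peptide(9, 1)
  expect_equal(extract_windows(p9)$windows, p9)
  expect_length(extract_windows(rand_peptide(26, 2))$windows, 18L)

  # M = L - 8 exhaustively over the supported range
  for (L in 9:30) {
    p <- rand_peptide(L, L)
    w <- extract_windows(p)
    expect_length(w$windows, L - 8L)
    expect_equal(w$windows,
                 substring(p, w$offsets + 1L, w$offsets + 9L))
  }
  expect_error(extract_windows("ACDEFGHI"), "length")
})

test_that("padding marks real positions and never touches window content", {
  pm <- pad_and_mask(rand_peptide(12, 3))
  expect_length(pm$tokens, 30L)
  expect_equal(sum(pm$mask), 12L)
  expect_true(all(pm$tokens[13:30] == hla2present:::PAD_ID))

  full <- pad_and_mask(rand_peptide(30, 4))
  expect_true(all(full$mask))

  expect_error(pad_and_mask(rand_peptide(31, 5)), "exceeds")

  p <- rand_peptide(14, 6)
  w_before <- extract_windows(p)
  invisible(pad_and_mask(p))
  expect_identical(extract_windows(p), w_before)
})

test_that("non-canonical residues map to the unknown token with a warning", {
  expect_warning(tok <- tokenize_peptide("ACDX"), "non-canonical")
  expect_equal(tok[4], hla2present:::UNK_ID)
  expect_silent(tokenize_peptide("ACDY"))
})

test_that("greedy clustering groups identical and near-identical peptides", {
  p <- rand_peptide(15, 7)
  q <- rand_peptide(15, 8)
  cl <- cluster_peptides(c(p, p))
  expect_equal(unname(cl[1]), unname(cl[2]))

  # no shared residues at any alignment -> distinct clusters
  a <- strrep("A", 12); k <- strrep("K", 12)
  cl2 <- cluster_peptides(c(a, k))
  expect_length(unique(cl2), 2L)

  # 10 copies + 1 unique: sizes {10, 1}, weights {0.1, 1.0}
  peps <- c(rep(p, 10), q)
  cl3 <- cluster_peptides(peps)
  rec <- data.frame(peptide = peps)
  rec <- assign_weights(rec, cl3)
  expect_equal(sort(unique(rec$weight)), c(0.1, 1.0))

  # single substitution keeps >= 0.8 identity at length 15
  p_mut <- p
  substr(p_mut, 3, 3) <- setdiff(aa_alphabet(), substr(p, 3, 3))[1]
  cl4 <- cluster_peptides(c(p, p_mut))
  expect_equal(unname(cl4[1]), unname(cl4[2]))

  expect_length(cluster_peptides(character(0)), 0L)
})

test_that("clustering is idempotent on representatives", {
  set.seed(9)
  peps <- vapply(1:30, function(i) rand_peptide(sample(12:18, 1)), "")
  cl <- cluster_peptides(peps)
  reps <- unique(unname(cl))
  cl2 <- cluster_peptides(reps)
  expect_equal(length(unique(cl2)), length(reps))
})

test_that("per-cluster weights sum to one", {
  set.seed(10)
  base <- vapply(1:8, function(i) rand_peptide(15), "")
  peps <- sample(rep(base, times = sample(1:6, 8, replace = TRUE)))
  rec <- data.frame(peptide = peps)
  rec <- assign_weights(rec, cluster_peptides(peps))
  sums <- tapply(rec$weight, rec$cluster_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_error(assign_weights(data.frame(peptide = "WWWWWWWWWWWW"),
                              cluster_peptides(base)), "cluster")
})

test_that("external cluster TSV import round-trips the member map", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("REPREPREPREP\tREPREPREPREP", "REPREPREPREP\tMEMMEMMEMMEM"), tmp)
  cl <- read_cluster_tsv(tmp)
  expect_equal(unname(cl["MEMMEMMEMMEM"]), "REPREPREPREP")
})

test_that("splitting respects ratios and keeps shared 9mers together", {
  set.seed(11)
  # 100 peptides with pairwise-disjoint 9mers: build from distinct 3-AA codes
  aa <- aa_alphabet()
  peps <- apply(expand.grid(aa[1:10], aa[1:10])[1:100, ], 1, function(r) {
    paste0(strrep(r[1], 6), strrep(r[2], 6))
  })
  rec <- data.frame(peptide = unname(peps))
  sp <- split_dataset(rec, seed = 1)
  expect_equal(nrow(sp$train), 80L)
  expect_equal(nrow(sp$validation), 10L)
  expect_equal(nrow(sp$test), 10L)

  # records sharing a 9mer land in the same split
  shared <- rand_peptide(16, 12)
  fam <- c(shared, paste0(substr(shared, 1, 15), "A"),
           paste0("C", substr(shared, 1, 14)))
  rec2 <- data.frame(peptide = c(fam, peps[1:40]))
  sp2 <- split_dataset(rec2, seed = 2)
  in_split <- vapply(fam, function(p) {
    which(c(p %in% sp2$train$peptide, p %in% sp2$validation$peptide,
            p %in% sp2$test$peptide))
  }, integer(1))
  expect_length(unique(in_split), 1L)

  expect_error(split_dataset(rec[1:5, , drop = FALSE]), "fewer than 10")
})

test_that("greedy split leaks no more 9mers than random splits", {
  set.seed(13)
  base <- vapply(1:15, function(i) rand_peptide(14), "")
  # families of overlapping peptides -> shared 9mers across members
  peps <- unlist(lapply(base, function(b) {
    c(b, substr(b, 2, 14), paste0(b, "A"), substr(b, 1, 12))
  }))
  rec <- data.frame(peptide = peps)
  sp <- split_dataset(rec, seed = 3)
  leaked_random <- replicate(100, {
    g <- sample(rep(1:3, times = c(48, 6, 6)))
    mers <- lapply(1:3, function(s) hla2present:::ninemer_set(peps[g == s]))
    sum(table(unlist(mers)) > 1)
  })
  expect_lte(sp$leaked_9mers, min(leaked_random))
})

test_that("length filtering drops unwindowable peptides", {
  rec <- data.frame(peptide = c(rand_peptide(8, 14), rand_peptide(9, 15),
                                rand_peptide(26, 16), rand_peptide(27, 17)))
  expect_message(out <- filter_length(rec), "2 peptide")
  expect_equal(nchar(out$peptide), c(9L, 26L))
})

test_that("FASTA and peptide tables round-trip", {
  seqs <- c(protA = rand_peptide(50, 18), protB = rand_peptide(80, 19))
  f <- tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)

  tb <- data.frame(peptide = c("ACDEFGHIK", "CDEFGHIKL"),
                   sample_id = c("s1", "s2"), label = c(1L, 0L))
  tf <- tempfile(fileext = ".tsv")
  write_peptide_table(tb, tf)
  expect_equal(read_peptide_table(tf), tb)
})
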