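test_that("window enumeration counts match brute force", {
  chain <- rand_peptide(20, 60)
  win <- enumerate_screen_windows(chain)
  # 12 nine-mers + sum over sizes 12..19 of (20 - w + 1) = 44
  expect_equal(nrow(win), 56L)
  expect_equal(sum(win$size == 9), 12L)
  for (w in 12:19) expect_equal(sum(win$size == w), 20L - w + 1L)
  expect_true(!anyDuplicated(win[c("start", "size")]))

  expect_equal(nrow(enumerate_screen_windows(rand_peptide(9, 61))), 1L)
  # external-model mode excludes 9mers
  expect_equal(sum(enumerate_screen_windows(chain, 12:19)$size == 9), 0L)
  expect_warning(out <- enumerate_screen_windows(rand_peptide(5, 62), 9L),
                 "shorter")
  expect_equal(nrow(out), 0L)
})

test_that("germline filtering removes exactly the scaffold cores", {
  germ <- generate_proteome(3, c(60, 80), seed = 63)
  db <- germline_db(germ)
  spliced <- substr(germ[2], 5, 13)
  expect_length(filter_germline(spliced, db), 0L)
  mutated <- spliced
  substr(mutated, 4, 4) <- setdiff(aa_alphabet(), substr(spliced, 4, 4))[1]
  if (!any(grepl(mutated, germ, fixed = TRUE))) {
    expect_equal(filter_germline(mutated, db), mutated)
  }
  cores <- c(spliced, mutated)
  once <- filter_germline(cores, db)
  expect_identical(filter_germline(once, db), once)  # idempotent
})

test_that("epitope counting recovers exactly the planted foreign cores", {
  w <- small_world()
  germ <- generate_proteome(4, c(90, 110), seed = 64)
  cores <- vapply(w$motifs, consensus_core, "")   # 3 distinct foreign cores
  ab <- make_toy_antibody(germ, cores, seed = 65)
  db <- germline_db(germ)

  # a perfect predictor flags only the spliced cores: exact equality
  perfect <- core_set_scorer(cores)
  rep <- count_epitopes(ab$chains, perfect, db, panel = "any")
  expect_equal(sort(unique(unlist(lapply(rep$chains, `[[`, "epitope_cores")))),
               sort(unique(unname(cores))))
  expect_equal(rep$total_unique, length(unique(cores)))

  # the Bayes oracle recovers at least every planted core
  orc <- oracle_scorer(w)
  rep_o <- count_epitopes(ab$chains, orc, db, panel = names(w$motifs))
  expect_true(all(cores %in% unlist(lapply(rep_o$chains, `[[`,
                                           "epitope_cores"))))

  # pure-germline chains yield zero epitopes regardless of scores
  rep0 <- count_epitopes(c(g = germ[3]), orc, db, panel = names(w$motifs))
  expect_equal(rep0$total_unique, 0L)

  # the same core spliced at two loci is still counted once
  ab2 <- make_toy_antibody(germ, c(cores[1], cores[1]), seed = 66)
  rep2 <- count_epitopes(ab2$chains["heavy"], core_set_scorer(cores[1]), db,
                         panel = "any")
  expect_equal(rep2$total_unique, 1L)
})

test_that("epitope counts are monotone non-increasing in the threshold", {
  w <- small_world()
  orc <- oracle_scorer(w)
  germ <- generate_proteome(4, c(90, 110), seed = 67)
  ab <- make_toy_antibody(germ, vapply(w$motifs, consensus_core, ""),
                          seed = 68)
  db <- germline_db(germ)
  counts <- vapply(c(0.3, 0.5, 0.9, 0.99), function(th) {
    count_epitopes(ab$chains, orc, db, panel = names(w$motifs),
                   threshold = th)$total_unique
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("hotspot vectors cover the planted cores and ignore window order", {
  w <- small_world()
  orc <- oracle_scorer(w)
  germ <- generate_proteome(4, c(90, 110), seed = 69)
  cores <- vapply(w$motifs, consensus_core, "")
  ab <- make_toy_antibody(germ, cores, seed = 70)
  db <- germline_db(germ)
  rep <- count_epitopes(ab$chains, orc, db, panel = names(w$motifs))
  for (ch in c("heavy", "light")) {
    hs <- hotspot_heatmap(rep, ch)
    ins <- ab$insertions[ab$insertions$chain == ch, ]
    for (i in seq_len(nrow(ins))) {
      expect_true(all(hs[(ins$start[i] + 1):(ins$start[i] + 9)] > 0))
    }
  }
  # permuting the window-size order changes nothing
  rep_b <- count_epitopes(ab$chains, orc, db, panel = names(w$motifs),
                          sizes = rev(c(9L, 12:19)))
  expect_equal(hotspot_heatmap(rep_b, "heavy"), hotspot_heatmap(rep, "heavy"))
})

test_that("single-core hotspot takes the core score over its 9 residues", {
  rep <- structure(list(chains = list(
    c1 = list(chain = "c1", epitope_cores = "X", epitope_count = 1L,
              hotspot = c(rep(0, 5), rep(0.9, 9), rep(0, 6)))),
    total_unique = 1L, threshold = 0.5), class = "epitope_report")
  hs <- hotspot_heatmap(rep, "c1")
  expect_equal(hs[6:14], rep(0.9, 9))
  expect_true(all(hs[c(1:5, 15:20)] == 0))
})

test_that("MAPPs coverage normalises by the maximum and flags misalignment", {
  chain <- "ACDEFGHIKLMNPQRSTVWY"
  peps <- c("ACDEF", "CDEFG", "CDEFG")   # duplicated observation counts twice
  hm <- mapps_heatmap(peps, chain)
  expect_equal(max(hm), 1)
  expect_equal(hm[2], 1)                 # position C covered 3x
  expect_true(all(hm >= 0 & hm <= 1))
  expect_error(mapps_heatmap("WWWWW", chain), "not found")
  # worked normalisation example: coverage 0,2,4,4,1 -> 0,.5,1,1,.25
  expect_equal(c(0, 2, 4, 4, 1) / 4, c(0, 0.5, 1, 1, 0.25))
})

test_that("duplicate antibody labels resolve by threshold side", {
  tb <- data.frame(
    sequence = c("AAA", "AAA", "BBB", "BBB", "CCC"),
    ada_fraction = c(3, 7, 5, 15, 50))
  out <- resolve_duplicate_labels(tb)
  expect_equal(sort(out$sequence), c("AAA", "CCC"))
  expect_false(out$immunogenic[out$sequence == "AAA"])
  expect_true(out$immunogenic[out$sequence == "CCC"])

  # 217 rows with 3 same-side and 2 conflicting duplicate pairs -> 210
  set.seed(71)
  uniq <- data.frame(sequence = sprintf("ab%03d", 1:207),
                     ada_fraction = runif(207, 0, 9))
  same <- data.frame(sequence = rep(c("dupA", "dupB", "dupC"), each = 2),
                     ada_fraction = c(1, 2, 15, 20, 3, 4))
  conf <- data.frame(sequence = rep(c("dupD", "dupE"), each = 2),
                     ada_fraction = c(5, 15, 2, 30))
  big <- rbind(uniq[1:203, ], same, conf)   # 203 + 6 + 4 = 213? keep exact
  big <- rbind(uniq, same, conf)            # 207 + 6 + 4 = 217 rows
  expect_equal(nrow(big), 217L)
  expect_equal(nrow(resolve_duplicate_labels(big)), 210L)
})

test_that("leave-one-out cutoffs separate separable counts perfectly", {
  counts <- c(1:5, 20:25)
  lab <- c(rep(FALSE, 5), rep(TRUE, 6))
  res <- loo_cutoff(counts, lab)
  expect_length(res$fold_cutoffs, 11L)
  expect_true(all(res$fold_cutoffs > 5 & res$fold_cutoffs <= 20))
  expect_true(all(res$youden == 1))
  expect_equal(res$f1, 1)
  expect_error(loo_cutoff(1:5, c(TRUE, rep(FALSE, 4))), "two antibodies")
})

test_that("shuffled labels give prevalence-level leave-one-out F1", {
  set.seed(72)
  counts <- rpois(40, 10)
  lab <- rep(c(TRUE, FALSE), each = 20)
  f1s <- replicate(100, loo_cutoff(counts, sample(lab))$f1)
  # chance-level F1 at prevalence 0.5 sits between random guessing
  # (~0.5) and an always-positive caller (2/3); far below the
  # separable-data F1 of 1
  expect_gt(mean(f1s), 0.3)
  expect_lt(mean(f1s), 0.75)
})

test_that("neoantigen tiering follows the documented boundaries", {
  w <- small_world()
  orc <- oracle_scorer(w)
  # a long peptide carrying a strong consensus core somewhere inside
  set.seed(73)
  core <- consensus_core(w$motifs[[1]])
  long <- paste0(rand_peptide(18), core, rand_peptide(13))
  expect_equal(nchar(long), 40L)
  res <- score_neoantigen(long, orc, panel = names(w$motifs))
  expect_equal(res$tier, "high-likelihood")
  expect_equal(res$core, core)
  expect_equal(res$core_start, 18L)

  # brute-force recomputation over all windows
  win <- enumerate_screen_windows(long)
  sc <- predict(orc, data.frame(peptide = win$peptide),
                panel = names(w$motifs))
  expect_equal(res$score, max(sc$score))

  expect_error(score_neoantigen("ACDEF", orc, panel = names(w$motifs)),
               "shorter")
})

# a scorer returning a fixed score, to pin the tier boundaries
predict.const_scorer <- function(object, newdata, registry = NULL,
                                 sample_alleles = NULL, panel = NULL, ...) {
  data.frame(peptide = newdata$peptide, sample_id = "s",
             score = rep(object$value, nrow(newdata)),
             core_offset = 0L, core_9mer = substr(newdata$peptide, 1, 9),
             best_allele = "A", presented = object$value >= 0.5,
             stringsAsFactors = FALSE)
}

test_that("tier boundaries are inclusive at 0.5 and 0.95", {
  registerS3method("predict", "const_scorer", predict.const_scorer,
                   envir = asNamespace("stats"))
  pep <- rand_peptide(15, 74)
  tier_at <- function(v) {
    sc <- structure(list(value = v), class = "const_scorer")
    score_neoantigen(pep, sc, panel = "A")$tier
  }
  expect_equal(tier_at(0.97), "high-likelihood")
  expect_equal(tier_at(0.95), "high-likelihood")
  expect_equal(tier_at(0.80), "low-likelihood")
  expect_equal(tier_at(0.50), "low-likelihood")
  expect_equal(tier_at(0.49), "not-presented")
})
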