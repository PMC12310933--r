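test_that("encoders produce the configured shapes", {
  cfg <- tiny_config()
  m <- hla2_init(cfg, seed = 1)
  p <- rand_peptide(12, 31)
  enc <- encode_peptide(m, p)
  expect_equal(dim(enc), c(12L, cfg$d_model))
  aenc <- encode_allele(m, rand_pseudo(32))
  expect_equal(dim(aenc), c(34L, cfg$d_model))
  expect_error(encode_allele(m, rand_peptide(20, 33)), "34-residue")
})

test_that("evaluation-mode forward passes are deterministic", {
  m <- hla2_init(tiny_config(), seed = 2)
  p <- rand_peptide(15, 34)
  expect_identical(encode_peptide(m, p), encode_peptide(m, p))
  al <- c(X = rand_pseudo(35), Y = rand_pseudo(36))
  s1 <- pair_scores(m, p, al)
  s2 <- pair_scores(m, p, al)
  expect_identical(s1$scores, s2$scores)
})

test_that("peptide encoding carries long-range dependencies", {
  m <- hla2_init(tiny_config(), seed = 3)
  p <- rand_peptide(20, 37)
  q <- p
  substr(q, 20, 20) <- setdiff(aa_alphabet(), substr(p, 20, 20))[1]
  ep <- encode_peptide(m, p)
  eq <- encode_peptide(m, q)
  # a distant mutation changes the representation at position 1
  expect_gt(max(abs(ep[1, ] - eq[1, ])), 0)
})

test_that("distinct pseudo-sequences yield distinct encodings", {
  m <- hla2_init(tiny_config(), seed = 4)
  ps <- vapply(1:60, function(i) rand_pseudo(1000 + i), "")
  ps <- unique(ps)
  encs <- vapply(ps, function(x) as.vector(encode_allele(m, x)),
                 numeric(34L * 16L))
  expect_equal(anyDuplicated(t(encs)), 0L)
})

test_that("final score is the brute-force maximum over the pair matrix", {
  m <- hla2_init(tiny_config(), seed = 5)
  al <- c(A1 = rand_pseudo(41), A2 = rand_pseudo(42), A3 = rand_pseudo(43))
  p <- rand_peptide(17, 44)
  ps <- pair_scores(m, p, al)
  expect_equal(dim(ps$scores), c(3L, 17L - 8L))
  expect_equal(ps$final_score, max(ps$scores))
  expect_equal(unname(ps$scores[ps$argmax$allele,
                                as.character(ps$argmax$offset)]),
               ps$final_score)
  expect_true(all(ps$scores > 0 & ps$scores < 1))
})

test_that("allele order permutation changes nothing", {
  m <- hla2_init(tiny_config(), seed = 6)
  al <- c(B = rand_pseudo(45), A = rand_pseudo(46), C = rand_pseudo(47))
  p <- rand_peptide(14, 48)
  s1 <- pair_scores(m, p, al)
  s2 <- pair_scores(m, p, al[c(3, 1, 2)])
  expect_equal(s1$final_score, s2$final_score)
  expect_equal(s1$argmax, s2$argmax)
  expect_equal(s1$scores, s2$scores)
})

test_that("adding an allele never decreases the final score", {
  m <- hla2_init(tiny_config(), seed = 7)
  al <- c(A = rand_pseudo(49), B = rand_pseudo(50), C = rand_pseudo(51))
  p <- rand_peptide(13, 52)
  s12 <- pair_scores(m, p, al[1:2])
  s123 <- pair_scores(m, p, al)
  expect_gte(s123$final_score, s12$final_score)
  # pair independence: existing pairs unchanged by the extra allele
  expect_equal(s123$scores[c("A", "B"), ], s12$scores[c("A", "B"), ])
})

test_that("scores are invariant to the pad length", {
  m <- hla2_init(tiny_config(), seed = 8)
  al <- c(A = rand_pseudo(53))
  p <- rand_peptide(12, 54)
  s30 <- pair_scores(m, p, al, pad_len = 30L)
  s26 <- pair_scores(m, p, al, pad_len = 26L)
  s12 <- pair_scores(m, p, al, pad_len = 12L)
  expect_equal(s26$scores, s30$scores, tolerance = 1e-5)
  expect_equal(s12$scores, s30$scores, tolerance = 1e-5)
})

test_that("interaction attention rows are normalised and recordable", {
  cfg <- tiny_config(n_int_blocks = 2L)
  m <- hla2_init(cfg, seed = 9)
  ps <- pair_scores(m, rand_peptide(11, 55), c(A = rand_pseudo(56)),
                    attention = TRUE)
  expect_equal(dim(ps$attention), c(2L, cfg$n_heads, 9L, 34L))
  sums <- apply(ps$attention, c(1, 2, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
})

test_that("allele capacity and length limits are enforced", {
  cfg <- tiny_config(max_alleles = 3L)
  m <- hla2_init(cfg, seed = 10)
  al <- stats::setNames(vapply(1:4, function(i) rand_pseudo(60 + i), ""),
                        paste0("A", 1:4))
  expect_error(pair_scores(m, rand_peptide(12, 57), al), "at most")
  expect_error(pair_scores(m, rand_peptide(8, 58), al[1:2]), "shorter than 9")
  expect_error(pair_scores(m, rand_peptide(31, 59), al[1:2]),
               "padded length")
})

test_that("ensemble of two identical models equals the single model", {
  m <- hla2_init(tiny_config(), seed = 11)
  ens <- hla2_ensemble(m, m)
  al <- c(A = rand_pseudo(70), B = rand_pseudo(71))
  p <- rand_peptide(16, 72)
  s1 <- pair_scores(m, p, al)
  s2 <- pair_scores(ens, p, al)
  expect_equal(s1$scores, s2$scores)
  expect_equal(s1$final_score, s2$final_score)
  nd <- data.frame(peptide = p)
  reg <- allele_registry(names(al), unname(al))
  pr1 <- predict(m, nd, reg, panel = names(al))
  pr2 <- predict(ens, nd, reg, panel = names(al))
  pr3 <- predict(ens, nd, reg, panel = names(al), aggregate = "mean_of_max")
  expect_equal(pr1$score, pr2$score)
  expect_equal(pr1$score, pr3$score)
})

test_that("default configuration matches the published architecture", {
  cfg <- hla2_config()
  expect_equal(cfg$n_blocks, 8L)
  expect_equal(cfg$n_heads, 8L)
  expect_equal(cfg$d_model, 128L)
  expect_equal(cfg$head_hidden, 1152L)
  expect_equal(cfg$max_peptide_len, 30L)
  expect_equal(cfg$max_alleles, 14L)
  expect_equal(cfg$dropout, 0.1)
  expect_error(hla2_config(d_model = 30L, n_heads = 8L))
})

test_that("analytic gradients match finite differences", {
  cfg <- hla2_config(n_blocks = 1L, n_heads = 2L, d_model = 8L,
                     n_int_blocks = 1L, max_peptide_len = 14L,
                     max_alleles = 3L)
  m <- hla2_init(cfg, seed = 12)
  params <- m$params
  tb <- hla2present:::tokens_batch(c(rand_peptide(12, 80), rand_peptide(10, 81)),
                                   cfg$max_peptide_len)
  atok <- hla2present:::allele_tokens(c(rand_pseudo(82), rand_pseudo(83)))
  aidx <- list(c(1L, 2L), 1L)
  labels <- c(1, 0); weights <- c(0.4, 1.1)
  loss_of <- function(pp) {
    fw <- hla2present:::model_forward(pp, cfg, tb, atok, aidx,
                                      training = FALSE, keep_cache = TRUE)
    ag <- hla2present:::aggregate_max(fw$logits, fw$pairs, 2L, aidx, 0)
    list(loss = weighted_bce(hla2present:::sigmoid(ag$logit), labels, weights),
         fw = fw, ag = ag)
  }
  base <- loss_of(params)
  s <- hla2present:::sigmoid(base$ag$logit)
  dlogits <- numeric(base$fw$pairs$n)
  dlogits[base$ag$sel] <- weights * (s - labels) / sum(weights)
  grads <- hla2present:::model_backward(params, cfg, base$fw, tb, dlogits,
                                        base$ag$sel)
  eps <- 1e-5
  set.seed(99)
  for (nm in c("emb_pep", "pos_all", "pep1.Wq", "pep1.ln1g", "all1.Wv",
               "int1.Wk", "int1.W2", "head_w", "head_b")) {
    i <- sample(length(params[[nm]]), 1L)
    pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
    lp <- loss_of(pp)$loss
    pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
    lm <- loss_of(pp)$loss
    num <- (lp - lm) / (2 * eps)
    expect_equal(grads[[nm]][i], num, tolerance = 1e-3,
                 label = paste("gradient of", nm))
  }
})

test_that("checkpoints round-trip the full model state", {
  m <- hla2_init(tiny_config(), seed = 13)
  m$scenario <- 2L
  f <- tempfile(fileext = ".rds")
  write_checkpoint(m, f)
  m2 <- read_checkpoint(f)
  expect_s3_class(m2, "hla2_model")
  expect_identical(m2$params, m$params)
  expect_identical(m2$scenario, 2L)
  expect_identical(m2$config, m$config)
})
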