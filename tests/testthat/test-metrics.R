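test_that("F1 follows the harmonic-mean formula", {
  # precision = recall = 0.5 -> F1 = 0.5; precision 1, recall 0.5 -> 2/3
  f1 <- function(p, r) 2 * p * r / (p + r)
  expect_equal(f1(0.5, 0.5), 0.5)
  expect_equal(f1(1, 0.5), 2 / 3)

  # construction realising precision 1, recall 0.5
  scores <- c(0.9, 0.1, 0.2, 0.1)
  labels <- c(1, 1, 0, 0)
  m <- classification_metrics(scores, labels)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 0.5)
  expect_equal(m$tpr, 0.5)
  expect_equal(m$f1, 2 / 3)
})

test_that("perfect separation gives unit AUCs; single class warns NA", {
  scores <- c(0.9, 0.8, 0.2, 0.1)
  labels <- c(1, 1, 0, 0)
  m <- classification_metrics(scores, labels)
  expect_equal(m$roc_auc, 1)
  expect_equal(m$pr_auc, 1)

  expect_warning(m1 <- classification_metrics(c(0.9, 0.2), c(1, 1)),
                 "both classes")
  expect_true(is.na(m1$roc_auc))
  expect_equal(m1$f1, 2 * 1 * 0.5 / 1.5)
})

test_that("F1 and ROC-AUC match independent implementations on random data", {
  set.seed(80)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    scores <- runif(n)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    m <- classification_metrics(scores, labels)
    # brute-force confusion matrix
    pred <- scores >= 0.5
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    fn <- sum(!pred & labels == 1)
    f1_bf <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
    expect_equal(m$f1, f1_bf)
    expect_true(m$f1 >= 0 && m$f1 <= 1)
    expect_true(m$roc_auc >= 0 && m$roc_auc <= 1)
    expect_true(m$pr_auc >= 0 && m$pr_auc <= 1)
  }
  # cross-check the midrank ROC-AUC against pROC
  set.seed(81)
  scores <- round(runif(300), 2)        # many ties
  labels <- rbinom(300, 1, 0.4)
  m <- classification_metrics(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(m$roc_auc, ref, tolerance = 1e-12)
})

test_that("per-allele TPR pools correctly and excludes empty alleles", {
  pred <- data.frame(
    allele = c("A", "A", "A", "B", "B", "C"),
    score = c(1, 1, 0.2, 1, 0.1, 0.3),
    label = c(1, 1, 1, 1, 1, 0))
  expect_warning(rep <- per_allele_report(pred), "without positives")
  tab <- rep$per_allele
  expect_equal(tab$tpr[tab$allele == "A"], 2 / 3)
  expect_equal(tab$tpr[tab$allele == "B"], 1 / 2)
  expect_equal(rep$overall, 3 / 5)
  expect_false("C" %in% tab$allele)

  allpos <- data.frame(allele = rep("A", 4), score = rep(1, 4),
                       label = rep(1, 4))
  expect_equal(per_allele_report(allpos)$per_allele$tpr, 1)
})

test_that("core accuracy separates correct, wrong and unsupported", {
  ann <- data.frame(peptide = c(rand_peptide(12, 82), rand_peptide(9, 83),
                                rand_peptide(35, 84)),
                    core_offset = c(2L, 0L, 5L))
  prd <- data.frame(peptide = ann$peptide, core_offset = c(2L, 0L, 1L))
  res <- core_accuracy(prd, ann)
  expect_equal(res$n_correct, 2L)
  expect_equal(res$n_wrong, 0L)
  expect_equal(res$n_unsupported, 1L)   # the 35mer exceeds the model range
  expect_equal(res$accuracy, 1)

  prd$core_offset[1] <- 3L
  expect_equal(core_accuracy(prd, ann)$n_wrong, 1L)
  bad <- data.frame(peptide = rand_peptide(10, 85), core_offset = 5L)
  expect_error(core_accuracy(prd, bad), "beyond peptide end")
})

test_that("positional entropy hits its closed forms and properties", {
  expect_equal(position_entropy(rep("ACDEFGHIK", 7)), rep(0, 9))
  set.seed(86)
  cores <- vapply(1:8000, function(i) rand_peptide(9), "")
  H <- position_entropy(cores)
  expect_true(all(abs(H - log2(20)) < 0.05))
  expect_true(all(H <= log2(20) + 1e-9))
  # permutation invariance over input order
  expect_equal(position_entropy(rev(cores)), H)
  # base is configurable
  expect_equal(position_entropy(cores, base = exp(1)), H * log(2))
  expect_error(position_entropy(character(0)), "at least one")
})

test_that("anchored cores have lower entropy at anchor positions", {
  m <- make_motif(seed = 87)
  set.seed(88)
  cores <- replicate(3000, hla2present:::sample_core(m$pssm))
  H <- position_entropy(cores)
  expect_lt(mean(H[m$anchors]), mean(H[setdiff(1:9, m$anchors)]))
})

test_that("contact maps use strict 5-angstrom heavy-atom cutoffs", {
  res_at <- function(x, y, z) matrix(c(x, y, z), 1, 3)
  pep <- list(res_at(0, 0, 0))
  expect_true(contact_map(pep, list(res_at(3, 0, 0)))[1, 1])
  expect_false(contact_map(pep, list(res_at(6, 0, 0)))[1, 1])
  expect_false(contact_map(pep, list(res_at(5, 0, 0)))[1, 1])   # strict <

  # rigid motion leaves contacts unchanged
  set.seed(89)
  pepc <- lapply(1:4, function(i) matrix(rnorm(9, sd = 3), 3, 3))
  chnc <- lapply(1:5, function(i) matrix(rnorm(9, sd = 3), 3, 3))
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  shift <- c(10, -4, 2)
  mv <- function(m) sweep(m %*% R, 2, -shift)
  expect_equal(contact_map(pepc, chnc),
               contact_map(lapply(pepc, mv), lapply(chnc, mv)))

  expect_warning(contact_map(list(matrix(numeric(0), 0, 3)),
                             list(res_at(0, 0, 0))), "without atoms")
})

test_that("attention recovery behaves at its analytic anchors", {
  contacts <- matrix(FALSE, 9, 34)
  contacts[cbind(1:9, c(3, 7, 11, 15, 19, 23, 27, 31, 34))] <- TRUE
  # attention exactly on the contact partners -> recovery 1
  attn <- array(0, c(1, 1, 9, 34))
  for (q in 1:9) attn[1, 1, q, which(contacts[q, ])] <- 1
  res <- attention_recovery(attn, contacts, k = 3)
  expect_equal(res$max, 1)

  # random attention recovers about k/34 of one-per-row contacts
  set.seed(90)
  recs <- replicate(300, {
    a <- array(stats::runif(9 * 34), c(1, 1, 9, 34))
    attention_recovery(a, contacts, k = 3)$per[1, 1]
  })
  expect_lt(abs(mean(recs) - 3 / 34), 0.02)

  # no contacts in the pseudo positions -> NA
  none <- matrix(FALSE, 9, 34)
  expect_true(is.na(attention_recovery(attn, none)$max))

  # global mode marks k cells in total
  g <- attention_recovery(attn, contacts, k = 3, mode = "global")
  expect_lte(g$max, 3 / 9)
})

test_that("core contact matrices map chain residues onto pseudo positions", {
  tab <- position_table(seq(1, 29, 2), seq(2, 38, 2))
  cma <- matrix(FALSE, 12, 40); cmb <- matrix(FALSE, 12, 40)
  cma[3, 1] <- TRUE     # core position 1 (offset 2) vs alpha groove pos 1
  cma[3, 4] <- TRUE     # alpha position 4 is not in the table: invisible
  cmb[4, 2] <- TRUE     # core position 2 vs beta groove pos 2
  cc <- core_contact_matrix(cma, cmb, core_offset = 2L, table = tab)
  expect_equal(dim(cc), c(9L, 34L))
  expect_true(cc[1, 1])          # alpha pos 1 -> pseudo column 1
  expect_true(cc[2, 16])         # beta pos 2 -> pseudo column 16
  expect_equal(sum(cc), 2L)      # the non-groove contact is excluded
})
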