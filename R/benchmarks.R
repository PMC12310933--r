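# Self-contained synthetic study runs: motif recovery on a planted
# world, and the cluster-weighting ablation. These are the package's
# reference experiments; the test suite and the reproduction script
# call them rather than re-scripting the pipeline.

#' Synthetic motif-recovery study
#'
#' Generates a monoallelic planted-motif world, clusters and weights
#' the positives, splits 8:1:1 by 9mer overlap, trains a compact model
#' (2 blocks, 32 latent dimensions, 2 heads by default), and evaluates
#' on the held-out test positives plus length-matched decoys: ROC-AUC,
#' F1 at 0.5, and the fraction of positives whose argmax window equals
#' the planted core. The Bayes-optimal oracle and an untrained model
#' are evaluated on the same records as ceiling and floor.
#'
#' @param seed Integer; drives world generation, training and decoys.
#' @param n_alleles,positives_per_allele World size (defaults 5 x 400).
#' @param config Model configuration (default 2 x 32 x 2 compact).
#' @param epochs,lr Training length and learning rate (defaults 8 and
#'   1e-3, sized to the compact model and small corpus).
#' @param scenario Decoy scenario (default 1).
#' @return List: `auc`, `f1`, `core_accuracy`, `oracle_auc`,
#'   `oracle_core_accuracy`, `untrained_auc`, `n_test`, `model`.
#' @export
recovery_benchmark <- function(seed = 1L, n_alleles = 5L,
                               positives_per_allele = 400L,
                               config = hla2_config(n_blocks = 2L,
                                                    n_heads = 2L,
                                                    d_model = 32L),
                               epochs = 8L, lr = 1e-3, scenario = 1L) {
  world <- generate_world(n_alleles = n_alleles, n_samples = n_alleles,
                          positives_per_sample = positives_per_allele,
                          polyallelic_max = 1L, seed = seed)
  pos <- world$positives
  pos <- assign_weights(pos, cluster_peptides(pos$peptide))
  sp <- split_dataset(pos, seed = seed + 1L)
  ctrl <- hla2_control(lr = lr, batch_size = 200L, max_epochs = epochs)
  model <- hla2_train(sp$train, sp$validation, world$sample_alleles,
                      world$registry, world$proteome, config, ctrl,
                      scenario = scenario, seed = seed + 2L)
  test_pos <- sp$test
  dec <- sample_decoys(test_pos, world$proteome, scenario = 1L,
                       seed = seed + 3L, epoch = 1L)
  eval_set <- rbind(
    data.frame(peptide = test_pos$peptide, sample_id = test_pos$sample_id,
               label = 1L, stringsAsFactors = FALSE),
    data.frame(peptide = dec$peptide, sample_id = dec$sample_id,
               label = 0L, stringsAsFactors = FALSE))
  score_of <- function(m) {
    predict(m, eval_set, world$registry,
            sample_alleles = world$sample_alleles)
  }
  pr <- score_of(model)
  met <- classification_metrics(pr$score, eval_set$label)
  core_acc <- mean(pr$core_offset[eval_set$label == 1L] ==
                     test_pos$core_offset)
  orc <- predict(oracle_scorer(world), eval_set,
                 sample_alleles = world$sample_alleles)
  omet <- classification_metrics(orc$score, eval_set$label)
  ocore <- mean(orc$core_offset[eval_set$label == 1L] ==
                  test_pos$core_offset)
  upr <- score_of(hla2_init(config, seed = seed + 4L))
  umet <- classification_metrics(upr$score, eval_set$label)
  list(auc = met$roc_auc, f1 = met$f1, core_accuracy = core_acc,
       oracle_auc = omet$roc_auc, oracle_core_accuracy = ocore,
       untrained_auc = umet$roc_auc, n_test = nrow(eval_set),
       model = model)
}

#' Cluster-weighting ablation study
#'
#' Generates a world in which 80% of positives are near-duplicates of a
#' few template peptides carrying one dominant motif (large clusters)
#' and the rest come from rarer motifs (small clusters), then trains
#' the same compact model twice — with and without inverse-cluster-size
#' loss weights — and reports held-out ROC-AUC separately for the
#' large-cluster and small-cluster bins. The spread between the bins
#' measures how strongly the model favours the dominant pattern;
#' weighting is expected to shrink it.
#'
#' @param seed Integer seed.
#' @param n_alleles,positives_per_sample,n_samples World size.
#' @param dominant_frac Fraction of positives from the dominant motif
#'   (default 0.8).
#' @param config,epochs,lr As in [recovery_benchmark()].
#' @return List with `spread_weighted`, `spread_unweighted` and the
#'   per-bin AUCs (`auc_large_*`, `auc_small_*`).
#' @export
weighting_ablation <- function(seed = 1L, n_alleles = 5L, n_samples = 5L,
                               positives_per_sample = 200L,
                               dominant_frac = 0.8,
                               config = hla2_config(n_blocks = 2L,
                                                    n_heads = 2L,
                                                    d_model = 32L),
                               epochs = 6L, lr = 1e-3) {
  world <- generate_world(n_alleles = n_alleles, n_samples = n_samples,
                          positives_per_sample = positives_per_sample,
                          polyallelic_max = 2L,
                          dominant_frac = dominant_frac, seed = seed)
  pos <- world$positives
  pos <- assign_weights(pos, cluster_peptides(pos$peptide))
  sp <- split_dataset(pos, seed = seed + 1L)
  test_pos <- sp$test
  dec <- sample_decoys(test_pos, world$proteome, scenario = 1L,
                       seed = seed + 7L, epoch = 1L)
  big <- test_pos$weight < 1 / 50        # members of dominant clusters
  eval_set <- rbind(
    data.frame(peptide = test_pos$peptide, sample_id = test_pos$sample_id,
               label = 1L, big = big, stringsAsFactors = FALSE),
    data.frame(peptide = dec$peptide, sample_id = dec$sample_id,
               label = 0L, big = big, stringsAsFactors = FALSE))
  run <- function(use_weights) {
    ctrl <- hla2_control(lr = lr, batch_size = 200L, max_epochs = epochs,
                         use_weights = use_weights)
    m <- hla2_train(sp$train, sp$validation, world$sample_alleles,
                    world$registry, world$proteome, config, ctrl,
                    scenario = 1L, seed = seed + 13L)
    pr <- predict(m, eval_set, world$registry,
                  sample_alleles = world$sample_alleles)
    a_big <- classification_metrics(pr$score[eval_set$big],
                                    eval_set$label[eval_set$big])$roc_auc
    a_small <- classification_metrics(pr$score[!eval_set$big],
                                      eval_set$label[!eval_set$big])$roc_auc
    c(big = a_big, small = a_small)
  }
  w <- run(TRUE); u <- run(FALSE)
  list(spread_weighted = abs(w["big"] - w["small"]),
       spread_unweighted = abs(u["big"] - u["small"]),
       auc_large_weighted = unname(w["big"]),
       auc_small_weighted = unname(w["small"]),
       auc_large_unweighted = unname(u["big"]),
       auc_small_unweighted = unname(u["small"]))
}
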