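# Training protocol: per-epoch decoy regeneration from a background
# proteome (two scenarios), inverse-cluster-size weighted binary
# cross-entropy, allele dropout inside the max aggregation, AdamW with
# plateau-triggered learning-rate decay and early stopping, and the
# two-scenario ensemble.

#' Training control parameters
#'
#' Defaults follow the published training schedule; the learning rate
#' in particular (1e-5) is tuned to the full-scale corpus and is
#' usually raised (e.g. to 1e-3) for small synthetic worlds.
#'
#' @param lr Initial AdamW learning rate.
#' @param batch_size Records per optimisation step.
#' @param max_epochs Maximum training epochs.
#' @param lr_decay Multiplicative decay factor applied on a validation
#'   plateau (default 0.7).
#' @param plateau_epochs Consecutive non-improving epochs that define a
#'   plateau (default 2).
#' @param plateau_tol Minimum validation-loss improvement that counts
#'   (default 1e-4).
#' @param patience_stop Stop when validation has not improved for this
#'   many epochs (default 5) ...
#' @param min_decays ... and the learning rate has decayed at least
#'   this many times (default 2).
#' @param grad_clip Global gradient-norm clip (default 1.0).
#' @param allele_dropout Fraction of alleles whose pair scores are
#'   dropped from the max in polyallelic samples (default 0.5).
#' @param weight_decay AdamW weight decay (default 0.01).
#' @param use_weights Use inverse-cluster-size loss weights (default
#'   `TRUE`; switch off for the weighting ablation).
#' @param verbose Print one line per epoch.
#' @return Object of class `hla2_control`.
#' @export
hla2_control <- function(lr = 1e-5, batch_size = 200L, max_epochs = 50L,
                         lr_decay = 0.7, plateau_epochs = 2L,
                         plateau_tol = 1e-4, patience_stop = 5L,
                         min_decays = 2L, grad_clip = 1.0,
                         allele_dropout = 0.5, weight_decay = 0.01,
                         use_weights = TRUE, verbose = FALSE) {
  stopifnot(lr > 0, batch_size >= 1, max_epochs >= 1,
            lr_decay > 0, lr_decay < 1, grad_clip > 0,
            allele_dropout >= 0, allele_dropout < 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), lr_decay = lr_decay,
                 plateau_epochs = as.integer(plateau_epochs),
                 plateau_tol = plateau_tol,
                 patience_stop = as.integer(patience_stop),
                 min_decays = as.integer(min_decays), grad_clip = grad_clip,
                 allele_dropout = allele_dropout,
                 weight_decay = weight_decay,
                 use_weights = isTRUE(use_weights),
                 verbose = isTRUE(verbose)),
            class = "hla2_control")
}

derive_seeds <- function(seed) {
  base <- as.integer(seed) %% 1000000L
  list(init = base * 7L + 1L, decoys = base * 7L + 2L,
       dropout = base * 7L + 3L, shuffle = base * 7L + 4L)
}

#' Sample length-matched proteome decoys
#'
#' Draws one decoy per presented peptide from the background proteome:
#' a uniformly placed substring of the same length, from a protein
#' chosen proportionally to the number of windows it offers. Each decoy
#' inherits its positive's `sample_id` and loss weight. Under scenario
#' 2 candidates sharing any 9mer with any presented peptide are
#' rejected and redrawn. The draw is a pure function of
#' `(seed, epoch)`.
#'
#' @param positives Data frame of presented records (columns `peptide`,
#'   `sample_id`, optionally `weight`).
#' @param proteome Named character vector of background protein
#'   sequences.
#' @param scenario 1 (unscreened) or 2 (9mer-disjoint from positives).
#' @param seed,epoch Integers seeding the draw.
#' @return Data frame of decoy records (`label = 0`), same number of
#'   rows and identical per-length counts as `positives`.
#' @export
sample_decoys <- function(positives, proteome, scenario = 1L, seed = 1L,
                          epoch = 1L) {
  stopifnot(scenario %in% c(1L, 2L), nrow(positives) >= 1L,
            length(proteome) >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed((as.integer(seed) + 1000003L * as.integer(epoch)) %% 2147483647L)

  plen <- nchar(proteome)
  pos_mers <- NULL
  if (scenario == 2L) {
    pos_mers <- new.env(hash = TRUE, parent = emptyenv())
    for (m in ninemer_set(positives$peptide)) assign(m, TRUE, envir = pos_mers)
  }
  L <- nchar(positives$peptide)
  dec <- character(nrow(positives))
  for (i in seq_along(L)) {
    wts <- pmax(0L, plen - L[i] + 1L)
    if (!any(wts > 0L)) {
      stop("background proteome has no protein of length >= ", L[i])
    }
    tries <- 0L
    repeat {
      tries <- tries + 1L
      pr <- sample.int(length(proteome), 1L, prob = wts)
      off <- sample.int(wts[pr], 1L)
      cand <- substr(proteome[pr], off, off + L[i] - 1L)
      if (scenario == 1L) break
      ok <- TRUE
      for (m in extract_windows(cand)$windows) {
        if (!is.null(pos_mers[[m]])) { ok <- FALSE; break }
      }
      if (ok) break
      if (tries >= 200L) {
        stop("could not draw a 9mer-disjoint decoy of length ", L[i],
             " after 200 tries; enlarge the background proteome")
      }
    }
    dec[i] <- cand
  }
  out <- data.frame(peptide = dec,
                    sample_id = positives$sample_id,
                    label = 0L,
                    stringsAsFactors = FALSE)
  if (!is.null(positives$weight)) out$weight <- positives$weight
  if (!is.null(positives$cluster_id)) out$cluster_id <- positives$cluster_id
  out$linked_to <- positives$peptide
  out
}

#' Drop allele score rows from the max aggregation
#'
#' Training regularisation for polyallelic samples: `floor(N * fraction)`
#' of the N allele rows of a pair score matrix are excluded from the
#' maximum for one step, forcing the model to explain presentation
#' through the remaining alleles. Monoallelic samples are untouched.
#' Dropped rows are returned as `NA` with the dropped allele indices in
#' attribute `"dropped"`.
#'
#' @param scores N x M matrix of pair scores (rows = alleles).
#' @param fraction Fraction of alleles to drop (default 0.5).
#' @return The matrix with dropped rows set to `NA`.
#' @export
allele_dropout <- function(scores, fraction = 0.5) {
  stopifnot(is.matrix(scores), fraction >= 0, fraction < 1)
  N <- nrow(scores)
  ndrop <- floor(N * fraction)
  if (N < 2L || ndrop < 1L) {
    attr(scores, "dropped") <- integer(0)
    return(scores)
  }
  dropped <- sample.int(N, ndrop)
  scores[dropped, ] <- NA_real_
  attr(scores, "dropped") <- sort(dropped)
  scores
}

#' Weighted binary cross-entropy
#'
#' `sum(w * bce(s, y)) / sum(w)`: the normalised form is invariant to
#' replicating any record k times at weight w/k, which is what makes
#' inverse-cluster-size weights equivalent to collapsing each cluster
#' to a single averaged example.
#'
#' @param scores Predicted probabilities in (0, 1).
#' @param labels 0/1 labels.
#' @param weights Positive record weights (default all 1).
#' @return Scalar loss.
#' @export
weighted_bce <- function(scores, labels, weights = rep(1, length(scores))) {
  stopifnot(length(scores) == length(labels),
            length(scores) == length(weights), all(weights > 0))
  if (any(!is.finite(scores))) stop("non-finite score passed to the loss")
  s <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  sum(weights * -(labels * log(s) + (1 - labels) * log(1 - s))) / sum(weights)
}

# Max aggregation over each record's pairs with optional allele
# dropout; returns selected pair index and logit per record.
aggregate_max <- function(logits, pairs, n_records, allele_idx,
                          dropout_fraction = 0) {
  sel <- integer(n_records)
  for (b in seq_len(n_records)) {
    idx <- which(pairs$pb == b)
    if (dropout_fraction > 0) {
      al <- allele_idx[[b]]
      ndrop <- floor(length(al) * dropout_fraction)
      if (length(al) >= 2L && ndrop >= 1L) {
        dropped <- al[sample.int(length(al), ndrop)]
        idx <- idx[!(pairs$pa[idx] %in% dropped)]
      }
    }
    sel[b] <- idx[which.max(logits[idx])]
  }
  list(sel = sel, logit = logits[sel])
}

# Evaluation-mode scoring of records in batches; returns per-record
# score, argmax offset and allele name.
eval_records <- function(params_list, cfg, peptides, allele_names_list,
                         registry, batch_size = 100L) {
  n <- length(peptides)
  all_names <- sort(unique(unlist(allele_names_list)))
  pseudo <- registry_lookup(registry, all_names)
  atok <- allele_tokens(pseudo)
  score <- numeric(n); core_offset <- integer(n); best_allele <- character(n)
  for (start in seq(1L, n, by = batch_size)) {
    ib <- start:min(start + batch_size - 1L, n)
    tb <- tokens_batch(peptides[ib], cfg$max_peptide_len)
    aidx <- lapply(allele_names_list[ib], function(an) {
      sort(match(sort(unique(an)), names(pseudo)))
    })
    pair_sc <- NULL
    fw <- NULL
    for (params in params_list) {
      fw <- model_forward(params, cfg, tb, atok, aidx, training = FALSE)
      sc <- sigmoid(fw$logits)
      pair_sc <- if (is.null(pair_sc)) sc else pair_sc + sc
    }
    pair_sc <- pair_sc / length(params_list)
    for (j in seq_along(ib)) {
      idx <- which(fw$pairs$pb == j)
      k <- idx[which.max(pair_sc[idx])]
      score[ib[j]] <- pair_sc[k]
      core_offset[ib[j]] <- fw$pairs$po[k]
      best_allele[ib[j]] <- names(pseudo)[fw$pairs$pa[k]]
    }
  }
  data.frame(peptide = peptides, score = score, core_offset = core_offset,
             core_9mer = substr(peptides, core_offset + 1L, core_offset + 9L),
             best_allele = best_allele, stringsAsFactors = FALSE)
}

#' Train a presentation model
#'
#' Fits the cross-attention multiple-instance model by weighted binary
#' cross-entropy with AdamW. Each epoch regenerates one length-matched
#' proteome decoy per presented peptide (classes stay exactly
#' balanced), shuffles, and optimises in minibatches; gradients flow
#' through each record's maximum-scoring window-allele pair.
#' Validation loss (against a fixed, seeded decoy set) drives the
#' plateau learning-rate decay and early stopping, and the best
#' validation checkpoint is returned.
#'
#' @param train,validation Data frames of presented peptides with
#'   columns `peptide`, `sample_id` and optionally `weight` (if absent,
#'   weights are computed by clustering the training peptides at 0.8
#'   identity).
#' @param sample_alleles Named list mapping each `sample_id` to its
#'   allele names (1 to `max_alleles` per sample).
#' @param registry Allele registry data frame ([allele_registry()]).
#' @param proteome Named character vector of background protein
#'   sequences for decoys.
#' @param config An [hla2_config()].
#' @param control An [hla2_control()].
#' @param scenario Decoy scenario: 1 unscreened, 2 screened to share no
#'   9mer with any presented peptide.
#' @param seed Integer; deterministically derives the named RNG streams
#'   (init, decoys, dropout, shuffle) recorded in the result.
#' @return Object of class `hla2_model`: parameters at the best
#'   validation epoch, configuration, control, scenario, seeds and a
#'   per-epoch training log.
#' @export
hla2_train <- function(train, validation, sample_alleles, registry, proteome,
                       config = hla2_config(), control = hla2_control(),
                       scenario = 1L, seed = 1L) {
  stopifnot(inherits(config, "hla2_config"), inherits(control, "hla2_control"),
            all(c("peptide", "sample_id") %in% names(train)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  if (is.null(train$weight)) {
    message("no 'weight' column: clustering training peptides at 0.8 identity")
    cl <- cluster_peptides(train$peptide)
    train <- assign_weights(train, cl)
  }
  if (!control$use_weights) {
    train$weight <- rep(1, nrow(train))
  }
  if (is.null(validation$weight)) validation$weight <- rep(1, nrow(validation))

  miss <- setdiff(unique(c(train$sample_id, validation$sample_id)),
                  names(sample_alleles))
  if (length(miss)) stop("samples without allele annotation: ",
                         paste(utils::head(miss, 3L), collapse = ", "))
  nall <- lengths(sample_alleles)
  if (any(nall > config$max_alleles)) {
    stop("sample(s) carry more than ", config$max_alleles, " alleles")
  }

  seeds <- derive_seeds(seed)
  set.seed(seeds$init)
  params <- init_params(config)
  opt <- adamw_init(params)

  all_names <- sort(unique(unlist(sample_alleles)))
  pseudo <- registry_lookup(registry, all_names)
  atok <- allele_tokens(pseudo)
  aidx_of <- function(sid) {
    lapply(sample_alleles[sid], function(an) sort(match(sort(unique(an)), names(pseudo))))
  }

  # fixed validation decoys (epoch 0 of the decoy stream)
  val_dec <- sample_decoys(validation, proteome, scenario, seeds$decoys, 0L)
  val_all <- rbind(data.frame(peptide = validation$peptide,
                              sample_id = validation$sample_id,
                              label = 1L, weight = validation$weight,
                              stringsAsFactors = FALSE),
                   data.frame(peptide = val_dec$peptide,
                              sample_id = val_dec$sample_id,
                              label = 0L, weight = val_dec$weight,
                              stringsAsFactors = FALSE))

  val_loss_of <- function(params) {
    sc <- eval_records(list(params), config, val_all$peptide,
                       sample_alleles[val_all$sample_id], registry,
                       control$batch_size)
    weighted_bce(sc$score, val_all$label, val_all$weight)
  }

  lr <- control$lr
  best_val <- Inf; best_params <- params
  epochs_since <- 0L; plateau_run <- 0L; decays <- 0L
  log <- NULL; step <- 0L

  for (epoch in seq_len(control$max_epochs)) {
    dec <- sample_decoys(train, proteome, scenario, seeds$decoys, epoch)
    recs <- rbind(data.frame(peptide = train$peptide, sample_id = train$sample_id,
                             label = 1L, weight = train$weight,
                             stringsAsFactors = FALSE),
                  data.frame(peptide = dec$peptide, sample_id = dec$sample_id,
                             label = 0L, weight = dec$weight,
                             stringsAsFactors = FALSE))
    set.seed((seeds$shuffle + epoch) %% 2147483647L)
    recs <- recs[sample.int(nrow(recs)), , drop = FALSE]

    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, nrow(recs), by = control$batch_size)) {
      ib <- start:min(start + control$batch_size - 1L, nrow(recs))
      step <- step + 1L
      set.seed((seeds$dropout + step) %% 2147483647L)
      bt <- recs[ib, , drop = FALSE]
      tb <- tokens_batch(bt$peptide, config$max_peptide_len)
      aidx <- aidx_of(bt$sample_id)
      fw <- model_forward(params, config, tb, atok, aidx,
                          training = TRUE, keep_cache = TRUE)
      ag <- aggregate_max(fw$logits, fw$pairs, length(ib), aidx,
                          control$allele_dropout)
      s <- sigmoid(ag$logit)
      loss <- weighted_bce(s, bt$label, bt$weight)
      if (!is.finite(loss)) {
        warning("non-finite training loss at epoch ", epoch,
                "; returning last good checkpoint")
        break
      }
      ep_loss <- ep_loss + loss; nb <- nb + 1L
      dlogits <- numeric(fw$pairs$n)
      dlogits[ag$sel] <- bt$weight * (s - bt$label) / sum(bt$weight)
      grads <- model_backward(params, config, fw, tb, dlogits, ag$sel)
      grads <- clip_gradients(grads, control$grad_clip)
      upd <- adamw_step(params, grads, opt, lr,
                        weight_decay = control$weight_decay)
      params <- upd$params; opt <- upd$state
    }
    vl <- val_loss_of(params)

    improved <- vl < best_val - control$plateau_tol
    if (vl < best_val) { best_val <- min(best_val, vl); best_params <- params }
    if (improved) {
      epochs_since <- 0L; plateau_run <- 0L
    } else {
      epochs_since <- epochs_since + 1L
      plateau_run <- plateau_run + 1L
      if (plateau_run >= control$plateau_epochs) {
        lr <- lr * control$lr_decay
        decays <- decays + 1L
        plateau_run <- 0L
      }
    }
    log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss / max(nb, 1L),
                                 val_loss = vl, lr = lr, n_decoys = nrow(dec),
                                 scenario = scenario, decays = decays))
    if (control$verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e  decays %d",
                      epoch, ep_loss / max(nb, 1L), vl, lr, decays))
    }
    if (epochs_since >= control$patience_stop && decays >= control$min_decays) break
  }

  structure(list(params = best_params, config = config, control = control,
                 scenario = as.integer(scenario), seeds = seeds, log = log,
                 best_val_loss = best_val, n_train = nrow(train)),
            class = "hla2_model")
}

#' Train the two-scenario decoy ensemble
#'
#' Trains one model per decoy scenario (unscreened; 9mer-screened) and
#' returns them as an ensemble whose predictions are the maximum over
#' the per-pair score matrices averaged across the two models.
#'
#' @inheritParams hla2_train
#' @return Object of class `hla2_ensemble`.
#' @export
hla2_train_ensemble <- function(train, validation, sample_alleles, registry,
                                proteome, config = hla2_config(),
                                control = hla2_control(), seed = 1L) {
  m1 <- hla2_train(train, validation, sample_alleles, registry, proteome,
                   config, control, scenario = 1L, seed = seed)
  m2 <- hla2_train(train, validation, sample_alleles, registry, proteome,
                   config, control, scenario = 2L, seed = seed + 1L)
  hla2_ensemble(m1, m2)
}

#' Combine trained models into a prediction ensemble
#'
#' @param ... Two or more `hla2_model` objects sharing a configuration.
#' @return Object of class `hla2_ensemble`.
#' @export
hla2_ensemble <- function(...) {
  models <- list(...)
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "hla2_model")))
  d <- vapply(models, function(m) m$config$d_model, integer(1))
  if (length(unique(d)) != 1L) stop("ensemble members must share a configuration")
  structure(list(models = models), class = "hla2_ensemble")
}
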