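# Prediction interface and standard S3 methods for fitted models and
# ensembles.

resolve_allele_sets <- function(newdata, sample_alleles, panel) {
  if (!is.null(sample_alleles)) {
    miss <- setdiff(unique(newdata$sample_id), names(sample_alleles))
    if (length(miss)) stop("samples without allele annotation: ",
                           paste(utils::head(miss, 3L), collapse = ", "))
    return(sample_alleles[newdata$sample_id])
  }
  if (is.null(panel)) stop("supply either 'sample_alleles' or 'panel'")
  rep(list(panel), nrow(newdata))
}

predict_core <- function(models, newdata, sample_alleles, panel, registry,
                         batch_size, aggregate) {
  cfg <- models[[1L]]$config
  if (is.null(newdata$sample_id)) newdata$sample_id <- "sample1"
  sets <- resolve_allele_sets(newdata, sample_alleles, panel)
  if (any(lengths(sets) > cfg$max_alleles)) {
    stop("sample(s) carry more than ", cfg$max_alleles, " alleles")
  }
  params_list <- lapply(models, `[[`, "params")
  if (aggregate == "max_of_mean" || length(models) == 1L) {
    sc <- eval_records(params_list, cfg, newdata$peptide, sets, registry,
                       batch_size)
  } else {
    # mean-of-max: aggregate each model first, then average the scores
    per <- lapply(params_list, function(p) {
      eval_records(list(p), cfg, newdata$peptide, sets, registry, batch_size)
    })
    sc <- per[[1L]]
    sc$score <- Reduce(`+`, lapply(per, `[[`, "score")) / length(per)
  }
  data.frame(peptide = newdata$peptide, sample_id = newdata$sample_id,
             score = sc$score, core_offset = sc$core_offset,
             core_9mer = sc$core_9mer, best_allele = sc$best_allele,
             presented = sc$score >= 0.5,
             stringsAsFactors = FALSE)
}

#' Predict peptide presentation
#'
#' Scores each peptide of `newdata` against its sample's alleles (or a
#' shared panel) and reports the final presentation score (maximum over
#' all window-allele pairs), the predicted binding core and its 0-based
#' offset, and the allele of the argmax pair. A peptide is called
#' presented at score >= 0.5, the natural cutoff of a model trained on
#' exactly balanced classes. For an ensemble the per-pair score
#' matrices are averaged across members before the maximum (default),
#' so the reported core is the argmax of the averaged matrix;
#' `aggregate = "mean_of_max"` averages the per-model final scores
#' instead.
#'
#' @param object An `hla2_model` or `hla2_ensemble`.
#' @param newdata Data frame with columns `peptide` and optionally
#'   `sample_id`.
#' @param registry Allele registry ([allele_registry()]).
#' @param sample_alleles Named list `sample_id -> allele names`, or
#'   `NULL` to use `panel` for every record.
#' @param panel Character vector of allele names shared by all records
#'   (default: ignored when `sample_alleles` is given).
#' @param batch_size Records scored per forward pass (default 100).
#' @param aggregate `"max_of_mean"` (default) or `"mean_of_max"`.
#' @param ... Unused.
#' @return Data frame: `peptide`, `sample_id`, `score`, `core_offset`,
#'   `core_9mer`, `best_allele`, `presented`.
#' @export
predict.hla2_model <- function(object, newdata, registry,
                               sample_alleles = NULL, panel = NULL,
                               batch_size = 100L,
                               aggregate = "max_of_mean", ...) {
  predict_core(list(object), newdata, sample_alleles, panel, registry,
               batch_size, aggregate)
}

#' @rdname predict.hla2_model
#' @export
predict.hla2_ensemble <- function(object, newdata, registry,
                                  sample_alleles = NULL, panel = NULL,
                                  batch_size = 100L,
                                  aggregate = c("max_of_mean", "mean_of_max"),
                                  ...) {
  aggregate <- match.arg(aggregate)
  predict_core(object$models, newdata, sample_alleles, panel, registry,
               batch_size, aggregate)
}

#' @export
pair_scores.hla2_ensemble <- function(object, peptide, alleles,
                                      attention = FALSE, pad_len = NULL) {
  cfg <- object$models[[1L]]$config
  check_allele_set(alleles, cfg)
  ord <- order(names(alleles))
  alleles <- alleles[ord]
  tb <- tokens_batch(peptide, cfg$max_peptide_len)
  atok <- allele_tokens(alleles)
  sc <- NULL; fw <- NULL
  for (m in object$models) {
    fw <- model_forward(m$params, cfg, tb, atok, list(seq_along(alleles)),
                        training = FALSE)
    s <- sigmoid(fw$logits)
    sc <- if (is.null(sc)) s else sc + s
  }
  finish_pair_scores(sc / length(object$models), fw, peptide,
                     names(alleles), cfg, FALSE)
}

#' @export
print.hla2_model <- function(x, ...) {
  cat("cross-attention presentation model\n")
  print(x$config)
  if (!is.na(x$scenario)) cat("  decoy scenario:", x$scenario, "\n")
  if (!is.null(x$log)) {
    cat(sprintf("  trained %d epoch(s); best validation loss %.4f\n",
                max(x$log$epoch), x$best_val_loss))
  } else {
    cat("  untrained (random initialisation)\n")
  }
  invisible(x)
}

#' @export
summary.hla2_model <- function(object, ...) {
  np <- sum(vapply(object$params, length, integer(1)))
  cat("cross-attention presentation model —", format(np, big.mark = ","),
      "parameters\n")
  print(object$config)
  if (!is.null(object$log)) {
    cat("training log (last epochs):\n")
    print(utils::tail(object$log, 5L), row.names = FALSE)
  }
  invisible(object)
}

#' @export
print.hla2_ensemble <- function(x, ...) {
  cat("presentation ensemble of", length(x$models), "model(s); scenarios:",
      paste(vapply(x$models, function(m) as.character(m$scenario),
                   character(1)), collapse = ", "), "\n")
  invisible(x)
}

#' Plot training curves
#'
#' Training and validation loss per epoch, with learning-rate decays
#' marked.
#'
#' @param x A trained `hla2_model`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.hla2_model <- function(x, ...) {
  if (is.null(x$log)) stop("model has no training log")
  graphics::matplot(x$log$epoch, cbind(x$log$train_loss, x$log$val_loss),
                    type = "b", pch = c(1, 2), lty = 1,
                    xlab = "epoch", ylab = "weighted BCE loss",
                    col = c("grey40", "firebrick"), ...)
  dec <- which(diff(c(0, x$log$decays)) > 0)
  if (length(dec)) graphics::abline(v = x$log$epoch[dec], lty = 3, col = "grey70")
  graphics::legend("topright", c("train", "validation"),
                   col = c("grey40", "firebrick"), pch = c(1, 2), bty = "n")
  invisible(x)
}
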