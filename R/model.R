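# The three-encoder presentation model.
#
# A peptide is embedded, self-encoded, and cut into all 9mer windows;
# each allele pseudo-sequence is embedded and self-encoded; every
# window queries every allele through a cross-attention interaction
# stack; each window-allele pair yields a sigmoid presentation
# likelihood from the flattened (9 x d_model) interaction features; the
# sample-level score is the maximum over all pairs (multiple-instance
# aggregation).

#' Model configuration
#'
#' @param n_blocks Transformer blocks in the peptide and allele
#'   encoders (default 8).
#' @param n_heads Attention heads per block (default 8); must divide
#'   `d_model`.
#' @param d_model Latent width of every layer, including embeddings
#'   (default 128).
#' @param n_int_blocks Cross-attention blocks in the interaction
#'   encoder (default: `n_blocks`).
#' @param dropout Dropout rate used in embedding, attention-residual
#'   and feed-forward-residual layers and before the output head
#'   (default 0.1; training only).
#' @param max_peptide_len Padded peptide length (default 30).
#' @param max_alleles Maximum alleles per sample (default 14).
#' @param positional Add learned positional embeddings in both encoders
#'   (default `TRUE`; switch off for ablations).
#' @param share_embedding Share one residue embedding table between the
#'   peptide and allele encoders (default `FALSE`).
#' @return Object of class `hla2_config`. `head_hidden` is the
#'   flattened interaction feature width, `9 * d_model` (1152 at the
#'   defaults).
#' @export
hla2_config <- function(n_blocks = 8L, n_heads = 8L, d_model = 128L,
                        n_int_blocks = n_blocks, dropout = 0.1,
                        max_peptide_len = 30L, max_alleles = 14L,
                        positional = TRUE, share_embedding = FALSE) {
  stopifnot(n_blocks >= 1L, n_int_blocks >= 1L, n_heads >= 1L,
            d_model %% n_heads == 0L, dropout >= 0, dropout < 1,
            max_peptide_len >= 9L, max_alleles >= 1L)
  structure(list(n_blocks = as.integer(n_blocks),
                 n_heads = as.integer(n_heads),
                 d_model = as.integer(d_model),
                 n_int_blocks = as.integer(n_int_blocks),
                 dropout = dropout,
                 max_peptide_len = as.integer(max_peptide_len),
                 max_alleles = as.integer(max_alleles),
                 positional = isTRUE(positional),
                 share_embedding = isTRUE(share_embedding),
                 head_hidden = 9L * as.integer(d_model)),
            class = "hla2_config")
}

#' @export
print.hla2_config <- function(x, ...) {
  cat("presentation model configuration\n")
  cat(sprintf("  encoders: %d blocks x %d heads, d_model %d\n",
              x$n_blocks, x$n_heads, x$d_model))
  cat(sprintf("  interaction: %d cross-attention blocks; head input %d\n",
              x$n_int_blocks, x$head_hidden))
  cat(sprintf("  peptide pad length %d, max alleles %d, dropout %.2f\n",
              x$max_peptide_len, x$max_alleles, x$dropout))
  invisible(x)
}

# Flat parameter list; names are "<stack><block>.<tensor>".
init_params <- function(cfg) {
  d <- cfg$d_model
  p <- list(emb_pep = matrix(stats::rnorm(VOCAB_SIZE * d, 0, 0.02), VOCAB_SIZE, d),
            pos_pep = matrix(stats::rnorm(cfg$max_peptide_len * d, 0, 0.02),
                             cfg$max_peptide_len, d),
            pos_all = matrix(stats::rnorm(34L * d, 0, 0.02), 34L, d))
  if (!cfg$share_embedding) {
    p$emb_all <- matrix(stats::rnorm(VOCAB_SIZE * d, 0, 0.02), VOCAB_SIZE, d)
  }
  add_blocks <- function(p, stack, n) {
    for (k in seq_len(n)) {
      bl <- init_block(d)
      names(bl) <- paste0(stack, k, ".", block_param_names)
      p <- c(p, bl)
    }
    p
  }
  p <- add_blocks(p, "pep", cfg$n_blocks)
  p <- add_blocks(p, "all", cfg$n_blocks)
  p <- add_blocks(p, "int", cfg$n_int_blocks)
  p$head_w <- matrix(stats::rnorm(cfg$head_hidden, 0, 1 / sqrt(cfg$head_hidden)),
                     cfg$head_hidden, 1L)
  p$head_b <- 0
  p
}

blocks_of <- function(params, stack, n) {
  lapply(seq_len(n), function(k) {
    bl <- params[paste0(stack, k, ".", block_param_names)]
    names(bl) <- block_param_names
    bl
  })
}

# reassemble per-block grad lists into flat names
flatten_block_grads <- function(grads, stack) {
  out <- list()
  for (k in seq_along(grads)) {
    g <- grads[[k]]
    names(g) <- paste0(stack, k, ".", block_param_names)
    out <- c(out, g)
  }
  out
}

#' Initialise an untrained model
#'
#' Draws fresh parameters (Glorot-uniform weights, small-normal
#' embeddings) from the given seed. The result behaves like a fitted
#' model object for every prediction and analysis function, which is
#' how random-baseline sanity checks (untrained AUC near 0.5) are run.
#'
#' @param config An [hla2_config()].
#' @param seed Integer seed for the initialisation RNG stream.
#' @return Object of class `hla2_model`.
#' @export
hla2_init <- function(config = hla2_config(), seed = 1L) {
  stopifnot(inherits(config, "hla2_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed %% 2147483647L)
  params <- init_params(config)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(params = params, config = config, scenario = NA_integer_,
                 seeds = list(init = seed), log = NULL, control = NULL),
            class = "hla2_model")
}

# --- batching helpers -------------------------------------------------

# Tokenise peptides into a B x P matrix plus mask. Errors on length
# violations (the model cannot window < 9 or pad > max_len).
tokens_batch <- function(peptides, max_len) {
  L <- nchar(peptides)
  if (any(L < 9L)) stop("peptide(s) shorter than 9 residues cannot be windowed")
  if (any(L > max_len)) {
    stop("peptide(s) longer than the padded length ", max_len, " supplied")
  }
  B <- length(peptides)
  tok <- matrix(PAD_ID, B, max_len)
  for (b in seq_len(B)) {
    t_b <- tokenize_peptide(peptides[b], warn = FALSE)
    tok[b, seq_along(t_b)] <- t_b
  }
  mask <- outer(L, seq_len(max_len), ">=")
  list(tokens = tok, mask = mask, lengths = L)
}

allele_tokens <- function(pseudo) {
  stopifnot(all(nchar(pseudo) == 34L))
  t(vapply(pseudo, function(s) tokenize_peptide(s, warn = FALSE),
           integer(34L)))
}

# Enumerate all window-allele pairs of a batch. allele_idx: list per
# record of indices into the batch allele set (each sorted ascending,
# i.e. canonical allele-name order). Pairs are ordered by record, then
# allele index, then offset, so a first-maximum scan realises the
# documented argmax tie-break.
build_pairs <- function(lengths, allele_idx) {
  pb <- integer(0); pa <- integer(0); po <- integer(0)
  for (b in seq_along(lengths)) {
    M <- lengths[b] - 8L
    for (a in allele_idx[[b]]) {
      pb <- c(pb, rep.int(b, M)); pa <- c(pa, rep.int(a, M))
      po <- c(po, 0:(M - 1L))
    }
  }
  list(pb = pb, pa = pa, po = po, n = length(pb))
}

# Full forward pass over a tokenised batch.  Returns pair logits plus
# (optionally) every cache needed for the backward pass.
model_forward <- function(params, cfg, tb, allele_tok, allele_idx,
                          training = FALSE, keep_cache = FALSE,
                          record_attention = FALSE) {
  d <- cfg$d_model
  P <- ncol(tb$tokens)
  B <- nrow(tb$tokens)
  A <- nrow(allele_tok)
  emb_all <- if (cfg$share_embedding) params$emb_pep else params$emb_all
  p_drop <- if (training) cfg$dropout else 0

  tok_flat <- as.vector(t(tb$tokens))
  Xp <- params$emb_pep[tok_flat, , drop = FALSE]
  if (cfg$positional) {
    Xp <- Xp + params$pos_pep[rep(seq_len(P), B), , drop = FALSE]
  }
  D_emb_p <- if (training) drop_mask(nrow(Xp), d, p_drop) else NULL
  Xp <- apply_drop(Xp, D_emb_p)
  pep <- self_stack_forward(Xp, tb$mask, blocks_of(params, "pep", cfg$n_blocks),
                            cfg$n_heads, training, p_drop, keep_cache)

  atok_flat <- as.vector(t(allele_tok))
  Xa <- emb_all[atok_flat, , drop = FALSE]
  if (cfg$positional) {
    Xa <- Xa + params$pos_all[rep(1:34, A), , drop = FALSE]
  }
  D_emb_a <- if (training) drop_mask(nrow(Xa), d, p_drop) else NULL
  Xa <- apply_drop(Xa, D_emb_a)
  amask <- matrix(TRUE, A, 34L)
  alle <- self_stack_forward(Xa, amask, blocks_of(params, "all", cfg$n_blocks),
                             cfg$n_heads, training, p_drop, keep_cache)

  pairs <- build_pairs(tb$lengths, allele_idx)
  qidx <- integer(pairs$n * 9L)
  for (p in seq_len(pairs$n)) {
    qidx[((p - 1L) * 9L + 1L):(p * 9L)] <-
      (pairs$pb[p] - 1L) * P + pairs$po[p] + 1:9
  }
  Xq <- pep$out[qidx, , drop = FALSE]
  int <- cross_stack_forward(Xq, pairs$pa, alle$out,
                             blocks_of(params, "int", cfg$n_int_blocks),
                             cfg$n_heads, training, p_drop, keep_cache,
                             record_attention)
  Fmat <- matrix(as.vector(t(int$out)), pairs$n, 9L * d, byrow = TRUE)
  D_head <- if (training) drop_mask(pairs$n, ncol(Fmat), p_drop) else NULL
  Fdrop <- apply_drop(Fmat, D_head)
  logits <- as.vector(Fdrop %*% params$head_w) + params$head_b

  list(logits = logits, pairs = pairs, qidx = qidx,
       pep = pep, alle = alle, int = int,
       Fmat = Fmat, Fdrop = Fdrop, D_head = D_head,
       D_emb_p = D_emb_p, D_emb_a = D_emb_a,
       tok_flat = tok_flat, atok_flat = atok_flat,
       P = P, B = B, A = A)
}

# Backward from per-pair logit gradients (nonzero only at each
# sample's argmax pair under max aggregation).
model_backward <- function(params, cfg, fw, tb, dlogits, sel_pairs) {
  d <- cfg$d_model
  grads <- list()
  dsel <- dlogits[sel_pairs]
  Fsel <- fw$Fdrop[sel_pairs, , drop = FALSE]
  grads$head_w <- crossprod(Fsel, dsel)
  grads$head_b <- sum(dsel)
  dFdrop <- dsel %*% t(params$head_w)          # (nsel) x 9d
  if (!is.null(fw$D_head)) {
    dFdrop <- dFdrop * fw$D_head[sel_pairs, , drop = FALSE]
  }
  nsel <- length(sel_pairs)
  dXq_sel <- matrix(as.vector(t(dFdrop)), nsel * 9L, d, byrow = TRUE)

  cb <- cross_stack_backward(dXq_sel, sel_pairs, fw$pairs$pa, fw$alle$out,
                             blocks_of(params, "int", cfg$n_int_blocks),
                             fw$int$caches, cfg$n_heads)
  grads <- c(grads, flatten_block_grads(cb$grads, "int"))

  # scatter query grads into the peptide-encoder output
  dPep <- matrix(0, nrow(fw$pep$out), d)
  sel_rows <- as.vector(outer(1:9, (sel_pairs - 1L) * 9L, "+"))
  dPep[fw$qidx[sel_rows], ] <- cb$dX
  pb <- self_stack_backward(dPep, tb$mask,
                            blocks_of(params, "pep", cfg$n_blocks),
                            fw$pep$caches, cfg$n_heads)
  grads <- c(grads, flatten_block_grads(pb$grads, "pep"))

  ab <- self_stack_backward(cb$dM, matrix(TRUE, fw$A, 34L),
                            blocks_of(params, "all", cfg$n_blocks),
                            fw$alle$caches, cfg$n_heads)
  grads <- c(grads, flatten_block_grads(ab$grads, "all"))

  dXp0 <- if (is.null(fw$D_emb_p)) pb$dX else pb$dX * fw$D_emb_p
  ep <- rowsum(dXp0, fw$tok_flat)
  demb_pep <- matrix(0, VOCAB_SIZE, d)
  demb_pep[as.integer(rownames(ep)), ] <- ep
  grads$emb_pep <- demb_pep
  if (cfg$positional) {
    grads$pos_pep <- rowsum(dXp0, rep(seq_len(fw$P), fw$B))
  }
  dXa0 <- if (is.null(fw$D_emb_a)) ab$dX else ab$dX * fw$D_emb_a
  ea <- rowsum(dXa0, fw$atok_flat)
  demb_all <- matrix(0, VOCAB_SIZE, d)
  demb_all[as.integer(rownames(ea)), ] <- ea
  if (cfg$share_embedding) {
    grads$emb_pep <- grads$emb_pep + demb_all
  } else {
    grads$emb_all <- demb_all
  }
  if (cfg$positional) {
    grads$pos_all <- rowsum(dXa0, rep(1:34, fw$A))
  }
  grads
}

# --- spec-level encoder operations -----------------------------------

params_of <- function(object) {
  if (inherits(object, "hla2_model")) return(object)
  stop("expected an 'hla2_model'")
}

#' Encode a peptide
#'
#' Runs the peptide through the embedding and self-attention encoder
#' stack in evaluation mode and returns the per-residue latent
#' representations (real positions only; padding positions are masked
#' out of every attention step and dropped from the result).
#'
#' @param object An `hla2_model`.
#' @param peptide Character scalar, 9 to `max_peptide_len` residues.
#' @return Numeric matrix, `nchar(peptide)` x `d_model`.
#' @export
encode_peptide <- function(object, peptide) {
  m <- params_of(object); cfg <- m$config
  tb <- tokens_batch(peptide, cfg$max_peptide_len)
  Xp <- m$params$emb_pep[as.vector(t(tb$tokens)), , drop = FALSE]
  if (cfg$positional) Xp <- Xp + m$params$pos_pep
  out <- self_stack_forward(Xp, tb$mask, blocks_of(m$params, "pep", cfg$n_blocks),
                            cfg$n_heads, FALSE, 0)$out
  out[seq_len(tb$lengths[1L]), , drop = FALSE]
}

#' Encode an allele pseudo-sequence
#'
#' @param object An `hla2_model`.
#' @param pseudo 34-residue pseudo-sequence (or an `allele_spec`).
#' @return Numeric matrix, 34 x `d_model`.
#' @export
encode_allele <- function(object, pseudo) {
  m <- params_of(object); cfg <- m$config
  if (inherits(pseudo, "allele_spec")) pseudo <- pseudo$pseudo
  if (!is.character(pseudo) || length(pseudo) != 1L || nchar(pseudo) != 34L) {
    stop("allele pseudo-sequence must be a single 34-residue string")
  }
  emb <- if (cfg$share_embedding) m$params$emb_pep else m$params$emb_all
  Xa <- emb[tokenize_peptide(pseudo, warn = FALSE), , drop = FALSE]
  if (cfg$positional) Xa <- Xa + m$params$pos_all
  self_stack_forward(Xa, matrix(TRUE, 1L, 34L),
                     blocks_of(m$params, "all", cfg$n_blocks),
                     cfg$n_heads, FALSE, 0)$out
}

#' Score every window-allele pair of one peptide
#'
#' Evaluates the full model on one peptide against a set of alleles and
#' returns the N x M matrix of per-pair presentation likelihoods, the
#' final (maximum) score, and the argmax pair. Alleles are sorted into
#' canonical name order first, and argmax ties break to the smallest
#' allele index then the smallest window offset, so reports are
#' reproducible under allele permutation.
#'
#' @param object An `hla2_model` or `hla2_ensemble`.
#' @param peptide Character scalar.
#' @param alleles Named character vector of 34-residue pseudo-sequences
#'   (names are allele names), at most `max_alleles`.
#' @param attention Record interaction-encoder attention for the argmax
#'   pair (single models only).
#' @param pad_len Padded length used for this call (default the
#'   configuration's `max_peptide_len`). Scores are invariant to the
#'   pad length because padding positions are masked out of every
#'   attention step.
#' @return Object of class `pair_score_matrix`: list with `scores`
#'   (N x M, rownames alleles, columns 0-based offsets), `final_score`,
#'   `argmax` (list with `allele`, `offset`), `core`, and optionally
#'   `attention` (n_int_blocks x n_heads x 9 x 34 array).
#' @export
pair_scores <- function(object, peptide, alleles, attention = FALSE,
                        pad_len = NULL) {
  UseMethod("pair_scores")
}

#' @export
pair_scores.hla2_model <- function(object, peptide, alleles,
                                   attention = FALSE, pad_len = NULL) {
  cfg <- object$config
  check_allele_set(alleles, cfg)
  if (is.null(pad_len)) pad_len <- cfg$max_peptide_len
  stopifnot(pad_len <= cfg$max_peptide_len)
  ord <- order(names(alleles))
  alleles <- alleles[ord]
  tb <- tokens_batch(peptide, pad_len)
  atok <- allele_tokens(alleles)
  fw <- model_forward(object$params, cfg, tb, atok,
                      list(seq_along(alleles)), training = FALSE,
                      record_attention = attention)
  scores <- sigmoid(fw$logits)
  finish_pair_scores(scores, fw, peptide, names(alleles), cfg, attention)
}

check_allele_set <- function(alleles, cfg) {
  if (!length(alleles)) stop("at least one allele is required")
  if (length(alleles) > cfg$max_alleles) {
    stop("sample carries ", length(alleles), " alleles; the model accepts at most ",
         cfg$max_alleles)
  }
  if (is.null(names(alleles)) || anyNA(names(alleles))) {
    stop("alleles must be a named vector of pseudo-sequences")
  }
  invisible(TRUE)
}

finish_pair_scores <- function(scores, fw, peptide, allele_names, cfg,
                               attention = FALSE) {
  M <- nchar(peptide) - 8L
  N <- length(allele_names)
  smat <- matrix(scores, nrow = N, ncol = M, byrow = TRUE,
                 dimnames = list(allele_names, 0:(M - 1L)))
  best <- which.max(scores)           # pairs ordered (allele, offset)
  a_i <- fw$pairs$pa[best]; off <- fw$pairs$po[best]
  out <- list(scores = smat,
              final_score = scores[best],
              argmax = list(allele = allele_names[a_i], offset = off),
              core = substr(peptide, off + 1L, off + 9L))
  if (attention && !is.null(fw$int$attention)) {
    nb <- length(fw$int$attention); nh <- cfg$n_heads
    arr <- array(0, c(nb, nh, 9L, 34L))
    rows <- ((best - 1L) * 9L + 1L):(best * 9L)
    for (k in seq_len(nb)) {
      for (h in seq_len(nh)) {
        arr[k, h, , ] <- fw$int$attention[[k]][[h]][rows, , drop = FALSE]
      }
    }
    out$attention <- arr
  }
  class(out) <- "pair_score_matrix"
  out
}

#' @export
print.pair_score_matrix <- function(x, ...) {
  cat(sprintf("pair score matrix: %d allele(s) x %d window(s)\n",
              nrow(x$scores), ncol(x$scores)))
  cat(sprintf("  final score %.4f; core %s at offset %d via %s\n",
              x$final_score, x$core, x$argmax$offset, x$argmax$allele))
  invisible(x)
}

# --- checkpoints ------------------------------------------------------

CHECKPOINT_FORMAT <- 1L

#' Write / read a model checkpoint
#'
#' A checkpoint is a single file holding the parameters, configuration,
#' decoy scenario tag, RNG stream seeds and training log, together with
#' a format-version field.
#'
#' @param model An `hla2_model`.
#' @param path File path.
#' @return `read_checkpoint` returns the `hla2_model`.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "hla2_model"))
  obj <- unclass(model)
  obj$format_version <- CHECKPOINT_FORMAT
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$format_version) || obj$format_version > CHECKPOINT_FORMAT) {
    stop("unsupported checkpoint format")
  }
  obj$format_version <- NULL
  structure(obj, class = "hla2_model")
}
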