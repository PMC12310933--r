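# Neural-network primitives: initialisation, layer norm, softmax,
# dropout, AdamW, and the two transformer stacks (masked self-attention
# over sequences; cross-attention of 9mer queries over allele memories)
# with hand-derived backward passes.
#
# Layout convention: a batch of B sequences of padded length P lives in
# a single (B*P) x d matrix in b-major order, i.e. rows
# ((b-1)*P + 1):(b*P) belong to sequence b.  This keeps every linear
# map a single BLAS call; only the attention score products loop over
# examples.

LN_EPS <- 1e-5

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax; -Inf entries (masked keys) get weight exactly 0.
row_softmax <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

# Inverted-dropout mask drawn from the current RNG stream.
drop_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= p) / (1 - p), nr, nc)
}

apply_drop <- function(x, m) if (is.null(m)) x else x * m

ln_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  invstd <- 1 / sqrt(rowMeans(xc * xc) + LN_EPS)
  xhat <- xc * invstd
  y <- xhat * rep(g, each = nrow(x)) + rep(b, each = nrow(x))
  list(y = y, xhat = xhat, invstd = invstd)
}

ln_backward <- function(dy, xhat, invstd, g) {
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- dy * rep(g, each = nrow(dy))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * invstd
  list(dx = dx, dg = dg, db = db)
}

block_param_names <- c("Wq", "Wk", "Wv", "Wo", "bo", "ln1g", "ln1b",
                       "W1", "b1", "W2", "b2", "ln2g", "ln2b")

init_block <- function(d) {
  list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
       Wo = glorot(d, d), bo = numeric(d),
       ln1g = rep(1, d), ln1b = numeric(d),
       W1 = glorot(d, d), b1 = numeric(d),
       W2 = glorot(d, d), b2 = numeric(d),
       ln2g = rep(1, d), ln2b = numeric(d))
}

zeros_like <- function(p) lapply(p, function(x) array(0, dim = if (is.matrix(x)) dim(x) else length(x)))

# ---------------------------------------------------------------------
# Masked self-attention encoder stack (peptide and allele encoders).
# X: (B*P) x d, mask: B x P logical (key positions that may be attended).

self_stack_forward <- function(X, mask, blocks, n_heads, training, p_drop,
                               keep_cache = FALSE) {
  B <- nrow(mask); P <- ncol(mask); d <- ncol(X)
  hd <- d %/% n_heads
  scale <- 1 / sqrt(hd)
  caches <- if (keep_cache) vector("list", length(blocks)) else NULL
  for (k in seq_along(blocks)) {
    bp <- blocks[[k]]
    Q <- X %*% bp$Wq; K <- X %*% bp$Wk; V <- X %*% bp$Wv
    H <- matrix(0, nrow(X), d)
    A_arr <- if (keep_cache) array(0, c(P, P, n_heads, B)) else NULL
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * P + 1L):(b * P)
      mb <- mask[b, ]
      Qb <- Q[rows, , drop = FALSE]
      Kb <- K[rows, , drop = FALSE]
      Vb <- V[rows, , drop = FALSE]
      for (h in seq_len(n_heads)) {
        cols <- ((h - 1L) * hd + 1L):(h * hd)
        S <- tcrossprod(Qb[, cols, drop = FALSE], Kb[, cols, drop = FALSE]) * scale
        if (!all(mb)) S[, !mb] <- -Inf
        A <- row_softmax(S)
        if (keep_cache) A_arr[, , h, b] <- A
        H[rows, cols] <- A %*% Vb[, cols, drop = FALSE]
      }
    }
    O <- H %*% bp$Wo + rep(bp$bo, each = nrow(X))
    D1 <- if (training) drop_mask(nrow(X), d, p_drop) else NULL
    R1 <- X + apply_drop(O, D1)
    l1 <- ln_forward(R1, bp$ln1g, bp$ln1b)
    F1 <- l1$y %*% bp$W1 + rep(bp$b1, each = nrow(X))
    F1 <- F1 * (F1 > 0)
    F2 <- F1 %*% bp$W2 + rep(bp$b2, each = nrow(X))
    D2 <- if (training) drop_mask(nrow(X), d, p_drop) else NULL
    R2 <- l1$y + apply_drop(F2, D2)
    l2 <- ln_forward(R2, bp$ln2g, bp$ln2b)
    if (keep_cache) {
      caches[[k]] <- list(X = X, Q = Q, K = K, V = V, A = A_arr, H = H,
                          D1 = D1, X1 = l1$y, xhat1 = l1$xhat,
                          invstd1 = l1$invstd, F1 = F1, D2 = D2,
                          xhat2 = l2$xhat, invstd2 = l2$invstd)
    }
    X <- l2$y
  }
  list(out = X, caches = caches)
}

self_stack_backward <- function(dX, mask, blocks, caches, n_heads) {
  B <- nrow(mask); P <- ncol(mask); d <- ncol(dX)
  hd <- d %/% n_heads
  scale <- 1 / sqrt(hd)
  grads <- vector("list", length(blocks))
  for (k in rev(seq_along(blocks))) {
    bp <- blocks[[k]]; cc <- caches[[k]]
    g <- zeros_like(bp)
    lb2 <- ln_backward(dX, cc$xhat2, cc$invstd2, bp$ln2g)
    g$ln2g <- lb2$dg; g$ln2b <- lb2$db
    dR2 <- lb2$dx
    dF2 <- apply_drop(dR2, cc$D2)
    g$W2 <- crossprod(cc$F1, dF2); g$b2 <- colSums(dF2)
    dF1 <- tcrossprod(dF2, bp$W2)
    dF1[cc$F1 <= 0] <- 0
    g$W1 <- crossprod(cc$X1, dF1); g$b1 <- colSums(dF1)
    dX1 <- dR2 + tcrossprod(dF1, bp$W1)
    lb1 <- ln_backward(dX1, cc$xhat1, cc$invstd1, bp$ln1g)
    g$ln1g <- lb1$dg; g$ln1b <- lb1$db
    dR1 <- lb1$dx
    dO <- apply_drop(dR1, cc$D1)
    g$Wo <- crossprod(cc$H, dO); g$bo <- colSums(dO)
    dH <- tcrossprod(dO, bp$Wo)
    dQ <- matrix(0, nrow(dX), d); dK <- dQ; dV <- dQ
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * P + 1L):(b * P)
      for (h in seq_len(n_heads)) {
        cols <- ((h - 1L) * hd + 1L):(h * hd)
        A <- cc$A[, , h, b]
        dHbh <- dH[rows, cols, drop = FALSE]
        Vbh <- cc$V[rows, cols, drop = FALSE]
        dA <- tcrossprod(dHbh, Vbh)
        dV[rows, cols] <- crossprod(A, dHbh)
        dS <- A * (dA - rowSums(A * dA))
        dQ[rows, cols] <- dS %*% cc$K[rows, cols, drop = FALSE] * scale
        dK[rows, cols] <- crossprod(dS, cc$Q[rows, cols, drop = FALSE]) * scale
      }
    }
    g$Wq <- crossprod(cc$X, dQ); g$Wk <- crossprod(cc$X, dK)
    g$Wv <- crossprod(cc$X, dV)
    dX <- dR1 + tcrossprod(dQ, bp$Wq) + tcrossprod(dK, bp$Wk) +
      tcrossprod(dV, bp$Wv)
    grads[[k]] <- g
  }
  list(dX = dX, grads = grads)
}

# ---------------------------------------------------------------------
# Cross-attention interaction stack.  Queries Xq: (n_pairs*9) x d in
# pair-major order; memory M: (A*34) x d allele encodings; pair_allele
# gives each pair's allele index into the memory.

cross_stack_forward <- function(Xq, pair_allele, M, blocks, n_heads,
                                training, p_drop, keep_cache = FALSE,
                                record_attention = FALSE) {
  d <- ncol(Xq); hd <- d %/% n_heads
  scale <- 1 / sqrt(hd)
  AL <- nrow(M) %/% 34L
  rows_by_allele <- lapply(seq_len(AL), function(a) {
    p <- which(pair_allele == a)
    if (!length(p)) return(integer(0))
    as.vector(outer(1:9, (p - 1L) * 9L, "+"))
  })
  caches <- if (keep_cache) vector("list", length(blocks)) else NULL
  attn <- if (record_attention) vector("list", length(blocks)) else NULL
  for (k in seq_along(blocks)) {
    bp <- blocks[[k]]
    Q <- Xq %*% bp$Wq; K <- M %*% bp$Wk; V <- M %*% bp$Wv
    H <- matrix(0, nrow(Xq), d)
    A_heads <- if (keep_cache || record_attention) {
      lapply(seq_len(n_heads), function(h) matrix(0, nrow(Xq), 34L))
    } else NULL
    for (a in seq_len(AL)) {
      ra <- rows_by_allele[[a]]
      if (!length(ra)) next
      ma <- ((a - 1L) * 34L + 1L):(a * 34L)
      for (h in seq_len(n_heads)) {
        cols <- ((h - 1L) * hd + 1L):(h * hd)
        S <- tcrossprod(Q[ra, cols, drop = FALSE],
                        K[ma, cols, drop = FALSE]) * scale
        A <- row_softmax(S)
        if (!is.null(A_heads)) A_heads[[h]][ra, ] <- A
        H[ra, cols] <- A %*% V[ma, cols, drop = FALSE]
      }
    }
    O <- H %*% bp$Wo + rep(bp$bo, each = nrow(Xq))
    D1 <- if (training) drop_mask(nrow(Xq), d, p_drop) else NULL
    R1 <- Xq + apply_drop(O, D1)
    l1 <- ln_forward(R1, bp$ln1g, bp$ln1b)
    F1 <- l1$y %*% bp$W1 + rep(bp$b1, each = nrow(Xq))
    F1 <- F1 * (F1 > 0)
    F2 <- F1 %*% bp$W2 + rep(bp$b2, each = nrow(Xq))
    D2 <- if (training) drop_mask(nrow(Xq), d, p_drop) else NULL
    R2 <- l1$y + apply_drop(F2, D2)
    l2 <- ln_forward(R2, bp$ln2g, bp$ln2b)
    if (keep_cache) {
      caches[[k]] <- list(X = Xq, Q = Q, K = K, V = V, A = A_heads, H = H,
                          D1 = D1, X1 = l1$y, xhat1 = l1$xhat,
                          invstd1 = l1$invstd, F1 = F1, D2 = D2,
                          xhat2 = l2$xhat, invstd2 = l2$invstd)
    }
    if (record_attention) attn[[k]] <- A_heads
    Xq <- l2$y
  }
  list(out = Xq, caches = caches, attention = attn,
       rows_by_allele = rows_by_allele)
}

# Backward restricted to a subset of pairs (the per-sample argmax pairs
# under max aggregation: all other pairs have zero gradient).
# sel_pairs: pair indices with gradient; dXq_sel: (length(sel)*9) x d.
cross_stack_backward <- function(dXq_sel, sel_pairs, pair_allele, M, blocks,
                                 caches, n_heads) {
  d <- ncol(dXq_sel); hd <- d %/% n_heads
  scale <- 1 / sqrt(hd)
  AL <- nrow(M) %/% 34L
  sel_rows <- as.vector(outer(1:9, (sel_pairs - 1L) * 9L, "+"))
  sel_allele <- pair_allele[sel_pairs]
  # row positions within the sliced (selected-row) matrices, per allele
  srows_by_allele <- lapply(seq_len(AL), function(a) {
    p <- which(sel_allele == a)
    if (!length(p)) return(integer(0))
    as.vector(outer(1:9, (p - 1L) * 9L, "+"))
  })
  grads <- vector("list", length(blocks))
  dM <- matrix(0, nrow(M), d)
  dX <- dXq_sel
  for (k in rev(seq_along(blocks))) {
    bp <- blocks[[k]]; cc <- caches[[k]]
    g <- zeros_like(bp)
    X1s <- cc$X1[sel_rows, , drop = FALSE]
    F1s <- cc$F1[sel_rows, , drop = FALSE]
    Hs <- cc$H[sel_rows, , drop = FALSE]
    Xs <- cc$X[sel_rows, , drop = FALSE]
    lb2 <- ln_backward(dX, cc$xhat2[sel_rows, , drop = FALSE],
                       cc$invstd2[sel_rows], bp$ln2g)
    g$ln2g <- lb2$dg; g$ln2b <- lb2$db
    dR2 <- lb2$dx
    dF2 <- if (is.null(cc$D2)) dR2 else dR2 * cc$D2[sel_rows, , drop = FALSE]
    g$W2 <- crossprod(F1s, dF2); g$b2 <- colSums(dF2)
    dF1 <- tcrossprod(dF2, bp$W2)
    dF1[F1s <= 0] <- 0
    g$W1 <- crossprod(X1s, dF1); g$b1 <- colSums(dF1)
    dX1 <- dR2 + tcrossprod(dF1, bp$W1)
    lb1 <- ln_backward(dX1, cc$xhat1[sel_rows, , drop = FALSE],
                       cc$invstd1[sel_rows], bp$ln1g)
    g$ln1g <- lb1$dg; g$ln1b <- lb1$db
    dR1 <- lb1$dx
    dO <- if (is.null(cc$D1)) dR1 else dR1 * cc$D1[sel_rows, , drop = FALSE]
    g$Wo <- crossprod(Hs, dO); g$bo <- colSums(dO)
    dH <- tcrossprod(dO, bp$Wo)
    dQ <- matrix(0, nrow(dX), d)
    dKf <- matrix(0, nrow(M), d); dVf <- matrix(0, nrow(M), d)
    for (a in seq_len(AL)) {
      sra <- srows_by_allele[[a]]
      if (!length(sra)) next
      ora <- sel_rows[sra]              # rows in the full cached matrices
      ma <- ((a - 1L) * 34L + 1L):(a * 34L)
      for (h in seq_len(n_heads)) {
        cols <- ((h - 1L) * hd + 1L):(h * hd)
        A <- cc$A[[h]][ora, , drop = FALSE]
        dHah <- dH[sra, cols, drop = FALSE]
        dA <- tcrossprod(dHah, cc$V[ma, cols, drop = FALSE])
        dVf[ma, cols] <- dVf[ma, cols] + crossprod(A, dHah)
        dS <- A * (dA - rowSums(A * dA))
        dQ[sra, cols] <- dS %*% cc$K[ma, cols, drop = FALSE] * scale
        dKf[ma, cols] <- dKf[ma, cols] +
          crossprod(dS, cc$Q[ora, cols, drop = FALSE]) * scale
      }
    }
    g$Wq <- crossprod(Xs, dQ)
    g$Wk <- crossprod(M, dKf)
    g$Wv <- crossprod(M, dVf)
    dM <- dM + tcrossprod(dKf, bp$Wk) + tcrossprod(dVf, bp$Wv)
    dX <- dR1 + tcrossprod(dQ, bp$Wq)
    grads[[k]] <- g
  }
  list(dX = dX, dM = dM, grads = grads)
}

# ---------------------------------------------------------------------
# AdamW

adamw_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0))
}

adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gg <- grads[[nm]]
    if (is.null(gg)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gg
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gg * gg
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

# Global-norm gradient clipping.
clip_gradients <- function(grads, max_norm) {
  sq <- sum(vapply(grads, function(g) sum(g * g), numeric(1)))
  gn <- sqrt(sq)
  if (is.finite(gn) && gn > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / gn))
  }
  attr(grads, "grad_norm") <- gn
  grads
}
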