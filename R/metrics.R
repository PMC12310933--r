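# Evaluation metrics: classification scores, per-allele true positive
# rates, binding-core accuracy, positional Shannon entropy, structural
# contact maps and attention-contact agreement.

#' Classification metrics at the 0.5 cutoff
#'
#' F1 is the harmonic mean of precision and recall,
#' `2 * precision * recall / (precision + recall)`, computed at the
#' fixed presentation cutoff. ROC-AUC uses the midrank (Wilcoxon)
#' estimator, which handles tied scores exactly; PR-AUC is the
#' trapezoidal area under the precision-recall curve.
#'
#' @param scores Numeric predicted scores.
#' @param labels 0/1 (or logical) labels.
#' @param threshold Classification cutoff (default 0.5).
#' @return List with `f1`, `precision`, `recall`, `tpr` (= recall),
#'   `roc_auc`, `pr_auc`. With a single class present the AUCs are `NA`
#'   with a warning (F1 is still computed).
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  y <- as.integer(as.logical(labels))
  pred <- scores >= threshold
  tp <- sum(pred & y == 1L); fp <- sum(pred & y == 0L)
  fn <- sum(!pred & y == 1L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("both classes are required for AUCs; returning NA")
    roc <- NA_real_; pr <- NA_real_
  } else {
    r <- rank(scores)                       # midranks for ties
    roc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    pr <- pr_auc_trapezoid(scores, y)
  }
  list(f1 = f1, precision = precision, recall = recall, tpr = recall,
       roc_auc = roc, pr_auc = pr)
}

pr_auc_trapezoid <- function(scores, y) {
  o <- order(scores, decreasing = TRUE)
  y <- y[o]; s <- scores[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # one point per distinct threshold
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / sum(y)
  rec <- c(0, rec); prec <- c(prec[1L], prec)
  sum(diff(rec) * (prec[-1] + prec[-length(prec)]) / 2)
}

#' Per-allele true positive rates on monoallelic predictions
#'
#' The fraction of presented peptides in each monoallelic sample that
#' the model calls presented, per allele and pooled. Alleles with no
#' positives are excluded with a warning.
#'
#' @param predictions Data frame with columns `allele`, `score`,
#'   `label` (1 = presented).
#' @param threshold Presentation cutoff (default 0.5).
#' @return List with `per_allele` (data frame `allele`, `tpr`,
#'   `n_positives`) and `overall` (pooled TPR).
#' @export
per_allele_report <- function(predictions, threshold = 0.5) {
  stopifnot(all(c("allele", "score", "label") %in% names(predictions)))
  pos <- predictions[predictions$label == 1L, , drop = FALSE]
  alleles <- unique(predictions$allele)
  empty <- setdiff(alleles, unique(pos$allele))
  if (length(empty)) {
    warning("allele(s) without positives excluded: ",
            paste(empty, collapse = ", "))
  }
  tab <- do.call(rbind, lapply(sort(unique(pos$allele)), function(a) {
    p <- pos[pos$allele == a, , drop = FALSE]
    data.frame(allele = a, tpr = mean(p$score >= threshold),
               n_positives = nrow(p), stringsAsFactors = FALSE)
  }))
  list(per_allele = tab, overall = mean(pos$score >= threshold))
}

#' Binding-core prediction accuracy against annotations
#'
#' Compares predicted argmax core offsets with structurally annotated
#' offsets. Peptides whose length the model does not support (shorter
#' than 9 or longer than `max_len`) are reported as unsupported rather
#' than wrong.
#'
#' @param predictions Data frame with columns `peptide`, `core_offset`
#'   (0-based), typically from scoring each annotated peptide against
#'   its annotated allele only.
#' @param annotations Data frame with columns `peptide`, `core_offset`
#'   (0-based truth).
#' @param max_len Model maximum peptide length (default 30).
#' @return List with `n_correct`, `n_wrong`, `n_unsupported` and
#'   `accuracy` (over supported peptides).
#' @export
core_accuracy <- function(predictions, annotations, max_len = 30L) {
  stopifnot(all(c("peptide", "core_offset") %in% names(predictions)),
            all(c("peptide", "core_offset") %in% names(annotations)))
  L <- nchar(annotations$peptide)
  bad_off <- annotations$core_offset + 9L > L
  if (any(bad_off)) stop("annotation core offset beyond peptide end")
  unsupported <- L < 9L | L > max_len
  n_corr <- 0L; n_wrong <- 0L
  for (i in which(!unsupported)) {
    j <- match(annotations$peptide[i], predictions$peptide)
    if (is.na(j)) stop("no prediction for annotated peptide: ",
                       annotations$peptide[i])
    if (predictions$core_offset[j] == annotations$core_offset[i]) {
      n_corr <- n_corr + 1L
    } else {
      n_wrong <- n_wrong + 1L
    }
  }
  list(n_correct = n_corr, n_wrong = n_wrong,
       n_unsupported = sum(unsupported),
       accuracy = if (n_corr + n_wrong > 0) n_corr / (n_corr + n_wrong) else NA_real_)
}

#' Positional Shannon entropy of binding cores
#'
#' Entropy (base 2 by default, i.e. bits) of the observed residue
#' frequencies at each of the 9 core positions. Low entropy marks
#' anchor positions with strong residue preferences; the maximum,
#' log2(20) ~ 4.32 bits, is reached by a uniform composition.
#'
#' @param cores Character vector of 9mers (at least one).
#' @param base Logarithm base (default 2).
#' @return Numeric vector of 9 entropies.
#' @export
position_entropy <- function(cores, base = 2) {
  if (!length(cores)) stop("at least one core is required")
  stopifnot(all(nchar(cores) == 9L))
  mat <- do.call(rbind, strsplit(cores, "", fixed = TRUE))
  vapply(1:9, function(p) {
    f <- table(mat[, p]) / nrow(mat)
    -sum(f * log(f)) / log(base)
  }, numeric(1))
}

#' Residue-residue contact map from atomic coordinates
#'
#' A peptide residue and a chain residue are in contact iff the
#' minimum pairwise distance between their heavy atoms is strictly
#' below the cutoff (5 angstrom by default). Residues without atoms
#' are skipped with a warning (their row/column stays `FALSE`).
#'
#' @param pep_atoms List over peptide residues of n x 3 coordinate
#'   matrices (heavy atoms).
#' @param chain_atoms List over chain residues of n x 3 coordinate
#'   matrices.
#' @param cutoff Distance cutoff in angstrom (default 5; strict `<`).
#' @return Logical matrix, peptide residues x chain residues.
#' @export
contact_map <- function(pep_atoms, chain_atoms, cutoff = 5) {
  stopifnot(is.list(pep_atoms), is.list(chain_atoms), cutoff > 0)
  np <- length(pep_atoms); nc <- length(chain_atoms)
  empty <- c(which(vapply(pep_atoms, NROW, integer(1)) == 0L),
             np + which(vapply(chain_atoms, NROW, integer(1)) == 0L))
  if (length(empty)) warning("residue(s) without atoms skipped")
  cm <- matrix(FALSE, np, nc)
  for (i in seq_len(np)) {
    A <- pep_atoms[[i]]
    if (NROW(A) == 0L) next
    for (j in seq_len(nc)) {
      B <- chain_atoms[[j]]
      if (NROW(B) == 0L) next
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
      cm[i, j] <- min(d2) < cutoff^2
    }
  }
  cm
}

#' Read a structure and extract per-residue heavy-atom coordinates
#'
#' `read_structure()` parses a PDB file (through bio3d);
#' `residue_coords()` returns, for one chain, a list of heavy-atom
#' coordinate matrices ordered by residue number — the input format of
#' [contact_map()]. Hydrogens are excluded.
#'
#' @param path Path to a PDB file.
#' @return `read_structure`: a bio3d `pdb` object.
#' @export
read_structure <- function(path) {
  bio3d::read.pdb(path)
}

#' @rdname read_structure
#' @param pdb A bio3d `pdb` object.
#' @param chain Chain identifier.
#' @return `residue_coords`: named list (residue numbers) of n x 3
#'   matrices.
#' @export
residue_coords <- function(pdb, chain) {
  at <- pdb$atom
  at <- at[at$chain == chain & at$type == "ATOM" &
             !(toupper(at$elesy) %in% "H"), , drop = FALSE]
  if (!nrow(at)) stop("no heavy atoms for chain ", chain)
  resnos <- sort(unique(at$resno))
  out <- lapply(resnos, function(r) {
    as.matrix(at[at$resno == r, c("x", "y", "z"), drop = FALSE])
  })
  names(out) <- resnos
  out
}

#' Restrict a contact map to the pseudo-sequence positions
#'
#' Builds the 9 x 34 contact matrix seen by the model: rows are the
#' 9 core residues of the peptide, columns the 15 alpha + 19 beta
#' groove positions of the position table. Contacts with chain residues
#' outside the pseudo-sequence are invisible to the model and are
#' excluded here.
#'
#' @param cm_alpha,cm_beta Logical contact maps (peptide x chain) for
#'   the alpha and beta chains from [contact_map()].
#' @param core_offset 0-based offset of the binding core in the
#'   peptide.
#' @param table A `position_table`.
#' @return 9 x 34 logical matrix.
#' @export
core_contact_matrix <- function(cm_alpha, cm_beta, core_offset,
                                table = read_position_table()) {
  stopifnot(inherits(table, "position_table"),
            core_offset + 9L <= nrow(cm_alpha),
            nrow(cm_alpha) == nrow(cm_beta))
  rows <- (core_offset + 1L):(core_offset + 9L)
  cbind(cm_alpha[rows, table$alpha, drop = FALSE],
        cm_beta[rows, table$beta, drop = FALSE])
}

#' Fraction of contacts recovered by top-k attention
#'
#' For each interaction-encoder layer and head, marks each core query
#' position's `k` most-attended pseudo-sequence positions and reports
#' the fraction of structural contacts (restricted to pseudo
#' positions) they recover. `mode = "global"` instead marks the `k`
#' largest cells of the whole 9 x 34 attention map. With no contacts in
#' the denominator the fraction is `NA`.
#'
#' @param attn Attention array, n_layers x n_heads x 9 x 34 (e.g. from
#'   `pair_scores(..., attention = TRUE)$attention`).
#' @param contacts 9 x 34 logical matrix from [core_contact_matrix()].
#' @param k Attended positions marked per query (default 3).
#' @param mode `"per_position"` (default) or `"global"`.
#' @return List with `per` (n_layers x n_heads matrix of recovered
#'   fractions), `max` and `which_max` (layer, head).
#' @export
attention_recovery <- function(attn, contacts, k = 3L,
                               mode = c("per_position", "global")) {
  mode <- match.arg(mode)
  stopifnot(length(dim(attn)) == 4L, dim(attn)[3L] == 9L,
            dim(attn)[4L] == 34L, is.matrix(contacts),
            all(dim(contacts) == c(9L, 34L)))
  nl <- dim(attn)[1L]; nh <- dim(attn)[2L]
  denom <- sum(contacts)
  per <- matrix(NA_real_, nl, nh)
  if (denom > 0L) {
    for (l in seq_len(nl)) {
      for (h in seq_len(nh)) {
        A <- attn[l, h, , ]
        marked <- matrix(FALSE, 9L, 34L)
        if (mode == "per_position") {
          for (q in 1:9) {
            marked[q, order(A[q, ], decreasing = TRUE)[seq_len(k)]] <- TRUE
          }
        } else {
          o <- order(A, decreasing = TRUE)[seq_len(k)]
          marked[o] <- TRUE
        }
        per[l, h] <- sum(marked & contacts) / denom
      }
    }
  }
  wm <- if (all(is.na(per))) c(NA_integer_, NA_integer_) else {
    which(per == max(per, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  }
  list(per = per, max = if (all(is.na(per))) NA_real_ else max(per, na.rm = TRUE),
       which_max = wm)
}
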