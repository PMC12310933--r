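# Antibody immunogenicity screening and neoantigen tiering.
#
# An "epitope" is simplified to a unique predicted 9mer binding core
# that is (i) the core of a window scored as presented and (ii) absent
# from the human antibody germline repertoire. Chains are screened by
# exhaustive sliding windows of 9 and 12--19 residues against a
# population panel of alleles.

SCREEN_SIZES <- c(9L, 12:19)

#' Build a germline 9mer database
#'
#' Collects every 9mer occurring in the supplied germline sequences.
#' Membership is substring-exact: a query core is germline iff it
#' appears contiguously in at least one germline sequence (which for
#' 9mer queries is equivalent to membership in this 9mer set).
#'
#' @param sequences Named character vector of germline amino-acid
#'   sequences (e.g. read with [read_fasta()]).
#' @return Object of class `germline_db`.
#' @export
germline_db <- function(sequences) {
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  mers <- ninemer_set(sequences)
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (m in mers) assign(m, TRUE, envir = env)
  structure(list(set = env, n_9mers = length(mers),
                 n_sequences = length(sequences)),
            class = "germline_db")
}

#' @export
print.germline_db <- function(x, ...) {
  cat(sprintf("germline database: %d unique 9mer(s) from %d sequence(s)\n",
              x$n_9mers, x$n_sequences))
  invisible(x)
}

is_germline <- function(cores, db) {
  stopifnot(inherits(db, "germline_db"))
  vapply(cores, function(m) !is.null(db$set[[m]]), logical(1), USE.NAMES = FALSE)
}

#' Remove germline cores
#'
#' @param cores Character vector of 9mers.
#' @param db A [germline_db()].
#' @return The cores not present in any germline sequence (idempotent).
#' @export
filter_germline <- function(cores, db) {
  if (!length(cores)) return(character(0))
  stopifnot(all(nchar(cores) == 9L))
  cores[!is_germline(cores, db)]
}

#' Enumerate screening windows of a chain
#'
#' All windows of each requested size, as (sequence, 0-based start,
#' size) triples. Sizes exceeding the chain length contribute nothing;
#' if no size fits, an empty frame is returned with a warning.
#'
#' @param chain Character scalar, a protein chain sequence.
#' @param sizes Window sizes (default 9 and 12--19; external models
#'   that cannot score 9mers use `12:19`).
#' @return Data frame with columns `peptide`, `start`, `size`.
#' @export
enumerate_screen_windows <- function(chain, sizes = SCREEN_SIZES) {
  stopifnot(is.character(chain), length(chain) == 1L, length(sizes) >= 1L)
  L <- nchar(chain)
  out <- NULL
  for (w in sort(unique(as.integer(sizes)))) {
    if (L < w) next
    st <- 0:(L - w)
    out <- rbind(out, data.frame(peptide = substring(chain, st + 1L, st + w),
                                 start = st, size = w,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    warning("chain of length ", L, " is shorter than every window size")
    return(data.frame(peptide = character(0), start = integer(0),
                      size = integer(0)))
  }
  out
}

# Score peptides with any scorer exposing the common predict()
# interface (hla2_model, hla2_ensemble, pssm_scorer).
score_with <- function(scorer, peptides, panel, registry = NULL) {
  stats::predict(scorer,
                 newdata = data.frame(peptide = peptides,
                                      stringsAsFactors = FALSE),
                 registry = registry, panel = panel)
}

#' Count epitopes of antibody chains
#'
#' The screening pipeline: enumerate windows of each chain, score each
#' window against the allele panel (maximum over alleles), keep windows
#' scoring at least `threshold`, locate their predicted 9mer cores in
#' the chain, drop germline cores, and count the unique survivors.
#' Per-residue hotspot scores take the maximum score over all retained
#' cores covering the residue.
#'
#' @param chains Named character vector of chain sequences (e.g.
#'   heavy/light).
#' @param scorer An `hla2_model`, `hla2_ensemble` or `pssm_scorer`.
#' @param panel Character vector of allele names (default the nine
#'   common DR alleles).
#' @param registry Allele registry (required for model scorers).
#' @param db A [germline_db()].
#' @param threshold Presentation cutoff (default 0.5).
#' @param sizes Window sizes (default 9 and 12--19).
#' @return Object of class `epitope_report`: list with per-chain
#'   reports (`epitope_cores`, `epitope_count`, `hotspot`, `details`)
#'   and `total_unique`, the number of unique non-germline cores across
#'   all chains.
#' @export
count_epitopes <- function(chains, scorer, db, panel = common_dr_panel(),
                           registry = NULL, threshold = 0.5,
                           sizes = SCREEN_SIZES) {
  stopifnot(is.character(chains), length(chains) >= 1L,
            inherits(db, "germline_db"))
  if (is.null(names(chains))) names(chains) <- paste0("chain", seq_along(chains))
  reports <- list()
  for (ch in names(chains)) {
    win <- enumerate_screen_windows(chains[[ch]], sizes)
    hotspot <- numeric(nchar(chains[[ch]]))
    if (nrow(win) == 0L) {
      reports[[ch]] <- list(chain = ch, epitope_cores = character(0),
                            epitope_count = 0L, hotspot = hotspot,
                            window_sizes = sizes,
                            details = data.frame())
      next
    }
    sc <- score_with(scorer, win$peptide, panel, registry)
    hit <- sc$score >= threshold
    det <- data.frame(core = sc$core_9mer[hit],
                      start = win$start[hit] + sc$core_offset[hit],
                      score = sc$score[hit],
                      window = win$peptide[hit],
                      stringsAsFactors = FALSE)
    if (nrow(det)) {
      keep <- !is_germline(det$core, db)
      det <- det[keep, , drop = FALSE]
    }
    if (nrow(det)) {
      for (i in seq_len(nrow(det))) {
        pos <- (det$start[i] + 1L):(det$start[i] + 9L)
        hotspot[pos] <- pmax(hotspot[pos], det$score[i])
      }
    }
    cores <- unique(det$core)
    reports[[ch]] <- list(chain = ch, epitope_cores = cores,
                          epitope_count = length(cores), hotspot = hotspot,
                          window_sizes = sizes, details = det)
  }
  structure(list(chains = reports,
                 total_unique = length(unique(unlist(
                   lapply(reports, `[[`, "epitope_cores")))),
                 threshold = threshold),
            class = "epitope_report")
}

#' @export
print.epitope_report <- function(x, ...) {
  for (r in x$chains) {
    cat(sprintf("chain %-8s: %3d unique non-germline core(s)\n",
                r$chain, r$epitope_count))
  }
  cat(sprintf("total unique epitopes across chains: %d (threshold %.2f)\n",
              x$total_unique, x$threshold))
  invisible(x)
}

#' Per-residue hotspot scores of a screened chain
#'
#' @param report An `epitope_report` from [count_epitopes()].
#' @param chain Chain name (default: first chain).
#' @return Numeric vector, one score per residue: the maximum score of
#'   all retained epitope cores covering the residue, 0 elsewhere.
#' @export
hotspot_heatmap <- function(report, chain = NULL) {
  stopifnot(inherits(report, "epitope_report"))
  if (is.null(chain)) chain <- names(report$chains)[1L]
  report$chains[[chain]]$hotspot
}

#' Per-residue coverage heatmap of observed (MAPPs) peptides
#'
#' Aligns each experimentally observed peptide to the chain by exact
#' substring match (every occurrence contributes) and reports the
#' per-residue coverage count normalised by its maximum, in the unit
#' interval.
#'
#' @param peptides Character vector of observed peptides.
#' @param chain Chain sequence they derive from.
#' @return Numeric vector of length `nchar(chain)`.
#' @export
mapps_heatmap <- function(peptides, chain) {
  cov <- numeric(nchar(chain))
  for (p in peptides) {
    hits <- gregexpr(p, chain, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) {
      stop("observed peptide not found in chain: ", p)
    }
    for (h in hits) cov[h:(h + nchar(p) - 1L)] <- cov[h:(h + nchar(p) - 1L)] + 1
  }
  if (max(cov) > 0) cov <- cov / max(cov)
  cov
}

#' Label antibodies by anti-drug-antibody response
#'
#' @param ada_fraction Percentage of patients developing anti-drug
#'   antibodies.
#' @param threshold Immunogenicity threshold in percent (default 10):
#'   immunogenic iff strictly above.
#' @return Logical vector.
#' @export
ada_label <- function(ada_fraction, threshold = 10) {
  ada_fraction > threshold
}

#' Resolve duplicated antibody sequences with conflicting labels
#'
#' Pairs (or larger groups) of identical sequences with anti-drug
#' antibody responses on the same side of the threshold keep a single
#' representative; groups straddling the threshold are removed
#' entirely as irreconcilable.
#'
#' @param tb Data frame with columns `sequence` and `ada_fraction`.
#' @param threshold Immunogenicity threshold in percent (default 10).
#' @return Deduplicated data frame with an added logical `immunogenic`
#'   column.
#' @export
resolve_duplicate_labels <- function(tb, threshold = 10) {
  stopifnot(all(c("sequence", "ada_fraction") %in% names(tb)))
  tb$immunogenic <- ada_label(tb$ada_fraction, threshold)
  keep <- logical(nrow(tb))
  for (s in unique(tb$sequence)) {
    rows <- which(tb$sequence == s)
    labs <- tb$immunogenic[rows]
    if (length(unique(labs)) == 1L) {
      keep[rows[1L]] <- TRUE
    }                                   # conflicting group: drop all
  }
  tb[keep, , drop = FALSE]
}

#' Leave-one-out epitope-count cutoff calibration
#'
#' For each fold (one antibody held out) the cutoff on the epitope
#' count that maximises Youden's J (TPR - FPR, i.e. simultaneously
#' maximises the true positive rate and minimises the false positive
#' rate) on the remaining antibodies is selected; the held-out antibody
#' is then classified at that fold cutoff (immunogenic iff count >=
#' cutoff). Candidate cutoffs follow the ROC convention: the smallest
#' observed count plus the midpoints between adjacent distinct counts
#' and one value above the maximum, with ties resolved to the smallest
#' cutoff. The overall cutoff is the mean of the fold cutoffs, and F1
#' is computed from the pooled leave-one-out predictions.
#'
#' @param counts Integer epitope counts, one per antibody.
#' @param immunogenic Logical labels (at least two per class).
#' @return List with `cutoff` (mean of fold cutoffs), `fold_cutoffs`,
#'   `f1`, `predictions` (logical leave-one-out calls) and `youden`
#'   (per-fold best J).
#' @export
loo_cutoff <- function(counts, immunogenic) {
  stopifnot(length(counts) == length(immunogenic))
  immunogenic <- as.logical(immunogenic)
  if (sum(immunogenic) < 2L || sum(!immunogenic) < 2L) {
    stop("cutoff calibration needs at least two antibodies per class")
  }
  n <- length(counts)
  fold_cut <- numeric(n); pred <- logical(n); jbest <- numeric(n)
  for (i in seq_len(n)) {
    cc <- counts[-i]; ll <- immunogenic[-i]
    u <- sort(unique(cc))
    cand <- c(u[1L], if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2,
              u[length(u)] + 1)
    best_j <- -Inf; best_c <- cand[1L]
    for (cut in cand) {
      p <- cc >= cut
      tpr <- sum(p & ll) / sum(ll)
      fpr <- sum(p & !ll) / sum(!ll)
      j <- tpr - fpr
      if (j > best_j + 1e-12) { best_j <- j; best_c <- cut }
    }
    fold_cut[i] <- best_c; jbest[i] <- best_j
    pred[i] <- counts[i] >= best_c
  }
  tp <- sum(pred & immunogenic); fp <- sum(pred & !immunogenic)
  fn <- sum(!pred & immunogenic)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(cutoff = mean(fold_cut), fold_cutoffs = fold_cut, f1 = f1,
       predictions = pred, youden = jbest)
}

#' Score and tier a neoantigen
#'
#' Long peptides (vaccine neoantigens frequently exceed the model's
#' 26-residue maximum) are windowed into model-supported lengths (9 and
#' 12--19, plus the full peptide when it is itself supported); the
#' presentation score is the maximum over all windows and panel
#' alleles, and tiers follow the score: `>= tiers[2]` high-likelihood,
#' `>= tiers[1]` low-likelihood, below that not-presented (both lower
#' bounds inclusive).
#'
#' @param peptide Character scalar (>= 9 residues; may exceed 26).
#' @param scorer An `hla2_model`, `hla2_ensemble` or `pssm_scorer`.
#' @param panel Allele names (default the nine common DR alleles).
#' @param registry Allele registry (required for model scorers).
#' @param tiers Numeric length-2 tier boundaries (default
#'   `c(0.5, 0.95)`).
#' @param sizes Window sizes (default 9 and 12--19).
#' @return List with `score`, `tier` (one of `"not-presented"`,
#'   `"low-likelihood"`, `"high-likelihood"`), `core` (best 9mer),
#'   `core_start` (0-based offset in the long peptide) and
#'   `best_allele`.
#' @export
score_neoantigen <- function(peptide, scorer,
                             panel = common_dr_panel(), registry = NULL,
                             tiers = c(0.5, 0.95), sizes = SCREEN_SIZES) {
  stopifnot(is.character(peptide), length(peptide) == 1L,
            length(tiers) == 2L, tiers[1L] < tiers[2L])
  L <- nchar(peptide)
  if (L < 9L) stop("neoantigen peptide shorter than 9 residues")
  win <- enumerate_screen_windows(peptide, sizes)
  if (L >= 9L && L <= 26L && !(L %in% sizes)) {
    win <- rbind(win, data.frame(peptide = peptide, start = 0L, size = L,
                                 stringsAsFactors = FALSE))
  }
  sc <- score_with(scorer, win$peptide, panel, registry)
  best <- which.max(sc$score)
  s <- sc$score[best]
  tier <- if (s >= tiers[2L]) "high-likelihood"
          else if (s >= tiers[1L]) "low-likelihood"
          else "not-presented"
  list(score = s, tier = tier, core = sc$core_9mer[best],
       core_start = win$start[best] + sc$core_offset[best],
       best_allele = sc$best_allele[best])
}
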