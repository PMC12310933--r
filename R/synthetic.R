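# Planted-motif synthetic immunopeptidomes.
#
# Each synthetic allele owns a 9-position binding motif (a position
# probability matrix with peaked anchor rows); presented peptides are
# background flanks with a motif-sampled core embedded at a random
# offset, organised into mono- or polyallelic samples. Ground truth
# (core offset, source allele) is retained, so training, binding-core
# recovery and screening are all testable without external data.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  if (!is.null(seed)) set.seed(as.integer(seed) %% 2147483647L)
  on.exit(if (!is.null(old) && !is.null(seed)) assign(".Random.seed", old, envir = globalenv()))
  expr
}

#' Build a synthetic 9-position binding motif
#'
#' Anchor rows concentrate probability on 1--3 preferred residues; the
#' peakedness is set by `concentration`: anchor row p is proportional
#' to `background * concentration^u`, where u is 1 for the top
#' preferred residue and halves for each next one. At
#' `concentration = 1` every row equals the background (maximum
#' entropy); as `concentration` grows the anchor rows approach one-hot
#' (entropy 0). Non-anchor rows get a mild concentration-scaled jitter
#' around the background. The default anchors 1, 4, 6, 9 mimic the
#' classic DR binding registers.
#'
#' @param anchors Anchor positions, subset of 1..9 (default
#'   `c(1, 4, 6, 9)`).
#' @param concentration Anchor peakedness, >= 1 (default 100).
#' @param background Length-20 residue background distribution
#'   (default uniform).
#' @param name Optional allele name to tag the motif with.
#' @param seed Optional seed (draws from the current RNG if `NULL`).
#' @return Object of class `motif_spec`: list with `pssm` (9 x 20 row
#'   stochastic matrix, columns [aa_alphabet()]), `anchors`,
#'   `concentration`, `name`.
#' @export
make_motif <- function(anchors = c(1L, 4L, 6L, 9L), concentration = 100,
                       background = rep(1 / 20, 20), name = NULL,
                       seed = NULL) {
  stopifnot(length(anchors) >= 1L, length(anchors) <= 9L,
            all(anchors %in% 1:9), concentration >= 1,
            length(background) == 20L, all(background > 0))
  background <- background / sum(background)
  with_seed(seed, {
    pssm <- matrix(rep(background, each = 9L), 9L, 20L,
                   dimnames = list(1:9, AA_LETTERS))
    lc <- log(concentration)
    for (p in anchors) {
      npref <- sample.int(3L, 1L)
      pref <- sample.int(20L, npref)
      u <- numeric(20L)
      u[pref] <- 2^-(seq_len(npref) - 1L)
      row <- background * exp(lc * u)
      pssm[p, ] <- row / sum(row)
    }
    for (p in setdiff(1:9, anchors)) {
      row <- background * exp(lc * 0.02 * stats::rnorm(20L))
      pssm[p, ] <- row / sum(row)
    }
    structure(list(pssm = pssm, anchors = sort(as.integer(anchors)),
                   concentration = concentration, name = name),
              class = "motif_spec")
  })
}

#' Consensus (modal) core of a motif
#'
#' @param motif A `motif_spec`.
#' @return The 9mer taking the most probable residue at each position.
#' @export
consensus_core <- function(motif) {
  stopifnot(inherits(motif, "motif_spec"))
  paste(AA_LETTERS[apply(motif$pssm, 1L, which.max)], collapse = "")
}

sample_from_probs <- function(n, probs) {
  AA_LETTERS[sample.int(20L, n, replace = TRUE, prob = probs)]
}

sample_core <- function(pssm) {
  paste(vapply(1:9, function(p) sample_from_probs(1L, pssm[p, ]), character(1)),
        collapse = "")
}

random_background_seq <- function(len, background) {
  paste(sample_from_probs(len, background), collapse = "")
}

#' Generate a background proteome
#'
#' I.i.d. background-composition protein sequences used as the decoy
#' source, standing in for "random peptides from the human proteome".
#'
#' @param n_proteins Number of proteins (0 gives an empty vector).
#' @param length_range Integer range of protein lengths (uniform;
#'   default 200--400).
#' @param background_freqs Length-20 residue distribution (default
#'   uniform; see [human_aa_freqs()] for a proteome-like preset).
#' @param seed Seed (default 1).
#' @return Named character vector of protein sequences.
#' @export
generate_proteome <- function(n_proteins, length_range = c(200L, 400L),
                              background_freqs = rep(1 / 20, 20),
                              seed = 1L) {
  stopifnot(n_proteins >= 0L, length(length_range) == 2L,
            length_range[1L] <= length_range[2L])
  if (n_proteins == 0L) return(stats::setNames(character(0), character(0)))
  background_freqs <- background_freqs / sum(background_freqs)
  with_seed(seed, {
    lens <- sample(length_range[1L]:length_range[2L], n_proteins, replace = TRUE)
    stats::setNames(vapply(lens, random_background_seq, character(1),
                           background = background_freqs),
                    sprintf("protein%04d", seq_len(n_proteins)))
  })
}

#' Generate a planted-motif synthetic world
#'
#' Creates `n_alleles` synthetic alleles (random 34-residue
#' pseudo-sequences plus a planted motif each), assembles mono- or
#' polyallelic samples, and emits presented peptides: a motif-sampled
#' core embedded in background flanks at a uniform random offset, with
#' ground truth retained. Lengths are drawn from a unimodal
#' distribution over 9--26 residues (peak near 15, as in eluted-ligand
#' data).
#'
#' With `dominant_frac > 0`, that fraction of every sample's positives
#' is sourced from the first allele's motif (added to every sample's
#' allele set) and generated as near-duplicates of `dup_templates`
#' template peptides (at most one substitution each), inducing the
#' skewed cluster-size distribution that the inverse-cluster-size loss
#' weights are designed to counter.
#'
#' @param n_alleles Number of synthetic alleles.
#' @param n_samples Number of samples.
#' @param positives_per_sample Presented peptides per sample.
#' @param polyallelic_max Maximum alleles per sample (default 14; 1
#'   gives monoallelic samples).
#' @param dominant_frac Fraction of positives sourced from the dominant
#'   (first) motif (default 0 = no skew).
#' @param dup_templates Number of template peptides behind the dominant
#'   motif's near-duplicates (default 8).
#' @param anchors,concentration,background_freqs Passed to
#'   [make_motif()] / flank generation.
#' @param n_proteins,protein_length_range Background proteome size.
#' @param seed Seed; the world is a pure function of its arguments.
#' @return Object of class `synthetic_world`: list with `registry`,
#'   `motifs` (named list of `motif_spec`), `sample_alleles` (named
#'   list), `positives` (data frame `peptide`, `sample_id`,
#'   `core_offset`, `source_allele`), `proteome`, `background_freqs`.
#' @export
generate_world <- function(n_alleles = 5L, n_samples = 10L,
                           positives_per_sample = 200L,
                           polyallelic_max = 14L, dominant_frac = 0,
                           dup_templates = 8L,
                           anchors = c(1L, 4L, 6L, 9L), concentration = 100,
                           background_freqs = rep(1 / 20, 20),
                           n_proteins = 50L,
                           protein_length_range = c(200L, 400L),
                           seed = 1L) {
  stopifnot(n_alleles >= 1L, n_samples >= 1L, positives_per_sample >= 1L,
            polyallelic_max >= 1L, dominant_frac >= 0, dominant_frac <= 1)
  background_freqs <- background_freqs / sum(background_freqs)
  with_seed(seed, {
    anames <- sprintf("SYN-%02d", seq_len(n_alleles))
    pseudo <- vapply(seq_len(n_alleles), function(i)
      random_background_seq(34L, background_freqs), character(1))
    registry <- allele_registry(anames, pseudo)
    motifs <- lapply(seq_len(n_alleles), function(i)
      make_motif(anchors, concentration, background_freqs, name = anames[i]))
    names(motifs) <- anames

    len_support <- 9:26
    len_probs <- stats::dnorm(len_support, 15, 3)
    len_probs <- len_probs / sum(len_probs)

    templates <- NULL
    if (dominant_frac > 0) {
      template_off <- integer(dup_templates)
      templates <- character(dup_templates)
      for (i in seq_len(dup_templates)) {
        L <- sample(len_support, 1L, prob = len_probs)
        off <- sample.int(L - 8L, 1L) - 1L
        core <- sample_core(motifs[[1L]]$pssm)
        templates[i] <- paste0(random_background_seq(off, background_freqs),
                               core,
                               random_background_seq(L - off - 9L,
                                                     background_freqs))
        template_off[i] <- off
      }
    }

    sids <- sprintf("sample%03d", seq_len(n_samples))
    sample_alleles <- vector("list", n_samples)
    names(sample_alleles) <- sids
    for (j in seq_len(n_samples)) {
      k <- sample.int(min(polyallelic_max, n_alleles), 1L)
      set <- sample(anames, k)
      if (dominant_frac > 0 && !(anames[1L] %in% set)) {
        set <- c(anames[1L], set[-1L])
      }
      sample_alleles[[j]] <- sort(set)
    }

    pep <- character(0); sid <- character(0)
    coff <- integer(0); src <- character(0)
    for (j in seq_len(n_samples)) {
      for (i in seq_len(positives_per_sample)) {
        if (dominant_frac > 0 && stats::runif(1) < dominant_frac) {
          t_i <- sample.int(dup_templates, 1L)
          p <- templates[t_i]
          if (stats::runif(1) < 0.8) {          # at most one substitution
            pos <- sample.int(nchar(p), 1L)
            substr(p, pos, pos) <- sample_from_probs(1L, background_freqs)
          }
          pep <- c(pep, p); coff <- c(coff, template_off[t_i])
          src <- c(src, anames[1L]); sid <- c(sid, sids[j])
        } else {
          a <- sample(sample_alleles[[j]], 1L)
          L <- sample(len_support, 1L, prob = len_probs)
          off <- sample.int(L - 8L, 1L) - 1L
          core <- sample_core(motifs[[a]]$pssm)
          p <- paste0(random_background_seq(off, background_freqs), core,
                      random_background_seq(L - off - 9L, background_freqs))
          pep <- c(pep, p); coff <- c(coff, off)
          src <- c(src, a); sid <- c(sid, sids[j])
        }
      }
    }
    proteome <- generate_proteome(n_proteins, protein_length_range,
                                  background_freqs,
                                  seed = sample.int(2147483646L, 1L))
    structure(list(registry = registry, motifs = motifs,
                   sample_alleles = sample_alleles,
                   positives = data.frame(peptide = pep, sample_id = sid,
                                          core_offset = coff,
                                          source_allele = src,
                                          stringsAsFactors = FALSE),
                   proteome = proteome, background_freqs = background_freqs,
                   anchors = sort(as.integer(anchors)),
                   concentration = concentration, seed = seed),
              class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic world: %d allele(s), %d sample(s), %d positives, %d background protein(s)\n",
              nrow(x$registry), length(x$sample_alleles),
              nrow(x$positives), length(x$proteome)))
  invisible(x)
}

#' Bayes-optimal oracle scorer for a synthetic world
#'
#' Scores a peptide by the maximum, over all 9mer windows and alleles,
#' of the log-likelihood ratio of the window under the allele's planted
#' motif versus the background, squashed through a sigmoid so that
#' scores live in (0, 1) with 0.5 at even odds. On data the world
#' generated this is the Bayes ceiling against which trained models are
#' compared; it also serves as a deterministic stand-in scorer for the
#' screening pipeline.
#'
#' @param world A `synthetic_world`.
#' @return Object of class `pssm_scorer` supporting [predict()] with
#'   the same interface and columns as [predict.hla2_model()].
#' @export
oracle_scorer <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  structure(list(motifs = world$motifs,
                 background = world$background_freqs),
            class = "pssm_scorer")
}

llr_window <- function(tokens9, pssm, logbg) {
  sum(log(pssm[cbind(1:9, tokens9)]) - logbg[tokens9])
}

#' @rdname oracle_scorer
#' @param object A `pssm_scorer`.
#' @param newdata Data frame with `peptide` (and optionally
#'   `sample_id`).
#' @param registry Ignored (kept for interface compatibility).
#' @param sample_alleles Named list `sample_id -> allele names`, or
#'   `NULL` to use `panel`.
#' @param panel Character vector of allele (motif) names.
#' @param ... Unused.
#' @export
predict.pssm_scorer <- function(object, newdata, registry = NULL,
                                sample_alleles = NULL, panel = NULL, ...) {
  if (is.null(newdata$sample_id)) newdata$sample_id <- "sample1"
  sets <- resolve_allele_sets(newdata, sample_alleles, panel)
  logbg <- log(object$background)
  n <- nrow(newdata)
  score <- numeric(n); core_offset <- integer(n); best_allele <- character(n)
  for (i in seq_len(n)) {
    toks <- match(aa_chars(newdata$peptide[i]), AA_LETTERS)
    if (anyNA(toks)) stop("non-canonical residues in peptide ",
                          newdata$peptide[i])
    L <- length(toks)
    if (L < 9L) stop("peptide shorter than 9 residues")
    alleles <- sort(unique(sets[[i]]))
    best <- -Inf; boff <- 0L; ba <- alleles[1L]
    for (a in alleles) {
      pssm <- object$motifs[[a]]$pssm
      if (is.null(pssm)) stop("unknown allele in panel: ", a)
      for (off in 0:(L - 9L)) {
        v <- llr_window(toks[(off + 1L):(off + 9L)], pssm, logbg)
        if (v > best) { best <- v; boff <- off; ba <- a }
      }
    }
    score[i] <- sigmoid(best); core_offset[i] <- boff; best_allele[i] <- ba
  }
  data.frame(peptide = newdata$peptide, sample_id = newdata$sample_id,
             score = score, core_offset = core_offset,
             core_9mer = substr(newdata$peptide, core_offset + 1L,
                                core_offset + 9L),
             best_allele = best_allele, presented = score >= 0.5,
             stringsAsFactors = FALSE)
}

#' Perfect scorer for a known core set
#'
#' A deterministic scorer that flags a peptide as presented iff it
#' contains one of the given 9mer cores, reporting that core as the
#' binding core. Useful as the "perfect predictor" in screening
#' fixtures where the set of true epitopes is known by construction:
#' unlike the probabilistic [oracle_scorer()], it can never flag a
#' window that merely overlaps a planted core.
#'
#' @param cores Character vector of 9mers.
#' @param hit,miss Scores assigned to containing / non-containing
#'   peptides (defaults 0.99 and 0.01).
#' @return Object of class `core_set_scorer` supporting [predict()]
#'   with the common scorer interface.
#' @export
core_set_scorer <- function(cores, hit = 0.99, miss = 0.01) {
  stopifnot(all(nchar(cores) == 9L), hit > miss)
  structure(list(cores = unique(cores), hit = hit, miss = miss),
            class = "core_set_scorer")
}

#' @rdname core_set_scorer
#' @param object A `core_set_scorer`.
#' @param newdata Data frame with a `peptide` column.
#' @param registry,sample_alleles,panel Ignored (interface
#'   compatibility).
#' @param ... Unused.
#' @export
predict.core_set_scorer <- function(object, newdata, registry = NULL,
                                    sample_alleles = NULL, panel = NULL,
                                    ...) {
  n <- nrow(newdata)
  score <- rep(object$miss, n)
  core_offset <- integer(n)
  for (i in seq_len(n)) {
    for (cc in object$cores) {
      pos <- regexpr(cc, newdata$peptide[i], fixed = TRUE)
      if (pos > 0L) {
        score[i] <- object$hit
        core_offset[i] <- as.integer(pos) - 1L
        break
      }
    }
  }
  data.frame(peptide = newdata$peptide,
             sample_id = if (is.null(newdata$sample_id)) "sample1" else newdata$sample_id,
             score = score, core_offset = core_offset,
             core_9mer = substr(newdata$peptide, core_offset + 1L,
                                core_offset + 9L),
             best_allele = NA_character_, presented = score >= 0.5,
             stringsAsFactors = FALSE)
}

#' Build a toy antibody with spliced foreign cores
#'
#' Constructs heavy and light chains from germline scaffold sequences
#' and splices the given foreign 9mer cores into them at random
#' interior positions, recording where. The scaffolds are entirely
#' germline, so after germline filtering the only legitimate epitopes
#' of the chains are the insertions — the ground truth for screening
#' tests.
#'
#' @param germline Named character vector of at least two germline
#'   scaffold sequences (>= 40 residues each); the first two become the
#'   heavy and light scaffolds and the whole vector is the germline
#'   database source.
#' @param foreign_cores Character vector of 9mers to splice in; none
#'   may occur as a substring of any germline sequence.
#' @param seed Seed for insertion placement.
#' @return List with `chains` (named character, `heavy` and `light`),
#'   `insertions` (data frame `chain`, `core`, `start` 0-based into the
#'   final chain) and `germline` (the scaffold source).
#' @export
make_toy_antibody <- function(germline, foreign_cores, seed = 1L) {
  stopifnot(length(germline) >= 2L, all(nchar(germline[1:2]) >= 40L),
            all(nchar(foreign_cores) == 9L))
  for (fc in foreign_cores) {
    if (any(grepl(fc, germline, fixed = TRUE))) {
      stop("foreign core ", fc, " occurs in the germline scaffold")
    }
  }
  with_seed(seed, {
    chains <- c(heavy = unname(germline[1L]), light = unname(germline[2L]))
    which_chain <- rep_len(c("heavy", "light"), length(foreign_cores))
    ins <- NULL
    for (i in seq_along(foreign_cores)) {
      ch <- which_chain[i]
      s <- chains[[ch]]
      pos <- sample(15:(nchar(s) - 15L), 1L)       # insert after 'pos'
      chains[[ch]] <- paste0(substr(s, 1L, pos), foreign_cores[i],
                             substr(s, pos + 1L, nchar(s)))
      ins <- rbind(ins, data.frame(chain = ch, core = foreign_cores[i],
                                   start = pos, stringsAsFactors = FALSE))
    }
    # inserting into the same chain twice shifts earlier coordinates;
    # recompute starts from the final chains
    ins$start <- vapply(seq_len(nrow(ins)), function(i) {
      as.integer(regexpr(ins$core[i], chains[[ins$chain[i]]], fixed = TRUE)) - 1L
    }, integer(1))
    if (any(ins$start < 0L)) stop("internal error: inserted core not found")
    list(chains = chains, insertions = ins, germline = germline)
  })
}
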