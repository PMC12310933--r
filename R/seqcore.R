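# Peptide records, 9mer window enumeration, padding, similarity
# clustering and cluster-size loss weights, and 9mer-aware data splits.
#
# Coordinates are 0-based half-open internally; only rendered reports
# use 1-based positions.

#' Enumerate all 9mer windows of a peptide
#'
#' Slides a 9-residue window over the peptide from left to right. These
#' windows are the candidate binding cores: a peptide of length L yields
#' M = L - 8 of them.
#'
#' @param peptide Character scalar, length >= 9.
#' @return List with `windows` (character vector of 9mers) and `offsets`
#'   (0-based start indices into the peptide).
#' @examples
#' extract_windows("ACDEFGHIKLM")
#' @export
extract_windows <- function(peptide) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  L <- nchar(peptide)
  if (L < 9L) {
    stop("peptide of length ", L, " has no 9mer window (length must be >= 9)")
  }
  off <- 0:(L - 9L)
  list(windows = substring(peptide, off + 1L, off + 9L), offsets = off)
}

# Set of distinct 9mers of one or many sequences (used for splits,
# decoy screening and germline databases).
ninemer_set <- function(seqs) {
  seqs <- seqs[nchar(seqs) >= 9L]
  if (!length(seqs)) return(character(0))
  unique(unlist(lapply(seqs, function(s) extract_windows(s)$windows),
                use.names = FALSE))
}

#' Pad a peptide to a fixed model length and build its mask
#'
#' The model consumes fixed-length token sequences; real positions are
#' marked by the mask and padding positions are never attended to.
#'
#' @param peptide Character scalar (length <= `max_len`).
#' @param max_len Integer, padded length (default 30, the model maximum).
#' @return List with `tokens` (integer vector of length `max_len`, pad
#'   token appended) and `mask` (logical vector, `TRUE` at real positions).
#' @export
pad_and_mask <- function(peptide, max_len = 30L) {
  L <- nchar(peptide)
  if (L > max_len) {
    stop("peptide length ", L, " exceeds maximum padded length ", max_len)
  }
  tok <- c(tokenize_peptide(peptide), rep(PAD_ID, max_len - L))
  list(tokens = tok, mask = c(rep(TRUE, L), rep(FALSE, max_len - L)))
}

# Best ungapped identity between two residue-id vectors over all
# offsets, defined as matches / shorter length. Offsets with overlap
# too small to reach `min_identity` are skipped.
ungapped_identity <- function(a, b, min_identity = 0) {
  la <- length(a); lb <- length(b)
  if (lb > la) { tmp <- a; a <- b; b <- tmp; tmp <- la; la <- lb; lb <- tmp }
  need <- ceiling(min_identity * lb)
  best <- 0L
  # shift = start of b relative to a (0 = aligned at a's first residue)
  for (shift in (-(lb - need)):(la - need)) {
    i1 <- max(1L, 1L + shift); i2 <- min(la, lb + shift)
    if (i2 - i1 + 1L < need) next
    j1 <- i1 - shift
    m <- sum(a[i1:i2] == b[j1:(j1 + (i2 - i1))])
    if (m > best) best <- m
  }
  best / lb
}

#' Cluster peptides by ungapped sequence identity
#'
#' Greedy star clustering: peptides are visited by decreasing length
#' (ties broken alphabetically) and each is assigned to the first
#' existing cluster representative whose best-offset ungapped identity
#' reaches `min_identity` (identity = matches / shorter length), otherwise it
#' founds a new cluster. Identical sequences always share a cluster.
#' The partition is deterministic. An externally produced clustering
#' (e.g. an MMseqs2 `easy-cluster` TSV) can be imported with
#' [read_cluster_tsv()] instead.
#'
#' @param peptides Character vector of peptide sequences.
#' @param min_identity Minimum fractional identity (default 0.8).
#' @return Named character vector mapping each input peptide to a
#'   cluster id (the representative sequence). Duplicated inputs map to
#'   the same id. Empty input gives an empty map.
#' @export
cluster_peptides <- function(peptides, min_identity = 0.8) {
  if (!length(peptides)) return(stats::setNames(character(0), character(0)))
  stopifnot(is.character(peptides), all(nchar(peptides) > 0L))
  uniq <- unique(peptides)
  ord <- order(-nchar(uniq), uniq)
  uniq <- uniq[ord]
  toks <- lapply(uniq, function(s) match(aa_chars(s), AA_LETTERS, nomatch = 0L))
  reps <- integer(0)             # indices into uniq that are representatives
  assign <- integer(length(uniq))
  for (i in seq_along(uniq)) {
    hit <- 0L
    for (r in reps) {
      if (ungapped_identity(toks[[r]], toks[[i]], min_identity) >= min_identity) {
        hit <- r; break
      }
    }
    if (hit == 0L) { reps <- c(reps, i); hit <- i }
    assign[i] <- hit
  }
  map <- stats::setNames(uniq[assign], uniq)
  stats::setNames(map[peptides], peptides)
}

#' Import an externally produced clustering
#'
#' Reads a two-column representative/member TSV in the dialect written
#' by MMseqs2 `easy-cluster`, returning the same member-to-cluster map
#' as [cluster_peptides()].
#'
#' @param path Path to a TSV with columns representative, member.
#' @return Named character vector mapping member to representative.
#' @export
read_cluster_tsv <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("representative", "member"),
                          colClasses = "character")
  stats::setNames(tb$representative, tb$member)
}

#' Assign inverse-cluster-size loss weights
#'
#' Each training record receives weight 1 / (number of records in its
#' peptide's cluster), counted over all peptide-sample rows supplied, so
#' that every cluster contributes total weight one to the loss. Decoys
#' are later given the weight of the presented record they are linked
#' to (see [sample_decoys()]).
#'
#' @param records Data frame with at least a `peptide` column (one row
#'   per peptide-sample pair).
#' @param clusters Named map peptide -> cluster id, e.g. from
#'   [cluster_peptides()].
#' @return `records` with `cluster_id` and `weight` columns added.
#' @export
assign_weights <- function(records, clusters) {
  stopifnot(is.data.frame(records), "peptide" %in% names(records))
  cid <- unname(clusters[records$peptide])
  if (anyNA(cid)) {
    stop("no cluster id for peptide(s): ",
         paste(utils::head(unique(records$peptide[is.na(cid)]), 3L), collapse = ", "))
  }
  sizes <- table(cid)
  records$cluster_id <- cid
  records$weight <- 1 / as.numeric(sizes[cid])
  records
}

#' Split records into train/validation/test minimising shared 9mers
#'
#' Records are grouped into connected components of the "shares a 9mer"
#' graph; whole components are then assigned greedily (largest first,
#' ties by lexicographically smallest member sequence, residual ties by
#' a seeded draw) to the split with the largest remaining capacity
#' deficit. Records sharing a 9mer therefore land in the same split
#' whenever capacity allows, and the number of 9mers leaking across
#' splits is reported.
#'
#' @param records Data frame with a `peptide` column.
#' @param ratios Numeric length-3 train/validation/test proportions
#'   (default `c(8, 1, 1)`).
#' @param seed Integer seed for residual tie-breaking.
#' @return List with `train`, `validation`, `test` (row subsets of
#'   `records`) and `leaked_9mers`, the count of distinct 9mers present
#'   in more than one split.
#' @export
split_dataset <- function(records, ratios = c(8, 1, 1), seed = 1L) {
  stopifnot(is.data.frame(records), "peptide" %in% names(records),
            length(ratios) == 3, all(ratios > 0))
  n <- nrow(records)
  if (n < 10L) stop("refusing to split fewer than 10 records")
  ratios <- ratios / sum(ratios)

  # union-find over records, unioned through shared 9mers
  parent <- seq_len(n)
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  mer_owner <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    p <- records$peptide[i]
    if (nchar(p) < 9L) next
    for (m in extract_windows(p)$windows) {
      o <- mer_owner[[m]]
      if (is.null(o)) assign(m, i, envir = mer_owner)
      else { ri <- findp(i); ro <- findp(o); if (ri != ro) parent[ri] <- ro }
    }
  }
  comp <- vapply(seq_len(n), findp, integer(1))
  comp_ids <- unique(comp)
  comp_rows <- split(seq_len(n), match(comp, comp_ids))
  sizes <- lengths(comp_rows)
  min_seq <- vapply(comp_rows, function(r) min(records$peptide[r]), character(1))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  ord <- order(-sizes, min_seq, stats::runif(length(sizes)))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  target <- ratios * n
  got <- c(0, 0, 0)
  assign_split <- integer(n)
  for (k in ord) {
    s <- which.max(target - got)
    assign_split[comp_rows[[k]]] <- s
    got[s] <- got[s] + sizes[k]
  }

  mers_by_split <- lapply(1:3, function(s) ninemer_set(records$peptide[assign_split == s]))
  all_m <- unlist(mers_by_split, use.names = FALSE)
  leaked <- sum(table(all_m) > 1L)
  list(train      = records[assign_split == 1L, , drop = FALSE],
       validation = records[assign_split == 2L, , drop = FALSE],
       test       = records[assign_split == 3L, , drop = FALSE],
       leaked_9mers = leaked)
}

#' Read / write peptide tables
#'
#' Peptide tables are TSV files with columns `peptide`, `sample_id` and
#' optionally `label` (1 = presented, 0 = decoy) plus any extra columns,
#' the dialect consumed by [hla2_train()] and emitted by the synthetic
#' generator.
#'
#' @param path File path.
#' @return `read_peptide_table`: a data frame.
#' @export
read_peptide_table <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  stopifnot(all(c("peptide", "sample_id") %in% names(tb)))
  tb
}

#' @rdname read_peptide_table
#' @param x Data frame with at least `peptide` and `sample_id`.
#' @export
write_peptide_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write FASTA files
#'
#' Thin wrappers around Biostrings that present sequences as a plain
#' named character vector, the representation used everywhere in this
#' package (background proteomes, antibody chains, germline databases).
#' Output wraps at 60 columns.
#'
#' @param path File path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(s), names(s))
}

#' @rdname read_fasta
#' @param x Named character vector of sequences.
#' @export
write_fasta <- function(x, path) {
  stopifnot(is.character(x))
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  s <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(s, path, width = 60L)
  invisible(path)
}

#' Filter peptides to the modellable length range
#'
#' Training peptides outside `[min_len, max_len]` are dropped with a
#' message. The lower bound defaults to 9 because the 9mer window is
#' undefined for shorter peptides; 8-residue peptides occur in eluted
#' ligand data but cannot be windowed and are excluded here.
#'
#' @param records Data frame with a `peptide` column.
#' @param min_len,max_len Inclusive length bounds (defaults 9 and 26).
#' @return Filtered data frame.
#' @export
filter_length <- function(records, min_len = 9L, max_len = 26L) {
  L <- nchar(records$peptide)
  drop <- L < min_len | L > max_len
  if (any(drop)) {
    message(sum(drop), " peptide record(s) outside [", min_len, ", ",
            max_len, "] residues removed")
  }
  records[!drop, , drop = FALSE]
}
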