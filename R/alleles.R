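# HLA class II allele registry and pseudo-sequence construction.
#
# An allele (a locus-specific alpha/beta heterodimer) is represented to
# the model by a 34-residue pseudo-sequence: the 15 groove-lining
# residues of the alpha chain followed by the 19 groove-lining residues
# of the beta chain, selected by a position table.

#' Read a binding-groove position table
#'
#' The table names which residues of the alpha and beta chains line the
#' peptide-binding groove and therefore enter the pseudo-sequence. The
#' file format is plain text: comment lines start with `#`, then one
#' line of 15 alpha-chain positions and one line of 19 beta-chain
#' positions, whitespace-separated and 1-based (converted to the
#' package's internal 0-based convention only at lookup time).
#'
#' A default table following the NetMHCIIpan-3.0 residue selection is
#' shipped at `system.file("extdata", "groove_positions.txt", package =
#' "hla2present")` and is deliberately editable data, not code: any
#' pseudo-sequence-derived result is conditional on this table.
#'
#' @param path Path to the table; default is the shipped table.
#' @return Object of class `position_table`: list with integer vectors
#'   `alpha` (15) and `beta` (19), strictly increasing, 1-based.
#' @export
read_position_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "groove_positions.txt",
                        package = "hla2present", mustWork = TRUE)
  }
  ln <- readLines(path)
  ln <- trimws(ln[!grepl("^\\s*(#|$)", ln)])
  if (length(ln) != 2L) stop("position table must have exactly two data lines")
  alpha <- as.integer(strsplit(ln[1L], "\\s+")[[1L]])
  beta <- as.integer(strsplit(ln[2L], "\\s+")[[1L]])
  position_table(alpha, beta)
}

#' @rdname read_position_table
#' @param alpha,beta Integer vectors of 1-based chain positions
#'   (15 and 19 entries).
#' @export
position_table <- function(alpha, beta) {
  stopifnot(length(alpha) == 15L, length(beta) == 19L,
            all(alpha >= 1L), all(beta >= 1L),
            all(diff(alpha) > 0L), all(diff(beta) > 0L))
  structure(list(alpha = as.integer(alpha), beta = as.integer(beta)),
            class = "position_table")
}

#' Build an allele pseudo-sequence from its chain sequences
#'
#' Selects the groove-lining residues of the alpha chain (15) and beta
#' chain (19) named by the position table and concatenates them (alpha
#' first) into the 34-residue pseudo-sequence that represents the
#' allele to the model. Pure function of its inputs.
#'
#' @param name Allele name, e.g. `"DRB1*01:01"`.
#' @param alpha_chain,beta_chain Mature chain amino-acid sequences.
#' @param table A `position_table` (default: shipped table).
#' @return Object of class `allele_spec`: list with `name`,
#'   `alpha_pseudo` (15 AA), `beta_pseudo` (19 AA) and `pseudo` (34 AA).
#' @export
build_pseudo <- function(name, alpha_chain, beta_chain,
                         table = read_position_table()) {
  stopifnot(inherits(table, "position_table"))
  if (max(table$alpha) > nchar(alpha_chain)) {
    stop("alpha chain of allele ", name, " (", nchar(alpha_chain),
         " AA) does not cover groove position ", max(table$alpha))
  }
  if (max(table$beta) > nchar(beta_chain)) {
    stop("beta chain of allele ", name, " (", nchar(beta_chain),
         " AA) does not cover groove position ", max(table$beta))
  }
  a <- paste(aa_chars(alpha_chain)[table$alpha], collapse = "")
  b <- paste(aa_chars(beta_chain)[table$beta], collapse = "")
  allele_spec(name, paste0(a, b))
}

#' Construct an allele from an explicit pseudo-sequence
#'
#' Used when the 34-residue pseudo-sequence is already known (registry
#' files, synthetic alleles) and chain construction is bypassed.
#'
#' @param name Allele name.
#' @param pseudo 34-residue pseudo-sequence (alpha 15 then beta 19).
#' @return An `allele_spec`.
#' @export
allele_spec <- function(name, pseudo) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(pseudo), nchar(pseudo) == 34L)
  if (!is_canonical_aa(pseudo)) {
    stop("pseudo-sequence of ", name, " contains non-canonical letters")
  }
  structure(list(name = name,
                 alpha_pseudo = substr(pseudo, 1L, 15L),
                 beta_pseudo = substr(pseudo, 16L, 34L),
                 pseudo = pseudo),
            class = "allele_spec")
}

#' @export
print.allele_spec <- function(x, ...) {
  cat(x$name, ": ", x$alpha_pseudo, " | ", x$beta_pseudo, "\n", sep = "")
  invisible(x)
}

#' The nine common HLA-DR alleles
#'
#' The representative panel of common DR alleles used for population
#' level screening (antibody immunogenicity, neoantigen tiering). All
#' nine pair the invariant DRA1 alpha chain (the DRA gene is effectively
#' non-polymorphic) with a polymorphic DRB1 beta chain.
#'
#' @return Character vector of the nine DRB1 allele names, with the
#'   shared alpha-chain gene in attribute `alpha_chain`.
#' @export
common_dr_panel <- function() {
  structure(c("DRB1*01:01", "DRB1*03:01", "DRB1*04:01", "DRB1*07:01",
              "DRB1*08:01", "DRB1*09:01", "DRB1*11:01", "DRB1*13:01",
              "DRB1*15:01"),
            alpha_chain = "DRA1*01:01")
}

#' Read / write an allele registry
#'
#' An allele registry is a TSV with columns `name`, `alpha_pseudo`
#' (15 AA) and `beta_pseudo` (19 AA); it round-trips exactly through
#' these two functions.
#'
#' @param path File path.
#' @return `read_allele_registry`: a data frame with columns `name`,
#'   `alpha_pseudo`, `beta_pseudo`, `pseudo`.
#' @export
read_allele_registry <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  stopifnot(all(c("name", "alpha_pseudo", "beta_pseudo") %in% names(tb)))
  allele_registry(tb$name, paste0(tb$alpha_pseudo, tb$beta_pseudo))
}

#' @rdname read_allele_registry
#' @param registry Data frame as returned by [allele_registry()].
#' @export
write_allele_registry <- function(registry, path) {
  utils::write.table(registry[, c("name", "alpha_pseudo", "beta_pseudo")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_allele_registry
#' @param name Character vector of allele names (unique).
#' @param pseudo Character vector of 34-residue pseudo-sequences.
#' @export
allele_registry <- function(name, pseudo) {
  stopifnot(length(name) == length(pseudo), !anyDuplicated(name),
            all(nchar(pseudo) == 34L), all(is_canonical_aa(pseudo)))
  data.frame(name = name,
             alpha_pseudo = substr(pseudo, 1L, 15L),
             beta_pseudo = substr(pseudo, 16L, 34L),
             pseudo = pseudo,
             stringsAsFactors = FALSE)
}

# Look up pseudo-sequences for a set of allele names, in canonical
# (sorted) name order -- the order used for deterministic argmax
# tie-breaking throughout the model.
registry_lookup <- function(registry, names) {
  names <- sort(unique(names))
  i <- match(names, registry$name)
  if (anyNA(i)) {
    stop("allele(s) not in registry: ", paste(names[is.na(i)], collapse = ", "))
  }
  stats::setNames(registry$pseudo[i], names)
}
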