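#' @keywords internal
"_PACKAGE"

# Canonical amino-acid alphabet and tokenisation.
#
# Token ids: 1..20 canonical residues (alphabetical one-letter codes),
# 21 = padding, 22 = unknown (B, J, O, U, X, Z and anything else).

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

PAD_ID <- 21L
UNK_ID <- 22L
VOCAB_SIZE <- 22L

#' Canonical amino-acid alphabet
#'
#' The 20 one-letter amino-acid codes used throughout the package, in
#' alphabetical order. Position in this vector is the token id of the
#' residue in the model's embedding tables.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() AA_LETTERS

# Split a sequence string into single letters.
aa_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' Tokenise an amino-acid sequence
#'
#' Maps each residue to its integer token id. Non-canonical letters
#' (B, J, O, U, X, Z, ...) map to a dedicated unknown token and raise a
#' warning, mirroring how mass-spectrometry peptide lists occasionally
#' carry ambiguity codes.
#'
#' @param x Character scalar, an amino-acid sequence.
#' @param warn Warn on non-canonical letters (default `TRUE`).
#' @return Integer vector of token ids (1--20 canonical, 22 unknown).
#' @export
tokenize_peptide <- function(x, warn = TRUE) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  ch <- aa_chars(toupper(x))
  ids <- match(ch, AA_LETTERS)
  bad <- is.na(ids)
  if (any(bad)) {
    if (warn) {
      warning(sprintf("non-canonical residue letter(s) %s mapped to unknown token",
                      paste(unique(ch[bad]), collapse = ", ")))
    }
    ids[bad] <- UNK_ID
  }
  as.integer(ids)
}

# Validate that a vector of sequences uses only canonical letters.
is_canonical_aa <- function(x) {
  !grepl(sprintf("[^%s]", paste(AA_LETTERS, collapse = "")), x)
}

# Background amino-acid frequencies resembling the human proteome
# (rounded composition of UniProt human entries), used as an alternative
# to the uniform default of the synthetic generator.
HUMAN_AA_FREQS <- c(
  A = 0.0702, C = 0.0230, D = 0.0474, E = 0.0710, F = 0.0365,
  G = 0.0658, H = 0.0263, I = 0.0433, K = 0.0573, L = 0.0996,
  M = 0.0213, N = 0.0359, P = 0.0631, Q = 0.0477, R = 0.0564,
  S = 0.0833, T = 0.0536, V = 0.0597, W = 0.0122, Y = 0.0266
)

#' Human-proteome-like residue frequencies
#'
#' A fixed 20-vector of amino-acid frequencies resembling the overall
#' composition of the human proteome, normalised to sum to one. Useful
#' as `background_freqs` for [generate_world()] and
#' [generate_proteome()] when uniform backgrounds are too artificial.
#'
#' @return Named numeric vector over [aa_alphabet()], summing to 1.
#' @export
human_aa_freqs <- function() {
  f <- HUMAN_AA_FREQS
  f / sum(f)
}
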