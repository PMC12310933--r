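# Shared fixtures, built in code. Kept deliberately tiny: anything
# expensive (real training runs) lives in the test that needs it.

tiny_config <- function(...) {
  hla2_config(n_blocks = 1L, n_heads = 2L, d_model = 16L, dropout = 0.1, ...)
}

# A deterministic random pseudo-sequence.
rand_pseudo <- function(seed) {
  set.seed(seed)
  paste(sample(aa_alphabet(), 34, replace = TRUE), collapse = "")
}

rand_peptide <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(aa_alphabet(), len, replace = TRUE), collapse = "")
}

# Small shared world for cheap end-to-end checks.
small_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) {
      w <<- generate_world(n_alleles = 3L, n_samples = 3L,
                           positives_per_sample = 60L, polyallelic_max = 1L,
                           n_proteins = 20L, seed = 404L)
    }
    w
  }
})

# Labelled evaluation set (positives + length-matched decoys).
world_eval_set <- function(world, seed = 5L) {
  pos <- world$positives
  dec <- sample_decoys(pos, world$proteome, scenario = 1L, seed = seed,
                       epoch = 1L)
  rbind(data.frame(peptide = pos$peptide, sample_id = pos$sample_id,
                   label = 1L, stringsAsFactors = FALSE),
        data.frame(peptide = dec$peptide, sample_id = dec$sample_id,
                   label = 0L, stringsAsFactors = FALSE))
}
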