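# Small cohorts and matrices shared across test files.  Everything is built
# in code under fixed seeds; nothing is read from disk.

small_cfg <- function(seed = 1L, ...) {
  args <- list(n_tumor = 60, n_normal = 15, n_background_genes = 40, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

toy_matrix <- function(genes = 5, samples = 8, seed = 99) {
  set.seed(seed)
  m <- matrix(rnorm(genes * samples, mean = 5), genes, samples,
              dimnames = list(sprintf("G%02d", seq_len(genes)),
                              sprintf("S%02d", seq_len(samples))))
  m
}

# Two well-separated duplicate blocks of samples: perfectly separable data.
two_block_matrix <- function(per_block = 5, genes = 10) {
  a <- matrix(rep(seq_len(genes), per_block), genes, per_block)
  b <- matrix(rep(rev(seq_len(genes)), per_block), genes, per_block)
  m <- cbind(a, b) + 0  # exact duplicates within each block
  dimnames(m) <- list(sprintf("G%02d", seq_len(genes)),
                      sprintf("S%02d", seq_len(2 * per_block)))
  m
}
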