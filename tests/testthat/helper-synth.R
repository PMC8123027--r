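# Shared small synthetic corpus, generated once per test session.
# Fingerprints of the ~200-molecule pool are cached inside the package,
# so repeated vectorization across test files is cheap.
synth_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_synthetic(synthetic_config(n_reactions = 400L, seed = 42L))
    }
    cache
  }
})

# Brute-force enumeration of all permutations of 1..m (oracle for the
# augmentation tests); returns a list of integer vectors.
enumerate_permutations <- function(m) {
  if (m == 1) return(list(1L))
  out <- list()
  for (p in enumerate_permutations(m - 1)) {
    for (pos in seq_len(m)) {
      out[[length(out) + 1]] <- append(p, m, after = pos - 1)
    }
  }
  out
}
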