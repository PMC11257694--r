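# Shared fixture builders for the statistics tests.

# n_subj symmetric zero-diagonal matrices of standard-normal edge values,
# optionally with a mean shift planted on given edges.
rand_edge_mats <- function(n_subj, n = 20, shift = 0, edges = NULL) {
  lapply(seq_len(n_subj), function(k) {
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- stats::rnorm(n * (n - 1) / 2)
    m <- m + t(m)
    if (!is.null(edges)) {
      for (r in seq_len(nrow(edges))) {
        i <- edges[r, 1]
        j <- edges[r, 2]
        m[i, j] <- m[i, j] + shift
        m[j, i] <- m[i, j]
      }
    }
    m
  })
}
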