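# O(N^2) brute-force Hausdorff oracle (pairwise distances over boundary
# pixels), kept independent of the package implementation.

brute_hausdorff <- function(a, b, label, spacing) {
  onb <- function(p, m) {
    r <- p[1]; c <- p[2]
    r == 1 || c == 1 || r == nrow(m) || c == ncol(m) ||
      !m[r - 1, c] || !m[r + 1, c] || !m[r, c - 1] || !m[r, c + 1]
  }
  bd <- function(m) {
    p <- which(m, arr.ind = TRUE)
    p[apply(p, 1, onb, m = m), , drop = FALSE]
  }
  pa <- bd(a == label)
  pb <- bd(b == label)
  D <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)), Vectorize(function(i, j)
    sqrt(sum(((pa[i, ] - pb[j, ]) * spacing)^2))))
  max(max(apply(D, 1, min)), max(apply(D, 2, min)))
}
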