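# Independent oracles used to cross-check the package's algorithms.

# Exact minimum Steiner tree length for a set of aligned haplotypes under
# unit-weight Hamming distance: Dreyfus-Wagner dynamic programme over the
# candidate vertex grid (every combination of per-column observed states,
# which by the Steiner property suffices). Independent of the network
# builder: no medians, no spanning heuristics.
steiner_min_length <- function(mat) {
  m <- ncol(mat)
  opts <- lapply(seq_len(m), function(j) sort(unique(mat[, j])))
  nV <- prod(lengths(opts))
  stopifnot(nV <= 5000)
  V <- as.matrix(expand.grid(opts, stringsAsFactors = FALSE))
  D <- matrix(0L, nV, nV)
  for (j in seq_len(m)) D <- D + outer(V[, j], V[, j], "!=")
  keyV <- apply(V, 1, paste, collapse = "")
  term <- match(apply(mat, 1, paste, collapse = ""), keyV)
  k <- length(term)
  if (k < 2) return(0)
  full <- 2L^k - 1L
  dp <- matrix(Inf, full, nV)
  bits <- bitwShiftL(1L, 0:(k - 1))
  for (t in seq_len(k)) dp[bits[t], ] <- D[term[t], ]
  for (S in seq_len(full)) {
    members <- which(bitwAnd(S, bits) > 0)
    if (length(members) < 2) next
    tb <- bits[members[1]]
    R <- S - tb
    merge <- rep(Inf, nV)
    sub <- bitwAnd(R - 1L, R)
    repeat {
      S2 <- R - sub
      if (S2 > 0) merge <- pmin(merge, dp[tb + sub, ] + dp[S2, ])
      if (sub == 0L) break
      sub <- bitwAnd(sub - 1L, R)
    }
    dp[S, ] <- apply(D + merge, 2, min)
  }
  min(dp[full, ])
}

# simple string-diff oracle: positions (keys) where two equal-length state
# vectors hold different unambiguous bases
diff_positions <- function(a, b, keys) {
  stopifnot(length(a) == length(b))
  bases <- c("A", "C", "G", "T")
  keys[a != b & a %in% bases & b %in% bases]
}
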