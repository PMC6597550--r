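# All permutations of 1..n (n small), for exhaustive permutation oracles.
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- combinat_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos)
    }
  }
  out
}
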