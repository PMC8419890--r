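# Independent brute-force oracle for the umbrella rank test.
# Enumerates all distinct bin-label arrangements as multiset permutations and
# counts pairs by direct loops over the definition; shares no code with the
# package implementation.

oracle_perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1, 1))
  out <- NULL
  for (u in unique(v)) {
    rest <- v[-match(u, v)]
    out <- rbind(out, cbind(u, oracle_perms(rest)))
  }
  out
}

oracle_u_lt <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + (x < y) + 0.5 * (x == y)
  s
}

oracle_umbrella_S <- function(values, labels, k) {
  r <- k %/% 2
  wrap <- function(x) ((x - 1) %% k) + 1
  sapply(seq_len(k), function(j) {
    rising <- wrap(seq(j - r, j))
    falling <- wrap(seq(j, j + (k - r - 1)))
    s <- 0
    for (i in seq_len(length(rising) - 1))
      for (h in seq(i + 1, length(rising)))
        s <- s + oracle_u_lt(values[labels == rising[i]],
                             values[labels == rising[h]])
    if (length(falling) > 1)
      for (i in seq_len(length(falling) - 1))
        for (h in seq(i + 1, length(falling)))
          s <- s + oracle_u_lt(values[labels == falling[h]],
                               values[labels == falling[i]])
    s
  })
}

oracle_umbrella_p <- function(values, labels) {
  k <- length(unique(labels))
  all_l <- unique(oracle_perms(labels), MARGIN = 1)
  S_obs <- oracle_umbrella_S(values, labels, k)
  Sm <- t(apply(all_l, 1, function(L) oracle_umbrella_S(values, L, k)))
  p <- sapply(seq_len(k), function(j) mean(Sm[, j] >= S_obs[j]))
  list(n_arrangements = nrow(all_l), p_per_peak = p,
       p_rain = min(1, k * min(p)), S_obs = S_obs)
}
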