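# Independent oracle: exact stationary solution of the small open exclusion
# process (uniform initiation alpha, hopping k, termination beta, footprint
# W, no drop-off) by brute-force master-equation enumeration. Used to verify
# the kinetic Monte Carlo engine on lattices small enough to enumerate.

enumerate_tasep_states <- function(L, W) {
  res <- list(integer(0))
  grow <- function(prefix, minpos) {
    for (p in seq(minpos, L)) {
      st <- c(prefix, p)
      res[[length(res) + 1L]] <<- st
      if (p + W <= L) grow(st, p + W)
    }
  }
  if (L >= 1) grow(integer(0), 1L)
  res
}

tasep_exact_current <- function(L, W, alpha, beta, k) {
  states <- enumerate_tasep_states(L, W)
  key <- vapply(states, function(s) paste0("s", paste(s, collapse = ",")), "")
  idx <- stats::setNames(seq_along(states), key)
  n <- length(states)
  Q <- matrix(0, n, n)
  add <- function(from, to, rate) {
    j <- idx[[paste0("s", paste(to, collapse = ","))]]
    Q[from, j] <<- Q[from, j] + rate
  }
  for (i in seq_len(n)) {
    s <- states[[i]]
    m <- length(s)
    if (m == 0 || s[1] > W) add(i, c(1L, s), alpha)
    for (j in seq_len(m)) {
      p <- s[j]
      if (p < L && (j == m || s[j + 1] - p > W)) {
        s2 <- s
        s2[j] <- p + 1L
        add(i, s2, k)
      }
    }
    if (m > 0 && s[m] == L) add(i, s[-m], beta)
  }
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi <- qr.solve(A, b)
  at_stop <- vapply(states, function(s) length(s) > 0 && s[length(s)] == L,
                    logical(1))
  list(current = beta * sum(pi[at_stop]), n_states = n, pi = pi,
       states = states)
}
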