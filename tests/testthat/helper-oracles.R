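# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive and share no code with the package internals.

# Exact signed-rank p-value by enumerating all 2^n sign assignments.
brute_wilcoxon <- function(values, alternative = "greater") {
  v <- values[values != 0]
  n <- length(v)
  r <- rank(abs(v))
  V_obs <- sum(r[v > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.vector(signs %*% r)
  p_ge <- mean(Vs >= V_obs - 1e-9)
  p_le <- mean(Vs <= V_obs + 1e-9)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# All permutations of a vector, by naive recursion.
brute_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in brute_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# Exact one-sided Spearman p-value by enumerating all n! permutations.
brute_spearman <- function(x, y, alternative = "greater") {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  rhos <- vapply(brute_perms(ry), function(p) cor(rx, p), 0)
  switch(alternative,
         greater = mean(rhos >= rho_obs - 1e-9),
         less = mean(rhos <= rho_obs + 1e-9),
         two.sided = min(1, 2 * min(mean(rhos >= rho_obs - 1e-9),
                                    mean(rhos <= rho_obs + 1e-9))))
}

# Literal step-up Benjamini-Hochberg.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- prev
  }
  adj
}

# Wrap a plain matrix + labels as an rdm for unit tests.
manual_rdm <- function(D, labels, metric = "crossnobis") {
  structure(list(D = D, labels = labels, metric = metric), class = "rdm")
}
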