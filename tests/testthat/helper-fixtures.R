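# Shared fixtures and independent oracles, built in code at test time.

# The two-class toy training set: class A = {(1,0),(1,1)}, class B =
# {(0,1),(0,1)}. Laplace conditionals by hand: A -> (0.75, 0.50),
# B -> (0.25, 0.75); priors (0.5, 0.5).
toy_dataset <- function() {
  fp <- rbind(c1 = c(1L, 0L), c2 = c(1L, 1L), c3 = c(0L, 1L), c4 = c(0L, 1L))
  activity_dataset(fp, list("A", "A", "B", "B"), labels = c("A", "B"))
}

# Direct (unlogged) product-arithmetic posterior over all classes -- the
# independent oracle for the log-space implementation. Only valid for
# small m where the products do not underflow.
brute_posterior <- function(x, priors, cond) {
  joints <- vapply(seq_along(priors), function(k) {
    priors[k] * prod(ifelse(x == 1, cond[, k], 1 - cond[, k]))
  }, numeric(1L))
  joints / sum(joints)
}

# Random Laplace-valid parameter set for the oracle-equivalence property.
random_nb_setup <- function(m, L) {
  n_class <- sample(0:30, L, replace = TRUE)
  cond <- vapply(seq_len(L), function(k) {
    n_on <- vapply(rep(n_class[k], m), function(nc) sample(0:nc, 1L), integer(1L))
    (1 + n_on) / (2 + n_class[k])
  }, numeric(m))
  pri <- sample.int(20L, L)
  list(cond = cond, priors = pri / sum(pri),
       x = sample(0:1, m, replace = TRUE))
}

# Exhaustive 2^n enumeration of the signed-rank null: the oracle for the
# convolution-based exact p-value.
brute_signrank_p <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.vector(signs %*% r)
  p_ge <- mean(Vs >= V - 1e-12)
  p_le <- mean(Vs <= V + 1e-12)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

tiny_study_config <- function(seed, null = FALSE) {
  generator_config(n_labels = 20L, n_compounds = 2000L,
                   signal_prob = if (null) 0.015 else 0.25, seed = seed)
}
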