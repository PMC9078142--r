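# Shared fixtures, built in code.

# A deterministic set of parseable drug-like molecules assembled from the
# generator's amide grammar (scaffold + acyl R-group), used wherever a pool
# of realistic structures is needed.
fixture_molecules <- function(n = 100, seed = 7) {
  alpha <- progsat:::substituent_alphabet()
  scaf <- progsat:::scaffold_smiles()
  set.seed(seed)
  r <- sample(alpha$r_group, n, replace = TRUE)
  s <- sample(scaf, n, replace = TRUE)
  tibble::tibble(id = sprintf("fx%03d", seq_len(n)),
                 smiles = paste0("O=C(", r, ")", s))
}

# Random scaled descriptor matrices for scoring-oracle tests.
random_points <- function(n, d = 7, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(n * d), nrow = n,
         dimnames = list(paste0("p", seq_len(n)), NULL))
}

# Naive O(n^2) oracles, kept deliberately independent of the package
# implementations (plain double loops, no shared helpers).
oracle_global_radius <- function(V, fraction = 0.01) {
  n <- nrow(V)
  k <- max(1, floor(fraction * (n - 1)))
  pooled <- c()
  for (i in seq_len(n)) {
    di <- c()
    for (j in seq_len(n)) {
      if (i != j) di <- c(di, sqrt(sum((V[i, ] - V[j, ])^2)))
    }
    pooled <- c(pooled, sort(di)[seq_len(k)])
  }
  stats::median(pooled)
}

oracle_members_within <- function(X, Y, r) {
  # which rows of X lie within r of at least one row of Y
  out <- logical(nrow(X))
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(nrow(Y))) {
      if (sqrt(sum((X[i, ] - Y[j, ])^2)) <= r) { out[i] <- TRUE; break }
    }
  }
  out
}

oracle_local_radius <- function(A) {
  d <- c()
  n <- nrow(A)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) d <- c(d, sqrt(sum((A[i, ] - A[j, ])^2)))
  }
  stats::median(d)
}
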