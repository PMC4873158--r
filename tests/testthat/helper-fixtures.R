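# Small fixtures built in code, shared across test files.

# Unpaired study with iid N(0,1) noise (pure null unless shifted afterwards).
make_null_study <- function(n_genes = 50, n_case = 10, n_control = 10,
                            seed = 1, name = "null") {
  set.seed(seed)
  X <- matrix(rnorm(n_genes * (n_case + n_control)), n_genes)
  rownames(X) <- sprintf("G%04d", seq_len(n_genes))
  colnames(X) <- sprintf("S%03d", seq_len(ncol(X)))
  ExpressionStudy(name, X, design = "unpaired",
                  group = rep(c("case", "control"), c(n_case, n_control)))
}

make_paired_study <- function(n_genes = 20, n_subjects = 6, seed = 1,
                              name = "paired") {
  set.seed(seed)
  n <- 2 * n_subjects
  X <- matrix(rnorm(n_genes * n), n_genes)
  rownames(X) <- sprintf("G%04d", seq_len(n_genes))
  subject <- rep(sprintf("P%02d", seq_len(n_subjects)), each = 2)
  timepoint <- rep(c("early", "late"), n_subjects)
  colnames(X) <- paste0(subject, "_", timepoint)
  ExpressionStudy(name, X, design = "paired", subject = subject,
                  timepoint = timepoint)
}

# Independent brute-force TOM oracle: literal triple loop over
# TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(K_i, K_j) + 1 - a_ij).
tom_brute <- function(A) {
  diag(A) <- 0
  p <- nrow(A)
  K <- rowSums(A)
  TOM <- diag(p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    num <- A[i, j]
    for (u in seq_len(p)) if (u != i && u != j) num <- num + A[i, u] * A[u, j]
    TOM[i, j] <- num / (min(K[i], K[j]) + 1 - A[i, j])
  }
  dimnames(TOM) <- dimnames(A)
  TOM
}

# Random valid unsigned adjacency (symmetric, entries in [0,1], zero diag).
random_adjacency <- function(p, seed) {
  set.seed(seed)
  A <- matrix(runif(p * p), p)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  rownames(A) <- colnames(A) <- sprintf("g%02d", seq_len(p))
  A
}

# One-set design used by several planted-signal tests.
one_set_design <- function(n_genes, set_size, effect_size, n_case, n_control,
                           seed, n_hubs = 0, rho_hub = 0, rho_background = 0,
                           affected = "all", effect_multiplier = 1,
                           regulator = NULL, direction = +1) {
  new_synthetic_design(
    n_genes = n_genes,
    studies = list(list(name = "A", design = "unpaired",
                        n_case = n_case, n_control = n_control)),
    gene_sets = list(list(name = "S1", members = seq_len(set_size),
                          direction = direction, effect_size = effect_size,
                          affected = affected)),
    hubs = list(n_hubs = n_hubs, rho_hub = rho_hub,
                rho_background = rho_background,
                effect_multiplier = effect_multiplier),
    regulator = regulator, seed = seed)
}
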