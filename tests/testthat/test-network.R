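test_that("TOM has its closed-form values on degenerate adjacencies", {
  # three mutually perfectly correlated genes: TOM = 1 everywhere
  A1 <- matrix(1, 3, 3) - diag(3)
  expect_true(all(abs(tom_from_adjacency(A1) - 1) < 1e-15))
  # empty graph: off-diagonal TOM = 0
  A0 <- matrix(0, 4, 4)
  T0 <- tom_from_adjacency(A0)
  expect_true(all(T0[upper.tri(T0)] == 0))
  expect_true(all(diag(T0) == 1))
})

test_that("TOM equals the brute-force triple-loop oracle", {
  for (s in 1:10) {
    set.seed(s)
    p <- sample(5:25, 1)
    n <- sample(10:30, 1)
    X <- matrix(rnorm(p * n), p,
                dimnames = list(sprintf("g%02d", 1:p), sprintf("s%02d", 1:n)))
    st <- ExpressionStudy("rnd", X,
                          group = rep(c("case", "control"),
                                      length.out = n))
    beta <- sample(c(1, 2, 4, 6, 9), 1)
    net <- tom_matrix(st, beta = beta)
    expect_lt(max(abs(net$tom - tom_brute(net$adjacency))), 1e-10)
    expect_equal(net$connectivity, rowSums(net$tom) - 1)
  }
})

test_that("TOM is bounded in [0,1] and invariant to common sample permutation", {
  for (s in 1:30) {
    TT <- tom_from_adjacency(random_adjacency(sample(4:15, 1), seed = s))
    expect_true(all(TT >= 0 & TT <= 1 + 1e-12))
  }
  st <- make_null_study(n_genes = 12, n_case = 8, n_control = 8, seed = 77)
  net <- tom_matrix(st, beta = 5)
  set.seed(1)
  perm <- sample(ncol(st$matrix))
  stp <- st
  stp$matrix <- st$matrix[, perm]
  stp$group <- st$group[perm]
  expect_equal(tom_matrix(stp, beta = 5)$tom, net$tom)
})

test_that("raising the soft power weakly decreases every adjacency", {
  st <- make_null_study(n_genes = 15, seed = 13)
  a4 <- tom_matrix(st, beta = 4)$adjacency
  a5 <- tom_matrix(st, beta = 5)$adjacency
  expect_true(all(a5 <= a4 + 1e-15))
  # and sparsifies the called edge set under a fixed cutoff
  expect_lte(sum(a5 > 0.1), sum(a4 > 0.1))
})

test_that("zero-variance genes are dropped from the network", {
  st <- make_null_study(n_genes = 10, seed = 41)
  st$matrix[4, ] <- 2
  expect_message(net <- tom_matrix(st, beta = 6), "zero-variance")
  expect_identical(length(net$genes), 9L)
})

test_that("soft-power selection reaches scale-free fit on modular data", {
  # five hub-structured modules (loadings tapering from rho = 0.7) plus
  # unconnected noise genes: the connectivity spread co-expression data show
  set.seed(99)
  n <- 80
  bsize <- 20
  X <- do.call(rbind, lapply(1:5, function(b) {
    f <- rnorm(n)
    rg <- 0.7 * seq(1, 1 / bsize, length.out = bsize)
    sqrt(rg) * matrix(f, bsize, n, byrow = TRUE) +
      sqrt(1 - rg) * matrix(rnorm(bsize * n), bsize, n)
  }))
  X <- rbind(X, matrix(rnorm(100 * n), 100, n))
  dimnames(X) <- list(sprintf("g%03d", seq_len(nrow(X))),
                      sprintf("s%02d", seq_len(n)))
  st <- ExpressionStudy("blocks", X,
                        group = rep(c("case", "control"), length.out = n))
  sel <- pick_soft_power(st)
  expect_lte(sel$beta, 12)
  expect_gte(max(sel$fit$sft_r2, na.rm = TRUE), 0.8)
  # determinism: same input, same choice
  expect_identical(pick_soft_power(st)$beta, sel$beta)
})

test_that("uncorrelated noise falls back with a warning", {
  st <- make_null_study(n_genes = 30, n_case = 30, n_control = 30, seed = 55)
  expect_warning(sel <- pick_soft_power(st, powers = c(1, 2)), "power")
  expect_true(sel$beta %in% c(1, 2, 6))
})

test_that("top-quantile edge calling keeps the expected number of pairs", {
  st <- make_null_study(n_genes = 15, n_case = 10, n_control = 10, seed = 61)
  net <- tom_matrix(st, beta = 4)
  calls <- call_edges(net, rule = "top_quantile", top_q = 0.03)
  # 105 pairs, distinct TOM values: round(0.03 * 105) = 3 edges
  expect_identical(sum(calls$edges$called), 3L)
  expect_identical(nrow(calls$edges), 105L)
  expect_false(any(duplicated(calls$edges[, c("gene_i", "gene_j")])))
  # tied pairs at the cutoff are all kept
  fake <- net
  fake$tom[,] <- 0.5
  diag(fake$tom) <- 1
  tied <- call_edges(fake, rule = "top_quantile", top_q = 0.03)
  expect_identical(sum(tied$edges$called), 105L)
})

test_that("edge q-values follow Benjamini-Hochberg on permutation p-values", {
  st <- make_null_study(n_genes = 10, n_case = 12, n_control = 12, seed = 62)
  net <- tom_matrix(st, beta = 3)
  calls <- call_edges(net, rule = "fdr", B = 100, fdr_q = 0.05, seed = 5)
  expect_equal(calls$edges$q, p.adjust(calls$edges$p, method = "BH"))
  expect_true(all(calls$edges$p >= 1 / (100 * nrow(calls$edges) + 1)))
  expect_true(all(calls$edges$q >= calls$edges$p - 1e-15))
})

test_that("strongly correlated blocks are called and null pairs are not", {
  d <- one_set_design(n_genes = 30, set_size = 10, effect_size = 0,
                      n_case = 15, n_control = 15, seed = 71,
                      n_hubs = 10, rho_hub = 0.8, rho_background = 0.8)
  st <- simulate_study(d, "A")$study
  net <- tom_matrix(st, beta = 6)
  calls <- call_edges(net, rule = "fdr", B = 100, fdr_q = 0.05, seed = 9)
  called <- calls$edges[calls$edges$called, ]
  block <- sprintf("G%05d", 1:10)
  expect_gt(sum(called$gene_i %in% block & called$gene_j %in% block), 35)
  expect_gt(mean(called$gene_i %in% block & called$gene_j %in% block), 0.6)
})

test_that("connectivity-significance correlation matches a hand oracle", {
  st <- make_null_study(n_genes = 4, n_case = 5, n_control = 5, seed = 81)
  net <- tom_matrix(st, beta = 2)
  net$connectivity[] <- c(3, 2, 1, 0.5)
  de <- welch_t(st)
  de$p <- 10^-c(2, 1.5, 1, 0.5)
  de$neglog10p <- -log10(de$p)
  cs <- connectivity_significance(net, de)
  # independent Pearson computation from first principles
  x <- c(3, 2, 1, 0.5); y <- c(2, 1.5, 1, 0.5)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cs$r, r_hand, tolerance = 1e-12)
  expect_identical(cs$table$gene[1], net$genes[which.max(net$connectivity)])

  flat <- net
  flat$connectivity[] <- 1
  expect_error(connectivity_significance(flat, de), "zero variance")
})

test_that("edge and node tables write called edges and DE classes", {
  st <- make_null_study(n_genes = 10, n_case = 10, n_control = 10, seed = 91)
  st$matrix[1, st$group == "case"] <- st$matrix[1, st$group == "case"] + 3
  st$matrix[2, st$group == "case"] <- st$matrix[2, st$group == "case"] - 3
  de <- welch_t(st)
  net <- tom_matrix(st, beta = 4)
  calls <- call_edges(net, rule = "top_quantile", top_q = 0.1, de = de)
  expect_identical(calls$nodes$de_class[1], "up-significant")
  expect_identical(calls$nodes$de_class[2], "down-significant")
  paths <- write_edges(calls, tempfile("net_"))
  edges <- read.delim(paths["edges"])
  expect_identical(nrow(edges), sum(calls$edges$called))
  nodes <- read.delim(paths["nodes"])
  expect_identical(nrow(nodes), 10L)
})
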