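write_tsv_fixture <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

test_that("TSV expression matrices read with their sample annotation", {
  f <- tempfile(fileext = ".tsv")
  write_tsv_fixture(data.frame(feature_id = c("g1", "g2", "g3"),
                               s1 = c(1, 2, 3), s2 = c(4, 5, 6)), f)
  ann <- data.frame(sample_id = c("s1", "s2"), group = c("case", "control"))
  st <- read_expression(f, ann, name = "demo")
  expect_identical(dim(st$matrix), c(3L, 2L))
  expect_identical(rownames(st$matrix), c("g1", "g2", "g3"))
  expect_identical(st$group, c("case", "control"))
  # annotation mismatch is an error
  expect_error(read_expression(f, data.frame(sample_id = "s1",
                                             group = "case")),
               "without annotation")
})

test_that("features with missing values are dropped with a message", {
  f <- tempfile(fileext = ".tsv")
  write_tsv_fixture(data.frame(feature_id = c("g1", "g2"),
                               s1 = c(1, NA), s2 = c(4, 5)), f)
  ann <- data.frame(sample_id = c("s1", "s2"), group = c("case", "control"))
  expect_message(st <- read_expression(f, ann), "missing values dropped")
  expect_identical(rownames(st$matrix), "g1")
})

test_that("series-matrix dialect parses the fenced table identically to TSV", {
  tsv <- tempfile(fileext = ".tsv")
  write_tsv_fixture(data.frame(feature_id = c("g1", "g2", "g3"),
                               GSM1 = c(7.1, 8.2, 9.3),
                               GSM2 = c(6.5, 8.0, 9.9)), tsv)
  sm <- tempfile(fileext = ".txt")
  writeLines(c(
    "!Series_title\t\"a synthetic series\"",
    "!Series_platform_id\t\"GPL0000\"",
    "!series_matrix_table_begin",
    "\"ID_REF\"\t\"GSM1\"\t\"GSM2\"",
    "\"g1\"\t7.1\t6.5",
    "\"g2\"\t8.2\t8.0",
    "\"g3\"\t9.3\t9.9",
    "!series_matrix_table_end"), sm)
  ann <- data.frame(sample_id = c("GSM1", "GSM2"),
                    group = c("case", "control"))
  a <- read_expression(tsv, ann)
  b <- read_expression(sm, ann, dialect = "series_matrix")
  expect_equal(b$matrix, a$matrix, ignore_attr = FALSE)
  expect_error(read_expression(tsv, ann, dialect = "series_matrix"), "fences")
})

test_that("raw-scale matrices trigger the log2 heuristic", {
  f <- tempfile(fileext = ".tsv")
  write_tsv_fixture(data.frame(feature_id = c("g1", "g2"),
                               s1 = c(100, 200), s2 = c(400, 800)), f)
  ann <- data.frame(sample_id = c("s1", "s2"), group = c("case", "control"))
  expect_message(st <- read_expression(f, ann), "log2")
  expect_equal(st$matrix["g1", "s1"], log2(101))
})

test_that("quantile normalization has its defining properties", {
  # hand-computed mean order statistics: [1,2,3] and [4,5,6] -> [2.5,3.5,4.5]
  X <- matrix(c(1, 2, 3, 4, 5, 6), 3,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  st <- ExpressionStudy("qn", X, group = c("case", "control"))
  qn <- quantile_normalize(st)
  expect_equal(unname(qn$matrix[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn$matrix[, 2]), c(2.5, 3.5, 4.5))

  # random matrix: all columns share the same sorted values; ranks preserved;
  # idempotent; identical columns are a fixed point
  rnd <- make_null_study(n_genes = 40, n_case = 4, n_control = 4, seed = 3)
  q1 <- quantile_normalize(rnd)
  ref <- unname(sort(q1$matrix[, 1]))
  for (j in 2:ncol(q1$matrix))
    expect_equal(unname(sort(q1$matrix[, j])), ref)
  for (j in seq_len(ncol(q1$matrix)))
    expect_identical(order(q1$matrix[, j]), order(rnd$matrix[, j]))
  q2 <- quantile_normalize(q1)
  expect_equal(q2$matrix, q1$matrix)

  same <- ExpressionStudy("same", matrix(c(1, 5, 9), 3, 4,
                                         dimnames = list(paste0("g", 1:3),
                                                         paste0("s", 1:4))),
                          group = c("case", "case", "control", "control"))
  expect_equal(quantile_normalize(same)$matrix, same$matrix)

  single <- same
  single$matrix <- single$matrix[, 1, drop = FALSE]
  expect_error(quantile_normalize(single), "at least 2 samples")
})

test_that("probe collapsing keeps the most significant probe per gene", {
  st <- make_null_study(n_genes = 6, n_case = 8, n_control = 8, seed = 4)
  # plant a strong shift on G0002 so it is clearly the better probe for geneB
  st$matrix["G0002", st$group == "case"] <-
    st$matrix["G0002", st$group == "case"] + 3
  map <- data.frame(probe = sprintf("G%04d", 1:5),
                    gene = c("geneA", "geneB", "geneB", "geneC", "geneD"))
  de <- welch_t(st)
  expect_message(coll <- collapse_probes(st, map, de), "without a gene mapping")
  expect_setequal(rownames(coll$matrix), c("geneA", "geneB", "geneC", "geneD"))
  expect_equal(unname(coll$matrix["geneB", ]), unname(st$matrix["G0002", ]))
  # single-probe genes pass through unchanged
  expect_equal(unname(coll$matrix["geneA", ]), unname(st$matrix["G0001", ]))
  # output gene count equals the number of distinct mapped genes
  expect_identical(nrow(coll$matrix), length(unique(map$gene)))
})

test_that("probe-collapsing ties break by |t| then lexicographic probe id", {
  # two probes with identical p (sign-flipped copies -> same |t|, same p):
  # lexicographically smaller probe id wins
  X <- rbind(a_probe2 = c(1, 2, 3, 4, 5, 6, 7, 9),
             a_probe1 = -c(1, 2, 3, 4, 5, 6, 7, 9))
  colnames(X) <- paste0("s", 1:8)
  st <- ExpressionStudy("tie", X, group = rep(c("case", "control"), each = 4))
  de <- welch_t(st)
  map <- data.frame(probe = c("a_probe1", "a_probe2"), gene = c("gA", "gA"))
  coll <- collapse_probes(st, map, de)
  expect_identical(rownames(coll$matrix), "gA")
  expect_equal(unname(coll$matrix["gA", ]), unname(X["a_probe1", ]))

  # oracle enumeration of the full rule over a replicated-probe study
  base <- make_null_study(n_genes = 8, n_case = 6, n_control = 6, seed = 9)
  rp <- replicate_probes(base, k_probes = 3, seed = 2)
  de_p <- welch_t(rp$study)
  coll2 <- collapse_probes(rp$study, rp$map, de_p)
  chosen <- vapply(unique(rp$map$gene), function(g) {
    cand <- rp$map$probe[rp$map$gene == g]
    sub <- de_p[match(cand, de_p$gene), ]
    sub <- sub[order(sub$p, -abs(sub$t), sub$gene), ]
    sub$gene[1]
  }, character(1))
  for (g in names(chosen))
    expect_equal(unname(coll2$matrix[g, ]),
                 unname(rp$study$matrix[chosen[[g]], ]))
})

test_that("GMT files round-trip and enforce set invariants", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("TLR\tdesc\tTLR2\tTLR4",
               "TCR\tanother\tCD3D\tCD3E\tCD247"), f)
  gs <- read_gmt(f)
  expect_identical(gs$sets$TLR, c("TLR2", "TLR4"))
  expect_identical(length(gs$sets$TCR), 3L)

  dup <- tempfile(fileext = ".gmt")
  writeLines("S\td\tB\tA\tB\tC", dup)
  expect_message(gd <- read_gmt(dup), "duplicate symbols")
  expect_identical(gd$sets$S, c("B", "A", "C"))

  bad <- tempfile(fileext = ".gmt")
  writeLines("ONLYNAME\tdesc", bad)
  expect_error(read_gmt(bad), "malformed")

  out <- tempfile(fileext = ".gmt")
  write_gmt(gs, out)
  expect_identical(read_gmt(out)$sets, gs$sets)
})

test_that("mapped sizes distinguish nominal and platform-mapped set size", {
  st <- make_null_study(n_genes = 10)
  gs <- GeneSetCollection(list(S1 = c("G0001", "G0002", "NOT_ON_ARRAY"),
                               S2 = c("G0003")))
  ms <- mapped_sizes(st, gs)
  expect_identical(ms$size, c(3L, 1L))
  expect_identical(ms$mapped, c(2L, 1L))
})

test_that("expression studies round-trip through write_expression", {
  st <- make_null_study(n_genes = 5, n_case = 3, n_control = 3, seed = 6)
  prefix <- tempfile("study_")
  paths <- write_expression(st, prefix)
  back <- read_expression(paths["expr"], paths["samples"], name = st$name,
                          log_check = FALSE)
  expect_equal(back$matrix, st$matrix, tolerance = 1e-12)
  expect_identical(back$group, st$group)

  pst <- make_paired_study(n_genes = 4, n_subjects = 3, seed = 7)
  paths2 <- write_expression(pst, tempfile("paired_"))
  back2 <- read_expression(paths2["expr"], paths2["samples"], name = pst$name,
                           log_check = FALSE)
  expect_identical(back2$design, "paired")
  expect_identical(back2$subject, pst$subject)
})
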