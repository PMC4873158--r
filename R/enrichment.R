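# One round of per-gene p-values under the study's exchangeability null:
# unpaired -> permuted group labels; paired -> random sign flip of each
# subject's late - early difference.
.null_pvec <- function(X, is_case = NULL, D = NULL) {
  if (!is.null(is_case)) {
    .welch_rows(X, sample(is_case))$p
  } else {
    signs <- sample(c(-1, 1), ncol(D), replace = TRUE)
    .paired_rows(sweep(D, 2L, signs, `*`))$p
  }
}

#' Permutation test for enrichment of differentially expressed genes
#'
#' For each gene set, counts the mapped member genes reaching `p < alpha` in
#' the study's per-gene differential expression and assesses the count
#' against a permutation null. Under `scheme = "label_permutation"` the group
#' labels are permuted (paired designs: each subject's late - early
#' difference is randomly sign-flipped) and the per-gene p-values recomputed
#' each round, which preserves the gene-gene correlation structure. Under
#' `scheme = "gene_sampling"` the observed significance calls are fixed and
#' m genes are drawn at random from the study per round (a competitive
#' null). The permutation p-value is `(1 + #{k_null >= k_obs}) / (B + 1)`.
#'
#' @param study an [ExpressionStudy] (the full, uncollapsed-to-sets matrix).
#' @param sets a [GeneSetCollection].
#' @param alpha per-gene significance threshold (default 0.05).
#' @param B number of permutations (>= 100; default 1000).
#' @param scheme `"label_permutation"` (default) or `"gene_sampling"`.
#' @param seed integer seed for the permutations.
#' @return An `EnrichmentResult` data frame with one row per set: `study`,
#'   `set`, `m` (mapped size), `k` (significant members), `proportion`,
#'   `label` (the printed "k/m (pct%)" string), `perm_p`, `B`, `scheme`.
#'   Sets with no mapped genes are skipped with a message.
#' @export
enrichment_test <- function(study, sets, alpha = 0.05, B = 1000,
                            scheme = c("label_permutation", "gene_sampling"),
                            seed = 1) {
  stopifnot(inherits(study, "ExpressionStudy"),
            inherits(sets, "GeneSetCollection"))
  scheme <- match.arg(scheme)
  if (B < 100) stop("B must be at least 100")
  genes <- rownames(study$matrix)
  members <- lapply(sets$sets, function(s) which(genes %in% s))
  skip <- vapply(members, length, integer(1)) == 0L
  if (any(skip)) {
    .msg("set(s) with no mapped genes skipped: ",
         paste(names(members)[skip], collapse = ", "))
    members <- members[!skip]
  }
  if (!length(members)) stop("no gene set maps into the study")

  de <- de_test(study)
  sig_obs <- de$p < alpha
  k_obs <- vapply(members, function(ix) sum(sig_obs[ix]), integer(1))
  m <- vapply(members, length, integer(1))

  set.seed(seed)
  exceed <- integer(length(members))
  if (scheme == "label_permutation") {
    is_case <- if (study$design == "unpaired") study$group == "case" else NULL
    D <- if (study$design == "paired") .paired_diffs(study) else NULL
    X <- study$matrix
    for (b in seq_len(B)) {
      p_null <- .null_pvec(X, is_case, D)
      sig <- p_null < alpha
      k_null <- vapply(members, function(ix) sum(sig[ix]), integer(1))
      exceed <- exceed + (k_null >= k_obs)
    }
  } else {
    n_genes <- length(genes)
    for (b in seq_len(B)) {
      for (j in seq_along(members)) {
        k_null <- sum(sig_obs[sample.int(n_genes, m[j])])
        exceed[j] <- exceed[j] + (k_null >= k_obs[j])
      }
    }
  }
  res <- data.frame(study = study$name, set = names(members), m = m, k = k_obs,
                    proportion = k_obs / m,
                    label = format_enrichment(k_obs, m),
                    perm_p = (1 + exceed) / (B + 1), B = B, scheme = scheme,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "alpha") <- alpha
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}

#' Format an enrichment proportion as "k/m (pct%)"
#'
#' @param k number of significant mapped genes.
#' @param m mapped set size.
#' @return Character vector of labels, e.g. `"53/104 (51%)"`.
#' @export
format_enrichment <- function(k, m) {
  sprintf("%d/%d (%d%%)", as.integer(k), as.integer(m),
          as.integer(round(100 * k / m)))
}

#' Tabulate enrichment results across studies
#'
#' Arranges per-study [enrichment_test()] results into a sets x studies grid
#' of "k/m (pct%)" labels, with the machine-readable long table attached.
#'
#' @param results a list of `EnrichmentResult` objects (or one).
#' @return A data frame with one row per set and one label column per study;
#'   `attr(, "long")` holds the row-bound machine-readable results.
#' @export
summarize_enrichment <- function(results) {
  if (inherits(results, "EnrichmentResult")) results <- list(results)
  long <- do.call(rbind, lapply(results, as.data.frame))
  if (!nrow(long)) stop("no enrichment results to summarize")
  studies <- unique(long$study)
  sets <- unique(long$set)
  grid <- data.frame(set = sets, stringsAsFactors = FALSE)
  for (st in studies) {
    sub <- long[long$study == st, ]
    grid[[st]] <- sub$label[match(sets, sub$set)]
  }
  attr(grid, "long") <- long
  grid
}
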