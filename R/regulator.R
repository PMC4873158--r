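#' Correlate a regulator gene with every pathway gene
#'
#' Computes, across all samples of a study (cases and controls pooled), the
#' Pearson correlation between a designated regulator gene (DNMT1 in the
#' motivating analysis) and each gene of each set, with the analytic
#' t-transform p-value, plus per-set summaries (mean r, fraction of positive
#' correlations). Genes are ranked by |r| for the "most correlated with the
#' regulator" report. Uses the same correlation kernel as [concordance()].
#'
#' @param study an [ExpressionStudy] containing the regulator.
#' @param sets a [GeneSetCollection].
#' @param regulator gene symbol of the regulator.
#' @param group optional sensitivity restriction: `"case"` or `"control"`
#'   (unpaired designs only); default uses all samples.
#' @return A `RegulatorCorrelation` list: `study`, `regulator`, `genes`
#'   (data frame `gene`, `set`, `r`, `p`, sorted by |r| descending) and
#'   `set_summary` (data frame `set`, `n`, `mean_r`, `fraction_positive`).
#' @export
regulator_correlations <- function(study, sets, regulator, group = NULL) {
  stopifnot(inherits(study, "ExpressionStudy"),
            inherits(sets, "GeneSetCollection"))
  X <- study$matrix
  if (!is.null(group)) {
    if (study$design != "unpaired")
      stop("group restriction applies to unpaired designs only")
    X <- X[, study$group == group, drop = FALSE]
  }
  if (!regulator %in% rownames(X)) stop("regulator not found: ", regulator)
  reg <- X[regulator, ]
  if (stats::sd(reg) == 0) stop("regulator has zero variance")
  rows <- list()
  for (nm in names(sets$sets)) {
    members <- setdiff(intersect(sets$sets[[nm]], rownames(X)), regulator)
    if (!length(members)) next
    rp <- t(vapply(members, function(g) {
      pr <- .pearson_r_p(reg, X[g, ])
      c(pr$r, pr$p)
    }, numeric(2)))
    rows[[nm]] <- data.frame(gene = members, set = nm, r = rp[, 1L],
                             p = rp[, 2L], row.names = NULL,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no set gene present in the study")
  genes <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  set_summary <- do.call(rbind, lapply(split(genes, genes$set), function(d) {
    data.frame(set = d$set[1L], n = nrow(d), mean_r = mean(d$r),
               fraction_positive = mean(d$r > 0), stringsAsFactors = FALSE)
  }))
  rownames(set_summary) <- NULL
  genes <- genes[order(-abs(genes$r)), , drop = FALSE]
  rownames(genes) <- NULL
  obj <- list(study = study$name, regulator = regulator, genes = genes,
              set_summary = set_summary)
  class(obj) <- "RegulatorCorrelation"
  obj
}

#' Differential expression of the regulator gene
#'
#' Extracts the regulator's row of the study's per-gene differential
#' expression and labels its direction.
#'
#' @param study an [ExpressionStudy] containing the regulator.
#' @param regulator gene symbol.
#' @param de optional precomputed `DEResult` for the study (recomputed with
#'   [de_test()] if omitted).
#' @return List with `gene`, `t`, `p`, `direction` (`"decreased"`,
#'   `"increased"` or `"unchanged"`).
#' @export
regulator_de <- function(study, regulator, de = NULL) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (!regulator %in% rownames(study$matrix))
    stop("regulator not found: ", regulator)
  if (is.null(de)) de <- de_test(study)
  row <- de[de$gene == regulator, , drop = FALSE]
  list(gene = regulator, t = row$t, p = row$p,
       direction = if (row$t < 0) "decreased"
                   else if (row$t > 0) "increased" else "unchanged")
}
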