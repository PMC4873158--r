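#' Cross-study concordance of t statistics within gene sets
#'
#' For each gene set, computes the Pearson correlation between the two
#' studies' per-gene t statistics over the set members measured in both
#' studies, with the analytic two-sided p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))`, df = n - 2. Sets with fewer than
#' three common genes are skipped with a message.
#'
#' @param de_a,de_b `DEResult` objects from two studies (see [de_test()]).
#' @param sets a [GeneSetCollection].
#' @return A `ConcordanceResult` data frame with one row per set: `study_a`,
#'   `study_b`, `set`, `n_common`, `r`, `p`. The per-set scatter data
#'   (`gene`, `t_a`, `t_b`, plus an identity-line flag for plotting) are in
#'   `attr(, "scatter")`.
#' @export
concordance <- function(de_a, de_b, sets) {
  stopifnot(inherits(de_a, "DEResult"), inherits(de_b, "DEResult"),
            inherits(sets, "GeneSetCollection"))
  rows <- list()
  scatter <- list()
  for (nm in names(sets$sets)) {
    common <- intersect(intersect(sets$sets[[nm]], de_a$gene), de_b$gene)
    if (length(common) < 3L) {
      .msg("set '", nm, "' has fewer than 3 common genes; skipped")
      next
    }
    ta <- de_a$t[match(common, de_a$gene)]
    tb <- de_b$t[match(common, de_b$gene)]
    pr <- .pearson_r_p(ta, tb)
    rows[[nm]] <- data.frame(study_a = attr(de_a, "study"),
                             study_b = attr(de_b, "study"), set = nm,
                             n_common = pr$n, r = pr$r, p = pr$p,
                             stringsAsFactors = FALSE)
    scatter[[nm]] <- data.frame(set = nm, gene = common, t_a = ta, t_b = tb,
                                identity_line = TRUE,
                                stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no set had >= 3 common genes")
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(res, "scatter") <- do.call(rbind, c(scatter,
                                           list(make.row.names = FALSE)))
  class(res) <- c("ConcordanceResult", "data.frame")
  res
}

#' Concordance matrix across all study pairs
#'
#' Arranges pairwise [concordance()] results into a sets x study-pairs grid
#' of correlation coefficients, with each set's min-max range formatted to
#' two decimals ("lo–hi").
#'
#' @param results list of `ConcordanceResult` objects (one per study pair).
#' @return Data frame with one row per set, one `r` column per pair, and a
#'   `range` column; `attr(, "long")` holds the combined long table.
#' @export
concordance_matrix <- function(results) {
  if (inherits(results, "ConcordanceResult")) results <- list(results)
  long <- do.call(rbind, lapply(results, as.data.frame))
  long$pair <- paste(long$study_a, long$study_b, sep = " vs ")
  sets <- unique(long$set)
  grid <- data.frame(set = sets, stringsAsFactors = FALSE)
  for (pr in unique(long$pair)) {
    sub <- long[long$pair == pr, ]
    grid[[pr]] <- sub$r[match(sets, sub$set)]
  }
  rng <- t(vapply(sets, function(s) range(long$r[long$set == s]),
                  numeric(2)))
  grid$range <- format_r_range(rng[, 1L], rng[, 2L])
  attr(grid, "long") <- long
  grid
}

#' Format a correlation range as "lo–hi" to two decimals
#'
#' @param lo,hi numeric vectors of range endpoints.
#' @return Character vector, e.g. `"0.57–0.71"`; a degenerate range
#'   collapses to a single value.
#' @export
format_r_range <- function(lo, hi) {
  ifelse(sprintf("%.2f", lo) == sprintf("%.2f", hi),
         sprintf("%.2f", lo),
         sprintf("%.2f–%.2f", lo, hi))
}
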