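# Vectorized row-wise two-sample Welch t. Genes with zero pooled standard
# error get t = 0, p = 1 (degenerate contract; count returned for logging).
.welch_rows <- function(X, is_case) {
  X1 <- X[, is_case, drop = FALSE]
  X0 <- X[, !is_case, drop = FALSE]
  n1 <- ncol(X1); n0 <- ncol(X0)
  m1 <- rowMeans(X1); m0 <- rowMeans(X0)
  v1 <- .row_vars(X1); v0 <- .row_vars(X0)
  se2 <- v1 / n1 + v0 / n0
  zero <- se2 <= 0
  tt <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  tt[zero] <- 0
  df[zero] <- n1 + n0 - 2
  p <- 2 * stats::pt(-abs(tt), df)
  p[zero] <- 1
  list(t = tt, p = p, df = df, n_zero = sum(zero))
}

# Vectorized row-wise one-sample t on a matrix of paired differences.
.paired_rows <- function(D) {
  n <- ncol(D)
  m <- rowMeans(D)
  v <- .row_vars(D)
  zero <- v <= 0
  tt <- m / sqrt(v / n)
  tt[zero] <- 0
  p <- 2 * stats::pt(-abs(tt), n - 1)
  p[zero] <- 1
  list(t = tt, p = p, df = rep(n - 1, length(m)), n_zero = sum(zero))
}

# late - early difference matrix, one column per subject.
.paired_diffs <- function(study) {
  subj <- unique(study$subject)
  li <- vapply(subj, function(s)
    which(study$subject == s & study$timepoint == "late"), integer(1))
  ei <- vapply(subj, function(s)
    which(study$subject == s & study$timepoint == "early"), integer(1))
  D <- study$matrix[, li, drop = FALSE] - study$matrix[, ei, drop = FALSE]
  colnames(D) <- subj
  D
}

.de_result <- function(study, tt, p, df, n_info) {
  res <- data.frame(gene = rownames(study$matrix), t = unname(tt),
                    p = unname(p), neglog10p = -log10(unname(p)),
                    direction = sign(unname(tt)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "study") <- study$name
  attr(res, "design") <- study$design
  attr(res, "n") <- n_info
  attr(res, "df") <- df
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Per-gene Welch t test (unpaired case vs control)
#'
#' Computes, for every feature, the Welch unequal-variance t statistic
#' oriented case minus control, its Satterthwaite degrees of freedom and the
#' two-sided p-value. Features with zero variance in both groups are reported
#' as t = 0, p = 1 (with a message).
#'
#' @param study an unpaired [ExpressionStudy] with >= 2 samples per group.
#' @return A `DEResult` data frame: `gene`, `t`, `p`, `neglog10p`,
#'   `direction`, with the per-gene degrees of freedom in `attr(, "df")`.
#' @export
welch_t <- function(study) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (study$design != "unpaired") stop("welch_t requires an unpaired design")
  is_case <- study$group == "case"
  if (sum(is_case) < 2L || sum(!is_case) < 2L)
    stop("each group needs at least 2 samples")
  w <- .welch_rows(study$matrix, is_case)
  if (w$n_zero > 0)
    .msg(w$n_zero, " feature(s) with zero variance in both groups (t = 0, p = 1)")
  .de_result(study, w$t, w$p, w$df,
             c(n_case = sum(is_case), n_control = sum(!is_case)))
}

#' Per-gene paired t test (late vs early timepoint)
#'
#' Computes, for every feature, the one-sample t statistic on within-subject
#' late minus early differences with its two-sided p-value. Features with
#' zero-variance differences are reported as t = 0, p = 1 (with a message).
#'
#' @param study a paired [ExpressionStudy] with >= 2 complete pairs.
#' @return A `DEResult` data frame (see [welch_t()]); `attr(, "n")` holds
#'   `n_pairs`.
#' @export
paired_t <- function(study) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (study$design != "paired") stop("paired_t requires a paired design")
  D <- .paired_diffs(study)
  if (ncol(D) < 2L) stop("need at least 2 complete subject pairs")
  w <- .paired_rows(D)
  if (w$n_zero > 0)
    .msg(w$n_zero, " feature(s) with zero-variance differences (t = 0, p = 1)")
  .de_result(study, w$t, w$p, w$df, c(n_pairs = ncol(D)))
}

#' Per-gene differential expression for either design
#'
#' Dispatches to [welch_t()] for unpaired studies and [paired_t()] for paired
#' studies.
#'
#' @param study an [ExpressionStudy].
#' @return A `DEResult` data frame.
#' @export
de_test <- function(study) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (study$design == "unpaired") welch_t(study) else paired_t(study)
}

#' Write a differential expression table
#'
#' @param de a `DEResult`.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_de <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
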