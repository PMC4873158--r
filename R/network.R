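# Soft-threshold adjacency from an expression matrix (genes x samples).
# Unsigned: |cor|^beta; signed: ((1 + cor)/2)^beta. Diagonal set to 0.
.adjacency <- function(X, beta, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  cc <- stats::cor(t(X))
  A <- if (mode == "unsigned") abs(cc)^beta else ((1 + cc) / 2)^beta
  diag(A) <- 0
  A
}

#' Topological overlap from an adjacency matrix
#'
#' Computes the unsigned topological overlap measure
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(K_i, K_j) + 1 - a_ij)` with
#' `K_i = sum_u a_iu`, diagonal set to 1. High TOM means two genes share
#' their network neighborhood as well as a direct connection.
#'
#' @param A symmetric adjacency matrix with entries in \[0, 1\] and zero
#'   diagonal.
#' @return The TOM matrix (same dimension, unit diagonal).
#' @export
tom_from_adjacency <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  diag(A) <- 0
  K <- rowSums(A)
  num <- A %*% A + A
  den <- outer(K, K, pmin) + 1 - A
  TOM <- num / den
  diag(TOM) <- 1
  dimnames(TOM) <- dimnames(A)
  TOM
}

#' Build a TOM co-expression network for a study
#'
#' Restricts the study to the requested genes (typically the union of the
#' pathway sets), forms the soft-threshold adjacency and its topological
#' overlap matrix, and computes each gene's TOM-based connectivity
#' `k_i = sum_{j != i} TOM_ij` — the hub-gene ranking statistic.
#'
#' @param study an [ExpressionStudy] with >= 3 samples.
#' @param beta soft-threshold power (see [pick_soft_power()]).
#' @param mode `"unsigned"` (default) or `"signed"` adjacency.
#' @param genes optional character vector restricting the network (e.g. the
#'   union of a [GeneSetCollection]); default all study genes. Zero-variance
#'   genes are dropped with a message.
#' @return A `TOMNetwork`: list with `study`, `genes`, `beta`, `mode`,
#'   `adjacency` (zero diagonal), `tom` (unit diagonal), `connectivity`.
#' @export
tom_matrix <- function(study, beta = 6, mode = c("unsigned", "signed"),
                       genes = NULL) {
  stopifnot(inherits(study, "ExpressionStudy"), beta > 0)
  mode <- match.arg(mode)
  X <- study$matrix
  if (!is.null(genes)) {
    genes <- intersect(genes, rownames(X))
    X <- X[genes, , drop = FALSE]
  }
  if (ncol(X) < 3L) stop("need at least 3 samples")
  v <- .row_vars(X)
  if (any(v <= 0)) {
    .msg(sum(v <= 0), " zero-variance gene(s) dropped from the network")
    X <- X[v > 0, , drop = FALSE]
  }
  if (nrow(X) < 3L) stop("need at least 3 genes with variance")
  A <- .adjacency(X, beta, mode)
  TOM <- tom_from_adjacency(A)
  k <- rowSums(TOM) - diag(TOM)
  obj <- list(study = study$name, genes = rownames(X), beta = beta,
              mode = mode, adjacency = A, tom = TOM, connectivity = k,
              expr = X)
  class(obj) <- "TOMNetwork"
  obj
}

#' @export
print.TOMNetwork <- function(x, ...) {
  cat(sprintf("TOMNetwork '%s': %d genes, beta = %g (%s)\n",
              x$study, length(x$genes), x$beta, x$mode))
  invisible(x)
}

#' Choose a soft-threshold power by scale-free topology fit
#'
#' For each candidate power, builds the adjacency, computes whole-network
#' connectivity `k_i = sum_j a_ij`, bins genes by k and fits the log-log
#' regression of log10 p(k) on log10 (mean k per bin). The fit index is the
#' regression R-squared when the slope is negative (a scale-free degree
#' distribution decays), else 0. The chosen power is the smallest candidate
#' with fit >= `r2_cut`, otherwise the candidate maximizing the fit,
#' otherwise (degenerate connectivity) the default 6 with a warning.
#'
#' @param study an [ExpressionStudy] with >= 10 genes and >= 4 samples.
#' @param powers candidate powers (default `c(1:10, 12, 14, 16, 18, 20)`).
#' @param mode adjacency mode, as in [tom_matrix()].
#' @param genes optional gene restriction, as in [tom_matrix()].
#' @param r2_cut scale-free fit threshold (default 0.8).
#' @param n_bins connectivity histogram bins (default 10).
#' @return List with `beta` (chosen power) and `fit`: a data frame of
#'   `power`, `sft_r2` (signed fit index), `slope`, `mean_k`.
#' @export
pick_soft_power <- function(study, powers = c(1:10, 12, 14, 16, 18, 20),
                            mode = c("unsigned", "signed"), genes = NULL,
                            r2_cut = 0.8, n_bins = 10) {
  stopifnot(inherits(study, "ExpressionStudy"))
  mode <- match.arg(mode)
  X <- study$matrix
  if (!is.null(genes)) X <- X[intersect(genes, rownames(X)), , drop = FALSE]
  if (nrow(X) < 10L) stop("need at least 10 genes")
  if (ncol(X) < 4L) stop("need at least 4 samples")
  v <- .row_vars(X)
  X <- X[v > 0, , drop = FALSE]
  cc <- stats::cor(t(X))
  fit <- do.call(rbind, lapply(powers, function(b) {
    A <- if (mode == "unsigned") abs(cc)^b else ((1 + cc) / 2)^b
    diag(A) <- 0
    k <- rowSums(A)
    data.frame(power = b, .scale_free_fit(k, n_bins), mean_k = mean(k))
  }))
  ok <- !is.na(fit$sft_r2)
  if (!any(ok)) {
    warning("degenerate connectivity; falling back to default power 6")
    return(list(beta = 6, fit = fit))
  }
  pass <- ok & fit$sft_r2 >= r2_cut
  beta <- if (any(pass)) {
    min(fit$power[pass])
  } else {
    fit$power[ok][which.max(fit$sft_r2[ok])]
  }
  if (!any(pass))
    warning("no candidate power reached the scale-free fit threshold; ",
            "using the best-fitting power ", beta)
  list(beta = beta, fit = fit)
}

# Scale-free fit of a connectivity vector: R^2 of log10 p(k) ~ log10 k over
# equal-width connectivity bins, signed to 0 when the slope is positive.
.scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins || diff(range(k)) < .Machine$double.eps)
    return(data.frame(sft_r2 = NA_real_, slope = NA_real_))
  cuts <- cut(k, breaks = n_bins)
  pk <- tapply(k, cuts, length) / length(k)
  mk <- tapply(k, cuts, mean)
  keep <- !is.na(pk) & pk > 0
  if (sum(keep) < 3L)
    return(data.frame(sft_r2 = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(pk[keep]) ~ log10(mk[keep]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[[2L]]
  data.frame(sft_r2 = if (slope < 0) r2 else 0, slope = slope)
}

# Upper-triangle pair index helper.
.pair_table <- function(TOM) {
  ut <- which(upper.tri(TOM), arr.ind = TRUE)
  data.frame(gene_i = rownames(TOM)[ut[, 1L]],
             gene_j = colnames(TOM)[ut[, 2L]],
             tom = TOM[ut], stringsAsFactors = FALSE)
}

#' Call network edges by top quantile and/or permutation FDR
#'
#' `rule = "top_quantile"` keeps the `round(top_q * P)` unordered gene pairs
#' with the largest TOM values (P = number of pairs); pairs tied with the
#' cutoff value are all kept and the realized fraction is logged.
#' `rule = "fdr"` builds a null TOM distribution by `B` rounds of permuting
#' every gene's sample order independently (destroying all gene-gene
#' correlation while preserving marginals), pools the null values across
#' pairs and rounds to raise resolution (p floor `1/(B*P + 1)` for P pairs),
#' converts each pair's empirical p to a Benjamini-Hochberg q-value, and
#' keeps pairs with `q < fdr_q`. `rule = "combined"` intersects the two —
#' the "top 3% of pairs at FDR < 0.1%" construction.
#'
#' @param net a `TOMNetwork` from [tom_matrix()].
#' @param rule `"top_quantile"`, `"fdr"` or `"combined"` (default).
#' @param top_q top fraction of pairs to keep (default 0.03).
#' @param fdr_q FDR threshold (default 0.001).
#' @param B permutation rounds for the null (>= 100; default 200).
#' @param seed integer seed for the permutations.
#' @param de optional `DEResult` used to attach a differential-expression
#'   class to each node (`up-significant` / `down-significant` /
#'   `not-significant` at `alpha`).
#' @param alpha per-gene significance threshold for the node classes.
#' @return An `EdgeCalls` list: `edges` (data frame `gene_i`, `gene_j`,
#'   `tom`, `p`, `q`, `in_top_quantile`, `called`), `rule`, `thresholds`,
#'   `nodes` (per-gene `gene`, `connectivity`, `de_class`).
#' @export
call_edges <- function(net, rule = c("combined", "top_quantile", "fdr"),
                       top_q = 0.03, fdr_q = 0.001, B = 200, seed = 1,
                       de = NULL, alpha = 0.05) {
  stopifnot(inherits(net, "TOMNetwork"))
  rule <- match.arg(rule)
  if (top_q <= 0 || top_q >= 1) stop("top_q must lie in (0, 1)")
  pairs <- .pair_table(net$tom)
  P <- nrow(pairs)

  if (rule %in% c("top_quantile", "combined")) {
    n_top <- max(1L, round(top_q * P))
    cutoff <- sort(pairs$tom, decreasing = TRUE)[n_top]
    pairs$in_top_quantile <- pairs$tom >= cutoff
    realized <- mean(pairs$in_top_quantile)
    if (realized > top_q + 1e-12)
      .msg(sprintf("ties at the top-%g%% cutoff kept; realized fraction %.2f%%",
                   100 * top_q, 100 * realized))
  } else {
    pairs$in_top_quantile <- NA
  }

  if (rule %in% c("fdr", "combined")) {
    if (B < 100) stop("B must be at least 100 for the FDR rule")
    p_floor <- 1 / (B * P + 1)
    if (p_floor > fdr_q)
      warning(sprintf("permutation resolution (p floor %.2g) is coarser than fdr_q = %g",
                      p_floor, fdr_q))
    set.seed(seed)
    X <- .study_matrix_for(net)
    null_vals <- vector("list", B)
    for (b in seq_len(B)) {
      Xp <- t(apply(X, 1L, sample))
      Ap <- .adjacency(Xp, net$beta, net$mode)
      Tp <- tom_from_adjacency(Ap)
      null_vals[[b]] <- Tp[upper.tri(Tp)]
    }
    null_sorted <- sort(unlist(null_vals))
    n_null <- length(null_sorted)
    n_ge <- n_null - findInterval(pairs$tom, null_sorted, left.open = TRUE)
    pairs$p <- (1 + n_ge) / (n_null + 1)
    pairs$q <- stats::p.adjust(pairs$p, method = "BH")
  } else {
    pairs$p <- NA_real_
    pairs$q <- NA_real_
  }

  pairs$called <- switch(rule,
    top_quantile = pairs$in_top_quantile,
    fdr = pairs$q < fdr_q,
    combined = pairs$in_top_quantile & pairs$q < fdr_q)

  nodes <- data.frame(gene = net$genes, connectivity = net$connectivity,
                      row.names = NULL, stringsAsFactors = FALSE)
  nodes$de_class <- if (is.null(de)) NA_character_ else {
    idx <- match(nodes$gene, de$gene)
    ifelse(is.na(idx) | de$p[idx] >= alpha, "not-significant",
           ifelse(de$t[idx] > 0, "up-significant", "down-significant"))
  }
  obj <- list(edges = pairs[order(-pairs$tom), , drop = FALSE],
              rule = rule,
              thresholds = list(top_q = top_q, fdr_q = fdr_q, B = B),
              nodes = nodes)
  class(obj) <- "EdgeCalls"
  obj
}

# call_edges needs the expression submatrix the network was built from; we
# stash it on the TOMNetwork at construction to keep the object self-contained.
.study_matrix_for <- function(net) {
  if (is.null(net$expr))
    stop("TOMNetwork carries no expression matrix; rebuild with tom_matrix()")
  net$expr
}

#' Correlation of TOM connectivity with differential-expression significance
#'
#' Tests whether hub genes (high TOM-based connectivity) are also the genes
#' whose expression changes most: the Pearson correlation between `k_i` and
#' `-log10 p_i`, with the per-gene table sorted by connectivity — the top of
#' which is the hub-gene report.
#'
#' @param net a `TOMNetwork`.
#' @param de a `DEResult` for the same study.
#' @param alpha significance threshold for the per-gene class labels.
#' @return List with `r`, `p` (correlation and its t-transform p-value),
#'   `n`, and `table`: per-gene `gene`, `connectivity`, `neglog10p`,
#'   `de_class`, sorted by connectivity descending.
#' @export
connectivity_significance <- function(net, de, alpha = 0.05) {
  stopifnot(inherits(net, "TOMNetwork"), inherits(de, "DEResult"))
  common <- intersect(net$genes, de$gene)
  if (length(common) < 3L) stop("fewer than 3 genes shared between network and DE")
  k <- net$connectivity[match(common, net$genes)]
  idx <- match(common, de$gene)
  nlp <- de$neglog10p[idx]
  pr <- .pearson_r_p(k, nlp)
  tab <- data.frame(gene = common, connectivity = k, neglog10p = nlp,
                    de_class = ifelse(de$p[idx] >= alpha, "not-significant",
                                      ifelse(de$t[idx] > 0, "up-significant",
                                             "down-significant")),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$connectivity), , drop = FALSE]
  rownames(tab) <- NULL
  list(r = pr$r, p = pr$p, n = pr$n, table = tab)
}

#' Write an edge network as TSV tables
#'
#' Emits `<prefix>.edges.tsv` (called edges) and `<prefix>.nodes.tsv`
#' (per-gene attributes) — the machine-readable form of a network figure.
#'
#' @param calls an `EdgeCalls` object.
#' @param prefix output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_edges <- function(calls, prefix) {
  stopifnot(inherits(calls, "EdgeCalls"))
  ep <- paste0(prefix, ".edges.tsv")
  np <- paste0(prefix, ".nodes.tsv")
  utils::write.table(calls$edges[calls$edges$called, , drop = FALSE], ep,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(calls$nodes, np, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edges = ep, nodes = np))
}
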