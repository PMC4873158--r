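#' Construct an expression study
#'
#' Container for one cohort: a numeric features x samples matrix plus its
#' design. Unpaired designs carry a case/control group label per sample;
#' paired designs carry a subject id and an early/late timepoint per sample,
#' with exactly one sample per subject per timepoint.
#'
#' @param name study label.
#' @param matrix numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param design `"unpaired"` or `"paired"`.
#' @param group for unpaired designs, character/factor of `"case"`/`"control"`
#'   per sample.
#' @param subject,timepoint for paired designs, per-sample subject ids and
#'   `"early"`/`"late"` labels.
#' @param log_scale logical; whether values are on a log2-like scale.
#' @return An object of class `ExpressionStudy`.
#' @export
ExpressionStudy <- function(name, matrix, design = c("unpaired", "paired"),
                            group = NULL, subject = NULL, timepoint = NULL,
                            log_scale = TRUE) {
  design <- match.arg(design)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (nrow(matrix) == 0L || ncol(matrix) == 0L) stop("empty expression matrix")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("matrix must have feature rownames and sample colnames")
  if (anyDuplicated(colnames(matrix))) stop("duplicated sample ids")
  if (anyDuplicated(rownames(matrix)))
    stop("duplicated feature ids; collapse or disambiguate probes first")
  if (anyNA(matrix)) stop("matrix contains missing values; filter on ingestion")
  n <- ncol(matrix)
  if (design == "unpaired") {
    group <- as.character(group)
    if (length(group) != n) stop("group must have one label per sample")
    if (!all(group %in% c("case", "control")))
      stop("group labels must be 'case' or 'control'")
    if (sum(group == "case") < 1L || sum(group == "control") < 1L)
      stop("both groups must be non-empty")
    obj <- list(name = name, matrix = matrix, design = design,
                group = group, log_scale = isTRUE(log_scale))
  } else {
    subject <- as.character(subject)
    timepoint <- as.character(timepoint)
    if (length(subject) != n || length(timepoint) != n)
      stop("subject and timepoint must have one entry per sample")
    if (!all(timepoint %in% c("early", "late")))
      stop("timepoint labels must be 'early' or 'late'")
    tab <- table(subject, timepoint)
    if (!all(dim(tab) == c(length(unique(subject)), 2L)) || !all(tab == 1L))
      stop("paired design requires exactly one early and one late sample per subject")
    obj <- list(name = name, matrix = matrix, design = design,
                subject = subject, timepoint = timepoint,
                log_scale = isTRUE(log_scale))
  }
  class(obj) <- "ExpressionStudy"
  obj
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat(sprintf("ExpressionStudy '%s': %d features x %d samples (%s design)\n",
              x$name, nrow(x$matrix), ncol(x$matrix), x$design))
  if (x$design == "unpaired") {
    cat(sprintf("  case: %d, control: %d\n",
                sum(x$group == "case"), sum(x$group == "control")))
  } else {
    cat(sprintf("  subjects: %d (early/late pairs)\n",
                length(unique(x$subject))))
  }
  invisible(x)
}

#' Read an expression matrix with sample annotation
#'
#' Reads a features x samples matrix from a plain TSV (header row = sample
#' ids, first column = feature ids) or from the offline GEO series-matrix text
#' dialect, where the data table sits between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` fences and ids may be double-quoted; the inner
#' table is parsed identically to the TSV dialect. Features containing any
#' missing value are dropped (with a message). If the matrix maximum exceeds
#' 30 the values are assumed to be on the raw intensity scale and log2(x+1)
#' is applied (with a message).
#'
#' @param path path to the expression file.
#' @param samples sample annotation: a data frame or path to a TSV with
#'   columns `sample_id` and `group` (unpaired) or `sample_id`, `subject`,
#'   `timepoint` (paired).
#' @param name study label (defaults to the file name).
#' @param dialect `"tsv"` or `"series_matrix"`.
#' @param log_check apply the log2 heuristic (default TRUE).
#' @return An [ExpressionStudy].
#' @export
read_expression <- function(path, samples, name = basename(path),
                            dialect = c("tsv", "series_matrix"),
                            log_check = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
      stop("series-matrix table fences not found in ", path)
    inner <- lines[(beg + 1L):(end - 1L)]
    tab <- utils::read.delim(text = inner, header = TRUE, sep = "\t",
                             quote = "\"", check.names = FALSE,
                             stringsAsFactors = FALSE)
    colnames(tab) <- gsub('^"|"$', "", colnames(tab))
  }
  if (ncol(tab) < 2L) stop("expression table needs feature ids plus >= 1 sample")
  feat <- gsub('^"|"$', "", as.character(tab[[1L]]))
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- feat
  keep <- !apply(is.na(mat), 1L, any)
  if (any(!keep)) {
    .msg(sum(!keep), " feature(s) with missing values dropped")
    mat <- mat[keep, , drop = FALSE]
  }
  if (nrow(mat) == 0L) stop("empty matrix after missing-value filtering")
  log_scale <- TRUE
  if (isTRUE(log_check) && max(mat) > 30) {
    .msg("matrix maximum > 30; applying log2(x + 1)")
    mat <- log2(mat + 1)
  }
  ann <- if (is.character(samples)) {
    utils::read.delim(samples, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(ann)) stop("annotation needs a sample_id column")
  missing <- setdiff(colnames(mat), ann$sample_id)
  if (length(missing))
    stop("samples without annotation: ", paste(missing, collapse = ", "))
  ann <- ann[match(colnames(mat), ann$sample_id), , drop = FALSE]
  if ("group" %in% names(ann)) {
    ExpressionStudy(name, mat, design = "unpaired", group = ann$group,
                    log_scale = log_scale)
  } else if (all(c("subject", "timepoint") %in% names(ann))) {
    ExpressionStudy(name, mat, design = "paired", subject = ann$subject,
                    timepoint = ann$timepoint, log_scale = log_scale)
  } else {
    stop("annotation needs either a 'group' or 'subject'+'timepoint' columns")
  }
}

#' Write an expression study to TSV files
#'
#' Emits `<prefix>.expr.tsv` (features x samples, first column `feature_id`)
#' and `<prefix>.samples.tsv` (the design annotation), the same layout
#' [read_expression()] ingests.
#'
#' @param study an [ExpressionStudy].
#' @param prefix output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_expression <- function(study, prefix) {
  expr_path <- paste0(prefix, ".expr.tsv")
  samp_path <- paste0(prefix, ".samples.tsv")
  df <- data.frame(feature_id = rownames(study$matrix), study$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ann <- if (study$design == "unpaired") {
    data.frame(sample_id = colnames(study$matrix), group = study$group,
               stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = colnames(study$matrix), subject = study$subject,
               timepoint = study$timepoint, stringsAsFactors = FALSE)
  }
  utils::write.table(ann, samp_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expr = expr_path, samples = samp_path))
}

#' Quantile-normalize an expression study
#'
#' Forces every sample (column) to share the same empirical distribution: the
#' value at rank r in each column becomes the mean of the rank-r order
#' statistics across columns (ties averaged). Ranks within each column are
#' preserved and the operation is idempotent.
#'
#' @param study an [ExpressionStudy] with at least two samples.
#' @return The study with its matrix quantile-normalized.
#' @export
quantile_normalize <- function(study) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (ncol(study$matrix) < 2L)
    stop("quantile normalization needs at least 2 samples")
  qn <- limma::normalizeQuantiles(study$matrix, ties = TRUE)
  dimnames(qn) <- dimnames(study$matrix)
  study$matrix <- qn
  study
}

#' Collapse probes to genes by differential-expression significance
#'
#' For genes measured by several probes, retains the probe with the smallest
#' differential-expression p-value (ties broken by larger |t|, then by
#' lexicographic probe id). Probes absent from the mapping are dropped with a
#' message.
#'
#' @param study probe-level [ExpressionStudy].
#' @param probe_to_gene data frame with columns `probe` and `gene`.
#' @param de probe-level [de_test()] result computed on `study`.
#' @return A gene-level [ExpressionStudy] with one row per mapped gene.
#' @export
collapse_probes <- function(study, probe_to_gene, de) {
  stopifnot(inherits(study, "ExpressionStudy"))
  map <- data.frame(probe = as.character(probe_to_gene$probe),
                    gene = as.character(probe_to_gene$gene),
                    stringsAsFactors = FALSE)
  probes <- rownames(study$matrix)
  unmapped <- setdiff(probes, map$probe)
  if (length(unmapped))
    .msg(length(unmapped), " probe(s) without a gene mapping dropped")
  map <- map[map$probe %in% probes, , drop = FALSE]
  if (nrow(map) == 0L) stop("no probes could be mapped to genes")
  if (!all(map$probe %in% de$gene))
    stop("de must be computed on the uncollapsed study (probe level)")
  idx <- match(map$probe, de$gene)
  map$p <- de$p[idx]
  map$abs_t <- abs(de$t[idx])
  # min p, then max |t|, then lexicographic probe id
  ord <- order(map$gene, map$p, -map$abs_t, map$probe)
  map <- map[ord, , drop = FALSE]
  keep <- map[!duplicated(map$gene), , drop = FALSE]
  mat <- study$matrix[keep$probe, , drop = FALSE]
  rownames(mat) <- keep$gene
  out <- study
  out$matrix <- mat
  out
}

#' Read or write gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Duplicate symbols within a line are removed (order preserved,
#' logged); lines with fewer than three fields are an error.
#'
#' @param path file path.
#' @return `read_gmt()` returns a `GeneSetCollection`: a list with `sets`
#'   (named list of character vectors) and `provenance`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list()
  desc <- character()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("malformed GMT line (fewer than 3 fields): ", substr(ln, 1, 60))
    nm <- fields[1L]
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      .msg("duplicate symbols in set '", nm, "' removed")
      members <- members[!duplicated(members)]
    }
    if (nm %in% names(sets)) stop("duplicated set name: ", nm)
    sets[[nm]] <- members
    desc[nm] <- fields[2L]
  }
  GeneSetCollection(sets, provenance = path, descriptions = desc)
}

#' @param sets named list of character vectors.
#' @param provenance free text recording where the sets came from.
#' @param descriptions optional per-set description strings.
#' @rdname read_gmt
#' @export
GeneSetCollection <- function(sets, provenance = "", descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be uniquely named")
  sets <- lapply(sets, function(s) as.character(s[!duplicated(s)]))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  obj <- list(sets = sets, provenance = provenance,
              descriptions = descriptions)
  class(obj) <- "GeneSetCollection"
  obj
}

#' @param collection a `GeneSetCollection`.
#' @rdname read_gmt
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(names(collection$sets), function(nm) {
    d <- collection$descriptions[[nm]]
    if (is.null(d) || !nzchar(d)) d <- "na"
    paste(c(nm, d, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d set(s)\n", length(x$sets)))
  for (nm in names(x$sets))
    cat(sprintf("  %s: %d genes\n", nm, length(x$sets[[nm]])))
  invisible(x)
}

#' Mapped size of each gene set within a study
#'
#' The analysis distinguishes a set's nominal size (the GMT list) from its
#' mapped size, the number of members actually measured on the study's
#' platform; all enrichment denominators use the mapped size.
#'
#' @param study an [ExpressionStudy].
#' @param sets a `GeneSetCollection`.
#' @return data frame with `set`, `size`, `mapped`.
#' @export
mapped_sizes <- function(study, sets) {
  feats <- rownames(study$matrix)
  data.frame(
    set = names(sets$sets),
    size = vapply(sets$sets, length, integer(1)),
    mapped = vapply(sets$sets, function(s) sum(s %in% feats), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
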