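#' Read a pipeline configuration from YAML
#'
#' The configuration mirrors the arguments of [run_all()]: a `studies` list
#' (each with `name`, `expr`, `samples`, optional `dialect`), `gmt`,
#' `alpha`, `enrichment` (`B`, `scheme`), `network` (`mode`, `beta` or
#' `"auto"`, `top_q`, `fdr_q`, `B`), `regulator`, a mandatory `seed`, and
#' `out_dir`.
#'
#' @param path path to a YAML file.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set a seed")
  cfg
}

.cfg_default <- function(x, default) if (is.null(x)) default else x

#' Run the full multi-study pathway analysis
#'
#' Orchestrates, for every configured study: per-gene differential
#' expression, permutation pathway enrichment, the TOM co-expression network
#' over the union of pathway genes with called edges and
#' connectivity-vs-significance correlation, and the regulator analysis;
#' then all pairwise cross-study concordances. Writes per-stage TSV tables
#' plus a single `report.json` holding the enrichment grid, the concordance
#' matrix with per-set ranges, per-study connectivity-significance
#' correlations and regulator summaries, along with the seed and all
#' thresholds. A study lacking the regulator gene is marked absent in the
#' report and the run completes.
#'
#' @param config a configuration list (see [read_run_config()]). `studies`
#'   entries may be file paths (`expr`, `samples`) or in-memory
#'   [ExpressionStudy] objects under `study`; `gmt` may be a path or a
#'   [GeneSetCollection]. A `seed` is mandatory.
#' @return Invisibly, the report list (also written to
#'   `<out_dir>/report.json`).
#' @export
run_all <- function(config) {
  if (is.null(config$seed)) stop("config must set a seed")
  seed <- as.integer(config$seed)
  out_dir <- .cfg_default(config$out_dir, tempfile("pathconcord_run_"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  alpha <- .cfg_default(config$alpha, 0.05)
  enr <- config$enrichment
  enr_B <- .cfg_default(enr$B, 1000)
  enr_scheme <- .cfg_default(enr$scheme, "label_permutation")
  net <- config$network
  net_mode <- .cfg_default(net$mode, "unsigned")
  net_top_q <- .cfg_default(net$top_q, 0.03)
  net_fdr_q <- .cfg_default(net$fdr_q, 0.001)
  net_B <- .cfg_default(net$B, 200)
  net_beta <- .cfg_default(net$beta, "auto")
  regulator <- .cfg_default(config$regulator, NULL)

  stage <- "load gene sets"
  report <- list()
  result <- try({
    sets <- if (inherits(config$gmt, "GeneSetCollection")) config$gmt
            else read_gmt(config$gmt)
    studies <- lapply(config$studies, function(entry) {
      if (inherits(entry$study, "ExpressionStudy")) return(entry$study)
      read_expression(entry$expr, entry$samples,
                      name = .cfg_default(entry$name, basename(entry$expr)),
                      dialect = .cfg_default(entry$dialect, "tsv"))
    })
    names(studies) <- vapply(studies, `[[`, character(1), "name")
    pathway_genes <- unique(unlist(sets$sets))

    de <- list(); enrich <- list(); consig <- list(); reg <- list()
    for (nm in names(studies)) {
      st <- studies[[nm]]
      stage <- paste("differential expression:", nm)
      de[[nm]] <- de_test(st)
      write_de(de[[nm]], file.path(out_dir, paste0("de_", nm, ".tsv")))

      stage <- paste("enrichment:", nm)
      enrich[[nm]] <- enrichment_test(st, sets, alpha = alpha, B = enr_B,
                                      scheme = enr_scheme, seed = seed)

      stage <- paste("network:", nm)
      beta <- if (identical(net_beta, "auto")) {
        pick_soft_power(st, mode = net_mode, genes = pathway_genes)$beta
      } else as.numeric(net_beta)
      network <- tom_matrix(st, beta = beta, mode = net_mode,
                            genes = pathway_genes)
      calls <- call_edges(network, rule = "combined", top_q = net_top_q,
                          fdr_q = net_fdr_q, B = net_B, seed = seed,
                          de = de[[nm]], alpha = alpha)
      write_edges(calls, file.path(out_dir, paste0("network_", nm)))
      consig[[nm]] <- connectivity_significance(network, de[[nm]],
                                                alpha = alpha)
      utils::write.table(consig[[nm]]$table,
                         file.path(out_dir, paste0("hubs_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)

      stage <- paste("regulator:", nm)
      reg[[nm]] <- if (is.null(regulator)) {
        list(present = FALSE)
      } else if (!regulator %in% rownames(st$matrix)) {
        .msg("regulator '", regulator, "' absent from study '", nm, "'")
        list(present = FALSE)
      } else {
        rc <- regulator_correlations(st, sets, regulator)
        rd <- regulator_de(st, regulator, de = de[[nm]])
        utils::write.table(rc$genes,
                           file.path(out_dir, paste0("regulator_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        list(present = TRUE,
             de = list(t = rd$t, p = rd$p, direction = rd$direction),
             sets = rc$set_summary)
      }
    }

    stage <- "cross-study concordance"
    pairs <- utils::combn(names(studies), 2L, simplify = FALSE)
    conc <- lapply(pairs, function(pr)
      concordance(de[[pr[1L]]], de[[pr[2L]]], sets))
    conc_grid <- concordance_matrix(conc)
    utils::write.table(attr(conc_grid, "long"),
                       file.path(out_dir, "concordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    enr_grid <- summarize_enrichment(enrich)
    utils::write.table(attr(enr_grid, "long"),
                       file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    report <- list(
      parameters = list(seed = seed, alpha = alpha,
                        enrichment = list(B = enr_B, scheme = enr_scheme),
                        network = list(mode = net_mode, beta = net_beta,
                                       top_q = net_top_q, fdr_q = net_fdr_q,
                                       B = net_B),
                        regulator = regulator,
                        package_version = as.character(
                          utils::packageVersion("pathconcord"))),
      mapped_sizes = lapply(studies, mapped_sizes, sets = sets),
      enrichment = list(grid = enr_grid,
                        long = attr(enr_grid, "long")),
      concordance = list(grid = conc_grid[setdiff(names(conc_grid), "range")],
                         range = stats::setNames(conc_grid$range,
                                                 conc_grid$set)),
      connectivity_significance = lapply(consig, function(cs)
        list(r = cs$r, p = cs$p, n = cs$n)),
      regulator = reg)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report
  }, silent = TRUE)
  if (inherits(result, "try-error"))
    stop("pipeline failed at stage [", stage, "]: ",
         attr(result, "condition")$message,
         "; partial outputs preserved in ", out_dir)
  invisible(c(result, list(out_dir = out_dir)))
}
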