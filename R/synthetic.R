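#' Parameterize a synthetic multi-cohort design
#'
#' Describes a family of expression studies sharing planted pathway effects,
#' hub-structured within-set correlation and a regulator gene coupled to the
#' set latent factors, so that every downstream stage (differential
#' expression, enrichment, concordance, networks, regulator correlation) can
#' be validated against known truth.
#'
#' Each gene in a set loads on that set's latent factor F_s (standard normal
#' per sample): `x_g = baseline + shift_g * I(case) + noise_sd * (sqrt(rho_g)
#' * F_s + sqrt(1 - rho_g) * eps)`, giving an exact pairwise correlation
#' `sqrt(rho_i * rho_j)` between set members. Hub genes (the first `n_hubs`
#' members primarily assigned to the set) use `rho_hub`; other members use
#' `rho_background`. The planted case (or late-timepoint) shift is
#' `direction * effect_size * u_g * noise_sd`, where the per-gene multiplier
#' `u_g ~ Unif(0, 2)` is drawn once per design and shared by all studies, so
#' both the mean shift (`direction * effect_size`, in standard-deviation
#' units) and the across-gene effect heterogeneity that drives cross-study
#' concordance are controlled. The regulator gene is a weighted sum of the
#' set factors, `x_reg = baseline + shift_reg * I(case) + noise_sd *
#' (sum_s w_s F_s + sqrt(1 - sum_s w_s^2) * eps)`, giving signed correlations
#' `w_s * sqrt(rho_g)` with set genes. Paired studies add a per-subject
#' random intercept (sd = `noise_sd`) to both timepoints.
#'
#' @param n_genes total number of genes simulated.
#' @param studies list of study descriptors: `list(name=, design="unpaired",
#'   n_case=, n_control=)` or `list(name=, design="paired", n_subjects=)`.
#' @param gene_sets list of set descriptors: `list(name=, members=` (integer
#'   gene indices, sets may overlap), `direction=` (+1, -1 or 0),
#'   `effect_size=` (standardized mean shift, >= 0), and optional
#'   `affected=` (`"all"` or `"hubs"`, which genes carry the shift).
#' @param hubs either one list `list(n_hubs=, rho_hub=, rho_background=,
#'   effect_multiplier=)` applied to every set, or a named list of such lists
#'   per set. `effect_multiplier` scales the planted shift of hub genes
#'   (default 2: pathway hubs are both the most connected and the most
#'   differentially expressed genes, the structure the motivating analysis
#'   reports); set it to 1 for homogeneous effects.
#' @param regulator `NULL` or `list(gene=, index=, couplings=` (named numeric
#'   per set, sum of squares < 1), `effect_size=`, `direction=)`.
#' @param noise_sd residual standard deviation.
#' @param baseline grand mean (log2-intensity-like).
#' @param seed integer root seed; all randomness derives from it.
#' @return A `SyntheticDesign`.
#' @export
new_synthetic_design <- function(n_genes = 2000,
                                 studies = list(
                                   list(name = "atherosclerosis", design = "unpaired",
                                        n_case = 48, n_control = 48),
                                   list(name = "stroke", design = "unpaired",
                                        n_case = 39, n_control = 24),
                                   list(name = "MI", design = "paired",
                                        n_subjects = 18)),
                                 gene_sets = list(
                                   list(name = "TLR", members = 1:106,
                                        direction = +1, effect_size = 0.4),
                                   list(name = "TCR", members = 107:210,
                                        direction = -1, effect_size = 0.4),
                                   list(name = "BCR", members = 187:258,
                                        direction = -1, effect_size = 0.4)),
                                 hubs = list(n_hubs = 10, rho_hub = 0.6,
                                             rho_background = 0.2,
                                             effect_multiplier = 2),
                                 regulator = list(gene = "DNMT1", index = 300,
                                                  couplings = c(TLR = -0.5,
                                                                TCR = 0.5,
                                                                BCR = 0.5),
                                                  effect_size = 0.5,
                                                  direction = -1),
                                 noise_sd = 1, baseline = 8, seed = 1) {
  stopifnot(n_genes >= 1, noise_sd > 0, is.numeric(seed))
  snames <- vapply(studies, `[[`, character(1), "name")
  if (anyDuplicated(snames)) stop("study names must be unique")
  for (st in studies) {
    if (st$design == "unpaired") {
      if (st$n_case < 1 || st$n_control < 1) stop("non-positive sample sizes")
    } else if (st$design == "paired") {
      if (st$n_subjects < 1) stop("non-positive sample sizes")
    } else stop("design must be 'unpaired' or 'paired'")
  }
  setnames <- vapply(gene_sets, `[[`, character(1), "name")
  if (anyDuplicated(setnames)) stop("set names must be unique")
  gene_sets <- lapply(gene_sets, function(gs) {
    gs$members <- unique(as.integer(gs$members))
    if (any(gs$members < 1L | gs$members > n_genes))
      stop("gene-set members must be indices in 1..n_genes")
    if (!gs$direction %in% c(-1, 0, 1)) stop("direction must be -1, 0 or +1")
    if (gs$effect_size < 0) stop("effect_size must be >= 0")
    if (is.null(gs$affected)) gs$affected <- "all"
    gs
  })
  if (!is.null(hubs$n_hubs))  # single spec recycled over sets
    hubs <- stats::setNames(rep(list(hubs), length(setnames)), setnames)
  hubs <- lapply(hubs, function(h) {
    if (h$rho_hub < 0 || h$rho_hub >= 1 || h$rho_background < 0 ||
        h$rho_background >= 1)
      stop("rho_hub and rho_background must lie in [0, 1)")
    if (is.null(h$effect_multiplier)) h$effect_multiplier <- 1
    h
  })
  if (!is.null(regulator)) {
    w <- regulator$couplings
    if (!all(names(w) %in% setnames)) stop("regulator couplings must name sets")
    if (sum(w^2) >= 1) stop("sum of squared regulator couplings must be < 1")
    if (any(abs(w) >= 1)) stop("|coupling strength| must be < 1")
    if (regulator$index < 1 || regulator$index > n_genes)
      stop("regulator index out of range")
    in_sets <- unlist(lapply(gene_sets, `[[`, "members"))
    if (regulator$index %in% in_sets)
      stop("regulator index must not belong to a gene set")
  }
  obj <- list(n_genes = as.integer(n_genes), studies = studies,
              gene_sets = gene_sets, hubs = hubs, regulator = regulator,
              noise_sd = noise_sd, baseline = baseline,
              seed = as.integer(seed))
  class(obj) <- "SyntheticDesign"
  obj
}

#' @export
print.SyntheticDesign <- function(x, ...) {
  cat(sprintf("SyntheticDesign: %d genes, %d studies, %d gene sets (seed %d)\n",
              x$n_genes, length(x$studies), length(x$gene_sets), x$seed))
  invisible(x)
}

# Gene ids: zero-padded generic symbols, regulator renamed.
.design_gene_ids <- function(design) {
  ids <- sprintf("G%05d", seq_len(design$n_genes))
  if (!is.null(design$regulator)) ids[design$regulator$index] <- design$regulator$gene
  ids
}

# Per-gene layout shared by all studies: primary set, loading rho, planted
# shift (in noise_sd units) and hub flag. Draws the per-gene effect
# multipliers from the design's root seed so every study sees the same truth.
.design_layout <- function(design) {
  set.seed(design$seed)
  u <- stats::runif(design$n_genes, 0, 2)
  primary <- rep(NA_character_, design$n_genes)
  rho <- numeric(design$n_genes)
  shift <- numeric(design$n_genes)
  hub <- logical(design$n_genes)
  for (gs in design$gene_sets) {
    new <- gs$members[is.na(primary[gs$members])]
    primary[new] <- gs$name
    h <- design$hubs[[gs$name]]
    hub_ids <- utils::head(new, h$n_hubs)
    hub[hub_ids] <- TRUE
    rho[new] <- ifelse(new %in% hub_ids, h$rho_hub, h$rho_background)
    affected <- switch(gs$affected, all = new, hubs = hub_ids,
                       stop("affected must be 'all' or 'hubs'"))
    mult <- ifelse(affected %in% hub_ids, h$effect_multiplier, 1)
    shift[affected] <- gs$direction * gs$effect_size * u[affected] * mult
  }
  list(primary = primary, rho = rho, shift = shift, hub = hub, u = u)
}

#' Simulate one study of a synthetic design
#'
#' Draws the expression matrix for the named study under the model described
#' in [new_synthetic_design()]. The per-gene truth (planted shifts, factor
#' loadings) is derived deterministically from the design's root seed and is
#' identical across studies; the study's own samples come from a substream
#' derived from (seed, study position), so repeated calls are bit-identical.
#'
#' @param design a `SyntheticDesign`.
#' @param study_name name of one of the design's studies.
#' @return A list with `study` (an [ExpressionStudy]) and `truth` (a
#'   `GroundTruth`, see [simulate_cohorts()]).
#' @export
simulate_study <- function(design, study_name) {
  stopifnot(inherits(design, "SyntheticDesign"))
  snames <- vapply(design$studies, `[[`, character(1), "name")
  idx <- match(study_name, snames)
  if (is.na(idx)) stop("unknown study name: ", study_name)
  st <- design$studies[[idx]]
  layout <- .design_layout(design)
  ids <- .design_gene_ids(design)

  set.seed((design$seed + 104729L * idx) %% .Machine$integer.max)
  if (st$design == "unpaired") {
    n <- st$n_case + st$n_control
    group <- rep(c("case", "control"), c(st$n_case, st$n_control))
    case_ind <- as.numeric(group == "case")
    sample_ids <- sprintf("%s_S%03d", st$name, seq_len(n))
  } else {
    n <- 2L * st$n_subjects
    subject <- rep(sprintf("P%02d", seq_len(st$n_subjects)), each = 2L)
    timepoint <- rep(c("early", "late"), st$n_subjects)
    case_ind <- as.numeric(timepoint == "late")
    sample_ids <- paste0(subject, "_", timepoint)
  }

  setn <- vapply(design$gene_sets, `[[`, character(1), "name")
  FF <- matrix(stats::rnorm(length(setn) * n), length(setn), n,
               dimnames = list(setn, NULL))
  eps <- matrix(stats::rnorm(design$n_genes * n), design$n_genes, n)
  rho <- layout$rho
  load <- matrix(0, design$n_genes, n)
  in_set <- !is.na(layout$primary)
  if (any(in_set))
    load[in_set, ] <- sqrt(rho[in_set]) * FF[layout$primary[in_set], , drop = FALSE]
  X <- design$baseline +
    design$noise_sd * (load + sqrt(1 - rho) * eps) +
    outer(layout$shift * design$noise_sd, case_ind)

  if (!is.null(design$regulator)) {
    reg <- design$regulator
    w <- reg$couplings
    resid <- sqrt(1 - sum(w^2))
    rshift <- reg$direction * reg$effect_size
    X[reg$index, ] <- design$baseline +
      design$noise_sd * (drop(w %*% FF[names(w), , drop = FALSE]) +
                           resid * eps[reg$index, ]) +
      rshift * design$noise_sd * case_ind
  }

  if (st$design == "paired") {
    b <- stats::rnorm(st$n_subjects, 0, design$noise_sd)
    X <- X + matrix(rep(b, each = 2L), nrow(X), n, byrow = TRUE)
  }

  dimnames(X) <- list(ids, sample_ids)
  study <- if (st$design == "unpaired") {
    ExpressionStudy(st$name, X, design = "unpaired", group = group)
  } else {
    ExpressionStudy(st$name, X, design = "paired", subject = subject,
                    timepoint = timepoint)
  }
  list(study = study, truth = .ground_truth(design, layout))
}

# Assemble the GroundTruth tables from a design layout.
.ground_truth <- function(design, layout) {
  ids <- .design_gene_ids(design)
  snames <- vapply(design$studies, `[[`, character(1), "name")
  gene_shifts <- do.call(rbind, lapply(snames, function(sn) {
    data.frame(study = sn, gene = ids, primary_set = layout$primary,
               shift = layout$shift * design$noise_sd, hub = layout$hub,
               stringsAsFactors = FALSE)
  }))
  set_genes <- which(!is.na(layout$primary))
  pairs <- if (length(set_genes) >= 2L) {
    cmb <- utils::combn(set_genes, 2L)
    data.frame(gene_i = ids[cmb[1L, ]], gene_j = ids[cmb[2L, ]],
               shared_factor = layout$primary[cmb[1L, ]] ==
                 layout$primary[cmb[2L, ]],
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_i = character(), gene_j = character(),
               shared_factor = logical())
  }
  sets <- data.frame(
    set = vapply(design$gene_sets, `[[`, character(1), "name"),
    direction = vapply(design$gene_sets, `[[`, numeric(1), "direction"),
    effect_size = vapply(design$gene_sets, `[[`, numeric(1), "effect_size"),
    size = vapply(design$gene_sets, function(g) length(g$members), integer(1)),
    stringsAsFactors = FALSE)
  obj <- list(gene_shifts = gene_shifts, pair_sharing = pairs,
              set_directions = sets)
  class(obj) <- "GroundTruth"
  obj
}

#' Simulate every study of a design
#'
#' @param design a `SyntheticDesign`.
#' @return List with `studies` (named list of [ExpressionStudy]), `truth`
#'   (a `GroundTruth` with tables `gene_shifts`, `pair_sharing`,
#'   `set_directions`) and `sets` (the design's [GeneSetCollection]).
#' @export
simulate_cohorts <- function(design) {
  stopifnot(inherits(design, "SyntheticDesign"))
  snames <- vapply(design$studies, `[[`, character(1), "name")
  studies <- lapply(snames, function(sn) simulate_study(design, sn)$study)
  names(studies) <- snames
  truth <- .ground_truth(design, .design_layout(design))
  list(studies = studies, truth = truth, sets = design_gene_sets(design))
}

#' Gene sets of a synthetic design as a GeneSetCollection
#'
#' @param design a `SyntheticDesign`.
#' @return A [GeneSetCollection] using the design's gene ids.
#' @export
design_gene_sets <- function(design) {
  ids <- .design_gene_ids(design)
  sets <- lapply(design$gene_sets, function(gs) ids[gs$members])
  names(sets) <- vapply(design$gene_sets, `[[`, character(1), "name")
  GeneSetCollection(sets, provenance = "synthetic design")
}

#' Write ground-truth tables to TSV
#'
#' Emits `gene_shifts.tsv`, `pair_sharing.tsv` and `set_directions.tsv`
#' under `dir`.
#'
#' @param truth a `GroundTruth`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the file paths.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "GroundTruth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(gene_shifts = file.path(dir, "gene_shifts.tsv"),
             pair_sharing = file.path(dir, "pair_sharing.tsv"),
             set_directions = file.path(dir, "set_directions.tsv"))
  for (nm in names(paths))
    utils::write.table(truth[[nm]], paths[[nm]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(paths)
}

#' Read ground-truth tables written by [write_truth()]
#'
#' @param dir directory holding the truth TSVs.
#' @return A `GroundTruth`.
#' @export
read_truth <- function(dir) {
  obj <- list(
    gene_shifts = utils::read.delim(file.path(dir, "gene_shifts.tsv"),
                                    stringsAsFactors = FALSE),
    pair_sharing = utils::read.delim(file.path(dir, "pair_sharing.tsv"),
                                     stringsAsFactors = FALSE),
    set_directions = utils::read.delim(file.path(dir, "set_directions.tsv"),
                                       stringsAsFactors = FALSE))
  class(obj) <- "GroundTruth"
  obj
}

#' Expand a gene-level study to probe level
#'
#' Replicates each gene as `k_probes` probes with independent measurement
#' noise, returning the probe-level study and the probe-to-gene mapping —
#' the input [collapse_probes()] expects.
#'
#' @param study a gene-level [ExpressionStudy].
#' @param k_probes probes per gene.
#' @param probe_noise_sd sd of per-probe measurement noise.
#' @param seed integer seed.
#' @return List with `study` (probe-level) and `map` (data frame `probe`,
#'   `gene`).
#' @export
replicate_probes <- function(study, k_probes = 2, probe_noise_sd = 0.25,
                             seed = 1) {
  stopifnot(inherits(study, "ExpressionStudy"), k_probes >= 1)
  set.seed(seed)
  genes <- rownames(study$matrix)
  probe <- paste0(rep(genes, each = k_probes), "_at",
                  rep(seq_len(k_probes), length(genes)))
  M <- study$matrix[rep(seq_along(genes), each = k_probes), , drop = FALSE]
  M <- M + matrix(stats::rnorm(length(M), 0, probe_noise_sd),
                  nrow(M), ncol(M))
  rownames(M) <- probe
  out <- study
  out$matrix <- M
  list(study = out, map = data.frame(probe = probe,
                                     gene = rep(genes, each = k_probes),
                                     stringsAsFactors = FALSE))
}
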