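#' Parameters for negative-binomial count simulation
#'
#' Describes a gene x sample NB count simulation: the design (sample to
#' stage-group map, control stage first), per-gene baseline means and
#' dispersions, a multiplicative library-size interval, and planted
#' per-stage true log2 fold changes.
#'
#' @param n_genes Number of genes.
#' @param design Data frame with columns `sample` and `group`; the first
#'   group level encountered is treated as the control stage.
#' @param dispersion NB dispersion alpha (`Var = mu + alpha mu^2`), scalar
#'   or per-gene vector (>= 0). Default 0.05.
#' @param mu0 Per-gene baseline means; a scalar is recycled. `NULL` (the
#'   default) draws log-normal means (meanlog `log(150)`, sdlog 1.2) when
#'   the counts are generated.
#' @param size_factor_range Interval from which per-sample library-size
#'   factors are drawn uniformly. Default `c(0.7, 1.4)`.
#' @param planted_effects Matrix of true log2 fold changes (genes in rows
#'   -- by index or rowname -- and non-control stages in columns), or
#'   `NULL` for a pure-null simulation.
#' @param gene_prefix Prefix for generated gene ids.
#' @return An object of class `count_sim_params`.
#' @export
count_sim_params <- function(n_genes, design, dispersion = 0.05, mu0 = NULL,
                             size_factor_range = c(0.7, 1.4),
                             planted_effects = NULL, gene_prefix = "GENE") {
  if (nrow(design) == 0) stop("empty design")
  stopifnot(all(c("sample", "group") %in% names(design)))
  if (any(dispersion < 0)) stop("dispersion must be >= 0")
  if (any(size_factor_range <= 0)) stop("size factors must be > 0")
  stages <- unique(design$group)
  if (!is.null(planted_effects)) {
    planted_effects <- as.matrix(planted_effects)
    if (nrow(planted_effects) > n_genes)
      stop("more planted genes than genes")
    if (!all(colnames(planted_effects) %in% stages[-1]))
      stop("planted effect columns must name non-control stages")
  }
  structure(list(n_genes = as.integer(n_genes), design = design,
                 stages = stages, dispersion = dispersion, mu0 = mu0,
                 size_factor_range = size_factor_range,
                 planted_effects = planted_effects,
                 gene_prefix = gene_prefix),
            class = "count_sim_params")
}

#' Generate a negative-binomial count matrix
#'
#' Counts are drawn `counts[g, s] ~ NB(mean = sf_s * mu0_g *
#' 2^lfc[g, stage(s)], dispersion alpha_g)`; dispersion 0 gives Poisson
#' draws. The true size factors, baseline means and planted effects are
#' attached as ground truth.
#'
#' @param params A [count_sim_params()].
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A [count_matrix()] with `truth` containing `size_factors`,
#'   `mu0`, `log2fc` (genes x stages matrix) and `planted` (logical).
#' @export
gen_counts <- function(params, seed = 1) {
  stopifnot(inherits(params, "count_sim_params"))
  set.seed(seed)
  g <- params$n_genes
  design <- params$design
  s <- nrow(design)
  gene_ids <- sprintf("%s%05d", params$gene_prefix, seq_len(g))
  mu0 <- params$mu0
  if (is.null(mu0)) mu0 <- stats::rlnorm(g, log(150), 1.2)
  mu0 <- rep_len(mu0, g)
  alpha <- rep_len(params$dispersion, g)
  sf <- stats::runif(s, params$size_factor_range[1], params$size_factor_range[2])
  lfc <- matrix(0, g, length(params$stages),
                dimnames = list(gene_ids, params$stages))
  planted <- rep(FALSE, g)
  pe <- params$planted_effects
  if (!is.null(pe)) {
    idx <- if (!is.null(rownames(pe)) &&
               all(rownames(pe) %in% gene_ids)) match(rownames(pe), gene_ids)
           else seq_len(nrow(pe))
    lfc[idx, colnames(pe)] <- pe
    planted[idx] <- TRUE
  }
  stage_of <- match(design$group, params$stages)
  mean_mat <- (mu0 * 2^lfc[, stage_of, drop = FALSE]) *
    rep(sf, each = g)
  counts <- matrix(NA_real_, g, s, dimnames = list(gene_ids, design$sample))
  pois <- alpha <= 0
  if (any(pois))
    counts[pois, ] <- stats::rpois(sum(pois) * s, mean_mat[pois, ])
  if (any(!pois))
    counts[!pois, ] <- stats::rnbinom(sum(!pois) * s,
                                      mu = mean_mat[!pois, ],
                                      size = 1 / alpha[!pois])
  count_matrix(counts, design,
               truth = list(size_factors = stats::setNames(sf, design$sample),
                            mu0 = stats::setNames(mu0, gene_ids),
                            dispersion = stats::setNames(alpha, gene_ids),
                            log2fc = lfc, planted = planted))
}

#' Human- and mouse-like stage designs
#'
#' The study designs of the two species: human non-failing controls
#' (`NF`, n = 4) versus compensated hypertrophy (`CH`, n = 5) and moderate
#' heart failure (`mHF`, n = 5); mouse sham controls (n = 4) versus 1 week
#' (`w1TAC`, n = 4) and 8 weeks (`w8TAC`, n = 5) after transverse aortic
#' constriction.
#'
#' @param species `"human"` or `"mouse"`.
#' @return A design data frame (`sample`, `group`), control stage first.
#' @export
stage_design <- function(species = c("human", "mouse")) {
  species <- match.arg(species)
  if (species == "human") {
    grp <- rep(c("NF", "CH", "mHF"), c(4, 5, 5))
  } else {
    grp <- rep(c("sham", "w1TAC", "w8TAC"), c(4, 4, 5))
  }
  data.frame(sample = paste0(substr(species, 1, 1), "_", grp,
                             "_", stats::ave(seq_along(grp), grp, FUN = seq_along)),
             group = grp)
}

#' Cross-species concordance simulation preset
#'
#' Defines paired human and mouse count simulations over a shared 1:1
#' ortholog universe with a null background and a set of planted genes
#' whose per-stage effects are concordant across species. The first
#' planted gene mimics the CRISPLD1 profile: human log2 fold changes 1.6
#' (CH) and 2.6 (mHF), mouse 1.5 (1wTAC) and 2.3 (8wTAC). The remaining
#' planted genes are progressive (second-stage effect one log2 unit above
#' the first) with magnitudes cycling through 1.8-2.4 and alternating
#' sign, mouse effects at 92% of the human magnitude. Planted genes get a
#' baseline mean of 300; background genes draw log-normal means.
#'
#' @param n_genes Ortholog pairs simulated per species (default 20000).
#' @param n_planted Number of planted concordant genes (default 25; 0
#'   gives a pure-null preset).
#' @param dispersion NB dispersion (default 0.05).
#' @return A list of class `concordance_preset` with `human` and `mouse`
#'   [count_sim_params()] and the `ortholog_map` data frame
#'   (`human_id`, `mouse_id`, `mapping_type`).
#' @export
concordance_preset <- function(n_genes = 20000, n_planted = 25,
                               dispersion = 0.05) {
  if (n_planted > n_genes) stop("n_planted must be <= n_genes")
  human_ids <- sprintf("HGENE%05d", seq_len(n_genes))
  mouse_ids <- sprintf("MGENE%05d", seq_len(n_genes))
  pe_h <- pe_m <- NULL
  if (n_planted > 0) {
    k <- seq_len(n_planted)
    mag1 <- 1.8 + 0.2 * ((k - 2) %% 4)
    sgn <- ifelse(k %% 2 == 1, 1, -1)
    h1 <- sgn * mag1; h2 <- sgn * (mag1 + 1)
    m1 <- 0.92 * h1; m2 <- 0.92 * h2
    # first planted gene: the CRISPLD1-like profile
    h1[1] <- 1.6; h2[1] <- 2.6; m1[1] <- 1.5; m2[1] <- 2.3
    pe_h <- cbind(CH = h1, mHF = h2)
    rownames(pe_h) <- human_ids[k]
    pe_m <- cbind(w1TAC = m1, w8TAC = m2)
    rownames(pe_m) <- mouse_ids[k]
  }
  mk <- function(species, pe) {
    p <- count_sim_params(n_genes, stage_design(species),
                          dispersion = dispersion,
                          planted_effects = pe,
                          gene_prefix = if (species == "human") "HGENE" else "MGENE")
    p$planted_mu0 <- 300
    p$n_planted <- n_planted
    p
  }
  structure(list(human = mk("human", pe_h),
                 mouse = mk("mouse", pe_m),
                 n_planted = as.integer(n_planted),
                 ortholog_map = data.frame(human_id = human_ids,
                                           mouse_id = mouse_ids,
                                           mapping_type = "one2one")),
            class = "concordance_preset")
}

# Generate counts for one species of a concordance preset, fixing the
# planted genes' baseline means.
.gen_species_counts <- function(params, seed) {
  cm <- gen_counts(params, seed)
  if (!is.null(params$n_planted) && params$n_planted > 0 &&
      !is.null(params$planted_mu0)) {
    # redraw the planted rows at the preset baseline mean, deterministically
    set.seed(seed + 999983L)
    idx <- seq_len(params$n_planted)
    tr <- cm$truth
    tr$mu0[idx] <- params$planted_mu0
    stage_of <- match(params$design$group, params$stages)
    mm <- (tr$mu0[idx] * 2^tr$log2fc[idx, stage_of, drop = FALSE]) *
      rep(tr$size_factors, each = length(idx))
    alpha <- tr$dispersion[idx]
    cm$counts[idx, ] <- stats::rnbinom(length(idx) * nrow(params$design),
                                       mu = mm, size = 1 / alpha)
    cm$truth <- tr
  }
  cm
}

#' Generate finished human and mouse DE tables from a concordance preset
#'
#' Runs [gen_counts()] per species and the full differential-expression
#' chain ([de_table()]) for both stage contrasts of each species,
#' returning the finished tables plus the 1:1 ortholog map and planted
#' flags.
#'
#' @param preset A [concordance_preset()].
#' @param seed Integer seed (the mouse simulation uses `seed + 1`).
#' @return A list: `human` and `mouse` (each a list of [de_table()]s named
#'   `ch` and `hf`), `ortholog_map`, `planted` (named logical over human
#'   ids), `counts` (the two [count_matrix()] objects).
#' @export
gen_de_tables <- function(preset, seed = 1) {
  stopifnot(inherits(preset, "concordance_preset"))
  cm_h <- .gen_species_counts(preset$human, seed)
  cm_m <- .gen_species_counts(preset$mouse, seed + 1L)
  human <- list(ch = de_table(cm_h, contrast = c("CH", "NF")),
                hf = de_table(cm_h, contrast = c("mHF", "NF")))
  mouse <- list(ch = de_table(cm_m, contrast = c("w1TAC", "sham")),
                hf = de_table(cm_m, contrast = c("w8TAC", "sham")))
  list(human = human, mouse = mouse,
       ortholog_map = preset$ortholog_map,
       planted = stats::setNames(cm_h$truth$planted,
                                 rownames(cm_h$counts)),
       counts = list(human = cm_h, mouse = cm_m))
}

#' Write a count matrix and design as TSV
#'
#' @param cm A [count_matrix()].
#' @param counts_path TSV path (first column `gene_id`, then samples).
#' @param design_path TSV path for the two-column design.
#' @return `counts_path`, invisibly.
#' @export
write_counts <- function(cm, counts_path, design_path = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(design_path))
    utils::write.table(cm$design, design_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(counts_path)
}

#' Read a count matrix and design from TSV
#'
#' @param counts_path TSV with `gene_id` column then one column per sample.
#' @param design_path TSV with `sample` and `group` columns.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, design_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  design <- utils::read.delim(design_path)
  count_matrix(m, design)
}
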