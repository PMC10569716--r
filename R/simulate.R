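#' Configuration for the synthetic multi-region dataset generator
#'
#' Describes a paired multi-region RNA/ATAC dataset with planted ground
#' truth: multinomial regional composition per cell type, negative-binomial
#' UMI counts with multiplicative region-biased gene effects, mixture
#' doublets with bimodal doublet scores, cross-well barcode contamination,
#' and logistic peak-accessibility links to metacell expression.
#'
#' @param n_cells,n_genes,n_peaks Dataset dimensions.
#' @param regions Region labels.
#' @param cell_types Cell type (class) labels.
#' @param type_props Cell type proportions: a single probability vector, or
#'   a samples x types matrix (rownames = sample ids) for sample-specific
#'   composition.
#' @param composition Cell types x regions matrix of per-type regional
#'   composition weights; rows must sum to 1. Default uniform.
#' @param n_subtypes Subtypes nested within each cell type.
#' @param region_bias Tibble with columns `gene`, `region`, `log2fc`:
#'   multiplicative (2^log2fc) expression effects for cells of that region.
#' @param shifted_regions Regions whose cells are displaced in the embedding
#'   (defaults to the regions named in `region_bias`).
#' @param region_shift Embedding displacement for shifted regions, in units
#'   of the embedding noise SD (default 3).
#' @param doublet_frac Fraction of cells that are two-parent doublets
#'   (must be < 0.5).
#' @param doublet_beta,singlet_beta Beta(a, b) parameters for doublet and
#'   singlet doublet scores; defaults Beta(8, 2) and Beta(2, 30) create the
#'   bimodal structure the cluster-mean flagging rule assumes.
#' @param contamination Tibble with columns `barcode`, `frac`, `donor`:
#'   cross-well contamination events for
#'   [inject_barcode_contamination()].
#' @param planted_links Tibble with columns `peak`, `gene`, `beta`: logistic
#'   accessibility-expression links for [simulate_atac()].
#' @param atac_base_rate Baseline open probability for unlinked peaks.
#' @param n_samples,barcodes_per_sample Sample / RT-barcode layout.
#' @param sample_props Sampling probabilities over samples (default
#'   uniform); cells are spread over a sample's barcodes uniformly.
#' @param mean_umi Mean library size (UMI per cell); library sizes are
#'   log-normal with `lib_sigma` log-SD.
#' @param lib_sigma Log-SD of the library size distribution.
#' @param dispersion Negative-binomial dispersion `alpha` with
#'   `var = mu + alpha * mu^2` (the edgeR/DESeq2 convention); 0 gives
#'   Poisson counts.
#' @param embed_dim Embedding dimensionality.
#' @param seed Integer seed; all generator output is deterministic given the
#'   config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 2000, n_genes = 100, n_peaks = 50,
                       regions = c("A", "B", "C", "D"),
                       cell_types = c("T1", "T2", "T3"),
                       type_props = NULL, composition = NULL,
                       n_subtypes = 3,
                       region_bias = NULL, shifted_regions = NULL,
                       region_shift = 3,
                       doublet_frac = 0, doublet_beta = c(8, 2),
                       singlet_beta = c(2, 30),
                       contamination = NULL, planted_links = NULL,
                       atac_base_rate = 0.1,
                       n_samples = 2, barcodes_per_sample = 6,
                       sample_props = NULL,
                       mean_umi = 1500, lib_sigma = 0.3, dispersion = 0.5,
                       embed_dim = 10, seed = 1) {
  if (is.null(type_props)) {
    type_props <- rep(1 / length(cell_types), length(cell_types))
  }
  if (is.null(dim(type_props))) {
    type_props <- matrix(type_props, nrow = n_samples,
                         ncol = length(cell_types), byrow = TRUE,
                         dimnames = list(paste0("S", seq_len(n_samples)),
                                         cell_types))
  }
  if (any(abs(rowSums(type_props) - 1) > 1e-8)) {
    abort("type_props rows must sum to 1.")
  }
  if (is.null(composition)) {
    composition <- matrix(1 / length(regions), length(cell_types),
                          length(regions),
                          dimnames = list(cell_types, regions))
  }
  if (any(abs(rowSums(composition) - 1) > 1e-8)) {
    abort("composition weights must sum to 1 per cell type.")
  }
  if (doublet_frac < 0 || doublet_frac >= 0.5) {
    abort("doublet_frac must be in [0, 0.5).")
  }
  if (dispersion < 0) abort("dispersion must be >= 0.")
  region_bias <- region_bias %||%
    tibble(gene = character(), region = character(), log2fc = numeric())
  if (nrow(region_bias) && !all(region_bias$region %in% regions)) {
    abort("region_bias references unknown regions.")
  }
  contamination <- contamination %||%
    tibble(barcode = character(), frac = numeric(), donor = character())
  if (nrow(contamination) &&
      (any(contamination$frac <= 0) || any(contamination$frac >= 1))) {
    abort("contamination mixing fractions must lie in (0, 1).")
  }
  planted_links <- planted_links %||%
    tibble(peak = character(), gene = character(), beta = numeric())
  shifted_regions <- shifted_regions %||% unique(region_bias$region)
  sample_props <- sample_props %||% rep(1 / n_samples, n_samples)
  if (length(sample_props) != n_samples ||
      abs(sum(sample_props) - 1) > 1e-8) {
    abort("sample_props must be a probability vector over the samples.")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))
peak_ids <- function(n) sprintf("p%04d", seq_len(n))

#' Simulate per-cell metadata with planted doublets and contamination
#'
#' Generates the label layer of the synthetic dataset only (no counts):
#' sample, RT barcode, cell class/subtype, region, cluster id and doublet
#' scores, with contamination events from the config applied. Doublets are
#' assigned to their own cluster (emulating a post-clustering doublet
#' cluster) with Beta(8, 2) scores; singlet clusters are one per cell type.
#'
#' @param config A [sim_config()].
#' @return A list with `meta` (per-cell tibble, including `is_doublet` and
#'   `contaminated` truth columns) and `truth` (list with the planted
#'   configuration).
#' @export
simulate_cells <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cells_impl(config))
}

simulate_cells_impl <- function(config) {
  n <- config$n_cells
  samples <- rownames(config$type_props)
  sample_id <- sample(samples, n, replace = TRUE, prob = config$sample_props)
  rt_barcode <- character(n)
  type_idx <- integer(n)
  for (s in samples) {
    idx <- which(sample_id == s)
    if (!length(idx)) next
    pool <- paste0(s, "_bc", seq_len(config$barcodes_per_sample))
    rt_barcode[idx] <- sample(pool, length(idx), replace = TRUE)
    type_idx[idx] <- sample.int(length(config$cell_types), length(idx),
                                replace = TRUE,
                                prob = config$type_props[s, ])
  }
  cell_class <- config$cell_types[type_idx]
  region <- character(n)
  # subtype proportions per class, shared across samples
  sub_props <- lapply(seq_along(config$cell_types), function(t) {
    w <- rgamma(config$n_subtypes, shape = 4)
    w / sum(w)
  })
  cell_subtype <- character(n)
  for (t in seq_along(config$cell_types)) {
    idx <- which(type_idx == t)
    if (!length(idx)) next
    region[idx] <- sample(config$regions, length(idx), replace = TRUE,
                          prob = config$composition[t, ])
    cell_subtype[idx] <- paste0(
      config$cell_types[t], ".",
      sample.int(config$n_subtypes, length(idx), replace = TRUE,
                 prob = sub_props[[t]]))
  }

  n_doub <- round(config$doublet_frac * n)
  is_doublet <- c(rep(TRUE, n_doub), rep(FALSE, n - n_doub))
  doublet_score <- ifelse(
    is_doublet,
    rbeta(n, config$doublet_beta[1], config$doublet_beta[2]),
    rbeta(n, config$singlet_beta[1], config$singlet_beta[2]))
  cluster_id <- ifelse(is_doublet, length(config$cell_types) + 1L, type_idx)

  meta <- tibble(
    cell_id = sprintf("cell%06d", seq_len(n)),
    sample_id = sample_id, rt_barcode = rt_barcode,
    region = region, region_subclass = region,
    cell_class = cell_class, cell_subtype = cell_subtype,
    cluster_id = as.integer(cluster_id),
    doublet_score = doublet_score,
    is_doublet = is_doublet, contaminated = FALSE,
    total_umi = NA_integer_, n_genes = NA_integer_,
    mito_frac = rbeta(n, 2, 98), frip = NA_real_
  )
  meta <- inject_contamination_impl(meta, config)
  list(meta = meta,
       truth = list(config = config,
                    doublet_cluster = length(config$cell_types) + 1L,
                    contaminated_barcodes = unique(config$contamination$barcode),
                    biased_genes = config$region_bias,
                    planted_links = config$planted_links))
}

inject_contamination_impl <- function(meta, config) {
  for (i in seq_len(nrow(config$contamination))) {
    ev <- config$contamination[i, ]
    host <- which(meta$rt_barcode == ev$barcode)
    if (!length(host)) abort(sprintf("barcode '%s' not found.", ev$barcode))
    donors <- which(meta$sample_id == ev$donor)
    if (!length(donors)) abort(sprintf("donor sample '%s' not found.", ev$donor))
    n_mix <- round(ev$frac * length(host))
    if (!n_mix) next
    swap <- sample(host, n_mix)
    src <- sample(donors, n_mix, replace = TRUE)
    for (col in c("cell_class", "cell_subtype", "region", "region_subclass")) {
      meta[[col]][swap] <- meta[[col]][src]
    }
    meta$contaminated[swap] <- TRUE
  }
  meta
}

#' Inject cross-well barcode contamination into per-cell metadata
#'
#' Reassigns, for each contamination event in the config, the stated
#' fraction of the barcode's cells to labels drawn from the donor sample's
#' empirical composition (class, subtype and region are copied from randomly
#' drawn donor cells), marking them in the `contaminated` column. With
#' `frac = 0` (no events) the table is returned unchanged.
#'
#' @param meta Per-cell metadata tibble (as from [simulate_cells()]).
#' @param config A [sim_config()] whose `contamination` table names existing
#'   barcodes and donor samples.
#' @return `meta` with labels reassigned and `contaminated` flags updated.
#' @export
inject_barcode_contamination <- function(meta, config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, inject_contamination_impl(meta, config))
}

#' Simulate a multi-region snRNA-seq dataset with planted structure
#'
#' Counts are negative-binomial with per-cell log-normal library sizes,
#' per-class expression profiles, and multiplicative `2^log2fc` effects for
#' the configured region-biased genes. The embedding places each class at a
#' Gaussian cluster center, displaces cells of shifted regions by
#' `region_shift` noise-SD units along a region-specific direction, and adds
#' isotropic noise; doublets sit at the mean of their two parents (rates and
#' coordinates) with elevated doublet scores. Deterministic given the config
#' seed.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` ([sc_counts], RNA), `meta` (per-cell
#'   tibble including truth columns), `embedding` (tibble `cell_id` +
#'   `e1..ed`), and `truth`.
#' @export
simulate_rna <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    sim <- simulate_cells_impl(config)
    meta <- sim$meta
    n <- config$n_cells
    genes <- gene_ids(config$n_genes)
    n_types <- length(config$cell_types)

    profiles <- matrix(rgamma(n_types * config$n_genes, shape = 0.5),
                       n_types, config$n_genes)
    profiles <- profiles / rowSums(profiles)
    colnames(profiles) <- genes

    type_idx <- match(meta$cell_class, config$cell_types)
    rate <- profiles[type_idx, , drop = FALSE]
    if (nrow(config$region_bias)) {
      for (i in seq_len(nrow(config$region_bias))) {
        b <- config$region_bias[i, ]
        j <- match(b$gene, genes)
        if (is.na(j)) abort(sprintf("region_bias gene '%s' unknown.", b$gene))
        hit <- meta$region == b$region
        rate[hit, j] <- rate[hit, j] * 2^b$log2fc
      }
    }
    lib <- exp(rnorm(n, log(config$mean_umi) - config$lib_sigma^2 / 2,
                     config$lib_sigma))
    mu <- rate * lib

    d <- config$embed_dim
    centers <- matrix(rnorm(n_types * d, sd = 5), n_types, d)
    shift_dirs <- matrix(0, length(config$regions), d,
                         dimnames = list(config$regions, NULL))
    for (r in config$shifted_regions) {
      v <- rnorm(d)
      shift_dirs[r, ] <- v / sqrt(sum(v^2)) * config$region_shift
    }
    coords <- centers[type_idx, , drop = FALSE] +
      shift_dirs[meta$region, , drop = FALSE] +
      matrix(rnorm(n * d), n, d)

    # doublets: mean of two singlet parents for both rates and coordinates
    doub <- which(meta$is_doublet)
    sing <- which(!meta$is_doublet)
    if (length(doub)) {
      p1 <- sample(sing, length(doub), replace = TRUE)
      p2 <- sample(sing, length(doub), replace = TRUE)
      mu[doub, ] <- (mu[p1, , drop = FALSE] + mu[p2, , drop = FALSE]) / 2
      coords[doub, ] <- (coords[p1, , drop = FALSE] +
                           coords[p2, , drop = FALSE]) / 2
    }

    counts <- if (config$dispersion > 0) {
      matrix(rnbinom(n * config$n_genes, mu = mu,
                     size = 1 / config$dispersion),
             n, config$n_genes)
    } else {
      matrix(rpois(n * config$n_genes, lambda = mu), n, config$n_genes)
    }
    dimnames(counts) <- list(meta$cell_id, genes)

    meta$total_umi <- as.integer(rowSums(counts))
    meta$n_genes <- as.integer(rowSums(counts > 0))

    embedding <- as_tibble(coords, .name_repair = ~ paste0("e", seq_len(d))) |>
      mutate(cell_id = meta$cell_id, .before = 1)

    list(counts = sc_counts(counts, "rna"), meta = meta,
         embedding = embedding, truth = sim$truth)
  })
}

#' Simulate a paired snATAC-seq matrix with planted peak-gene links
#'
#' For each planted link `(peak, gene, beta)` the probability that a cell is
#' open at the peak is `plogis(b0 + beta * log2CPM_gene(metacell))`, where
#' the gene's log2CPM is the pseudobulk value of the cell's metacell and
#' `b0` centers the mean open rate at `atac_base_rate`. Unlinked peaks open
#' at the constant base rate. Deterministic given the config seed.
#'
#' @param config A [sim_config()] with `planted_links` filled.
#' @param rna The RNA [sc_counts] (paired cells).
#' @param metacells A [build_metacells()] assignment covering all cells.
#' @return An ATAC [sc_counts] (binary) over the same cells.
#' @export
simulate_atac <- function(config, rna, metacells) {
  stopifnot(inherits(config, "sim_config"), inherits(rna, "sc_counts"))
  cells <- rownames(rna$counts)
  if (!all(cells %in% metacells$cells)) {
    abort("metacell assignment must cover all cells.")
  }
  peaks <- peak_ids(config$n_peaks)
  genes <- colnames(rna$counts)
  if (nrow(config$planted_links) &&
      !all(config$planted_links$gene %in% genes)) {
    abort("planted link references unknown gene.")
  }
  withr::with_seed(config$seed + 2L, {
    n <- length(cells)
    if (!config$n_peaks) {
      m <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, 0),
                                dimnames = list(cells, character()))
      return(sc_counts(m, "atac"))
    }
    prob <- matrix(config$atac_base_rate, n, config$n_peaks,
                   dimnames = list(cells, peaks))
    if (nrow(config$planted_links)) {
      expr <- pseudobulk_log2cpm(rna, metacells)
      mc <- metacells$metacell_id[match(cells, metacells$cells)]
      for (i in seq_len(nrow(config$planted_links))) {
        lk <- config$planted_links[i, ]
        if (!lk$peak %in% peaks) abort(sprintf("unknown peak '%s'.", lk$peak))
        e <- expr[mc + 1L, lk$gene]
        b0 <- qlogis(config$atac_base_rate) - lk$beta * mean(e)
        prob[, lk$peak] <- plogis(b0 + lk$beta * e)
      }
    }
    open <- matrix(rbinom(length(prob), 1, prob), n, config$n_peaks,
                   dimnames = dimnames(prob))
    sc_counts(open, "atac")
  })
}

#' Simulate an external regulatory-evidence stream for peak-gene pairs
#'
#' Emulates an integration-based regulatory score (e.g. embedding cosine
#' similarity with a one-sided test): planted pairs receive small p-values,
#' null pairs uniform ones, with scores on a `-log10(p)` scale. Used to
#' close the loop on the two-stream candidate rule without re-training any
#' integration model.
#'
#' @param pairs Tibble with `gene_id`, `peak_id` (the tested pairs).
#' @param planted Tibble with `gene`, `peak` naming the true links.
#' @param seed Integer seed.
#' @param planted_rate Beta-like scale for planted p-values (upper bound of
#'   the planted uniform; default `1e-5`).
#' @return `pairs` with `external_score`, `external_p`, `external_p_adj`
#'   (BH across the table) appended.
#' @export
simulate_external_evidence <- function(pairs, planted, seed = 1,
                                       planted_rate = 1e-5) {
  withr::with_seed(seed, {
    key <- paste(pairs$gene_id, pairs$peak_id)
    hit <- key %in% paste(planted$gene, planted$peak)
    p <- runif(nrow(pairs))
    p[hit] <- runif(sum(hit), 0, planted_rate)
    pairs |>
      mutate(external_score = -log10(p), external_p = p,
             external_p_adj = p.adjust(p, method = "BH"))
  })
}

#' Simulate a full paired multiome dataset
#'
#' Convenience wrapper: RNA simulation, metacell construction on the true
#' embedding, then ATAC simulation with the configured planted links.
#'
#' @param config A [sim_config()].
#' @param target_per_metacell Target cells per metacell for
#'   [choose_n_meta()] (default 100).
#' @return A list with `rna`, `atac`, `meta`, `embedding`, `metacells`,
#'   `truth`.
#' @export
simulate_multiome <- function(config, target_per_metacell = 100) {
  rna <- simulate_rna(config)
  n_meta <- choose_n_meta(config$n_cells, target_per_metacell)
  mc <- build_metacells(rna$embedding, n_meta, seed = config$seed + 3L)
  atac <- simulate_atac(config, rna$counts, mc)
  list(rna = rna$counts, atac = atac, meta = rna$meta,
       embedding = rna$embedding, metacells = mc, truth = rna$truth)
}
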