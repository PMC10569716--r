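test_that("metacell count targets the mean occupancy by flooring", {
  expect_identical(choose_n_meta(2583967, 250), 10335L)
  expect_identical(choose_n_meta(1000, 250), 4L)
  expect_identical(choose_n_meta(999, 250), 3L)
  expect_error(choose_n_meta(100, 250), "at least")
  withr::with_seed(1, {
    for (i in 1:20) {
      n <- sample(1000:50000, 1); t <- sample(10:500, 1)
      if (n < t) next
      k <- choose_n_meta(n, t)
      expect_true(k * t <= n && n < (k + 1) * t)
    }
  })
})

test_that("metacell construction is deterministic and separates blobs", {
  withr::with_seed(3, {
    coords <- rbind(matrix(rnorm(100 * 2, mean = 0), 100, 2),
                    matrix(rnorm(100 * 2, mean = 20), 100, 2))
    rownames(coords) <- sprintf("c%03d", 1:200)
  })
  a <- build_metacells(coords, 2, seed = 7)
  b <- build_metacells(coords, 2, seed = 7)
  expect_identical(a$metacell_id, b$metacell_id)
  # assignment equals blob identity (up to label swap)
  blob <- rep(0:1, each = 100)
  agree <- mean(a$metacell_id == blob)
  expect_true(agree %in% c(0, 1))
  # n_meta = 1 puts everything in metacell 0
  one <- build_metacells(coords, 1, seed = 1)
  expect_true(all(one$metacell_id == 0L))
  expect_error(build_metacells(coords, 200, seed = 1), "smaller")
})

test_that("pseudobulk log2CPM matches hand arithmetic", {
  counts <- toy_counts(rbind(c(10, 990), c(3, 7)), cells = c("a", "b"),
                       genes = c("g1", "g2"))
  assign <- structure(list(cells = c("a", "b"), metacell_id = c(0L, 1L),
                           n_meta = 2L), class = "sc_metacells")
  pb <- pseudobulk_log2cpm(counts, assign)
  # single cell, gene count 10 of 1000 total: CPM 10000 -> log2(10001)
  expect_equal(pb["0", "g1"], log2(1e6 * 10 / 1000 + 1))
  expect_equal(round(pb["0", "g1"], 3), 13.288)
  # zero-count gene in a metacell -> log2(0 + 1) = 0
  counts0 <- toy_counts(rbind(c(0, 100)), cells = "a", genes = c("g1", "g2"))
  a0 <- structure(list(cells = "a", metacell_id = 0L, n_meta = 1L),
                  class = "sc_metacells")
  expect_equal(pseudobulk_log2cpm(counts0, a0)["0", "g1"], 0)
})

test_that("pseudobulk is order-invariant and CPM sums to one million", {
  cfg <- sim_config(n_cells = 300, n_genes = 25, seed = 2)
  sim <- simulate_rna(cfg)
  mc <- build_metacells(sim$embedding, 6, seed = 4)
  pb <- pseudobulk_log2cpm(sim$counts, mc)
  perm <- withr::with_seed(1, sample(300))
  shuffled <- sc_counts(sim$counts$counts[perm, ], "rna")
  expect_equal(pseudobulk_log2cpm(shuffled, mc), pb)
  expect_equal(unname(rowSums(2^pb - 1)), rep(1e6, 6))
})

test_that("peak-gene pairing honours the inclusive 150 kb window", {
  genes <- add_promoters(tibble::tibble(
    gene_id = "g", chrom = "chr1", strand = "+", tss = 500000L))
  # promoter is [498000, 500001); peaks at gap 0, 150000 and 150001
  peaks <- tibble::tibble(
    peak_id = c("overlap", "at_window", "beyond"),
    chrom = "chr1",
    start = c(499000L, 500001L + 150000L, 500001L + 150001L),
    end = c(499100L, 500001L + 150100L, 500001L + 150101L))
  out <- pair_peaks_genes(peaks, genes)
  expect_setequal(out$peak_id, c("overlap", "at_window"))
  # nearest covered peak base is 499099, i.e. 901 bp upstream of the TSS
  expect_equal(out$signed_distance[out$peak_id == "overlap"], -901L)
})

test_that("signed distances are strand-aware and zero on the TSS", {
  genes <- add_promoters(tibble::tibble(
    gene_id = c("gp", "gm"), chrom = "chr1", strand = c("+", "-"),
    tss = c(10000L, 10000L)))
  peaks <- tibble::tibble(peak_id = c("left", "on", "right"), chrom = "chr1",
                          start = c(8000L, 9950L, 12000L),
                          end = c(8100L, 10050L, 12100L))
  out <- pair_peaks_genes(peaks, genes)
  get <- function(g, p) out$signed_distance[out$gene_id == g & out$peak_id == p]
  expect_equal(get("gp", "on"), 0L)
  expect_lt(get("gp", "left"), 0)   # upstream of + gene
  expect_gt(get("gp", "right"), 0)
  expect_gt(get("gm", "left"), 0)   # downstream of - gene
  expect_lt(get("gm", "right"), 0)
})

test_that("pairing equals the brute-force oracle and ignores input order", {
  for (s in 1:8) {
    iv <- random_intervals(25, 6, span = 8e5, seed = s)
    out <- pair_peaks_genes(iv$peaks, iv$genes)
    expect_equal(as.data.frame(out), as.data.frame(oracle_pairs(iv$peaks, iv$genes)))
    perm <- withr::with_seed(s, sample(nrow(iv$peaks)))
    out2 <- pair_peaks_genes(iv$peaks[perm, ], iv$genes)
    expect_equal(out2, out)
  }
})

test_that("chromosomes present in one input only are skipped with warning", {
  genes <- add_promoters(tibble::tibble(gene_id = "g", chrom = "chrX",
                                        strand = "+", tss = 5000L))
  peaks <- tibble::tibble(peak_id = "p", chrom = "chr1", start = 100L,
                          end = 200L)
  expect_warning(out <- pair_peaks_genes(peaks, genes), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("link logistic regression flags degenerate inputs", {
  assign <- structure(list(cells = paste0("c", 1:40),
                           metacell_id = rep(0:3, each = 10), n_meta = 4L),
                      class = "sc_metacells")
  open <- rep(c(0, 1), 20)
  expect_equal(fit_link_logistic(open, assign, rep(5, 4))$reason,
               "constant_predictor")
  expect_equal(fit_link_logistic(rep(0, 40), assign, c(1, 2, 3, 4))$reason,
               "constant_response")
  # perfectly separated metacells -> separation flag, capped beta, NA p
  sep <- rep(c(0, 0, 1, 1), each = 10)
  out <- fit_link_logistic(sep, assign, c(1, 2, 30, 31))
  expect_equal(out$reason, "separation")
  expect_true(is.na(out$p))
  expect_lte(abs(out$beta), 25)
})

test_that("link logistic slope recovers the generative coefficient", {
  # planted beta = +2 on 50 metacells x 100 cells
  cfg <- sim_config(n_cells = 5000, n_genes = 60, n_peaks = 8,
                    planted_links = tibble::tibble(peak = "p0001",
                                                   gene = "g0001", beta = 2),
                    seed = 23)
  mm <- simulate_multiome(cfg, target_per_metacell = 100)
  pb <- pseudobulk_log2cpm(mm$rna, mm$metacells)
  out <- fit_link_logistic(as.numeric(mm$atac$counts[, "p0001"]),
                           mm$metacells, pb[, "g0001"])
  expect_lt(abs(out$beta - 2), 0.5)
  expect_lt(out$p, 1e-6)
})

test_that("aggregated binomial fit equals the per-cell glm", {
  withr::with_seed(11, {
    mc <- rep(0:9, each = 30)
    x_mc <- rnorm(10)
    x <- x_mc[mc + 1]
    y <- rbinom(300, 1, plogis(-1 + 0.8 * x))
  })
  assign <- structure(list(cells = paste0("c", 1:300),
                           metacell_id = as.integer(mc), n_meta = 10L),
                      class = "sc_metacells")
  out <- fit_link_logistic(y, assign, x_mc)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(out$beta, unname(coef(ref)[2]), tolerance = 1e-6)
  ref_lrt <- pchisq(ref$null.deviance - ref$deviance, 1, lower.tail = FALSE)
  expect_equal(out$p, ref_lrt, tolerance = 1e-6)
})

test_that("null pairs are calibrated near the nominal type-I rate", {
  cfg <- sim_config(n_cells = 3000, n_genes = 60, n_peaks = 60, seed = 29)
  mm <- simulate_multiome(cfg, target_per_metacell = 100)
  pb <- pseudobulk_log2cpm(mm$rna, mm$metacells)
  pairs <- tibble::tibble(
    gene_id = rep(colnames(pb)[1:20], each = 10),
    peak_id = rep(colnames(mm$atac$counts)[1:10], 20))
  out <- fit_peak_gene_links(mm$atac, mm$metacells, pb, pairs)
  fpr <- mean(out$p < 0.05, na.rm = TRUE)
  expect_lt(fpr, 0.12)
})

test_that("evidence combination applies the two-stream candidate rule", {
  links <- tibble::tibble(
    beta = c(1.3, 0.8, -2, 0.5),
    p_adj = c(0.01, 0.01, 0.001, 0.2),
    external_p_adj = c(0.02, 0.2, 0.03, 0.01))
  out <- combine_evidence(links)
  expect_equal(out$candidate, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$direction, c("positive", NA, "negative", NA))
  # missing external evidence -> untestable, not rejected
  na_out <- combine_evidence(dplyr::mutate(links,
                                           external_p_adj = NA_real_))
  expect_true(all(is.na(na_out$candidate)))
})

test_that("external score p-values are monotone in the score", {
  pairs <- tibble::tibble(gene_id = letters[1:5], peak_id = LETTERS[1:5],
                          external_score = c(0.1, 5, 2, 8, 1))
  out <- external_score_pvalues(pairs)
  expect_true(all(diff(out$external_p[order(out$external_score)]) <= 0))
  out2 <- external_score_pvalues(pairs, null_scores = rep(0, 1000))
  expect_true(all(out2$external_p[out2$external_score > 0] < 0.01))
})

test_that("ridge logistic matches glm at negligible penalty", {
  withr::with_seed(5, {
    x <- rnorm(500)
    y <- rbinom(500, 1, plogis(-0.5 + 1.2 * x))
  })
  b <- scregion:::ridge_logistic(x, y, lambda = 1e-10)
  expect_equal(unname(b), unname(coef(glm(y ~ x, family = binomial()))),
               tolerance = 1e-4)
})

test_that("differential accessibility marks class-specific peaks", {
  withr::with_seed(8, {
    classes <- rep(c("A", "B"), each = 100)
    m <- cbind(
      specific = c(rbinom(100, 1, 0.9), rbinom(100, 1, 0.05)),
      flat = rbinom(200, 1, 0.4),
      closed = rep(0, 200))
  })
  atac <- toy_counts(m, "atac", cells = paste0("c", 1:200),
                     genes = colnames(m))
  meta <- tibble::tibble(cell_id = paste0("c", 1:200), cell_class = classes)
  out <- differential_accessibility(atac, meta)
  get <- function(p, cl) out[out$peak_id == p & out$cell_class == cl, ]
  expect_true(get("specific", "A")$is_marker)
  expect_false(get("specific", "B")$is_marker)
  expect_false(get("flat", "A")$is_marker)
  cz <- get("closed", "A")
  expect_equal(cz$log2fc, 0)
  expect_false(cz$is_marker)
})

test_that("marker flags are invariant to cell order", {
  withr::with_seed(12, {
    classes <- sample(c("A", "B", "C"), 150, TRUE)
    m <- matrix(rbinom(150 * 5, 1, 0.3), 150, 5)
    m[classes == "B", 2] <- rbinom(sum(classes == "B"), 1, 0.95)
  })
  atac <- toy_counts(m, "atac", cells = paste0("c", 1:150),
                     genes = paste0("p", 1:5))
  meta <- tibble::tibble(cell_id = paste0("c", 1:150), cell_class = classes)
  out <- differential_accessibility(atac, meta)
  perm <- withr::with_seed(3, sample(150))
  atac2 <- sc_counts(atac$counts[perm, ], "atac")
  out2 <- differential_accessibility(atac2, meta)
  expect_equal(dplyr::arrange(out2, peak_id, cell_class),
               dplyr::arrange(out, peak_id, cell_class))
  expect_true(out$is_marker[out$peak_id == "p2" & out$cell_class == "B"])
})
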