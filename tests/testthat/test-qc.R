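rna_meta <- function(umi, genes, mito) {
  tibble::tibble(cell_id = paste0("c", seq_along(umi)),
                 total_umi = umi, n_genes = genes, mito_frac = mito)
}

test_that("RNA nucleus filter boundary semantics match the printed rules", {
  m <- rna_meta(umi = c(100L, 99L, 5000L, 5000L),
                genes = c(2499L, 10L, 2500L, 100L),
                mito = c(0.049, 0, 0.01, 0.05))
  out <- filter_nuclei(m, qc_thresholds(), "rna")
  expect_equal(out$kept, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$reason, c(NA, "min_umi", "max_genes", "max_mito"))
})

test_that("ATAC toy table keeps exactly the cells inside the UMI/FRiP rules", {
  m <- tibble::tibble(cell_id = paste0("c", 1:6),
                      total_umi = c(500L, 1000L, 99999L, 100000L, 2000L, 3000L),
                      frip = 0.5)
  out <- filter_nuclei(m, qc_thresholds(), "atac")
  expect_equal(sum(out$kept), 4)
  expect_equal(out$cell_id[out$kept], c("c2", "c3", "c5", "c6"))
  expect_equal(out$reason[!out$kept], c("umi_low", "umi_high"))
  # frip boundary is inclusive
  mf <- tibble::tibble(cell_id = "x", total_umi = 2000L, frip = 0.30)
  expect_true(filter_nuclei(mf, qc_thresholds(), "atac")$kept)
})

test_that("nucleus filtering is idempotent and order-independent", {
  withr::with_seed(1, {
    m <- rna_meta(umi = sample(50:300, 50, TRUE),
                  genes = sample(10:3000, 50, TRUE),
                  mito = runif(50, 0, 0.1))
  })
  out1 <- filter_nuclei(m, qc_thresholds(), "rna")
  perm <- sample(nrow(m))
  out2 <- filter_nuclei(m[perm, ], qc_thresholds(), "rna")
  expect_equal(out2[order(perm), ]$kept, out1$kept)
  kept <- m[out1$kept, ]
  expect_true(all(filter_nuclei(kept, qc_thresholds(), "rna")$kept))
})

test_that("missing FRiP for the ATAC modality is an error", {
  m <- tibble::tibble(cell_id = "c1", total_umi = 2000L, frip = NA_real_)
  expect_error(filter_nuclei(m, qc_thresholds(), "atac"), "frip")
})

test_that("per-cell doublet flag uses a strict inequality at 0.20", {
  m <- tibble::tibble(cell_id = paste0("c", 1:3),
                      doublet_score = c(0.20, 0.21, 0.19))
  out <- flag_doublet_cells(m)
  expect_equal(out$is_doublet, c(FALSE, TRUE, FALSE))
  expect_warning(
    out2 <- flag_doublet_cells(tibble::tibble(cell_id = "c",
                                              doublet_score = NA_real_)),
    "missing")
  expect_true(is.na(out2$is_doublet))
})

test_that("cluster doublet rule flags on the mean score, strictly above cut", {
  m <- tibble::tibble(cell_id = paste0("c", 1:6),
                      cluster_id = c(1L, 1L, 1L, 2L, 2L, 2L),
                      doublet_score = c(0.04, 0.05, 0.06, 0.15, 0.16, 0.17))
  out <- flag_doublet_clusters(m)
  expect_equal(out$flagged, c(FALSE, TRUE))
  # all means at or below the cut -> nothing flagged
  m2 <- dplyr::mutate(m, doublet_score = 0.15)
  expect_false(any(flag_doublet_clusters(m2)$flagged))
})

test_that("cluster flags agree with a brute-force group-by mean", {
  for (s in 1:5) {
    m <- withr::with_seed(s, tibble::tibble(
      cell_id = paste0("c", 1:200),
      cluster_id = sample.int(8, 200, TRUE),
      doublet_score = runif(200, 0, 0.3)))
    out <- flag_doublet_clusters(m, cut = 0.15)
    oracle <- tapply(m$doublet_score, m$cluster_id, mean) > 0.15
    expect_equal(out$flagged,
                 as.vector(oracle[as.character(out$cluster_id)]))
  }
})

test_that("planted doublet cluster is flagged, singlet clusters are not", {
  cfg <- sim_config(n_cells = 2000, doublet_frac = 0.08, seed = 21)
  sim <- simulate_cells(cfg)
  out <- flag_doublet_clusters(sim$meta)
  expect_true(out$flagged[out$cluster_id == sim$truth$doublet_cluster])
  expect_false(any(out$flagged[out$cluster_id != sim$truth$doublet_cluster]))
})

test_that("barcode screen: sample-mean composition gives zero JSD", {
  # two barcodes with identical composition
  m <- tibble::tibble(
    cell_id = paste0("c", 1:40),
    sample_id = "S1",
    rt_barcode = rep(c("b1", "b2"), each = 20),
    cell_class = rep(rep(c("X", "Y"), c(15, 5)), 2),
    cell_subtype = rep(rep(c("X.1", "X.2", "Y.1"), c(10, 5, 5)), 2))
  out <- screen_barcodes(m)
  expect_equal(out$class_jsd, c(0, 0), tolerance = 1e-12)
  expect_false(any(out$flagged))
})

test_that("barcode screen flags large, divergent barcodes only", {
  # 5 clean big barcodes (90% X), one divergent big barcode (2% X), one
  # divergent small barcode below the cell-count cut
  withr::with_seed(2, {
    sizes <- c(rep(11000L, 5), 11000L, 500L)
    names(sizes) <- c(paste0("clean", 1:5), "big_div", "small_div")
    probs <- rbind(matrix(rep(c(0.9, 0.1), 5), 5, 2, byrow = TRUE),
                   c(0.02, 0.98), c(0.02, 0.98))
    m <- purrr::map2(names(sizes), seq_along(sizes), function(b, i) {
      tibble::tibble(
        sample_id = "S1", rt_barcode = b,
        cell_class = sample(c("X", "Y"), sizes[i], TRUE, prob = probs[i, ]))
    }) |> purrr::list_rbind()
    m$cell_id <- paste0("c", seq_len(nrow(m)))
    m$cell_subtype <- paste0(m$cell_class, ".", sample(1:2, nrow(m), TRUE))
  })
  out <- screen_barcodes(m)
  expect_true(out$flagged[out$rt_barcode == "big_div"])
  expect_false(out$flagged[out$rt_barcode == "small_div"]) # too few cells
  expect_false(any(out$flagged[grepl("clean", out$rt_barcode)]))
})

test_that("a sample with one barcode is never flagged", {
  m <- tibble::tibble(cell_id = paste0("c", 1:30), sample_id = "S1",
                      rt_barcode = "only",
                      cell_class = rep(c("X", "Y"), c(20, 10)),
                      cell_subtype = rep(c("X.1", "Y.1"), c(20, 10)))
  out <- screen_barcodes(m)
  expect_equal(out$class_jsd, 0, tolerance = 1e-12)
  expect_false(out$flagged)
})

test_that("synthetic 50%-contaminated barcode is caught by the screen", {
  # small-scale version of the contamination screen (lowered cell-count cut);
  # host and donor samples differ in their majority class
  cfg <- sim_config(
    n_cells = 20000, n_samples = 2, barcodes_per_sample = 12,
    sample_props = c(0.85, 0.15),
    type_props = matrix(c(0.97, 0.015, 0.015, 0.015, 0.97, 0.015), 2, 3,
                        byrow = TRUE,
                        dimnames = list(c("S1", "S2"), c("T1", "T2", "T3"))),
    contamination = tibble::tibble(barcode = "S1_bc1", frac = 0.5,
                                   donor = "S2"),
    seed = 31)
  sim <- simulate_cells(cfg)
  out <- screen_barcodes(sim$meta,
                         qc_thresholds(barcode_min_cells = 1000L))
  expect_equal(out$rt_barcode[out$flagged], "S1_bc1")
})
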