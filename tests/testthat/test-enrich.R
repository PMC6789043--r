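# Enrichment module: DE sets, hypergeometric p-values, net-benefit matrix,
# single-cell QC, and cluster z-scores.

toy_table <- function() {
  # control mean 10; treated gene folds (after +1 pseudocount) span the
  # 1.5 threshold: 2x in, 1.4x out, exact boundary out
  genes <- c("up2x", "mid14", "bound", "down3x", "flat")
  ctrl <- matrix(10, 5, 2, dimnames = list(genes, NULL))
  fold <- c(2, 1.4, 1.5, 1 / 3, 1)
  trt <- matrix((10 + 1) * fold - 1, 5, 2, dimnames = list(genes, NULL))
  expression_table(cbind(ctrl, trt), c("EV", "EV", "TRT", "TRT"))
}

test_that("DE thresholds are strict on the ratio scale", {
  de <- de_sets(toy_table(), "TRT", "EV")
  expect_setequal(de$up, "up2x")
  expect_setequal(de$down, "down3x")
  expect_false("bound" %in% c(de$up, de$down))  # fold exactly 1.5 excluded
  expect_error(de_sets(toy_table(), "missing", "EV"), "absent")
})

test_that("hypergeometric p matches enumeration on small universes", {
  # closed form: universe 10, pathway 5, set 3, overlap 3 -> C(5,3)/C(10,3)
  uni <- letters[1:10]
  p <- hypergeom_enrichment(letters[1:3], letters[1:5], uni)
  expect_equal(p, choose(5, 3) / choose(10, 3), tolerance = 1e-12)
  expect_equal(p, 1 / 12, tolerance = 1e-12)
  # pathway = universe gives p = 1 for any set
  expect_equal(hypergeom_enrichment(letters[2:4], uni, uni), 1)
  # randomized instances vs brute-force enumeration, |universe| <= 12
  set.seed(42)
  for (i in 1:20) {
    N <- sample(6:12, 1)
    uni <- paste0("g", seq_len(N))
    pw <- sample(uni, sample.int(N - 1, 1))
    st <- sample(uni, sample.int(N - 1, 1))
    expect_equal(hypergeom_enrichment(st, pw, uni),
                 oracle_hypergeom_enum(st, pw, uni), tolerance = 1e-10)
  }
  expect_error(hypergeom_enrichment("x", letters[1:3], letters[1:5]),
               "subsets")
})

test_that("net benefit is antisymmetric and matches hand computation", {
  bulk <- gen_omics("bulk_expr", seed = 21, n_genes = 100, n_up = 8,
                    n_down = 8)
  uni <- rownames(bulk$table$expr)
  coll <- pathway_collection(
    list(up_enriched = bulk$truth$up,        # planted among up-genes only
         neutral = uni[41:60]),
    universe = uni)
  nb <- net_benefit_matrix(bulk$table, coll, conditions = "MiMaC")
  de <- de_sets(bulk$table, "MiMaC", "EV")
  p_up <- hypergeom_enrichment(de$up, bulk$truth$up, uni)
  p_dn <- hypergeom_enrichment(de$down, bulk$truth$up, uni)
  expect_equal(nb$score["up_enriched", "MiMaC"],
               log10(p_dn) - log10(p_up), tolerance = 1e-12)
  expect_gt(nb$score["up_enriched", "MiMaC"], 0)
  # p_up = p_down gives score 0; swapping sets flips the sign
  expect_equal(log10(1) - log10(1), 0)
  p_swap <- log10(p_up) - log10(p_dn)
  expect_equal(p_swap, -nb$score["up_enriched", "MiMaC"], tolerance = 1e-12)
  # serialization round-trips with labels
  f <- withr::local_tempfile(fileext = ".csv")
  write_net_benefit_csv(nb, f)
  back <- read_net_benefit_csv(f)
  expect_equal(back, nb$score, tolerance = 1e-6)
})

test_that("QC filter applies strict thresholds with boundary equality kept", {
  counts <- Matrix::Matrix(0, 4, 300, sparse = TRUE)
  colnames(counts) <- c("MT-1", sprintf("G%03d", 1:299))
  rownames(counts) <- sprintf("c%d", 1:4)
  # boundary cell: exactly 200 genes, 2000 UMIs, mito fraction exactly 0.40
  counts[1, 1] <- 800                      # mito: 800/2000 = 0.40 exactly
  counts[1, 2:199] <- rep(6, 198)          # 198 nuclear genes
  counts[1, 200] <- 12                     # 200th detected gene, 2000 UMIs
  stopifnot(Matrix::rowSums(counts)[1] == 2000,
            Matrix::rowSums(counts > 0)[1] == 200)
  # clear failures, one per reason
  counts[2, 1] <- 900; counts[2, 2:250] <- 5   # mito 0.42
  counts[3, 1] <- 50; counts[3, 2:150] <- 20   # 150 genes
  counts[4, 1] <- 50; counts[4, 2:250] <- 5    # 1295 UMIs
  qc <- qc_filter_cells(counts)
  expect_equal(qc$per_cell$keep, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(qc$per_cell$reason[2:4], c("mito", "genes", "umis"))
})

test_that("QC filter equals a row-wise recomputation oracle", {
  set.seed(17)
  sc <- gen_omics("sc_counts", seed = 17, n_cells = 50)
  # corrupt a few extra cells with random sparse noise
  extra <- Matrix::rsparsematrix(10, ncol(sc$counts), density = 0.02,
                                 rand.x = function(n) rpois(n, 20) + 1)
  colnames(extra) <- colnames(sc$counts)
  rownames(extra) <- sprintf("RND%02d", 1:10)
  counts <- rbind(sc$counts, extra)
  qc <- qc_filter_cells(counts)
  expect_equal(qc$per_cell$keep, oracle_qc_keep(counts))
  expect_error(qc_filter_cells(counts[, !grepl("^MT-", colnames(counts))]),
               "no mitochondrial gene")
})

test_that("cluster z-scores are centered and rank planted differences", {
  set.seed(33)
  expr <- cbind(markerA = c(rnorm(30, 10), rnorm(30, 20)),
                markerB = rnorm(60, 5),
                flatgene = rep(3, 60))
  clusters <- rep(c("c1", "c2"), each = 30)
  cz <- cluster_zscores(expr, clusters, c("markerA", "markerB", "flatgene"))
  # per-gene z-scores average to zero across all cells, so the
  # cluster-size-weighted mean of cluster means is zero
  expect_equal(mean(cz$z["markerA", ]), 0, tolerance = 1e-10)
  expect_gt(cz$z["markerA", "c2"], 0)
  expect_lt(cz$z["markerA", "c1"], 0)
  # constant gene flagged, not NaN
  expect_equal(cz$flagged, "flatgene")
  expect_true(all(is.na(cz$z["flatgene", ])))
  expect_false(any(is.nan(cz$z)))
})
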