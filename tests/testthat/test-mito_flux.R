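# Mitochondrial flux module: normalization, mitostress decomposition,
# palmitate utilization, and noise propagation.

mito_seg <- rep(c("basal", "oligomycin", "FCCP", "antimycin_rotenone"),
                each = 3)
palm_seg <- rep(c("baseline", "palmitate1", "palmitate2", "etomoxir"),
                each = 3)

test_that("per-cell normalization divides by the well cell count", {
  assay <- ocr_assay(matrix(1000, 12, 2), segments = mito_seg,
                     cell_counts = c(10, 20))
  norm <- normalize_ocr(assay)
  expect_equal(unname(norm$ocr[1, ]), c(100, 50))
  expect_error(normalize_ocr(ocr_assay(matrix(1, 12, 1),
                                       segments = mito_seg)),
               "missing")
  expect_error(ocr_assay(matrix(1, 12, 1), segments = mito_seg,
                         cell_counts = 0), "positive")
})

test_that("normalization commutes with the metric computation", {
  sim <- gen_ocr("Mut_12D_GlcFA", wells = 3,
                 noise = noise_model("gaussian", sd = 40, seed = 6))
  m1 <- mitostress_metrics(normalize_ocr(sim$assay))$per_well
  m2 <- mitostress_metrics(sim$assay)$per_well
  for (col in c("basal", "max_ocr", "atp_production", "proton_leak"))
    expect_equal(m1[[col]], m2[[col]] / sim$truth$cells_per_well,
                 tolerance = 1e-12)
})

test_that("mitostress arithmetic matches the quoted definitions", {
  ocr <- matrix(rep(c(100, 30, 250, 10), each = 3), ncol = 1)
  m <- mitostress_metrics(ocr_assay(ocr, segments = mito_seg,
                                    cell_counts = 1) |> normalize_ocr())
  expect_equal(unname(m$mean["atp_production"]), 70)
  expect_equal(unname(m$mean["proton_leak"]), 20)
  expect_equal(unname(m$mean["max_ocr"]), 220)
  expect_equal(unname(m$mean["non_mito"]), 10)
  expect_error(mitostress_metrics(
    ocr_assay(ocr[1:9, , drop = FALSE], segments = mito_seg[1:9],
              cell_counts = 1)), "missing mitostress segment")
})

test_that("atp + leak + non_mito = basal holds to machine precision", {
  sim <- gen_ocr("KO_12D_GlcFA", wells = 5,
                 noise = noise_model("gaussian", sd = 25, seed = 3))
  m <- mitostress_metrics(normalize_ocr(sim$assay))$per_well
  expect_equal(m$atp_production + m$proton_leak + m$non_mito, m$basal,
               tolerance = 1e-12)
})

test_that("metrics are invariant to well permutation", {
  sim <- gen_ocr("WT_12D_GlcFA", wells = 4,
                 noise = noise_model("gaussian", sd = 30, seed = 12))
  a <- sim$assay
  perm <- c(3, 1, 4, 2)
  b <- ocr_assay(a$ocr[, perm], time = a$time, segments = a$segments,
                 cell_counts = a$cell_counts[perm])
  ma <- mitostress_metrics(normalize_ocr(a))
  mb <- mitostress_metrics(normalize_ocr(b))
  expect_equal(sort(ma$per_well$max_ocr), sort(mb$per_well$max_ocr))
  expect_equal(unname(ma$mean), unname(mb$mean), tolerance = 1e-12)
})

test_that("palmitate utilization is palmitate2 mean minus last palmitate1", {
  ocr <- matrix(c(50, 50, 50, 70, 75, 80, 120, 120, 120, 40, 40, 40),
                ncol = 1)
  a <- ocr_assay(ocr, segments = palm_seg, cell_counts = 1)
  expect_equal(palmitate_utilization(normalize_ocr(a))$mean, 40)
  # flat vehicle assay gives zero
  flat <- ocr_assay(matrix(80, 12, 1), segments = palm_seg, cell_counts = 1)
  expect_equal(palmitate_utilization(normalize_ocr(flat))$mean, 0)
  expect_error(palmitate_utilization(
    ocr_assay(ocr[1:6, , drop = FALSE], segments = palm_seg[1:6],
              cell_counts = 1)), "missing palmitate2")
  # generator plants the utilization target
  sim <- gen_ocr(assay = "palmitate", wells = 2, cells_per_well = 1,
                 palmitate_utilization = 33)
  expect_equal(palmitate_utilization(normalize_ocr(sim$assay))$mean, 33)
})

test_that("metric noise scales like sigma * sqrt(2/m)", {
  sigma <- 20; m_pts <- 3
  set.seed(99)
  atp <- replicate(400, {
    sim <- gen_ocr("WT_12D_GlcFA", wells = 1, cells_per_well = 1,
                   points_per_segment = m_pts,
                   noise = noise_model("gaussian", sd = sigma))
    # noise can push the low antimycin plateau negative; that path warns
    suppressWarnings(
      mitostress_metrics(normalize_ocr(sim$assay))$per_well$atp_production)
  })
  expect_equal(sd(atp), sigma * sqrt(2 / m_pts), tolerance = 0.12)
})
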