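# Synthetic-data generators: seeded determinism, analytic ground truth,
# noise statistics, and planted effects.

test_that("presets store cited parameters with units and unique names", {
  presets <- cp_presets()
  expect_false(anyDuplicated(names(presets)) > 0)
  for (p in presets) {
    df <- as.data.frame(p)
    expect_true(all(nzchar(df$source)))
    expect_true(all(!is.na(df$value)))
    expect_true(is.character(df$units))
  }
  expect_error(cp_preset("no_such_group"), "unknown preset")
  expect_error(preset_value("EV", "ca_tau"), "no parameter")
})

test_that("noiseless imaging stack matches the analytic waveform exactly", {
  sim <- gen_imaging("WT_12D_GlcFA")
  frames <- sim$stack$frames
  # oracle: mean over the true mask minus true background vs analytic trace
  oracle <- oracle_trace_from_truth(sim)
  expect_equal(oracle, sim$truth$trace$value, tolerance = 1e-12)
  # background pixels are constant at the nominal level
  bg_px <- frames[, 1, 1]
  expect_true(all(bg_px == sim$truth$background))
  # peak fluorescence encodes the preset fold on the corrected scale
  expect_equal(max(sim$truth$trace$value) / min(sim$truth$trace$value),
               preset_value("WT_12D_GlcFA", "ca_fold"))
})

test_that("seeded generation is reproducible and noise follows the CLT", {
  n1 <- noise_model("gaussian", sd = 0.05, seed = 7)
  s1 <- gen_imaging("WT_12D_GlcFA", n_beats = 5, noise = n1)
  s2 <- gen_imaging("WT_12D_GlcFA", n_beats = 5, noise = n1)
  expect_identical(s1$stack$frames, s2$stack$frames)
  # per-frame background mean over ~1000 background pixels stays within
  # 3 * sd/sqrt(n) of nominal (checked on a sample of frames)
  bg_idx <- which(!s1$mask)
  n_bg <- length(bg_idx)
  expect_gt(n_bg, 1000)
  for (ti in c(1, 50, 100)) {
    fr <- s1$stack$frames[ti, , ]
    expect_lt(abs(mean(fr[bg_idx]) - s1$truth$background),
              3 * 0.05 / sqrt(n_bg))
  }
  # beat-event series are bit-reproducible too
  b1 <- gen_electro("Mut_Glc", "beat_events", n = 50, seed = 11)
  b2 <- gen_electro("Mut_Glc", "beat_events", n = 50, seed = 11)
  expect_identical(b1$series$intervals, b2$series$intervals)
})

test_that("generator preconditions are enforced", {
  expect_error(noise_model("gaussian", sd = -1), "non-negative")
  expect_error(gen_imaging("WT_12D_GlcFA", n_beats = 3), "at least 5 beats")
  expect_error(gen_imaging("WT_12D_GlcFA", frame_rate = 10), "20 fps")
  expect_error(gen_electro("Mut_Glc", "beat_events", n = 5), "n >= 10")
  expect_error(gen_electro("Mut_Glc", "beat_events", n = 20,
                           lag_cov = matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")
  expect_error(gen_micropost("EV", n_posts = 0), "at least one post")
  expect_error(gen_micropost("EV", k = -5), "k must be")
  expect_error(gen_ocr("WT_12D_GlcFA", non_mito = -20), "negative OCR")
})

test_that("micropost generator plants the preset force with linear scaling", {
  sim <- gen_micropost("EV", n_posts = 4)
  defl <- compute_deflections(sim$recording)
  expect_equal(max(rowSums(defl)) * sim$recording$k_post, 24,
               tolerance = 1e-10)
  # doubling all deflections doubles the ground-truth force
  rec2 <- sim$recording
  for (j in 1:2) {
    rest <- sim$recording$rest_positions[, j]
    rec2$positions[, , j] <- sweep(
      2 * sweep(matrix(sim$recording$positions[, , j],
                       dim(defl)[1], dim(defl)[2]), 2, rest), 2, -rest)
  }
  defl2 <- compute_deflections(rec2)
  expect_equal(max(rowSums(defl2)) * rec2$k_post, 48, tolerance = 1e-10)
})

test_that("OCR generator plateaus reproduce the metric arithmetic", {
  # plateau set (100, 30, 250, 10): atp 70, leak 20, max 220, non-mito 10
  sim <- gen_ocr("WT_12D_GlcFA", wells = 2, cells_per_well = 1)
  # overwrite plateaus directly through a custom preset-free construction
  seg <- rep(c("basal", "oligomycin", "FCCP", "antimycin_rotenone"), each = 3)
  ocr <- matrix(rep(rep(c(100, 30, 250, 10), each = 3), 2), ncol = 2)
  assay <- ocr_assay(ocr, segments = seg, cell_counts = c(1, 1))
  mm <- mitostress_metrics(normalize_ocr(assay))
  expect_equal(unname(mm$mean[c("atp_production", "proton_leak",
                                "max_ocr", "non_mito")]),
               c(70, 20, 220, 10))
  # all plateaus equal: every difference metric is zero
  flat <- ocr_assay(matrix(50, 12, 2), segments = seg, cell_counts = c(1, 1))
  mf <- mitostress_metrics(normalize_ocr(flat))
  expect_equal(unname(mf$mean[c("atp_production", "proton_leak", "max_ocr")]),
               c(0, 0, 0))
})

test_that("planted omics effects are recovered exactly", {
  bulk <- gen_omics("bulk_expr", seed = 3, n_up = 10, n_down = 10)
  de <- de_sets(bulk$table, "MiMaC", "EV")
  expect_setequal(de$up, bulk$truth$up)
  expect_setequal(de$down, bulk$truth$down)

  sc <- gen_omics("sc_counts", seed = 4, fail_mito = 3, fail_genes = 2,
                  fail_umis = 2)
  qc <- qc_filter_cells(sc$counts)
  expect_equal(unname(qc$removed["total"]), 7)
  expect_equal(unname(qc$removed[c("mito", "genes", "umis")]), c(3, 2, 2))
  removed_cells <- qc$per_cell$cell[!qc$per_cell$keep]
  expect_setequal(removed_cells, sc$truth$failing$cell)

  lip <- gen_omics("lipid_table", seed = 5)
  expect_s3_class(lip$table, "lipid_table")
  # at least one species per summarized class
  classes <- vapply(Filter(Negate(is.null), lip$table$species),
                    function(s) s$lipid_class, character(1))
  expect_true(all(c("CL", "MLCL", "AC", "TG", "FFA") %in% classes))
})

test_that("ground-truth objects round-trip losslessly through the writers", {
  sim <- gen_imaging("Mut_12D_GlcFA")
  tf <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(sim$truth$trace, tf)
  back <- read_trace_csv(tf)
  expect_equal(back$time, sim$truth$trace$time, tolerance = 1e-15)
  expect_equal(back$value, sim$truth$trace$value, tolerance = 1e-15)

  pf <- withr::local_tempfile(fileext = ".yaml")
  write_preset_yaml("WT_12D_GlcFA", pf)
  expect_equal(read_preset_yaml(pf)$parameters,
               cp_preset("WT_12D_GlcFA")$parameters)

  jf <- withr::local_tempfile(fileext = ".json")
  truth <- gen_ocr("KO_12D_GlcFA")$truth
  write_truth_json(truth, jf)
  back <- read_truth_json(jf)
  expect_equal(back$proton_leak, truth$proton_leak, tolerance = 1e-12)
  expect_equal(unname(unlist(back$plateaus)), unname(truth$plateaus),
               tolerance = 1e-12)
})
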