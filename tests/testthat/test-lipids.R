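# Lipidomics: name grammar, mTIC normalization, class sums and CL queries.

test_that("the species grammar parses every documented production", {
  sp <- parse_lipid_name("tetra[18:2]-CL")
  expect_equal(sp$lipid_class, "CL")
  expect_equal(nrow(sp$chains), 4)
  expect_true(all(sp$chains$carbons == 18 & sp$chains$double_bonds == 2))
  expect_false(any(sp$chains$hydroxyl))

  oh <- parse_lipid_name("AC(16:0-OH)")
  expect_equal(oh$lipid_class, "AC")
  expect_equal(oh$chains$carbons, 16)
  expect_true(oh$chains$hydroxyl)

  br <- parse_lipid_name("[18:1][18:1][18:2][18:2]")
  expect_equal(br$lipid_class, "CL")
  expect_equal(sum(br$chains$double_bonds), 6)

  tg <- parse_lipid_name("TG(16:0/18:1/18:2)")
  expect_equal(nrow(tg$chains), 3)
  expect_equal(parse_lipid_name("MLCL(18:1/18:2/18:2)")$lipid_class, "MLCL")
  expect_equal(parse_lipid_name("FFA(16:1)")$chains$double_bonds, 1)

  # chain-count invariants are enforced with a typed error
  expect_error(parse_lipid_name("CL(18:2/18:2)"),
               class = "lipid_parse_error")
  expect_error(parse_lipid_name("not_a_lipid"), class = "lipid_parse_error")
  err <- tryCatch(parse_lipid_name("CL(18:2/18:2)"),
                  lipid_parse_error = function(e) e)
  expect_true(err$position >= 1)
})

test_that("parse -> render -> parse is the identity on species", {
  names <- c("tetra[18:2]-CL", "CL(14:0/18:1/18:2/18:2)",
             "[18:1][18:1][18:2][18:2]", "MLCL(18:1/18:2/18:2)",
             "AC(16:0)", "AC(16:0-OH)", "FFA(18:1)",
             "TG(16:0/18:1/18:2)")
  for (nm in names) {
    sp1 <- parse_lipid_name(nm)
    sp2 <- parse_lipid_name(render_lipid_name(sp1))
    expect_equal(sp2$lipid_class, sp1$lipid_class)
    expect_equal(sp2$chains, sp1$chains)
  }
})

test_that("mTIC normalization equalizes identified sums and is idempotent", {
  ab <- rbind("AC(16:0)" = c(100, 300),
              "TG(16:0/18:1/18:2)" = c(300, 500),
              unknown1 = c(40, 80))
  colnames(ab) <- c("s1", "s2")
  tab <- lipid_table(ab, groups = c("WT", "KO"))
  expect_equal(sum(tab$identified), 2)
  norm <- mtic_normalize(tab)
  sums <- colSums(norm$abundance[norm$identified, ])
  expect_equal(unname(sums[1]), unname(sums[2]))
  # hand computation: mean identified sum (400+800)/2 = 600
  expect_equal(unname(sums[1]), 600)
  expect_equal(unname(norm$abundance["AC(16:0)", ]), c(150, 225))
  expect_equal(unname(norm$abundance["unknown1", ]), c(60, 60))
  # rescaling one sample's raw values leaves the normalized table unchanged
  # up to the global anchor (the cross-sample mean of identified sums moves
  # with the rescaling; all within- and between-sample ratios are invariant)
  ab2 <- ab; ab2[, 2] <- 10 * ab2[, 2]
  norm2 <- mtic_normalize(lipid_table(ab2, groups = c("WT", "KO")))
  expect_equal(norm2$abundance / norm2$abundance[1, 1],
               norm$abundance / norm$abundance[1, 1], tolerance = 1e-12)
  # and idempotence: normalizing twice changes nothing
  expect_equal(mtic_normalize(norm)$abundance, norm$abundance,
               tolerance = 1e-12)
})

test_that("class sums and CL chain queries match hand computation", {
  ab <- rbind("tetra[18:2]-CL" = c(3, 3),
              "[18:1][18:1][18:2][18:2]" = c(1, 1),
              "AC(16:0)" = c(5, 10),
              "AC(8:0)" = c(2, 2),
              "AC(16:0-OH)" = c(4, 8),
              "TG(16:0/18:1/18:2)" = c(7, 7))
  colnames(ab) <- c("a", "b")
  tab <- lipid_table(ab, groups = c("WT", "Mut"))
  # CLs containing an 18:1 chain: only the mixed species (sum 1)
  s <- class_summaries(tab, lipid_query("CL", contains_chain = c(18, 1)))
  expect_equal(s$sum, c(1, 1))
  # tetra[18:2]-CL is 3 of 4 total CL signal
  rel <- cl_relative_amount(tab, "tetra[18:2]-CL")
  expect_equal(rel$fraction, c(0.75, 0.75))
  # long-chain acyl-carnitines (>= 14 C), plain vs hydroxylated
  lc <- class_summaries(tab, lipid_query("AC", min_chain_carbons = 14))
  expect_equal(lc$sum, c(9, 18))
  oh <- class_summaries(tab, lipid_query("AC", min_chain_carbons = 14,
                                         hydroxyl = TRUE))
  expect_equal(oh$sum, c(4, 8))
  # empty predicate: no C14+ species among medium-chain-only subset
  mc <- class_summaries(tab, lipid_query("AC", max_chain_carbons = 12,
                                         min_chain_carbons = 14))
  expect_equal(mc$sum, c(0, 0))
  # partition additivity: long + medium = all AC
  all_ac <- class_summaries(tab, lipid_query("AC"))
  med <- class_summaries(tab, lipid_query("AC", max_chain_carbons = 12))
  expect_equal(lc$sum + med$sum, all_ac$sum)
})

test_that("fold changes are anchored to the reference group", {
  lip <- gen_omics("lipid_table", seed = 44,
                   lipid_groups = c(WT = 3, Mut = 3))
  tab <- mtic_normalize(lip$table)
  fc <- fold_change_matrix(tab, "WT")
  ref_cols <- tab$groups == "WT"
  expect_equal(unname(rowMeans(fc[, ref_cols])),
               rep(1, nrow(fc)), tolerance = 1e-12)
  expect_error(fold_change_matrix(tab, "nope"), "absent")
  # zero reference mean flags the row
  ab <- rbind("AC(16:0)" = c(0, 0, 5, 5), "AC(18:1)" = c(1, 1, 2, 2))
  colnames(ab) <- sprintf("s%d", 1:4)
  t2 <- lipid_table(ab, groups = c("WT", "WT", "KO", "KO"))
  expect_warning(fc2 <- fold_change_matrix(t2, "WT"), "flagged")
  expect_true(all(is.na(fc2["AC(16:0)", ])))
  # post-mTIC fold changes are invariant to arbitrary per-sample rescaling
  # of the raw data (mTIC absorbs sample-level scale)
  ab3 <- tab$abundance %*% diag(c(1, 10, 0.2, 3, 1, 7))
  dimnames(ab3) <- dimnames(tab$abundance)
  t3 <- lipid_table(ab3, groups = tab$groups, identified = tab$identified)
  expect_equal(fold_change_matrix(mtic_normalize(t3), "WT"),
               fold_change_matrix(tab, "WT"), tolerance = 1e-12)
})

test_that("the presence filter drops group-sparse species", {
  ab <- rbind("AC(16:0)" = c(1, 1, 1, 1),
              "AC(18:1)" = c(1, 0, 0, 0),
              "FFA(16:1)" = c(1, 1, 0, 1))
  colnames(ab) <- sprintf("s%d", 1:4)
  tab <- lipid_table(ab, groups = c("WT", "WT", "KO", "KO"))
  kept <- filter_presence(tab, 0.5)
  expect_setequal(rownames(kept$abundance), c("AC(16:0)", "FFA(16:1)"))
})
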