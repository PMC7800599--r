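# Hand-built Ct table: explicit wells for deterministic ddCt arithmetic.
ct_fixture <- function(gene_dct_ctrl, gene_dct_kd, nrep = 2, ref_ct = 20) {
  rows <- list()
  for (r in seq_len(nrep)) {
    for (cond in c("control", "knockdown")) {
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, replicate = sprintf("r%d", r), gene = "Ras", ct = ref_ct)
      dct <- if (cond == "control") gene_dct_ctrl else gene_dct_kd
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, replicate = sprintf("r%d", r), gene = names(dct),
        ct = ref_ct + dct)
    }
  }
  ct_table(do.call(rbind, rows), "Ras")
}

test_that("ddCt arithmetic: identity, halving, and the efficiency exponent", {
  # equal Ct everywhere -> fold change 1
  ct <- ct_fixture(c(gA = 2), c(gA = 2))
  expect_equal(relative_expression(ct, "gA")$fold_change, 1.0)
  # ddCt = +1 at efficiency 2 -> fold 0.5
  ct2 <- ct_fixture(c(gA = 2), c(gA = 3))
  expect_equal(relative_expression(ct2, "gA")$fold_change, 0.5)
  # efficiency generalizes: 1.9^(-1)
  expect_equal(relative_expression(ct2, "gA", efficiency = 1.9)$fold_change, 1 / 1.9)
  # ddCt = -1 -> fold 2
  ct3 <- ct_fixture(c(gA = 2), c(gA = 1))
  expect_equal(relative_expression(ct3, "gA")$fold_change, 2)
})

test_that("input contracts: reference gene, missing conditions, bad thresholds", {
  ct <- ct_fixture(c(gA = 2), c(gA = 2))
  expect_error(relative_expression(ct, "Ras"), "reference")
  expect_error(relative_expression(ct, "ghost"), "ghost")
  df <- as.data.frame(ct)
  df <- df[!(df$gene == "gA" & df$condition == "knockdown"), ]
  expect_error(relative_expression(ct_table(df, "Ras"), "gA"), "knockdown")
  # reference must be present in every (condition, replicate)
  df2 <- as.data.frame(ct)[-1, ]
  expect_error(ct_table(df2, "Ras"), "Ras")
  expect_error(classify_response(1.0, threshold = 0), "threshold")
  expect_error(classify_response(1.0, threshold = 1), "threshold")
})

test_that("classification thresholds are inclusive step functions of fold change", {
  expect_equal(classify_response(0.80), "down")      # decreased by exactly 20%
  expect_equal(classify_response(0.799), "down")
  expect_equal(classify_response(0.801), "unchanged")
  expect_equal(classify_response(1.19), "unchanged")
  expect_equal(classify_response(1.20), "up")
  expect_equal(classify_response(1.0), "unchanged")
  # exactly two breakpoints, at 1 - t and 1 + t
  fc <- seq(0.5, 1.6, by = 0.001)
  cl <- classify_response(fc, 0.2)
  flips <- which(cl[-1] != cl[-length(cl)])
  expect_length(flips, 2)
  expect_equal(fc[flips + 1], c(0.801, 1.200), tolerance = 1e-9)
})

test_that("normalization invariance: per-replicate Ct offsets cancel", {
  ct <- ct_fixture(c(gA = 2, gB = -1), c(gA = 3, gB = -2), nrep = 3)
  base <- relative_expression(ct, "gA")
  df <- as.data.frame(ct)
  sel <- df$replicate == "r2"          # a pipetting offset on one replicate
  df$ct[sel] <- df$ct[sel] + 1.7
  shifted <- ct_table(df, "Ras")
  for (g in c("gA", "gB")) {
    expect_equal(relative_expression(shifted, g)$fold_change,
                 relative_expression(ct, g)$fold_change)
  }
  expect_equal(relative_expression(shifted, "gA")$sem, base$sem)
})

test_that("knockdown efficiency is the reciprocal fold with the 5x validity flag", {
  # ddCt = log2(5) -> fold decrease exactly 5, boundary flag true
  ct5 <- ct_fixture(c(tgt = 0), c(tgt = log2(5)))
  ke <- knockdown_efficiency(ct5, "tgt")
  expect_equal(ke$fold_decrease, 5.0)
  expect_true(ke$effective)
  ct0 <- ct_fixture(c(tgt = 0), c(tgt = 0))
  ke0 <- knockdown_efficiency(ct0, "tgt")
  expect_equal(ke0$fold_decrease, 1.0)
  expect_false(ke0$effective)
})

test_that("planted fold changes are recovered exactly at zero noise and within 3 SEM with noise", {
  cfg <- simulation_config(seed = 101, ct_noise_sd = 0)
  ct0 <- generate_qpcr(cfg)
  truth <- attr(ct0, "truth")
  for (i in seq_len(nrow(truth))) {
    expect_equal(relative_expression(ct0, truth$gene[i], cfg$efficiency)$fold_change,
                 truth$fold_change[i], tolerance = 1e-12)
  }
  # reference gene's own fold change is 1 by construction
  df <- as.data.frame(ct0); df$gene[df$gene == "Ras"] <- "RasCopy"
  df <- rbind(as.data.frame(ct0), df[df$gene == "RasCopy", ])
  expect_equal(relative_expression(ct_table(df, "Ras"), "RasCopy")$fold_change, 1.0)
  # noisy planted 0.7 recovered within 3 SEM
  cfgn <- simulation_config(seed = 103, ct_noise_sd = 0.1,
                            qpcr_fold_changes = c(gX = 0.7), qpcr_replicates = 3)
  ctn <- generate_qpcr(cfgn)
  re <- relative_expression(ctn, "gX")
  expect_lt(abs(re$fold_change - 0.7), 3 * max(re$sem, 0.02))
  # planted 8-fold knockdown recovered
  ke <- knockdown_efficiency(ctn, cfgn$target_gene)
  expect_lt(abs(ke$fold_decrease - 8), 1)
  expect_true(ke$effective)
})

test_that("the synthetic 21-gene panel classifies 7 down / 3 up / 11 unchanged", {
  cfg <- simulation_config(seed = 107, ct_noise_sd = 0.05, qpcr_replicates = 3)
  ct <- generate_qpcr(cfg)
  panel <- expression_panel(ct, efficiency = cfg$efficiency, threshold = 0.20)
  assayed <- panel[panel$gene %in% names(cfg$qpcr_fold_changes), ]
  expect_equal(nrow(assayed), 21)
  tab <- table(factor(assayed$response, levels = c("down", "up", "unchanged")))
  expect_equal(as.vector(tab), c(7, 3, 11))
  # determinism of the generator
  expect_identical(as.data.frame(generate_qpcr(cfg)), as.data.frame(ct))
})
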