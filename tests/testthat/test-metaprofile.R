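make_track <- function(values_list, sizes) signal_track(values_list, sizes)

test_that("a constant track yields a constant profile matrix", {
  sizes <- c(c1 = 50000)
  tr <- make_track(list(c1 = Rle(3.25, 50000)), sizes)
  sites <- site_set("c1", c(10000, 20000, 30000), "s")
  pm <- extract_profile_matrix(tr, sites, flank = 1000, bin_width = 50)
  expect_equal(dim(pm), c(3, 41))
  expect_true(all(pm == 3.25))
  ap <- average_profile(pm)
  expect_true(all(ap$mean == 3.25))
  expect_true(all(ap$n == 3))
  expect_equal(ap$bin_center, seq(-1000, 1000, by = 50))
})

test_that("bins with no track data are no-data, half-covered anchors split left/right", {
  sizes <- c(c1 = 50000)
  v <- rep(NA_real_, 50000)
  v[25000:50000] <- 7        # defined only right of the anchor
  tr <- make_track(list(c1 = Rle(v)), sizes)
  sites <- site_set("c1", 25000, "s")
  pm <- extract_profile_matrix(tr, sites, flank = 1000, bin_width = 50)
  centers <- attr(pm, "bin_centers")
  expect_true(all(is.na(pm[1, centers < -25])))
  expect_true(all(pm[1, centers >= 25] == 7, na.rm = FALSE))
  # sites off the track's chromosomes warn and give all-NA rows
  sites2 <- site_set(c("c1", "cX"), c(25000, 100), "s2")
  expect_warning(pm2 <- extract_profile_matrix(tr, sites2, 1000, 50), "cX")
  expect_true(all(is.na(pm2[2, ])))
})

test_that("bin values are length-weighted means of a step function", {
  sizes <- c(c1 = 10000)
  v <- rep(2, 10000)
  # inside the central bin of site 5000 (0-based offsets -25..24 -> 1-based 4976..5025):
  # 10 bases at 8, 15 bases at 4, rest 2 -> mean = (10*8 + 15*4 + 25*2)/50 = 3.8
  v[4976:4985] <- 8
  v[4986:5000] <- 4
  tr <- make_track(list(c1 = Rle(v)), sizes)
  pm <- extract_profile_matrix(tr, site_set("c1", 5000, "s"), flank = 1000, bin_width = 50)
  centers <- attr(pm, "bin_centers")
  expect_equal(unname(pm[1, centers == 0]), (10 * 8 + 15 * 4 + 25 * 2) / 50)
})

test_that("profile extraction is linear in the track and translation equivariant", {
  set.seed(41)
  sizes <- c(c1 = 60000)
  v <- runif(60000, 1, 5)
  tr <- make_track(list(c1 = Rle(v)), sizes)
  sites <- site_set("c1", c(15000, 30000, 42000), "s")
  pm <- extract_profile_matrix(tr, sites, 2000, 100)
  # linearity
  tr2 <- make_track(list(c1 = Rle(3 * v + 1)), sizes)
  pm2 <- extract_profile_matrix(tr2, sites, 2000, 100)
  expect_equal(unclass(pm2), 3 * unclass(pm) + 1, ignore_attr = TRUE)
  # translation: shift sites and track by the same offset
  off <- 777
  v_shift <- c(rep(NA_real_, off), v)[1:60000]
  tr3 <- make_track(list(c1 = Rle(v_shift)), sizes)
  sites3 <- site_set("c1", sites$pos + off, "s")
  pm3 <- extract_profile_matrix(tr3, sites3, 2000, 100)
  expect_equal(unclass(pm3), unclass(pm), ignore_attr = TRUE)
})

test_that("average_profile means, counts and the balanced-design identity", {
  m <- structure(matrix(c(1, 3, 2, NA), nrow = 2), class = c("profile_matrix", "matrix"),
                 bin_centers = c(-50, 0), flank = 50, bin_width = 50, set_name = "x")
  ap <- average_profile(m)
  expect_equal(ap$mean, c(2, 2))
  expect_equal(ap$n, c(2, 1))
  # all-NA bin -> no-data mean
  m[, 2] <- NA
  ap2 <- average_profile(m)
  expect_true(is.na(ap2$mean[2]))
  expect_equal(ap2$n[2], 0)
  # balanced design: grand mean equals mean of row means when complete
  set.seed(2)
  mm <- matrix(runif(50), 5, 10)
  attr(mm, "bin_centers") <- seq(-225, 225, by = 50)
  class(mm) <- c("profile_matrix", "matrix")
  attr(mm, "flank") <- 225; attr(mm, "bin_width") <- 50
  expect_equal(mean(average_profile(mm)$mean), mean(rowMeans(mm)))
})

test_that("log2 enrichment matches the per-base formula and handles missing data", {
  set.seed(6)
  sizes <- c(c1 = 2000)
  t_v <- runif(2000, 0, 50); c_v <- runif(2000, 0, 50)
  t_v[100:199] <- NA; c_v[150:249] <- NA
  tr_t <- make_track(list(c1 = Rle(t_v)), sizes)
  tr_c <- make_track(list(c1 = Rle(c_v)), sizes)
  expect_error(log2_enrichment(tr_t, tr_c, pseudocount = 0), "pseudocount")
  enr <- log2_enrichment(tr_t, tr_c, pseudocount = 1)
  got <- as.numeric(enr$values$c1)
  want <- log2((t_v + 1) / (c_v + 1))
  expect_equal(got, want)
  expect_true(all(is.na(got[100:249])))
  # identity and doubling limits
  same <- log2_enrichment(tr_c, tr_c, 1)
  expect_true(all(as.numeric(same$values$c1)[!is.na(c_v)] == 0))
  big <- make_track(list(c1 = Rle(1e6, 2000)), sizes)
  dbl <- make_track(list(c1 = Rle(2e6, 2000)), sizes)
  expect_equal(as.numeric(log2_enrichment(dbl, big, 1)$values$c1)[1], 1, tolerance = 1e-5)
})

test_that("three-curve bundle: self-comparison, constant track, determinism", {
  set.seed(9)
  cfg <- small_config()
  gen <- generate_genome(cfg)
  # constant track -> three flat identical curves
  tr <- make_track(lapply(gen$chrom_sizes, function(L) Rle(2.5, L)), gen$chrom_sizes)
  prom <- sample_random_promoters(gen$genes, 150, seed = 33)
  bundle <- three_curve_bundle(tr, prom, gen$genes, gen$chrom_sizes, seed = 33,
                               flank = 1000, bin_width = 50)
  df <- as.data.frame(bundle)
  expect_true(all(df$mean_factor == 2.5 & df$mean_promoters == 2.5 & df$mean_random == 2.5))
  # factor sites sampled with the same seed as the promoter control -> identical curves
  expect_identical(df$mean_factor, df$mean_promoters)
  # determinism of the seeded control samplers
  bundle2 <- three_curve_bundle(tr, prom, gen$genes, gen$chrom_sizes, seed = 33,
                                flank = 1000, bin_width = 50)
  expect_identical(as.data.frame(bundle), as.data.frame(bundle2))
})

test_that("planted enrichment is recovered by the factor curve and not the controls", {
  cfg <- simulation_config(seed = 19, chrom_lengths = c(c1 = 1.5e6, c2 = 1.2e6),
                           n_genes = 600, bump_amplitude = 5, bump_width = 200,
                           noise_sd = 1, signal_bin = 25)
  gen <- generate_genome(cfg)
  factor_sites <- sample_random_sites(gen$chrom_sizes, 400, seed = 50, margin = 4000)
  tr <- generate_signal_track(gen$chrom_sizes, factor_sites, cfg, "enrich", seed = 51)
  bundle <- three_curve_bundle(tr, factor_sites, gen$genes, gen$chrom_sizes,
                               seed = 52, flank = 3000, bin_width = 50)
  pf <- bundle$profiles$factor
  centers <- pf$bin_center
  ctr <- which(centers == 0)
  far <- abs(centers) >= 2500
  # per-site paired peak-above-own-flank estimate (bins within a site are
  # correlated, so the SE comes from site-to-site variation); neighbouring
  # sites' bumps elevate every bin equally and cancel in the difference
  m <- bundle$matrices$factor
  amp_i <- m[, ctr] - rowMeans(m[, far, drop = FALSE], na.rm = TRUE)
  expect_lt(abs(mean(amp_i) - cfg$bump_amplitude),
            3 * stats::sd(amp_i) / sqrt(length(amp_i)))
  expect_lte(abs(centers[which.max(pf$mean)]), 50)
  # control curves flat: per-site central-minus-flank difference within noise
  for (nm in c("promoters", "random")) {
    mc <- bundle$matrices[[nm]]
    flat_i <- rowMeans(mc[, abs(centers) <= 100, drop = FALSE], na.rm = TRUE) -
      rowMeans(mc[, far, drop = FALSE], na.rm = TRUE)
    flat_i <- flat_i[is.finite(flat_i)]
    expect_lt(abs(mean(flat_i)), 3 * stats::sd(flat_i) / sqrt(length(flat_i)))
  }
})

test_that("planted depletion pulls the central bins strictly below the flanks", {
  cfg <- simulation_config(seed = 29, chrom_lengths = c(c1 = 1.4e6), n_genes = 350,
                           bump_amplitude = 5, bump_width = 200, noise_sd = 1)
  gen <- generate_genome(cfg)
  sites <- sample_random_sites(gen$chrom_sizes, 300, seed = 60, margin = 4000)
  tr <- generate_signal_track(gen$chrom_sizes, sites, cfg, "deplete", seed = 61)
  pm <- extract_profile_matrix(tr, sites, flank = 3000, bin_width = 50)
  ap <- average_profile(pm)
  central <- ap$mean[abs(ap$bin_center) <= 100]
  flankb <- ap$mean[abs(ap$bin_center) >= 2000]
  expect_true(all(central < min(flankb)))
})
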