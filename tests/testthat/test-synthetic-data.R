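test_that("panel and library meet the study design", {
  pl <- build_panel_and_library(seed = 1)
  expect_equal(nrow(pl$panel), 209)
  # 202 targets x 2 guides + 50 controls
  expect_equal(nrow(pl$library), 454)
  expect_equal(sum(pl$library$is_control), 50)
  expect_equal(sum(!pl$library$is_control), 404)
  # controls carry identity effects
  ctrl <- pl$library[pl$library$is_control, ]
  expect_true(all(ctrl$depletion_factor == 1))
  expect_true(all(ctrl$induction_z == 0 & ctrl$delta_z == 0))
  # zonation markers present with the right slopes
  mk <- zonation_markers()
  pp <- pl$panel[pl$panel$gene %in% mk$periportal, ]
  pc <- pl$panel[pl$panel$gene %in% mk$pericentral, ]
  expect_equal(nrow(pp), 7)
  expect_equal(nrow(pc), 16)
  expect_true(all(pp$zonal_slope > 0))
  expect_true(all(pc$zonal_slope < 0))
  # determinism
  pl2 <- build_panel_and_library(seed = 1)
  expect_identical(pl$library$guide, pl2$library$guide)
  expect_identical(pl$panel$baseline, pl2$panel$baseline)
})

test_that("transduction follows the configured Poisson structure", {
  lib <- tibble::tibble(guide = sprintf("g%03d", 1:100))
  scr <- simulate_tissue(1e5, field_um = 2000, lambda = 0.3,
                         library = lib, seed = 11)
  nb <- lengths(scr$cells$barcodes)
  # fraction with >= 1 barcode ~ 1 - exp(-0.3) = 25.9%
  expect_equal(mean(nb > 0), 1 - exp(-0.3), tolerance = 0.02)
  # among positives, exactly one ~ lambda e^-l / (1 - e^-l) = 85.7%
  expect_equal(mean(nb[nb > 0] == 1),
               0.3 * exp(-0.3) / (1 - exp(-0.3)), tolerance = 0.01)
  # chi-squared goodness of fit against Poisson(0.3) multiplicities
  ks <- 0:3
  obs <- c(table(factor(pmin(nb, 3), levels = ks)))
  p_exp <- c(dpois(0:2, 0.3), 1 - ppois(2, 0.3))
  gof <- suppressWarnings(chisq.test(obs, p = p_exp))
  expect_gt(gof$p.value, 0.001)
  # sextile subtypes: all z < 1/6 cells are Hep1, z > 5/6 are Hep6
  expect_true(all(scr$cells$subtype[scr$cells$z < 1 / 6] == "Hep1"))
  expect_true(all(scr$cells$subtype[scr$cells$z > 5 / 6] == "Hep6"))
  # reproducibility under the seed
  scr2 <- simulate_tissue(1000, field_um = 200, lambda = 0.3,
                          library = lib, seed = 4)
  scr3 <- simulate_tissue(1000, field_um = 200, lambda = 0.3,
                          library = lib, seed = 4)
  expect_identical(scr2$cells, scr3$cells)
})

test_that("count model plants depletion, zonal slopes and control identity", {
  pl <- build_panel_and_library(n_genes = 40, n_targets = 10,
                                n_controls = 5, depletion_factor = 0.2,
                                n_induction = 0, n_zonal_shift = 0,
                                seed = 2)
  dep_guide <- pl$library$guide[!pl$library$is_control][1]
  tgt <- pl$library$target[pl$library$guide == dep_guide][1]
  ctrl_guide <- pl$library$guide[pl$library$is_control][1]
  n_half <- 5000
  scr <- simulate_tissue(2 * n_half, field_um = 1100, lambda = 0.3,
                         library = pl$library, seed = 3)
  scr$cells$barcodes <- c(rep(list(dep_guide), n_half),
                          rep(list(ctrl_guide), n_half))
  scr <- simulate_counts(scr, pl$panel, mean_library_size = 200, seed = 5)
  mean_dep <- mean(scr$true_counts[1:n_half, tgt])
  mean_ctrl <- mean(scr$true_counts[n_half + 1:n_half, tgt])
  # E[count | KO] = 0.2 x control expectation (up to renormalization of
  # the fixed library size; tolerance covers both noise and that shift)
  expect_equal(mean_dep / mean_ctrl, 0.2, tolerance = 0.1)
  # control cells: no gene deviates from the unperturbed expectation
  mu <- merscreen:::expected_means(scr$cells[n_half + 1:n_half, ],
                                   pl$panel, NULL, 200)
  expect_equal(colMeans(scr$true_counts[n_half + 1:n_half, ]),
               colMeans(mu), tolerance = 0.05)
  # planted zonal slope recovered by regressing log-mean on z; the
  # expected value comes from the generative means themselves (library
  # renormalization shears the raw per-gene slope, so the oracle is the
  # same regression on the expected means)
  marker <- "Pck1" # periportal, slope +2
  z <- scr$cells$z[n_half + 1:n_half]
  y <- scr$true_counts[n_half + 1:n_half, marker]
  bins <- cut(z, breaks = seq(0, 1, 0.1))
  zmid <- tapply(z, bins, mean)
  slope_of <- function(v) {
    logmean <- tapply(v, bins, function(w) log(mean(w)))
    unname(coef(lm(logmean ~ zmid))[2])
  }
  expect_equal(slope_of(y), slope_of(mu[, marker]), tolerance = 0.1)
  expect_gt(slope_of(y), 0) # periportal marker rises with z
})

test_that("rendered images conserve molecules and realize the flip rates", {
  fx <- small_screen(n_cells = 80, seed = 13)
  cb <- codebook_for(colnames(fx$screen$true_counts))
  scr <- render_bit_images(fx$screen, cb, p_1to0 = 0.05, p_0to1 = 0.02,
                           seed = 7)
  # conservation: every rendered molecule has a ground-truth record
  expect_equal(nrow(scr$molecules), sum(scr$true_counts))
  expect_true(all(scr$molecules$gene %in% colnames(scr$true_counts)))
  # per-molecule counts by cell match true_counts
  tab <- table(scr$molecules$cell_id)
  expect_equal(unname(c(tab[as.character(scr$cells$cell_id)])),
               unname(rowSums(scr$true_counts)))
  # realized per-bit flip frequencies approximate the configuration
  true_bits <- do.call(rbind, scr$molecules$bits_true)
  rend_bits <- do.call(rbind, scr$molecules$bits_rendered)
  on <- true_bits == 1L
  expect_equal(mean(rend_bits[on] == 0L), 0.05, tolerance = 0.25)
  expect_equal(mean(rend_bits[!on] == 1L), 0.02, tolerance = 0.25)
  # masks partition cell interiors: labels are cell ids or background
  expect_true(all(unique(as.vector(scr$masks)) %in%
                    c(0L, scr$cells$cell_id)))
})

test_that("flex tables separate true guides from ambient counts", {
  fx <- small_screen(n_cells = 200, seed = 17, mean_library_size = 50)
  scr <- fx$screen
  # capture efficiency 1, ambient 0: transcriptome equals truth and
  # non-true guide probes are all zero
  fl <- simulate_flex_counts(scr, capture_efficiency = 1,
                             ambient_rate = 0, seed = 6)
  genes <- colnames(scr$true_counts)
  expect_equal(fl$flex_umis[, genes], scr$true_counts)
  probes <- fl$flex_umis[, grepl("^probe_", colnames(fl$flex_umis))]
  for (i in seq_len(nrow(scr$cells))) {
    absent <- setdiff(colnames(probes),
                      paste0("probe_", scr$cells$barcodes[[i]]))
    expect_equal(sum(probes[i, absent]), 0L)
  }
  # with defaults, a single true guide out-counts every other probe
  fl2 <- simulate_flex_counts(scr, seed = 8)
  probes2 <- fl2$flex_umis[, grepl("^probe_", colnames(fl2$flex_umis))]
  singles <- which(lengths(scr$cells$barcodes) == 1)
  hit <- vapply(singles, function(i) {
    names(which.max(probes2[i, ])) ==
      paste0("probe_", scr$cells$barcodes[[i]][1])
  }, logical(1))
  expect_gte(mean(hit), 0.99)
})
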