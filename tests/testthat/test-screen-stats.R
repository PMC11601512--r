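test_that("tp10k scaling, z-scoring and covariate removal are exact", {
  counts <- rbind(a = c(2, 3, 5), b = c(1, 1, 2), c = c(4, 4, 2),
                  d = c(2, 2, 6))
  colnames(counts) <- c("g1", "g2", "g3")
  norm <- normalize_and_zscore(counts, control = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(norm$tp10k_log[1, ], log1p(c(g1 = 2000, g2 = 3000,
                                            g3 = 5000)))
  # z layer of control cells has per-gene mean 0 and sd 1
  zc <- norm$z[1:3, ]
  expect_equal(unname(colMeans(zc)), rep(0, 3))
  expect_equal(unname(apply(zc, 2, sd)), rep(1, 3))
  # residuals orthogonal to covariates
  cov <- matrix(rnorm(8), 4, 2)
  norm2 <- normalize_and_zscore(counts, control = rep(TRUE, 4),
                                covariates = cov)
  centered <- sweep(cov, 2, colMeans(cov))
  expect_equal(max(abs(crossprod(centered, norm2$residual))), 0,
               tolerance = 1e-8)
  # zero-total cells are an error; zero-variance genes are flagged
  expect_error(normalize_and_zscore(rbind(c(0, 0), c(1, 1)),
                                    control = c(TRUE, TRUE)), "zero-total")
  # g1 keeps a constant share of every cell's library, so its tp10k-log
  # value is constant across controls
  flat <- cbind(g1 = c(1L, 2L, 4L), g2 = c(4L, 7L, 17L),
                g3 = c(5L, 11L, 19L))
  expect_message(
    norm3 <- normalize_and_zscore(flat, control = rep(TRUE, 3)),
    "zero-variance"
  )
  expect_true(all(is.na(norm3$z[, "g1"])))
})

test_that("Holm-Sidak adjustment matches the step-down definition", {
  p <- c(0.001, 0.01, 0.04, 0.2, 0.9)
  adj <- merscreen:::holm_sidak(p)
  # hand-rolled reference: order, adjust, enforce monotonicity
  m <- length(p)
  ref <- cummax(1 - (1 - sort(p))^(m - seq_len(m) + 1))[rank(p)]
  expect_equal(adj, pmin(ref, 1))
  expect_true(all(adj >= p))
})

test_that("vectorized rank-sum tests agree with wilcox.test", {
  set.seed(7)
  x <- matrix(rnorm(60 * 4), 60, 4)
  x[1:30, 2] <- x[1:30, 2] + 1
  x[, 3] <- round(x[, 3]) # ties
  mine <- merscreen:::rank_sum_tests(x, 1:30, 31:60)
  ref <- vapply(1:4, function(j) {
    suppressWarnings(wilcox.test(x[1:30, j], x[31:60, j], exact = FALSE,
                                 correct = TRUE)$p.value)
  }, numeric(1))
  expect_equal(mine$p, ref, tolerance = 1e-8)
})

test_that("energy distance matches direct evaluation and a null is clean", {
  # identical point sets cancel exactly
  y <- matrix(rnorm(40), 20)
  d <- merscreen:::pair_dists(rbind(y, y), "sqeuclidean")
  expect_equal(merscreen:::edist_from_d(d, 1:20), 0)
  # two singletons at (0,0) and (3,4): 2 d(x,y) with no within terms
  pts <- rbind(c(0, 0), c(3, 4))
  expect_equal(merscreen:::edist_from_d(
    merscreen:::pair_dists(pts, "sqeuclidean"), 1), 50)
  expect_equal(merscreen:::edist_from_d(
    merscreen:::pair_dists(pts, "euclidean"), 1), 10)
  # permutation statistics recompute the same blocks as edist_from_d
  set.seed(5)
  z <- matrix(rnorm(30 * 3), 30)
  dz <- merscreen:::pair_dists(z, "sqeuclidean")
  perm <- merscreen:::edist_permutations(dz, 10, 50)
  expect_equal(length(perm), 50)
  # brute-force one permutation with the same membership size
  expect_equal(merscreen:::edist_from_d(dz, 1:10),
               local({
                 n <- 30; x <- 1:10; yy <- 11:30
                 2 * mean(dz[x, yy]) - mean(dz[x, x]) - mean(dz[yy, yy])
               }))
  # null groups from one distribution: no Holm-Sidak significance
  set.seed(9)
  lab <- c(rep("control", 200), rep(sprintf("g%02d", 1:10), each = 50))
  mat <- matrix(rnorm(length(lab) * 30), length(lab), 30)
  res <- energy_distance_test(mat, lab, "control", n_pcs = 10,
                              n_permutations = 200, seed = 12)
  expect_equal(sum(res$significant), 0)
  expect_true(all(res$p > 0 & res$p <= 1))
  # tidy/glance interfaces
  expect_s3_class(generics::tidy(res), "tbl_df")
  expect_equal(generics::glance(res)$n_groups, 10)
  # a strong planted shift is detected
  mat2 <- mat
  mat2[lab == "g01", 1:5] <- mat2[lab == "g01", 1:5] + 2
  res2 <- energy_distance_test(mat2, lab, "control", n_pcs = 10,
                               n_permutations = 200, seed = 12)
  expect_true(res2$significant[res2$group == "g01"])
})

test_that("differential expression recovers planted effects with FDR control", {
  fx <- small_screen(n_cells = 400, seed = 25, mean_library_size = 200)
  counts <- fx$screen$true_counts
  norm <- normalize_and_zscore(counts, control = rep(TRUE, nrow(counts)))
  # group identical to control: nothing significant
  de0 <- differential_expression(norm$tp10k_log, 1:200, 1:200)
  expect_equal(sum(de0$significant), 0)
  # planted 2x fold change at n = 200 per group is significant
  boosted <- counts
  boosted[1:200, 5] <- boosted[1:200, 5] * 2L
  norm2 <- normalize_and_zscore(boosted, control = c(rep(FALSE, 200),
                                                     rep(TRUE, 200)))
  de <- differential_expression(norm2$tp10k_log, 1:200, 201:400)
  expect_true(de$significant[5])
  expect_gt(de$log2fc[5], 0.5)
  # null split: average fraction of adjusted discoveries stays at bay
  set.seed(31)
  fp <- replicate(5, {
    idx <- sample(400, 200)
    de_null <- differential_expression(norm$tp10k_log, idx,
                                       setdiff(1:400, idx))
    mean(de_null$p_adj < 0.05)
  })
  expect_lte(mean(fp), 0.05)
})

test_that("pseudobulk profiles correlate same-effect guides", {
  fx <- small_screen(n_cells = 900, seed = 27, mean_library_size = 200)
  lib <- fx$library
  dep <- lib$guide[!lib$is_control & lib$template == "depletion"]
  tgt_gene <- lib$target[lib$guide == dep[1]][1]
  dep_pair <- lib$guide[lib$target == tgt_gene]
  scr <- fx$screen
  scr$cells$barcodes <- c(rep(list(dep_pair[1]), 200),
                          rep(list(dep_pair[2]), 200),
                          rep(list(lib$guide[lib$is_control][1]), 200),
                          rep(list(lib$guide[lib$is_control][2]), 200),
                          rep(list(character()), 100))
  scr <- simulate_counts(scr, fx$panel, mean_library_size = 200, seed = 6)
  labels <- c(rep(c("sgA", "sgB", "ctrlA", "ctrlB"), each = 200),
              rep("control", 100))
  norm <- normalize_and_zscore(scr$true_counts,
                               control = labels %in% c("ctrlA", "ctrlB",
                                                       "control"))
  pb <- pseudobulk_profiles(norm$z, labels, "control",
                            control_expression = norm$tp10k_log,
                            top_n = 25)
  expect_equal(length(pb$support_genes), 25)
  expect_equal(unname(diag(pb$correlations)), rep(1, nrow(pb$correlations)))
  # two guides sharing an effect template correlate above two controls
  expect_gt(pb$correlations["sgA", "sgB"],
            pb$correlations["ctrlA", "ctrlB"])
})

test_that("gene-set and zonation scores follow their definitions", {
  genes <- c(zonation_markers()$periportal, zonation_markers()$pericentral,
             "other")
  z <- matrix(0, 3, length(genes), dimnames = list(NULL, genes))
  z[1, zonation_markers()$periportal] <- 1
  z[2, zonation_markers()$pericentral] <- 1
  zs <- zonation_score(z)
  expect_equal(zs$score, c(7, -16, 0))
  split <- zonation_score(z, split = TRUE)
  expect_equal(split$periportal, c(7, 0, 0))
  expect_equal(split$pericentral, c(0, 16, 0))
  expect_error(zonation_score(z[, 1:5, drop = FALSE]), "absent")
  # gene-set score: controls center at zero; planted shift is recovered
  set.seed(13)
  zz <- matrix(rnorm(300 * 10), 300, 10,
               dimnames = list(NULL, paste0("g", 1:10)))
  lab <- rep(c("control", "up"), each = 150)
  zz[lab == "up", 1:4] <- zz[lab == "up", 1:4] + 1
  gs <- gene_set_score(zz, paste0("g", 1:4), lab, "control")
  expect_equal(gs$score, 1, tolerance = 0.15)
  expect_true(gs$significant)
  gs_ctrl <- gene_set_score(zz[lab == "control", , drop = FALSE],
                            paste0("g", 1:4),
                            rep(c("control", "pseudo"), 75), "control")
  expect_equal(gs_ctrl$score, 0, tolerance = 0.25)
  expect_error(gene_set_score(zz, c("nope1", "nope2"), lab, "control"),
               "absent")
})

test_that("intensity effects are z-scored within sample and BY-corrected", {
  set.seed(17)
  n <- 600
  lab <- rep(c("control", "sgX", "ctrl2"), each = n / 3)
  smp <- rep(c("s1", "s2"), n / 2)
  intens <- matrix(rnorm(n * 3), n, 3,
                   dimnames = list(NULL, c("chA", "chB", "chC")))
  intens[lab == "sgX", 2] <- intens[lab == "sgX", 2] - 1
  ie <- intensity_effects(intens, lab, "control", sample = smp)
  hit <- ie[ie$guide == "sgX" & ie$channel == "chB", ]
  expect_lt(hit$mean_z, -0.5)
  expect_true(hit$significant)
  # a control pseudo-guide shows nothing
  expect_equal(sum(ie$significant[ie$guide == "ctrl2"]), 0)
  # control z has per-channel mean 0 within each sample by construction
  for (s in c("s1", "s2")) {
    sel <- smp == s & lab == "control"
    mu <- colMeans(intens[sel, ])
    sdv <- apply(intens[sel, ], 2, sd)
    zc <- sweep(sweep(intens[sel, ], 2, mu), 2, sdv, "/")
    expect_equal(unname(colMeans(zc)), rep(0, 3))
  }
})
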