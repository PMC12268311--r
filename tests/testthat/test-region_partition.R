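test_that("dense square of tumor centroids closes to its analytic area", {
  # 500x500 um square filled on a 20 um grid
  gx <- seq(10, 490, by = 20)
  pts <- expand.grid(x = gx + 250, y = gx + 250)  # square at [260, 740]
  nuc <- data.frame(nucleus_id = seq_len(nrow(pts)), x_um = pts$x,
                    y_um = pts$y, class_label = "TUMOR")
  sl <- slide_nuclei(nuc, extent_um = c(1000, 1000))
  tm <- build_tumor_mask(sl)
  area <- sum(tm$mask) * tm$pixel_um^2
  expect_equal(tm$n_components, 1L)
  expect_lt(abs(area - 480^2) / 480^2, 0.05)  # grid spans 480 um + raster slack
})

test_that("a single isolated tumor nucleus is removed as sub-threshold", {
  nuc <- data.frame(nucleus_id = "a", x_um = 500, y_um = 500,
                    class_label = "TUMOR")
  sl <- slide_nuclei(nuc, extent_um = c(1000, 1000))
  tm <- build_tumor_mask(sl)  # one closed point: area << 10000 um2
  expect_equal(sum(tm$mask), 0L)
  expect_equal(tm$n_components, 0L)
})

test_that("two dense clusters far apart give exactly two components", {
  mk <- function(cx, cy) {
    g <- expand.grid(x = seq(-100, 100, 20), y = seq(-100, 100, 20))
    data.frame(x_um = g$x + cx, y_um = g$y + cy)
  }
  pts <- rbind(mk(400, 400), mk(2400, 400))
  nuc <- data.frame(nucleus_id = seq_len(nrow(pts)), pts,
                    class_label = "TUMOR")
  sl <- slide_nuclei(nuc, extent_um = c(2800, 800))
  tm <- build_tumor_mask(sl)
  expect_equal(tm$n_components, 2L)
  # brute-force connectivity oracle: flood fill over the 8-neighbour graph
  m <- tm$mask
  seen <- matrix(FALSE, nrow(m), ncol(m)); comp <- 0
  for (s in which(m == 1L)) {
    if (seen[s]) next
    comp <- comp + 1
    queue <- s
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      if (seen[cur]) next
      seen[cur] <- TRUE
      i <- (cur - 1) %% nrow(m) + 1; j <- (cur - 1) %/% nrow(m) + 1
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m) &&
            m[ii, jj] == 1L && !seen[ii + (jj - 1) * nrow(m)])
          queue <- c(queue, ii + (jj - 1) * nrow(m))
      }
    }
  }
  expect_equal(comp, 2)
})

test_that("tumorless slide yields an empty mask and an all-stromal partition", {
  nuc <- data.frame(nucleus_id = c("a", "b"), x_um = c(100, 200),
                    y_um = c(100, 200), class_label = "LYMPHOCYTE")
  sl <- slide_nuclei(nuc, extent_um = c(500, 500))
  expect_warning(tm <- build_tumor_mask(sl), "no TUMOR nuclei")
  expect_true(tm$tumorless)
  rm <- label_regions(tm)
  expect_true(all(rm$labels == 0L))
  sl2 <- assign_nuclei_regions(sl, rm)
  prof <- count_tils(sl2, rm)
  expect_equal(c(prof$i_tils, prof$p_tils, prof$s_tils), c(0L, 0L, 2L))
  expect_true(prof$tumorless)
})

test_that("peritumoral band around a disk tumor matches the annulus area", {
  sl <- disk_tumor_slide(radius = 200, center = c(1000, 1000),
                         extent = c(2000, 2000))
  tm <- build_tumor_mask(sl)
  rm <- label_regions(tm)
  a <- region_areas(rm)
  annulus <- pi * (500^2 - 200^2)
  expect_lt(abs(a[["PERITUMORAL"]] - annulus) / annulus, 0.03)
  # disk area itself as a sanity anchor
  expect_lt(abs(a[["INTRATUMOR"]] - pi * 200^2) / (pi * 200^2), 0.06)
})

test_that("zero band width removes the peritumoral zone", {
  sl <- disk_tumor_slide(radius = 150, center = c(500, 500),
                         extent = c(1000, 1000))
  p <- partition_params(band_um = 0)
  rm <- label_regions(build_tumor_mask(sl, p), p)
  expect_equal(sum(rm$labels == 1L), 0L)
  expect_gt(sum(rm$labels == 2L), 0L)
})

test_that("partition labels are exhaustive and mutually exclusive", {
  for (seed in c(2, 5, 8)) {
    sim <- simulate_slide(slide_sim_params(
      extent_um = c(1500, 1500), n_tumor_nests = 2,
      nest_radius_um = c(250, 40), tumor_density = 0.004,
      lambda_i = 4e-4, lambda_p = 6e-4, lambda_s = 3e-4,
      lambda_other = 2e-4, seed = seed))
    rm <- label_regions(build_tumor_mask(sim$slide))
    expect_equal(sum(rm$labels %in% c(0L, 1L, 2L)), length(rm$labels))
    # distance invariants: peri cells within (0, band], stromal beyond
    d <- rm$distance_um
    tol <- rm$pixel_um * sqrt(2) / 2
    expect_true(all(d[rm$labels == 1L] <= 300 + 1e-9))
    expect_true(all(d[rm$labels == 1L] > 0))
    expect_true(all(d[rm$labels == 0L] > 300 - tol))
  }
})

test_that("nuclei take the label of their containing cell; lymphocytes become I/P/S TILs", {
  lymph <- rbind(c(1000, 1000),   # center of the disk -> intratumor
                 c(1000 + 350, 1000),  # 150 um outside boundary -> peritumoral
                 c(1000 + 600, 1000))  # 400 um outside -> stromal
  sl <- disk_tumor_slide(radius = 200, center = c(1000, 1000),
                         extent = c(2000, 2000), lymph = lymph)
  rm <- label_regions(build_tumor_mask(sl))
  sl2 <- assign_nuclei_regions(sl, rm)
  ly <- sl2$nuclei[sl2$nuclei$class_label == "LYMPHOCYTE", ]
  expect_equal(ly$region_label, c("INTRATUMOR", "PERITUMORAL", "STROMAL"))
  expect_true(all(sl2$nuclei$region_label != "UNASSIGNED"))
})

test_that("labels agree with brute-force point-to-mask distance outside the tolerance band", {
  set.seed(14)
  lymph <- cbind(runif(1000, 0, 2000), runif(1000, 0, 2000))
  sl <- disk_tumor_slide(radius = 250, center = c(1000, 1000),
                         extent = c(2000, 2000), lymph = lymph)
  tm <- build_tumor_mask(sl)
  rm <- label_regions(tm)
  sl2 <- assign_nuclei_regions(sl, rm)
  ly <- sl2$nuclei[sl2$nuclei$class_label == "LYMPHOCYTE", ]
  d <- brute_force_mask_distance(ly$x_um, ly$y_um, tm)
  tol <- rm$pixel_um * sqrt(2) / 2
  decided <- abs(d - 300) > tol & d > 0
  exp_lab <- ifelse(d == 0, "INTRATUMOR",
                    ifelse(d <= 300, "PERITUMORAL", "STROMAL"))
  expect_true(all(ly$region_label[decided] == exp_lab[decided]))
  expect_true(all(ly$region_label[d == 0] == "INTRATUMOR"))
})

test_that("widening the band never loses P-TILs nor gains S-TILs", {
  for (seed in c(21, 22, 23)) {
    sim <- simulate_slide(slide_sim_params(
      extent_um = c(1500, 1500), n_tumor_nests = 2,
      nest_radius_um = c(250, 40), tumor_density = 0.004,
      lambda_i = 4e-4, lambda_p = 6e-4, lambda_s = 4e-4,
      lambda_other = 0, seed = seed))
    tm <- build_tumor_mask(sim$slide)
    prev_p <- -1; prev_s <- Inf
    for (band in c(0, 100, 200, 300, 450, 600)) {
      p <- partition_params(band_um = band)
      rm <- label_regions(build_tumor_mask(sim$slide, p), p)
      prof <- count_tils(assign_nuclei_regions(sim$slide, rm), rm)
      expect_gte(prof$p_tils, prev_p)
      expect_lte(prof$s_tils, prev_s)
      prev_p <- prof$p_tils; prev_s <- prof$s_tils
    }
  }
})

test_that("halving the raster cell changes labels only near region boundaries", {
  sim <- simulate_slide(slide_sim_params(
    extent_um = c(1500, 1500), n_tumor_nests = 2,
    nest_radius_um = c(250, 40), tumor_density = 0.005,
    lambda_i = 5e-4, lambda_p = 8e-4, lambda_s = 4e-4, lambda_other = 0,
    seed = 31))
  lab <- list()
  for (px in c(4, 2)) {
    p <- partition_params(pixel_um = px)
    rm <- label_regions(build_tumor_mask(sim$slide, p), p)
    sl2 <- assign_nuclei_regions(sim$slide, rm)
    lab[[as.character(px)]] <- sl2$nuclei$region_label
  }
  # nuclei well away from the true tumor boundary and band edge must agree
  nests <- sim$truth$nests
  d <- rep(Inf, nrow(sim$slide$nuclei))
  for (k in seq_len(nrow(nests)))
    d <- pmin(d, sqrt((sim$slide$nuclei$x_um - nests$x[k])^2 +
                        (sim$slide$nuclei$y_um - nests$y[k])^2) - nests$r[k])
  safe <- abs(d) > 12 & abs(d - 300) > 12   # 3 coarse cells of slack
  expect_gt(mean(lab[["4"]][safe] == lab[["2"]][safe]), 0.999)
  expect_gt(sum(safe), 1000)
})

test_that("region mask exports to PNG + sidecar and reads back identically", {
  sl <- disk_tumor_slide(radius = 150, center = c(500, 500),
                         extent = c(1000, 1000))
  rm <- label_regions(build_tumor_mask(sl))
  path <- withr::local_tempfile(fileext = ".png")
  write_region_mask(rm, path)
  back <- read_region_mask(path)
  expect_identical(back$labels, rm$labels)
  expect_equal(back$pixel_um, rm$pixel_um)
  expect_equal(back$band_um, rm$band_um)
})

test_that("grid mismatch between mask and params is fatal", {
  sl <- disk_tumor_slide(radius = 150, center = c(500, 500),
                         extent = c(1000, 1000))
  tm <- build_tumor_mask(sl)
  expect_error(label_regions(tm, partition_params(pixel_um = 8)),
               "grid mismatch")
})
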