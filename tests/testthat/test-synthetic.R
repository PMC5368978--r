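test_that("scene generation is deterministic and internally consistent", {
  s1 <- make_scene("injury", "gsh", n_cells = 8, image_shape = c(224, 224),
                   diam_range = c(30, 40), seed = 7)
  s2 <- make_scene("injury", "gsh", n_cells = 8, image_shape = c(224, 224),
                   diam_range = c(30, 40), seed = 7)
  expect_identical(s1$label_map, s2$label_map)
  expect_identical(s1$cells, s2$cells)
  s3 <- make_scene("injury", "gsh", n_cells = 8, image_shape = c(224, 224),
                   diam_range = c(30, 40), seed = 8)
  expect_false(identical(s1$label_map, s3$label_map))

  # planted geometry is recoverable from the ground truth exactly
  for (i in s1$cells$cell_id) {
    px <- which(s1$label_map == i, arr.ind = TRUE)
    expect_gt(nrow(px), 0)
    # pixel-count area within the discretisation error of the planted disc
    expect_equal(nrow(px), pi * (s1$cells$diameter[i] / 2)^2,
                 tolerance = 0.15)
    d <- sqrt((px[, 1] - s1$cells$row[i])^2 + (px[, 2] - s1$cells$col[i])^2)
    expect_lte(max(d), s1$cells$diameter[i] / 2 + 1e-9)
  }
  expect_true(all(s1$cells$diameter >= 30 & s1$cells$diameter <= 40))

  # per-pixel truth maps congruent with labels
  pos <- s1$cells$positive
  for (i in s1$cells$cell_id[pos])
    expect_equal(unique(s1$tau2_map[s1$label_map == i]), 225)

  # empty scene
  s0 <- make_scene("control", "gsh", n_cells = 0, image_shape = c(64, 64),
                   seed = 1)
  expect_true(all(s0$label_map == 0L))
  expect_equal(nrow(s0$cells), 0)
})

test_that("injury template plants two dim subpopulations; labels follow the weights", {
  tpl_inj <- scene_template("injury", "gsh")
  tpl_ctl <- scene_template("control", "gsh")
  expect_length(tpl_inj$pop_means, 2)
  expect_true(all(tpl_inj$pop_means < tpl_ctl$pop_means))
  sc <- make_scene("injury", "gsh", n_cells = 60, image_shape = c(700, 700),
                   diam_range = c(30, 40), seed = 11,
                   config = list(positive_frac = 1))
  lab <- sc$cells$subpop
  expect_true(all(lab %in% 1:2))
  # 50/50 mixing weight: component-1 count within a 99.9% binomial band
  expect_gt(sum(lab == 1), qbinom(5e-4, 60, 0.5))
  expect_lt(sum(lab == 1), qbinom(1 - 5e-4, 60, 0.5))
  # planted intensities come from the labelled component
  m <- tapply(sc$cells$intensity, lab, mean)
  expect_lt(abs(m[["1"]] - tpl_inj$pop_means[1]), 5 * tpl_inj$pop_sds[1])
  expect_lt(abs(m[["2"]] - tpl_inj$pop_means[2]), 5 * tpl_inj$pop_sds[2])
})

test_that("overfull scenes fail loudly", {
  expect_error(make_scene("control", "gsh", n_cells = 50,
                          image_shape = c(100, 100), seed = 1),
               "infeasible packing")
})

test_that("rendering conserves photons and reproduces the decay shape", {
  acq <- make_acq(64)
  sc <- make_scene("control", "gsh", n_cells = 2, image_shape = c(96, 96),
                   diam_range = c(30, 36), seed = 5)
  st <- render_flim(sc, acq, seed = 6)
  st2 <- render_flim(sc, acq, seed = 6)
  expect_identical(st$counts, st2$counts)  # bit-identical for equal seeds
  img <- render_intensity(st)
  expect_equal(sum(img), sum(st$counts))  # exact photon conservation
  expect_equal(dim(img), c(96, 96))

  # all-zero amplitude gives an all-zero stack
  sc0 <- make_scene("control", "gsh", n_cells = 0, image_shape = c(48, 48),
                    background_level = 0, seed = 1)
  st0 <- render_flim(sc0, acq, seed = 1)
  expect_true(all(st0$counts == 0L))
  expect_true(all(render_intensity(st0) == 0))

  # empirical decay of a high-photon background-only scene matches the
  # analytic periodic model: Pearson chi-square per dof near 1
  scb <- make_scene("control", "gsh", n_cells = 0, image_shape = c(64, 64),
                    background_level = 300, seed = 2)
  stb <- render_flim(scb, acq, seed = 3)
  h <- roi_decay(stb, matrix(TRUE, 64, 64))
  mu <- periodic_bin_means(scb$background_params, acq)
  mu <- mu / sum(mu) * scb$background_level * 64 * 64
  chisq <- sum((h - mu)^2 / mu) / length(h)
  expect_gt(chisq, 0.6)
  expect_lt(chisq, 1.5)

  # reacted pixels put a larger fraction of photons in late bins
  gsh <- flim_probes("P-GSH")
  late <- function(rf) {
    p <- mix_decay(rf, gsh)
    b <- periodic_bin_means(p, acq)
    sum(b[33:64]) / sum(b)
  }
  expect_gt(late(1), late(0))
})

test_that("single pixel intensity image is the bin sum", {
  acq <- acquisition_spec(80, 16)
  counts <- array(0L, c(1, 1, 16))
  counts[1, 1, 1:3] <- c(3L, 2L, 1L)
  st <- flim_stack(counts, acq)
  expect_equal(render_intensity(st)[1, 1], 6)
})
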