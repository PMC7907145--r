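# AEP projection, Clough-Tocher interpolation, normalisation, sequences.

test_that("AEP maps the apex to the origin and preserves arc distances", {
  m <- eegtopoclass:::new_montage(
    c("apex", "front"), rbind(c(0, 0, 1), c(1, 0, 0)))
  m <- aep_project(m)
  expect_equal(m$pos2d[1, ], c(0, 0), ignore_attr = TRUE)
  expect_equal(m$pos2d[2, ], c(pi / 2, 0), ignore_attr = TRUE,
               tolerance = 1e-12)
  # property: planar radius == arccos(z) on random montages
  for (s in 1:3) {
    rm <- random_montage(25, seed = s)
    r2d <- sqrt(rowSums(rm$pos2d^2))
    expect_equal(r2d, acos(pmin(1, rm$pos3d[, 3])), tolerance = 1e-9,
                 ignore_attr = TRUE)
    o <- order(acos(pmin(1, rm$pos3d[, 3])))
    expect_equal(o, order(r2d))
  }
  expect_error(eegtopoclass:::new_montage("x", rbind(c(0, 0, 0))), "zero-norm")
})

test_that("Clough-Tocher reproduces constants and affine fields; 32x32 output", {
  mon <- aep_project(template_montage())
  g <- interpolate_grid(mon$pos2d, rep(2.5, 60))
  expect_equal(dim(g), c(32L, 32L))
  inside <- topo_operator(mon$pos2d)$inside
  expect_lt(max(abs(g[inside] - 2.5)), 1e-6)
  expect_true(all(g[!inside] == 0))
  # affine precision, checked against the closed-form field on the grid
  st <- eegtopoclass:::topo_setup(mon$pos2d, 32L)
  f <- 1.7 * mon$pos2d[, 1] - 0.9 * mon$pos2d[, 2] + 0.4
  gl <- interpolate_grid(mon$pos2d, f)
  ref <- outer(st$grid_y, st$grid_x, function(y, x) 1.7 * x - 0.9 * y + 0.4)
  expect_lt(max(abs((gl - ref)[inside])), 1e-6)
})

test_that("the interpolant passes through the electrode values", {
  for (s in 1:2) {
    rm <- random_montage(18, seed = s + 10)
    set.seed(s)
    vals <- rnorm(18)
    st <- eegtopoclass:::topo_setup(rm$pos2d, 32L)
    loc <- eegtopoclass:::ct_locate(st$dt, rm$pos2d)
    gx <- drop(st$grads$gx %*% vals); gy <- drop(st$grads$gy %*% vals)
    cp <- eegtopoclass:::ct_control_points(st$dt, vals, gx, gy)
    bern <- eegtopoclass:::ct_bernstein(loc$uvw)
    pred <- rowSums(bern * cp[(loc$tri_id - 1) * 3 + loc$patch, ])
    expect_true(all(loc$inside))
    expect_lt(max(abs(pred - vals)), 1e-6)
  }
})

test_that("degenerate electrode clouds error; linear operator equals direct path", {
  line <- cbind(1:5, 2 * (1:5))
  expect_error(interpolate_grid(line, rnorm(5)), "degenerate|triangulation")
  rm <- random_montage(15, seed = 30)
  set.seed(2)
  v <- rnorm(15)
  op <- topo_operator(rm$pos2d, 16L)
  direct <- interpolate_grid(rm$pos2d, v, 16L)
  expect_equal(matrix(op$W %*% v, 16, 16), direct, tolerance = 1e-10)
})

test_that("normalizer maps bands to [0,1], degenerate band to 0, clips held-out", {
  set.seed(6)
  tr_grids <- lapply(1:3, function(b) matrix(runif(64, b, b + 2), 8, 8))
  nm <- fit_normalizer(tr_grids)
  img <- assemble_rgb(tr_grids, nm)
  expect_equal(dim(img), c(8, 8, 3))
  expect_true(all(unclass(img) >= 0 & unclass(img) <= 1))
  # degenerate band: constant grids map to 0
  cg <- lapply(1:3, function(b) matrix(b, 4, 4))
  nm2 <- fit_normalizer(cg)
  img2 <- assemble_rgb(cg, nm2)
  expect_true(all(unclass(img2) == 0))
  # identity normalizer leaves in-range grids unchanged
  g01 <- lapply(1:3, function(b) matrix(runif(16), 4, 4))
  img3 <- assemble_rgb(g01, identity_normalizer())
  for (b in 1:3) expect_equal(img3[, , b], g01[[b]])
  # held-out values outside the fitted range clip into [0,1]
  held <- lapply(tr_grids, function(g) g + 5)
  img4 <- assemble_rgb(held, nm)
  expect_true(all(unclass(img4) >= 0 & unclass(img4) <= 1))
  expect_error(assemble_rgb(list(matrix(0, 2, 2), matrix(0, 3, 3),
                                 matrix(0, 2, 2)), nm), "mismatch")
})

test_that("make_sequence emits one image per frame and is channel-order invariant", {
  mon <- aep_project(template_montage())
  set.seed(8)
  frames <- lapply(0:5, function(k) {
    structure(list(window_index = k,
                   values = matrix(runif(60 * 3), 60, 3),
                   feature_name = "fuzzyen"), class = "feature_frame")
  })
  seq6 <- make_sequence(frames, mon, identity_normalizer(), label = 1L)
  expect_length(seq6$frames, 6)
  expect_equal(attr(seq6$frames[[3]], "window_index"), 2)
  seq1 <- make_sequence(frames[1], mon, identity_normalizer())
  expect_length(seq1$frames, 1)
  # permuting channels together with montage rows yields identical images
  perm <- sample(60)
  mon_p <- aep_project(eegtopoclass:::new_montage(mon$labels[perm],
                                                  mon$pos3d[perm, ]))
  frames_p <- lapply(frames, function(fr) {
    fr$values <- fr$values[perm, ]; fr
  })
  seq_p <- make_sequence(frames_p, mon_p, identity_normalizer())
  for (k in 1:6)
    expect_equal(unclass(seq_p$frames[[k]]), unclass(seq6$frames[[k]]),
                 tolerance = 1e-8)
  bad <- frames
  bad[[1]]$values <- bad[[1]]$values[1:10, ]
  expect_error(make_sequence(bad, mon, identity_normalizer()), "channel")
})
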