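# A template with no prebleach frames and 3 delays, for hand-built stacks.
tpl_tiny <- acq_template(delays_ns = c(0, 2, 4), n_prebleach = 0,
                         frame_shape = c(20, 20))

const_stack <- function(values, tpl = tpl_tiny, bg = 0) {
  gated_stack(lapply(values, function(v) matrix(v, tpl$frame_shape[1],
                                                tpl$frame_shape[2])),
              tpl, fixed_background_dn = bg)
}

test_that("intensity integration subtracts the fixed background", {
  tpl12 <- acq_template(frame_shape = c(20, 20))
  st <- const_stack(rep(10, 12), tpl12, bg = 10)
  expect_true(all(build_intensity_image(st) == 0))

  frames <- lapply(1:12, function(i) {
    m <- matrix(10, 20, 20); m[5, 7] <- 110; m
  })
  st2 <- gated_stack(frames, tpl12, fixed_background_dn = 10)
  img <- build_intensity_image(st2)
  expect_equal(img[5, 7], 1200)
  expect_equal(sum(img != 0), 1L)

  # negative sums clamp to zero without touching the raw frames
  st3 <- const_stack(rep(5, 12), tpl12, bg = 10)
  expect_true(all(build_intensity_image(st3) == 0))
  expect_true(all(st3$frames[[1]] == 5))
})

test_that("noiseless rendered intensity matches the forward model", {
  sc <- scene_spec(
    foci = data.frame(row = 48.4, col = 31.7, amplitude_dn = 2e4,
                      tau_ns = 4),
    autofluor_rate_dn = 0, camera_offset_dn = 80, noise = "none",
    bleach_rate = 0)
  out <- render_gated_stack(sc, tpl_small, irf_sim)
  img <- build_intensity_image(out$stack)
  g <- flimhca:::frame_factors(4, tpl_small, irf_sim, 0)
  spot <- flimhca:::add_gaussian_spot(matrix(0, 96, 96), 48.4, 31.7,
                                      2e4, 0.35)
  expected <- spot * sum(g)
  nz <- expected > 1e-6 * max(expected)
  expect_lt(max(abs(img[nz] - expected[nz]) / expected[nz]), 1e-6)
})

test_that("dead cells are masked by size and brightness together", {
  # uniform image: nothing to exclude
  expect_false(any(mask_dead_cells(matrix(7, 50, 50))))

  with_seed <- flimhca:::with_seed
  img <- with_seed(11, matrix(stats::rpois(100 * 100, 50), 100, 100))
  # a bright blob well above the robust threshold, area ~ 300 px
  rr <- matrix(1:100, 100, 100); cc <- t(rr)
  blob <- (rr - 30)^2 + (cc - 40)^2 <= 100
  img_b <- img + blob * 5000
  m <- mask_dead_cells(img_b)
  expect_true(all(m[blob]))
  # a small bright speck (sub-area) is left alone
  img_s <- img
  img_s[70:71, 70:71] <- 6000
  expect_false(any(mask_dead_cells(img_s)))
})

test_that("injected dead cells are fully excluded and foci survive", {
  hits <- vapply(1:20, function(s) {
    sc <- random_scene(tpl_small, n_cells = 6, tau_ns = 4,
                       focus_amplitude_dn = 400, foci_per_cell = 1,
                       seed = 6000 + s)
    # place the blob at the frame corner quadrant farthest from all foci
    cand <- expand.grid(row = c(20, 76), col = c(20, 76))
    dmin <- apply(cand, 1, function(p) {
      min((sc$foci$row - p[1])^2 + (sc$foci$col - p[2])^2)
    })
    best <- cand[which.max(dmin), ]
    sc$dead_cells <- data.frame(row = best$row, col = best$col,
                                radius_px = 9, amplitude_dn = 3000)
    out <- render_gated_stack(sc, tpl_small, irf_sim)
    img <- build_intensity_image(out$stack)
    m <- mask_dead_cells(img)
    rr <- matrix(0:95, 96, 96); cc <- t(rr)
    inblob <- (rr - best$row)^2 + (cc - best$col)^2 <= 81
    blob_covered <- all(m[inblob])
    focus_clear <- !any(m[cbind(round(out$truth$row) + 1,
                                round(out$truth$col) + 1)])
    blob_covered && focus_clear
  }, logical(1))
  expect_true(all(hits))
})

test_that("NTH detection finds isolated peaks and honors the tie rule", {
  img <- matrix(10, 30, 30)
  img[12, 17] <- 100
  cen <- detect_foci_nth(img)
  expect_equal(nrow(cen), 1L)
  expect_equal(c(cen$row, cen$col), c(11, 16))     # 0-based

  # two equal-valued pixels in one component: smallest row-major index wins
  img2 <- matrix(10, 30, 30)
  img2[12, 17] <- 100
  img2[13, 17] <- 100
  cen2 <- detect_foci_nth(img2)
  expect_equal(nrow(cen2), 1L)
  expect_equal(c(cen2$row, cen2$col), c(11, 16))

  # near-edge peaks are discarded so the 7x7 ring always fits
  img3 <- matrix(10, 30, 30)
  img3[2, 15] <- 100
  expect_equal(nrow(detect_foci_nth(img3)), 0L)
})

test_that("detection is invariant to intensity rescaling", {
  out <- render_replicate_fov(77, tau = 4, n_cells = 4)
  img <- build_intensity_image(out$stack)
  a <- detect_foci_nth(img)
  b <- detect_foci_nth(img * 3.7)
  expect_equal(a[c("row", "col")], b[c("row", "col")])
})

test_that("foci at peak SNR >= 5 are recovered with high recall/precision", {
  # quick version of the segmentation-quality acceptance check (5 seeds)
  stats <- t(vapply(1:5, function(s) {
    sc <- random_scene(tpl_small, n_cells = 6, tau_ns = 4,
                       focus_amplitude_dn = 400, foci_per_cell = 1,
                       seed = 300 + s)
    out <- render_gated_stack(sc, tpl_small, irf_sim)
    img <- build_intensity_image(out$stack)
    m <- match_foci(detect_foci_nth(img, mask_dead_cells(img)), out$truth)
    c(m$recall, m$precision)
  }, numeric(2)))
  expect_gte(stats::median(stats[, 1]), 0.95)
  expect_gte(stats::median(stats[, 2]), 0.90)
})

test_that("TVB subtraction uses the hollow-square median per frame", {
  frames <- lapply(c(12, 9, 7), function(v) {
    m <- matrix(5, 20, 20)
    m[9:11, 9:11] <- v          # member 3x3 block at center (9,9) 0-based
    m
  })
  st <- gated_stack(frames, tpl_tiny)
  regions <- subtract_tvb(st, data.frame(row = 9, col = 9))
  expect_length(regions, 1L)
  r <- regions[[1]]
  expect_equal(nrow(r$member_px), 9L)
  expect_equal(nrow(r$ring_px), 24L)
  expect_equal(r$per_frame_tvb_dn, c(5, 5, 5))
  expect_equal(r$decay_dn, c(63, 36, 18))     # 9 * (v - 5)
  expect_equal(r$total_signal_dn, 117)

  # median robustness: one hot ring pixel does not move the TVB
  frames2 <- frames
  frames2[[1]][6, 6] <- 100                    # a ring pixel of the focus
  st2 <- gated_stack(frames2, tpl_tiny)
  r2 <- subtract_tvb(st2, data.frame(row = 9, col = 9))[[1]]
  expect_equal(r2$per_frame_tvb_dn[1], 5)
})

test_that("rings exclude masked pixels and other foci's members", {
  frames <- lapply(1:3, function(i) matrix(10, 20, 20))
  st <- gated_stack(frames, tpl_tiny)
  # two foci 3 px apart: each ring overlaps the other's member block
  centers <- data.frame(row = c(9, 9), col = c(6, 9))
  regions <- subtract_tvb(st, centers)
  for (r in regions) {
    other <- regions[[which(vapply(regions, function(x)
      !identical(x$center_px, r$center_px), logical(1)))]]
    mem_keys <- paste(other$member_px[, 1], other$member_px[, 2])
    ring_keys <- paste(r$ring_px[, 1], r$ring_px[, 2])
    expect_length(intersect(ring_keys, mem_keys), 0L)
  }
  # an exclusion mask eating the ring drops the focus with a warning
  excl <- matrix(FALSE, 20, 20)
  excl[4:15, 4:15] <- TRUE
  excl[9:11, 9:11] <- FALSE    # keep members clear, kill the ring
  expect_warning(
    out <- subtract_tvb(st, data.frame(row = 9, col = 9), excl),
    "dropped")
  expect_length(out, 0L)
})

test_that("spatially uniform per-frame backgrounds cancel exactly", {
  out <- render_replicate_fov(55, tau = 2.5, n_cells = 3)
  st <- out$stack
  img <- build_intensity_image(st)
  centers <- detect_foci_nth(img)
  r0 <- subtract_tvb(st, centers)
  offsets <- stats::runif(st$template$n_frames, 0, 500)
  st2 <- st
  st2$frames <- lapply(seq_along(st$frames),
                       function(f) st$frames[[f]] + offsets[f])
  r1 <- subtract_tvb(st2, centers)
  for (i in seq_along(r0)) {
    expect_lt(max(abs(r1[[i]]$decay_dn - r0[[i]]$decay_dn) /
                    pmax(abs(r0[[i]]$decay_dn), 1)), 1e-9)
  }
})
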