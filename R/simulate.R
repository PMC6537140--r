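#' Scene specification for the synthetic gated microscope
#'
#' Describes one synthetic field of view: yeast cells as ellipses of
#' autofluorescent cytoplasm, 1-2 diffraction-limited kinetochore foci per
#' cell with low photon budgets, occasional large bright dead cells, a
#' camera offset, Poisson-like noise, and per-frame photobleaching during
#' the prebleach phase. All positions are 0-based (row, col) pixel
#' coordinates; subpixel focus positions are rendered by analytic Gaussian
#' integration over pixel areas.
#'
#' @param cells Data frame of cell ellipses: `row`, `col` (center),
#'   `ax_row`, `ax_col` (semi-axes in px). May have zero rows.
#' @param foci Data frame of emitters: `row`, `col` (subpixel center),
#'   `amplitude_dn` (total emitted DN per excitation period),
#'   `tau_ns` (ground-truth lifetime).
#' @param dead_cells Data frame of bright dead-cell blobs: `row`, `col`,
#'   `radius_px`, `amplitude_dn` (per-pixel per-period amplitude).
#' @param autofluor_rate_dn Per-pixel per-period autofluorescence amplitude
#'   inside cells (DN).
#' @param autofluor_tau_ns Autofluorescence lifetime (ns).
#' @param psf_sigma_px Isotropic Gaussian PSF width (px).
#' @param camera_offset_dn Fixed background added to every pixel (DN).
#' @param noise One of `"poisson"` (Poisson sampling on a pseudo-photon
#'   scale followed by multiplication by `gain`) or `"none"`.
#' @param gain DN per pseudo-photon for the Poisson noise model.
#' @param bleach_rate Per-frame multiplicative signal loss during the
#'   prebleach phase; FLIM frames carry the accumulated factor.
#' @param seed Integer seed; the same spec and seed render bit-identically.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(cells = empty_cells(), foci = empty_foci(),
                       dead_cells = empty_dead_cells(),
                       autofluor_rate_dn = 20, autofluor_tau_ns = 1.2,
                       psf_sigma_px = 0.35, camera_offset_dn = 100,
                       noise = c("poisson", "none"), gain = 1,
                       bleach_rate = 0.01, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(psf_sigma_px > 0, autofluor_rate_dn >= 0, camera_offset_dn >= 0,
            gain > 0, bleach_rate >= 0, bleach_rate < 1)
  if (nrow(foci) && any(foci$amplitude_dn < 0)) {
    stop("focus amplitudes must be nonnegative")
  }
  structure(
    list(cells = cells, foci = foci, dead_cells = dead_cells,
         autofluor_rate_dn = autofluor_rate_dn,
         autofluor_tau_ns = autofluor_tau_ns,
         psf_sigma_px = psf_sigma_px, camera_offset_dn = camera_offset_dn,
         noise = noise, gain = gain, bleach_rate = bleach_rate,
         seed = as.integer(seed)),
    class = "scene_spec"
  )
}

#' @rdname scene_spec
#' @export
empty_cells <- function() {
  data.frame(row = numeric(), col = numeric(), ax_row = numeric(),
             ax_col = numeric())
}

#' @rdname scene_spec
#' @export
empty_foci <- function() {
  data.frame(row = numeric(), col = numeric(), amplitude_dn = numeric(),
             tau_ns = numeric())
}

#' @rdname scene_spec
#' @export
empty_dead_cells <- function() {
  data.frame(row = numeric(), col = numeric(), radius_px = numeric(),
             amplitude_dn = numeric())
}

is_scene_spec <- function(x) inherits(x, "scene_spec")

# Analytic integral of a unit-mass isotropic Gaussian over pixel areas,
# accumulated into `map` (modified copy returned). 0-based coordinates;
# pixel (r, c) covers [r - 0.5, r + 0.5] x [c - 0.5, c + 0.5].
add_gaussian_spot <- function(map, row0, col0, mass, sigma) {
  nr <- nrow(map); nc <- ncol(map)
  half <- ceiling(5 * sigma) + 1
  r <- max(0, floor(row0) - half):min(nr - 1, ceiling(row0) + half)
  c <- max(0, floor(col0) - half):min(nc - 1, ceiling(col0) + half)
  wr <- stats::pnorm((r + 0.5 - row0) / sigma) -
    stats::pnorm((r - 0.5 - row0) / sigma)
  wc <- stats::pnorm((c + 0.5 - col0) / sigma) -
    stats::pnorm((c - 0.5 - col0) / sigma)
  map[r + 1, c + 1] <- map[r + 1, c + 1] + mass * outer(wr, wc)
  map
}

# Per-frame temporal factors for a unit-amplitude emitter of lifetime tau,
# covering prebleach frames (gate at their recorded delay) and flim frames,
# including the prebleach bleaching schedule.
frame_factors <- function(tau_ns, template, irf, bleach_rate) {
  g <- gated_exp_signals(tau_ns, 1, template$frame_delays_ns,
                         template$gate_width_ns, template$period_ns, irf)
  pre <- template$frame_roles == "prebleach"
  npre <- sum(pre)
  bl <- rep((1 - bleach_rate)^npre, template$n_frames)
  if (npre) bl[pre] <- (1 - bleach_rate)^(seq_len(npre) - 1)
  g * bl
}

#' Render a synthetic gated stack
#'
#' Forward model of the acquisition: every emitter contributes, at each
#' temporal frame, its amplitude times the gate-integrated, IRF-convolved,
#' period-wrapped exponential at that frame's gate delay (the same model the
#' fitting stage assumes, computed by the closed-form gate integrals of
#' [model_gated_decay()]); focus signal is spread spatially by analytic
#' Gaussian PSF integration; prebleach frames apply cumulative bleach
#' factors; the camera offset is added; noise is applied last.
#'
#' With `noise = "poisson"` the frames are integer DN (gain 1) and can be
#' written losslessly by [write_fov_stack()]; with `noise = "none"` the
#' frames are exact continuous expectations, used by the analytic oracles.
#'
#' @param scene A [scene_spec()].
#' @param template An [acq_template()].
#' @param irf An [irf_profile()] on the template's period.
#' @param fov_id,well_id,strain_id Identifiers for the produced stack.
#' @return A list with `stack` (a [gated_stack()]) and `truth` (data frame
#'   of ground-truth focus positions, amplitudes and lifetimes).
#' @export
render_gated_stack <- function(scene, template, irf, fov_id = "fov",
                               well_id = "well", strain_id = "strain") {
  stopifnot(is_scene_spec(scene), is_acq_template(template),
            is_irf_profile(irf))
  nr <- template$frame_shape[1]; nc <- template$frame_shape[2]
  if (nrow(scene$foci)) {
    bad <- scene$foci$row < 0 | scene$foci$row > nr - 1 |
      scene$foci$col < 0 | scene$foci$col > nc - 1
    if (any(bad)) {
      stop("focus placed outside the frame at rows ",
           paste(which(bad), collapse = ", "))
    }
  }

  # spatial amplitude maps, one per emitter class (autofluor+dead share tau)
  af_map <- matrix(0, nr, nc)
  if (nrow(scene$cells)) {
    rr <- matrix(0:(nr - 1), nr, nc)
    cc <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
    for (i in seq_len(nrow(scene$cells))) {
      e <- scene$cells[i, ]
      inside <- ((rr - e$row) / e$ax_row)^2 + ((cc - e$col) / e$ax_col)^2 <= 1
      af_map[inside] <- af_map[inside] + scene$autofluor_rate_dn
    }
  }
  if (nrow(scene$dead_cells)) {
    rr <- matrix(0:(nr - 1), nr, nc)
    cc <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
    for (i in seq_len(nrow(scene$dead_cells))) {
      d <- scene$dead_cells[i, ]
      inside <- (rr - d$row)^2 + (cc - d$col)^2 <= d$radius_px^2
      af_map[inside] <- af_map[inside] + d$amplitude_dn
    }
  }

  foci_maps <- list()
  if (nrow(scene$foci)) {
    for (tau in unique(scene$foci$tau_ns)) {
      m <- matrix(0, nr, nc)
      sel <- scene$foci[scene$foci$tau_ns == tau, , drop = FALSE]
      for (i in seq_len(nrow(sel))) {
        m <- add_gaussian_spot(m, sel$row[i], sel$col[i],
                               sel$amplitude_dn[i], scene$psf_sigma_px)
      }
      foci_maps[[as.character(tau)]] <- m
    }
  }

  g_af <- frame_factors(scene$autofluor_tau_ns, template, irf,
                        scene$bleach_rate)
  g_foci <- lapply(names(foci_maps), function(tau) {
    frame_factors(as.numeric(tau), template, irf, scene$bleach_rate)
  })
  frames <- vector("list", template$n_frames)
  for (f in seq_len(template$n_frames)) {
    fr <- matrix(scene$camera_offset_dn, nr, nc)
    fr <- fr + af_map * g_af[f]
    for (j in seq_along(foci_maps)) {
      fr <- fr + foci_maps[[j]] * g_foci[[j]][f]
    }
    frames[[f]] <- fr
  }

  if (scene$noise == "poisson") {
    frames <- with_seed(scene$seed, {
      lapply(frames, function(fr) {
        matrix(stats::rpois(length(fr), fr / scene$gain) * scene$gain, nr, nc)
      })
    })
  }

  truth <- scene$foci
  stack <- gated_stack(frames, template, fov_id = fov_id, well_id = well_id,
                       strain_id = strain_id,
                       fixed_background_dn = scene$camera_offset_dn)
  list(stack = stack, truth = truth)
}

#' Draw a randomized scene
#'
#' Places `n_cells` ellipse cells uniformly in the frame (with an edge
#' margin), gives each cell 1 or 2 kinetochore foci near its center with
#' amplitudes jittered around `focus_amplitude_dn`, and injects a large
#' bright dead-cell blob with probability `dead_cell_prob`. Deterministic
#' given `seed`.
#'
#' @param template An [acq_template()] (for the frame shape).
#' @param n_cells Number of cells.
#' @param tau_ns Ground-truth donor lifetime for all foci (ns).
#' @param focus_amplitude_dn Mean per-focus amplitude (total emitted DN per
#'   period); individual foci jitter uniformly within +/-30 %.
#' @param amplitude_scale Multiplier on all focus amplitudes.
#' @param foci_per_cell Vector to sample the per-cell focus count from.
#' @param dead_cell_prob Probability of one injected dead cell.
#' @param dead_cell_amplitude_dn Per-pixel amplitude of the dead cell.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [scene_spec()].
#' @return A [scene_spec()].
#' @export
random_scene <- function(template, n_cells = 8, tau_ns = 4,
                         focus_amplitude_dn = 25000, amplitude_scale = 1,
                         foci_per_cell = c(1, 2), dead_cell_prob = 0,
                         dead_cell_amplitude_dn = 3000, seed = 1L, ...) {
  stopifnot(is_acq_template(template))
  nr <- template$frame_shape[1]; nc <- template$frame_shape[2]
  margin <- 8
  with_seed(seed, {
    cells <- data.frame(
      row = stats::runif(n_cells, margin, nr - 1 - margin),
      col = stats::runif(n_cells, margin, nc - 1 - margin),
      ax_row = stats::runif(n_cells, 3.5, 5),
      ax_col = stats::runif(n_cells, 3.5, 5)
    )
    foci <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
      k <- sample(foci_per_cell, 1)
      data.frame(
        row = pmin(pmax(cells$row[i] + stats::runif(k, -2, 2), 4), nr - 5),
        col = pmin(pmax(cells$col[i] + stats::runif(k, -2, 2), 4), nc - 5),
        amplitude_dn = focus_amplitude_dn * amplitude_scale *
          stats::runif(k, 0.7, 1.3),
        tau_ns = tau_ns
      )
    }))
    if (is.null(foci)) foci <- empty_foci()
    dead <- empty_dead_cells()
    if (stats::runif(1) < dead_cell_prob) {
      dead <- data.frame(
        row = stats::runif(1, 15, nr - 16),
        col = stats::runif(1, 15, nc - 16),
        radius_px = stats::runif(1, 8, 12),
        amplitude_dn = dead_cell_amplitude_dn
      )
    }
    scene_spec(cells = cells, foci = foci, dead_cells = dead,
               seed = child_seed(seed, 1L), ...)
  })
}

#' Generate a synthetic reference-dye decay
#'
#' Samples the period-wrapped, IRF-convolved exponential of lifetime
#' `tau_ref_ns` on a uniform grid (default 25 ps over the whole period),
#' optionally adding Poisson-scaled Gaussian noise. With
#' `tau_ref_ns = 0.1` this emulates the heavily quenched short-lifetime
#' reference (~100 ps).
#'
#' @param tau_ref_ns Reference lifetime (ns), in `(0, period)`.
#' @param irf An [irf_profile()].
#' @param template An [acq_template()].
#' @param amplitude_dn Peak-scale amplitude (total DN per period).
#' @param noise_scale Noise multiplier; 0 (default) gives the exact model.
#' @param seed Integer seed for the noise.
#' @param dt_ns Sample spacing (ns), default 0.025 (25 ps).
#' @return A [reference_decay()].
#' @export
generate_reference_decay <- function(tau_ref_ns, irf, template,
                                     amplitude_dn = 1e6, noise_scale = 0,
                                     seed = 1L, dt_ns = 0.025) {
  stopifnot(is_acq_template(template), is_irf_profile(irf))
  period <- template$period_ns
  if (!(tau_ref_ns > 0 && tau_ref_ns < period)) {
    stop("tau_ref_ns must lie in (0, period)")
  }
  n <- round(period / dt_ns)
  t <- (0:(n - 1)) * dt_ns
  w <- irf$values * irf$dt_ns
  keep <- w > 0
  tk <- irf$times_ns[keep]; w <- w[keep]
  denom <- 1 - exp(-period / tau_ref_ns)
  vals <- vapply(t, function(ti) {
    sum(w * exp(-((ti - tk) %% period) / tau_ref_ns)) / denom
  }, numeric(1))
  vals <- vals * amplitude_dn / tau_ref_ns
  if (noise_scale > 0) {
    vals <- with_seed(seed, {
      vals + stats::rnorm(n, 0, noise_scale * sqrt(pmax(vals, 0)))
    })
    vals[vals < 0] <- 0
  }
  reference_decay(t, vals, tau_ref_ns, period)
}

#' Generate a reference decay for a Gaussian IRF in closed form
#'
#' Exact samples of the period-wrapped convolution of a monoexponential
#' decay with a continuous Gaussian IRF (the wrapped exponentially modified
#' Gaussian), evaluated analytically rather than from a sampled IRF. Used
#' when the reference must be free of sampling artifacts, e.g. for
#' validating the reconvolution identity at tight tolerances.
#'
#' @inheritParams generate_reference_decay
#' @param sigma_ns Gaussian IRF width (ns).
#' @param center_ns Gaussian IRF center (ns).
#' @return A [reference_decay()].
#' @export
gaussian_reference_decay <- function(tau_ref_ns, sigma_ns, center_ns = 1,
                                     template = acq_template(),
                                     amplitude_dn = 1e6, noise_scale = 0,
                                     seed = 1L, dt_ns = 0.025) {
  stopifnot(is_acq_template(template), sigma_ns > 0)
  period <- template$period_ns
  if (!(tau_ref_ns > 0 && tau_ref_ns < period)) {
    stop("tau_ref_ns must lie in (0, period)")
  }
  n <- round(period / dt_ns)
  t <- (0:(n - 1)) * dt_ns
  erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))
  emg <- function(u) {
    arg <- sigma_ns^2 / (2 * tau_ref_ns^2) - (u - center_ns) / tau_ref_ns
    (1 / (2 * tau_ref_ns)) * exp(arg) *
      erfc((center_ns + sigma_ns^2 / tau_ref_ns - u) / (sigma_ns * sqrt(2)))
  }
  kmax <- ceiling(45 * tau_ref_ns / period) + 2
  vals <- numeric(n)
  for (k in -1:kmax) vals <- vals + emg(t + k * period)
  vals <- vals * amplitude_dn
  if (noise_scale > 0) {
    vals <- with_seed(seed, {
      vals + stats::rnorm(n, 0, noise_scale * sqrt(pmax(vals, 0)))
    })
    vals[vals < 0] <- 0
  }
  reference_decay(t, vals, tau_ref_ns, period)
}

#' Generate a whole synthetic plate
#'
#' Renders one gated stack per (well, FOV) of the layout, with cell and
#' focus placement randomized per FOV from a deterministic per-FOV substream
#' of the master seed, and the ground-truth lifetime/amplitude of each
#' strain taken from `strain_truth`.
#'
#' @param layout A [plate_layout()].
#' @param strain_truth Data frame with columns `strain_id`, `tau_ns` and
#'   optionally `amplitude_scale` (default 1).
#' @param template An [acq_template()].
#' @param irf An [irf_profile()].
#' @param seed Master integer seed.
#' @param dir If non-`NULL`, stacks are written there as TIFF + sidecar and
#'   the ground truth as `ground_truth.csv`; otherwise stacks are returned
#'   in memory.
#' @param ... Scene parameters forwarded to [random_scene()] (e.g.
#'   `n_cells`, `focus_amplitude_dn`, `dead_cell_prob`, `noise`).
#' @return A list with `stacks` (list of [gated_stack()], or file paths when
#'   `dir` is given), `truth` (per-focus ground-truth table), and `fovs`
#'   (the enumerated FOV table).
#' @export
generate_plate <- function(layout, strain_truth, template, irf, seed = 1L,
                           dir = NULL, ...) {
  stopifnot(is_plate_layout(layout), is.data.frame(strain_truth),
            all(c("strain_id", "tau_ns") %in% names(strain_truth)))
  if (!"amplitude_scale" %in% names(strain_truth)) {
    strain_truth$amplitude_scale <- 1
  }
  fovs <- enumerate_fovs(layout)
  missing <- setdiff(unique(fovs$strain_id), strain_truth$strain_id)
  if (length(missing)) {
    stop("no ground-truth entry for strain(s): ",
         paste(missing, collapse = ", "))
  }
  if (!is.null(dir) && !dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  stacks <- vector("list", nrow(fovs))
  truth_list <- vector("list", nrow(fovs))
  for (i in seq_len(nrow(fovs))) {
    st <- strain_truth[strain_truth$strain_id == fovs$strain_id[i], ]
    scene <- random_scene(template,
                          tau_ns = st$tau_ns[1],
                          amplitude_scale = st$amplitude_scale[1],
                          seed = child_seed(seed, i), ...)
    out <- render_gated_stack(scene, template, irf,
                              fov_id = fovs$fov_id[i],
                              well_id = fovs$well_id[i],
                              strain_id = fovs$strain_id[i])
    if (nrow(out$truth)) {
      out$truth$fov_id <- fovs$fov_id[i]
      out$truth$well_id <- fovs$well_id[i]
      out$truth$strain_id <- fovs$strain_id[i]
    }
    truth_list[[i]] <- out$truth
    if (is.null(dir)) {
      stacks[[i]] <- out$stack
    } else {
      p <- file.path(dir, paste0(fovs$fov_id[i], ".tif"))
      write_fov_stack(out$stack, p, quantize = TRUE)
      stacks[[i]] <- p
    }
  }
  truth <- do.call(rbind, truth_list[vapply(truth_list, nrow, 0L) > 0])
  if (!is.null(dir)) {
    utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  list(stacks = stacks, truth = truth, fovs = fovs)
}
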