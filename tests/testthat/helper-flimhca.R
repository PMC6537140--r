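# Shared fixtures: a reduced 96x96 frame geometry for rendered scenes (the
# temporal geometry is always the full 5 prebleach + 7 flim default), the
# default full-frame template for structural checks, a Gaussian-IRF
# Coumarin-6-like reference, and independent numerical oracles.

tpl_small <- acq_template(frame_shape = c(96, 96))
tpl_full <- acq_template()

irf_sim <- gaussian_irf(0.2, center_ns = 1, dt_ns = 0.025)
ref_fix <- gaussian_reference_decay(2.5, sigma_ns = 0.2, center_ns = 1,
                                    template = tpl_small)

# Brute-force forward-model oracle: circular convolution of the wrapped
# exponential with a Gaussian IRF on a fine uniform grid (default 1 ps),
# then rectangular-gate quadrature from the trapezoid cumulative integral.
# Deliberately independent of the package's closed-form gate integrals.
oracle_gates <- function(tau, A, template, sigma, center = 1, dt = 0.001) {
  T <- template$period_ns
  W <- template$gate_width_ns
  n <- round(T / dt)
  t <- (0:(n - 1)) * dt
  irf <- 0
  for (m in -2:2) irf <- irf + exp(-0.5 * ((t - center + m * T) / sigma)^2)
  irf <- irf / (sum(irf) * dt)
  # node-centered bin averages of the wrapped exponential (the function
  # jumps at the wrap, so pointwise samples would carry a first-order
  # quadrature bias; off-center bins would carry a half-bin shift)
  denom <- 1 - exp(-T / tau)
  a <- t - dt / 2
  b <- t + dt / 2
  seg <- ifelse(a < 0,
                (exp(-(a + T) / tau) - exp(-T / tau)) +
                  (1 - exp(-b / tau)),
                exp(-a / tau) - exp(-b / tau))
  fp <- (A / denom) * seg / dt
  d <- Re(stats::fft(stats::fft(irf) * stats::fft(fp), inverse = TRUE)) / n * dt
  dext <- c(d, d[1])
  cum <- c(0, cumsum((dext[-1] + dext[-(n + 1)]) / 2 * dt))
  cum_at <- function(x) {
    k <- floor(x / T); r <- x - k * T
    j <- pmin(floor(r / dt), n - 1); frac <- r / dt - j
    v0 <- dext[j + 1]; v1 <- dext[j + 2]
    k * cum[n + 1] + cum[j + 1] + dt * (v0 * frac + (v1 - v0) * frac^2 / 2)
  }
  vapply(template$delays_ns, function(d0) cum_at(d0 + W) - cum_at(d0),
         numeric(1))
}

# One rendered replicate FOV at the near-QC-threshold photon budget.
render_replicate_fov <- function(seed, tau = 2.5, n_cells = 2,
                                 amplitude = 25000, template = tpl_small,
                                 irf = irf_sim) {
  sc <- random_scene(template, n_cells = n_cells, tau_ns = tau,
                     focus_amplitude_dn = amplitude, foci_per_cell = 1,
                     seed = seed)
  render_gated_stack(sc, template, irf)
}

# Match detections to ground-truth foci within a pixel radius.
match_foci <- function(centers, truth, radius = 2) {
  if (!nrow(truth)) return(list(recall = NA, precision = NA))
  if (!nrow(centers)) return(list(recall = 0, precision = NA))
  dmat <- outer(centers$row, truth$row, "-")^2 +
    outer(centers$col, truth$col, "-")^2
  hit_truth <- apply(dmat, 2, min) <= radius^2
  hit_det <- apply(dmat, 1, min) <= radius^2
  list(recall = mean(hit_truth), precision = mean(hit_det))
}

# Build a bare focus_region carrying only the fields the fitting and QC
# stages read.
stub_region <- function(decay_dn) {
  structure(list(center_px = c(row = 10, col = 10),
                 member_px = NULL, ring_px = NULL,
                 decay_dn = decay_dn, all_frames_dn = NULL,
                 per_frame_tvb_dn = NULL,
                 total_signal_dn = sum(decay_dn)),
            class = "focus_region")
}

# One simulated two-strain screening plate (negative control vs query,
# 3 wells x 15 FOVs per strain), rendered at reduced frame geometry with a
# per-FOV photon budget comfortably above the QC threshold, analyzed by the
# full pipeline and compared by the Bonferroni-corrected rank-sum test.
# Returns TRUE when the query is called significant.
tpl_plate <- acq_template(frame_shape = c(80, 80))
ref_plate <- gaussian_reference_decay(2.5, sigma_ns = 0.2, center_ns = 1,
                                      template = tpl_plate)

run_screen_plate <- function(delta_ps, seed, tau_ctrl = 4,
                             fovs_per_well = 15) {
  strains <- data.frame(strain_id = c("ctrl", "qry"), group_id = "g1",
                        role = c("negative_control", "query"))
  lay <- make_plate_layout(strains, fovs_per_well = fovs_per_well,
                           replicate_wells_per_strain = 3)
  truth <- data.frame(strain_id = c("ctrl", "qry"),
                      tau_ns = c(tau_ctrl, tau_ctrl - delta_ps / 1000))
  pl <- generate_plate(lay, truth, tpl_plate, irf_sim, seed = seed,
                       n_cells = 4, foci_per_cell = 1)
  res <- analyze_fovs(pl$stacks, ref_plate)
  rep_out <- build_report(res, lay)
  isTRUE(rep_out$comparisons$significant)
}

# Noisy decay-level FOV: model gates at the given budget plus Poisson noise
# (used where the property under test concerns fitting or statistics, not
# image formation).
simulate_decay <- function(tau, amplitude, template, irf, seed) {
  g <- model_gated_decay(tau, amplitude, template, irf)
  with_seed <- flimhca:::with_seed
  with_seed(seed, stats::rpois(length(g), g))
}
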