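test_that("strain summaries report median, quartiles and notch CI", {
  s <- summarize_strain(c(3.8, 3.9, 4.0, 4.1, 4.2))
  expect_equal(s$median_ns, 4.0)
  expect_equal(s$iqr_ns, 0.2)
  expect_true(s$ci95_low_ns < s$median_ns && s$median_ns < s$ci95_high_ns)

  # notch half-width follows 1.57 * IQR / sqrt(n); at the IQR scale the
  # screen reports (240 ps) with n = 45 that is 56.2 ps
  x <- seq(0, 1, length.out = 45)
  x <- 4 + (x - 0.5) * 0.240 / 0.5             # IQR exactly 0.240 ns
  s45 <- summarize_strain(x)
  expect_equal(s45$iqr_ns, 0.240, tolerance = 1e-9)
  expect_equal(s45$ci95_high_ns - s45$median_ns, 1.57 * 0.240 / sqrt(45),
               tolerance = 1e-9)
  expect_equal(s45$ci95_high_ns - s45$median_ns, 0.05617, tolerance = 1e-4)

  # degenerate distribution: zero IQR, CI collapses onto the median
  s0 <- summarize_strain(rep(4, 10))
  expect_equal(s0$iqr_ns, 0)
  expect_equal(s0$ci95_low_ns, 4)
  expect_equal(s0$ci95_high_ns, 4)

  # too few values: CI flagged undefined
  s2 <- summarize_strain(c(4, 4.1))
  expect_false(s2$ci_defined)
  expect_true(is.na(s2$ci95_low_ns))
})

test_that("the two-sided rank-sum p matches exhaustive enumeration", {
  # enumeration oracle: all C(6,3) = 20 assignments of ranks to group 1
  enum_p <- function(x, y) {
    pooled <- c(x, y)
    r <- rank(pooled)
    w_obs <- sum(r[seq_along(x)])
    combos <- utils::combn(length(pooled), length(x))
    w_all <- apply(combos, 2, function(i) sum(r[i]))
    lo <- mean(w_all <= w_obs)
    hi <- mean(w_all >= w_obs)
    min(1, 2 * min(lo, hi))
  }
  expect_equal(enum_p(1:3, 4:6), 0.100, tolerance = 1e-12)
  expect_equal(flimhca:::rank_sum_p(1:3, 4:6), 0.100, tolerance = 1e-12)

  # agreement with enumeration across random small samples
  with_seed <- flimhca:::with_seed
  with_seed(5, {
    for (i in 1:20) {
      x <- round(stats::rnorm(4), 3)
      y <- round(stats::rnorm(5) + stats::runif(1, -1, 1), 3)
      expect_equal(flimhca:::rank_sum_p(x, y), enum_p(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("identical samples give p = 1 and no significance", {
  x <- c(3.9, 4.0, 4.1, 4.05, 3.95)
  expect_equal(flimhca:::rank_sum_p(x, x), 1)
})

test_that("the two-sided p-value is symmetric in its arguments", {
  with_seed <- flimhca:::with_seed
  with_seed(17, {
    for (i in 1:20) {
      x <- stats::rnorm(sample(4:30, 1))
      y <- stats::rnorm(sample(4:30, 1), mean = stats::runif(1, -1, 1))
      if (i %% 3 == 0) y[1] <- x[1]            # inject a tie sometimes
      expect_equal(flimhca:::rank_sum_p(x, y), flimhca:::rank_sum_p(y, x),
                   tolerance = 1e-12)
    }
  })
})

test_that("normal approximation tracks the exact test at n = 8", {
  with_seed <- flimhca:::with_seed
  diffs <- with_seed(23, {
    vapply(1:200, function(i) {
      x <- stats::rnorm(8)
      y <- stats::rnorm(8, mean = stats::runif(1, -1.5, 1.5))
      p_ex <- stats::wilcox.test(x, y, exact = TRUE)$p.value
      p_ap <- stats::wilcox.test(x, y, exact = FALSE,
                                 correct = TRUE)$p.value
      abs(p_ex - p_ap)
    }, numeric(1))
  })
  expect_lt(max(diffs), 0.02)
})

test_that("group comparison applies Bonferroni over query strains only", {
  mk <- function(id, role, mu) {
    summarize_strain(mu + seq(-0.2, 0.2, length.out = 9), id, "g1", role)
  }
  grp <- list(mk("ctrl", "negative_control", 4),
              mk("q1", "query", 3.6),
              mk("q2", "query", 3.95),
              mk("q3", "query", 4.02),
              mk("pos", "positive_control", 3.0))
  cmp <- compare_group(grp)
  expect_equal(nrow(cmp), 4L)
  expect_equal(unique(cmp$n_comparisons_in_group), 3L)
  expect_equal(unique(cmp$alpha_corrected), 0.05 / 3, tolerance = 1e-12)
  expect_equal(cmp$significant, cmp$p_value < 0.05 / 3)
  pos_row <- cmp[cmp$query_strain == "pos", ]
  expect_equal(pos_row$role, "positive_control")
  expect_equal(pos_row$delta_median_ps, -1000, tolerance = 1e-9)

  expect_error(compare_group(grp[-1]), "negative_control")
})

test_that("reports pool lifetimes across runs and flag empty strains", {
  strains <- data.frame(strain_id = c("ctrl", "qry"), group_id = "g1",
                        role = c("negative_control", "query"))
  lay <- make_plate_layout(strains)
  mk_run <- function(seed, n = 45) {
    with_seed <- flimhca:::with_seed
    with_seed(seed, data.frame(
      fov_id = sprintf("f%03d", 1:(2 * n)),
      well_id = "w", strain_id = rep(c("ctrl", "qry"), each = n),
      n_foci = 5, total_signal_dn = 2e5, qc_pass = TRUE,
      tau_ns = c(stats::rnorm(n, 4, 0.05), stats::rnorm(n, 3.75, 0.05)),
      amplitude_dn = 1e5, fit_residual = 0.01
    ))
  }
  two_runs <- rbind(mk_run(1), mk_run(2))
  rep_out <- build_report(two_runs, lay)
  expect_equal(rep_out$strains$n_fov, c(90L, 90L))
  expect_true(rep_out$comparisons$significant)
  expect_lt(rep_out$comparisons$delta_median_ps, -200)

  # box-plot quantities follow the 1.5 IQR whisker convention
  b <- rep_out$boxplots[["ctrl"]]
  expect_gte(b$whisker_low, b$q1 - 1.5 * b$iqr)
  expect_lte(b$whisker_high, b$q3 + 1.5 * b$iqr)
  expect_true(all(b$outliers < b$whisker_low | b$outliers > b$whisker_high))

  # a strain whose FOVs all fail QC is excluded with a warning
  bad <- mk_run(3)
  bad$qc_pass[bad$strain_id == "qry"] <- FALSE
  expect_warning(r2 <- build_report(bad, lay), "qry")
  expect_equal(r2$strains$strain_id, "ctrl")

  # files are written on request
  out_dir <- file.path(tempdir(), "report_out")
  build_report(two_runs, lay, out_dir = out_dir, meta = list(seed = 1))
  expect_true(file.exists(file.path(out_dir, "strains.csv")))
  expect_true(file.exists(file.path(out_dir, "comparisons.csv")))
  rep_json <- jsonlite::read_json(file.path(out_dir, "report.json"))
  expect_equal(rep_json$n_fov, 180L)
  expect_equal(rep_json$meta$seed, 1L)
})

test_that("detection frequency grows with the true lifetime separation", {
  # decay-level plates: per-FOV aggregate decays fitted and compared, so
  # the power curve reflects fitting noise at the QC-threshold budget
  tpl <- tpl_small
  n_fov <- 12
  n_plate <- 15
  amp <- 1.2e5 / 2.21                          # total near the QC threshold
  with_seed <- flimhca:::with_seed
  sim_tau <- function(tau, seed) {
    g <- model_gated_decay(tau, amp, tpl, irf_sim)
    with_seed(seed, {
      vapply(seq_len(n_fov), function(i) {
        fit_fov_lifetime(stats::rpois(length(g), g), tpl, ref_fix)$tau_ns
      }, numeric(1))
    })
  }
  power_at <- function(delta_ps) {
    hits <- vapply(seq_len(n_plate), function(p) {
      ctrl <- sim_tau(4, 9100 + 7 * p)
      qry <- sim_tau(4 - delta_ps / 1000, 9400 + 7 * p)
      flimhca:::rank_sum_p(qry, ctrl) < 0.05
    }, logical(1))
    mean(hits)
  }
  pw <- vapply(c(0, 100, 250, 1000), power_at, numeric(1))
  expect_true(all(diff(pw) >= 0))
  expect_lte(pw[1], 0.2)
  expect_equal(pw[4], 1)
})
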