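ref <- ref_protocol()

test_that("efficiency curves equal independent single-point simulations", {
  grid <- seq(-12, -4, by = 1)
  cv <- efficiency_curve(grid, tag_dG = -12, protocol = ref)
  direct <- vapply(grid, function(dg) {
    run_pcr(pa_primer(dG_binding = dg, dG_tag = -12), cycles = ref$cycles,
            conditions = ref$conditions,
            anneal = "equilibrium")$equivalent_efficiency
  }, 0)
  expect_equal(cv$efficiency, direct, tolerance = 1e-12)
  expect_true(all(diff(cv$efficiency) <= 1e-10))  # monotone in dG
  expect_error(efficiency_curve(rev(grid), -12, ref), "sorted")
})

test_that("tag curves dominate conventional curves; saturating grids are flat", {
  grid <- seq(-13, -3, by = 0.5)
  conv <- efficiency_curve(grid, tag_dG = 0, protocol = ref)
  tag <- efficiency_curve(grid, tag_dG = -12, protocol = ref)
  expect_true(all(tag$efficiency >= conv$efficiency - 1e-12))

  sat <- efficiency_curve(seq(-20, -16, by = 1), tag_dG = 0, protocol = ref)
  expect_true(all(abs(sat$efficiency - 1) < 1e-3))
})

test_that("dynamic range reads crossings and is stable under refinement", {
  coarse <- efficiency_curve(seq(-14, -2, by = 0.5), tag_dG = -12,
                             protocol = ref)
  fine <- efficiency_curve(seq(-14, -2, by = 0.25), tag_dG = -12,
                           protocol = ref)
  w1 <- dynamic_range(coarse)$width
  w2 <- dynamic_range(fine)$width
  expect_lt(abs(w1 - w2) / w2, 0.02)     # +/- 2% at 2x resolution
  dr <- dynamic_range(fine)
  expect_gt(dr$width, 0)
  expect_lt(dr$dG_upper_eff, dr$dG_lower_eff)
  # logistic reader also available
  expect_s3_class(dynamic_range(fine, method = "logistic"),
                  "pa_dynamic_range")

  # an (almost) ideal step curve has (almost) zero width
  step <- data.frame(dG = seq(-10, -6, by = 0.05),
                     efficiency = ifelse(seq(-10, -6, by = 0.05) < -8, 1, 0))
  class(step) <- c("pa_curve", "data.frame")
  expect_lt(dynamic_range(step)$width, 0.05 + 1e-9)

  # crossings outside the evaluated grid are reported explicitly
  flat <- efficiency_curve(seq(-20, -16, by = 1), tag_dG = 0, protocol = ref)
  expect_error(dynamic_range(flat), "not bracketed")
})

test_that("truncation scans track the removed NN stack exactly", {
  conds <- ref$conditions
  p <- pa_primer(binding_region = "ACGTGCATGCAGTCAG", dG_tag = -12,
                 conditions = conds)
  sc <- truncation_scan(p, n_truncations = 3, protocol = ref)
  expect_equal(nrow(sc), 4L)
  # zero truncations reproduces the original primer's metrics
  expect_equal(sc$dG[1], p$dG_binding)
  expect_equal(sc$sequence[1], "ACGTGCATGCAGTCAG")

  # each step's dG change equals the independently recomputed difference
  for (k in 2:4) {
    expect_equal(sc$dG[k] - sc$dG[k - 1],
                 oracle_duplex_dG(sc$sequence[k], 60, 0.18) -
                   oracle_duplex_dG(sc$sequence[k - 1], 60, 0.18),
                 tolerance = 1e-10)
  }
  # efficiency never increases as the binding region weakens...
  # (not strictly guaranteed per-step: a removed TA stack can stabilize;
  # here the scanned sequence only loses stabilizing stacks)
  expect_true(all(diff(sc$efficiency) <= 1e-10))
  expect_true(all(diff(sc$Ct) >= -1e-10))

  expect_error(truncation_scan(p, n_truncations = 12, protocol = ref),
               "over-truncation")
})

test_that("tag primers blunt the efficiency cost of truncation", {
  win_c <- transition_window(0, ref)
  win_t <- transition_window(-12, ref)
  panel_c <- generate_primer_panel(30, dg_range = sort(win_c), seed = 31)
  panel_t <- generate_primer_panel(30, dg_range = sort(win_t), seed = 32)
  d_c <- median_truncation_drop(panel_c, tag_dG = 0, protocol = ref,
                                n_truncations = 2)
  d_t <- median_truncation_drop(panel_t, tag_dG = -12, protocol = ref,
                                n_truncations = 2)
  expect_lt(d_t$median_drop_pct, d_c$median_drop_pct)
  expect_gt(nrow(d_c$events), 30)
  # stronger tags never make truncation more damaging
  d_t2 <- median_truncation_drop(panel_t, tag_dG = -16, protocol = ref,
                                 n_truncations = 2)
  expect_lte(d_t2$median_drop_pct, d_c$median_drop_pct)
  expect_error(median_truncation_drop(character(0)), "empty")
})

test_that("condition sweeps re-derive dG(T) and respect known monotonicities", {
  p <- pa_primer(binding_region = "ACGTGCATGCAGTCAG", dG_tag = -12,
                 conditions = ref$conditions)
  sw <- condition_sweep(p, temperatures = c(55, 60, 65), times = c(10, 30),
                        protocol = ref)
  expect_equal(nrow(sw), 6L)
  # dG re-evaluated per temperature, matching the oracle
  for (tt in c(55, 60, 65)) {
    expect_equal(sw$dG[sw$temperature == tt][1],
                 oracle_duplex_dG("ACGTGCATGCAGTCAG", tt, 0.18),
                 tolerance = 1e-10)
  }
  # higher temperature destabilizes and lowers efficiency (dS < 0)
  at30 <- sw[sw$time == 30, ]
  expect_true(all(diff(at30$efficiency[order(at30$temperature)]) <= 1e-9))
  # longer extension time never lowers efficiency (up to solver noise)
  for (tt in c(55, 60, 65)) {
    sub <- sw[sw$temperature == tt, ]
    expect_gte(sub$efficiency[sub$time == 30],
               sub$efficiency[sub$time == 10] - 1e-6)
  }
  # sweep cells equal direct single-condition evaluations
  conds <- ref$conditions
  conds$temperature <- 55
  conds$extension_time <- 10
  dg55 <- duplex_thermo("ACGTGCATGCAGTCAG", conds)$dG
  direct <- run_pcr(pa_primer(dG_binding = dg55, dG_tag = -12),
                    cycles = ref$cycles, conditions = conds)
  expect_equal(sw$efficiency[sw$temperature == 55 & sw$time == 10],
               direct$equivalent_efficiency, tolerance = 1e-6)
})

test_that("tag dynamic range exceeds conventional across temperatures and times", {
  grid <- seq(-16, 0, by = 0.5)
  for (tt in c(55, 60, 65)) {
    for (ext in c(30, 120)) {
      proto <- ref
      proto$conditions$temperature <- tt
      proto$conditions$extension_time <- ext
      w_conv <- dynamic_range(efficiency_curve(grid, 0, proto))$width
      w_tag <- dynamic_range(efficiency_curve(grid, -12, proto))$width
      expect_gt(w_tag, w_conv)
    }
  }
})
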