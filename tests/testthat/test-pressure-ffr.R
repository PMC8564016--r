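mu0 <- 3.5e-3
rho0 <- 1060

test_that("aortic pressure estimate and ischemia classification", {
  expect_equal(mean_aortic_pressure(134, 77), 89.2, tolerance = 1e-12)
  expect_equal(mean_aortic_pressure(134, 77, offset = 0), 96, tolerance = 1e-12)
  expect_error(mean_aortic_pressure(90, 90), "sbp > dbp")
  expect_true(classify_ischemic(0.80))   # boundary inclusive
  expect_false(classify_ischemic(0.81))
  expect_true(classify_ischemic(0.72))
  expect_error(classify_ischemic(1.2), "0, 1")
})

test_that("Poiseuille and taper closed forms match hand values and each other", {
  # q = 0 gives zero drop
  expect_equal(poiseuille_drop(0, mu0, 0.01, 7e-6), 0)
  # hand-computed reference: 17.61 Pa
  a15 <- pi * (1.5e-3)^2
  expect_equal(poiseuille_drop(1e-6, mu0, 0.01, a15), 17.605, tolerance = 1e-3)
  # linear in length
  expect_equal(poiseuille_drop(1e-6, mu0, 0.02, a15),
               2 * poiseuille_drop(1e-6, mu0, 0.01, a15))
  expect_error(poiseuille_drop(1e-6, mu0, 0.01, 0), "occluded")

  # taper limit r1 = r2 equals Poiseuille: 44.56 Pa
  expect_equal(taper_viscous_drop(1e-6, mu0, 1e-3, 1e-3, 5e-3),
               poiseuille_drop(1e-6, mu0, 5e-3, pi * 1e-6), tolerance = 1e-9)
  expect_equal(taper_viscous_drop(1e-6, mu0, 1e-3, 1e-3, 5e-3), 44.56,
               tolerance = 1e-3)
  # hand-computed taper 1.5 -> 1.0 mm over 5 mm: 20.91 Pa
  expect_equal(taper_viscous_drop(1e-6, mu0, 1.5e-3, 1e-3, 5e-3), 20.906,
               tolerance = 1e-3)
  # bounded by the Poiseuille drops at the end radii, random draws
  set.seed(2)
  for (i in 1:50) {
    r1 <- runif(1, 0.5e-3, 2e-3); r2 <- runif(1, 0.5e-3, 2e-3)
    L <- runif(1, 1e-3, 2e-2); q <- runif(1, 5e-7, 5e-6)
    d <- taper_viscous_drop(q, mu0, r1, r2, L)
    dmin <- poiseuille_drop(q, mu0, L, pi * max(r1, r2)^2)
    dmax <- poiseuille_drop(q, mu0, L, pi * min(r1, r2)^2)
    expect_gte(d, dmin - 1e-12); expect_lte(d, dmax + 1e-12)
  }
})

test_that("contraction and expansion losses match hand values and vanish in limits", {
  expect_equal(contraction_loss(3e-6, rho0, 6e-6, 2e-6, 0), 0)
  expect_equal(contraction_loss(3e-6, rho0, 6e-6, 6e-6, 30), 0)
  expect_equal(contraction_loss(3e-6, rho0, 6e-6, 2e-6, 30), 97.76,
               tolerance = 1e-3)
  expect_error(contraction_loss(3e-6, rho0, 2e-6, 6e-6, 30), "a_s <= a_p")

  expect_equal(expansion_loss(3e-6, rho0, 2e-6, 2e-6, 30), 0)
  # beta large enough that zeta_e caps at 1: 530 Pa (~3.98 mmHg)
  expect_equal(expansion_loss(3e-6, rho0, 2e-6, 6e-6, 45), 530,
               tolerance = 1e-3)
  expect_equal(expansion_loss(3e-6, rho0, 2e-6, 6e-6, 45) / 133.322387415,
               3.975, tolerance = 1e-3)
  # sub-cap angle scales by 2.6 sin(beta)
  expect_equal(expansion_loss(3e-6, rho0, 2e-6, 6e-6, 10),
               530 * 2.6 * sin(10 * pi / 180), tolerance = 1e-3)
})

test_that("three-segment lesion drop: limits, hand value, oracle agreement", {
  # uniform lesion with zero angles reduces exactly to Poiseuille over L
  f <- linear_lesion_fixture(1.2e0, 1.2, 1.2, 3, 4, 3, n_per_seg = 4)
  l <- f$lesion
  d <- lesion_pressure_drop(l, 2e-6)
  pois <- poiseuille_drop(2e-6, mu0, 10e-3, pi * (1.2e-3)^2) / 133.322387415
  expect_equal(d$dp1, pois, tolerance = 1e-12)
  # q = 0: all components zero
  d0 <- lesion_pressure_drop(l, 0)
  expect_equal(unlist(d0), c(dp_ps = 0, dp_ss = 0, dp_sd = 0, dp1 = 0))

  # hand-computed full example: A_p = A_d = 6e-6 m^2, A_s = 2e-6, L = 10 mm,
  # L_ps = L_sd = 3 mm, q = 3e-6 -> ~710 Pa total
  rp <- sqrt(6e-6 / pi) * 1e3; rs <- sqrt(2e-6 / pi) * 1e3
  fx <- linear_lesion_fixture(rp, rs, rp, 3, 4, 3, n_per_seg = 400)
  d2 <- lesion_pressure_drop(fx$lesion, 3e-6)
  to_pa <- 133.322387415
  expect_equal(d2$dp1 * to_pa, 710, tolerance = 2e-3)
  # component check: throat Poiseuille 263.9 Pa; per-taper viscous 72.8 Pa;
  # contraction 37.4 Pa; expansion 263.3 Pa
  expect_equal(d2$dp_ss * to_pa, 263.9, tolerance = 1e-2)
  expect_equal((d2$dp_ps + d2$dp_sd - d2$dp_ss * 0) * to_pa,
               72.8 * 2 + 37.4 + 263.3, tolerance = 1e-2)
  # oracle equivalence on the same geometry
  expect_lt(rel_err(d2$dp1,
                    oracle_pressure_drop(fx$branch, list(fx$lesion), 3e-6)),
            1e-4)

  expect_error(lesion_pressure_drop(
    within(fx$lesion, L_sd <- 9), 1e-6))
})

test_that("dp1 sensitivity: increases as A_s shrinks, q grows, L grows", {
  base <- function(rs = 1.0, q = 3e-6, Lss = 4)
    lesion_pressure_drop(linear_lesion_fixture(1.6, rs, 1.6, 3, Lss, 3,
                                               n_per_seg = 4)$lesion, q)$dp1
  d_rs <- vapply(seq(1.3, 0.5, by = -0.1), function(r) base(rs = r), 0)
  expect_true(all(diff(d_rs) > 0))
  d_q <- vapply(seq(1e-6, 6e-6, by = 1e-6), function(q) base(q = q), 0)
  expect_true(all(diff(d_q) > 0))
  d_L <- vapply(seq(2, 12, by = 2), function(L) base(Lss = L), 0)
  expect_true(all(diff(d_L) > 0))
})

test_that("upstream drop is additive over the path and excludes lesions", {
  # uniform branch upstream of the lesion equals the closed form exactly
  tr <- make_straight_tube(40, 1.5, 0.25)
  a0 <- pi * 1.5^2
  l <- lesion("root", s_prox = 15, s_dist = 20, s_throat_start = 16,
              s_throat_end = 19, A_p = a0, A_s = a0, A_d = a0, L = 5,
              L_ps = 1, L_sd = 1, alpha = 0, beta = 0, ds = 0.3)
  fa <- allocate_branch_flows(tr, 2)
  fh <- hyperemic_flows(fa, tr, list(l), patient_context())
  dp2 <- upstream_drop(tr, fh, l)
  q_si <- fh$branches$root$seg$q[1] * 1e-6
  closed <- poiseuille_drop(q_si, mu0, 15e-3, a0 * 1e-6) / 133.322387415
  expect_lt(rel_err(dp2, closed), 1e-9)
  # the lesion interval itself is excluded: extending the vessel query past
  # the lesion adds nothing inside [s_prox, s_dist]
  l_past <- l; l_past$s_prox <- 25
  dp2_past <- upstream_drop(tr, fh, l_past, lesions = list(l))
  # the mask zeroes the density strictly inside the lesion; the trapezoid
  # keeps half a grid strip at each lesion edge, i.e. one step of density
  d0 <- 8 * pi * mu0 * q_si / (a0 * 1e-6)^2
  closed_past <- (poiseuille_drop(q_si, mu0, 20e-3, a0 * 1e-6) +
                    d0 * 0.25e-3) / 133.322387415
  expect_lt(rel_err(dp2_past, closed_past), 1e-9)

  # lesion at the ostium: zero-length upstream path
  tr0 <- resample_tree(make_stenosed_vessel(
    stenosis_spec(0.5, L = 10, L_ps = 3, L_sd = 3, center_s = 6),
    0.25, vessel_length = 30), 0.25)
  les0 <- find_lesions(tr0, window = 0)
  fh0 <- hyperemic_flows(allocate_branch_flows(tr0, 2), tr0, les0,
                         patient_context())
  l0 <- les0[[1]]
  l0$s_prox <- 0  # pin to the ostium
  expect_equal(upstream_drop(tr0, fh0, l0), 0, tolerance = 1e-12)

  # two-branch path: drop equals the sum of per-branch drops, each at its
  # own flow (root via closed form, stenosed child via the numeric oracle
  # on its truncated profile)
  tr2 <- make_bifurcating_tree(2, root_radius = 1.8,
                               child_ratios = c(0.9, 0.7), step = 0.25)
  tr2 <- add_stenosis(tr2, "rootL", 0.5, center_s = 12)
  tr2 <- resample_tree(tr2, 0.25)
  les2 <- find_lesions(tr2, window = 0)
  fh2 <- hyperemic_flows(allocate_branch_flows(tr2, 3), tr2, les2,
                         patient_context())
  l2 <- les2[[1]]
  dp2b <- upstream_drop(tr2, fh2, l2)
  rootlen <- diff(range(tr2$branches$root$s))
  part_root <- poiseuille_drop(fh2$branches$root$seg$q[1] * 1e-6, mu0,
                               rootlen * 1e-3, pi * 1.8e-3^2) / 133.322387415
  child <- tr2$branches$rootL
  keep <- child$s <= l2$s_prox + 1e-9
  child_trunc <- branch("c", child$s[keep], child$area[keep])
  part_child <- oracle_pressure_drop(child_trunc, list(),
                                     fh2$branches$rootL$seg$q[1] * 1e-6)
  expect_lt(rel_err(dp2b, part_root + part_child), 1e-9)
})

test_that("FFR profile: arithmetic, interpolation, monotone decrease", {
  # no lesions, negligible length: FFR ~ 1 everywhere
  tube <- make_straight_tube(2, 2, 0.5)
  fh <- hyperemic_flows(allocate_branch_flows(tube, 1), tube, list(),
                        patient_context())
  pr <- ffr_profile(tube, fh, list(), pa = 89.2)
  expect_true(all(pr$branches$root$ffr > 0.999))
  expect_equal(ffr_at(pr, tree_location("root", 0)), 1)

  # pa = 90, dp_cum = 18 at a point -> ffr = 0.8 (direct arithmetic)
  expect_equal(1 - 18 / 90, 0.8)

  # interpolated value lies between bracketing grid values
  tr <- resample_tree(make_stenosed_vessel(stenosis_spec(0.55), 0.25), 0.25)
  les <- find_lesions(tr, window = 0)
  fhs <- hyperemic_flows(allocate_branch_flows(tr, 1.5), tr, les,
                         patient_context())
  prs <- ffr_profile(tr, fhs, les, pa = 89.2)
  df <- prs$branches$root
  i <- which.max(df$s_mm > 14)
  v <- ffr_at(prs, tree_location("root", (df$s_mm[i] + df$s_mm[i + 1]) / 2))
  expect_true(v <= max(df$ffr[i:(i + 1)]) && v >= min(df$ffr[i:(i + 1)]))
  # exact at a grid point
  expect_equal(ffr_at(prs, tree_location("root", df$s_mm[i])), df$ffr[i])

  # ffr non-increasing downstream on random stenosed trees
  ctx <- patient_context()
  for (seed in 1:10) {
    trr <- resample_tree(random_stenosed_tree(3, seed), 0.5)
    lr <- find_lesions(trr, window = 1)
    fr <- hyperemic_flows(allocate_branch_flows(trr, 3), trr, lr, ctx)
    p <- suppressWarnings(ffr_profile(trr, fr, lr, pa = 89.2))
    for (id in names(p$branches))
      expect_true(all(diff(p$branches[[id]]$ffr) <= 1e-12))
  }
  expect_error(ffr_profile(tube, fh, list(), pa = -1), "positive")
})

test_that("dimensional consistency: SI kernels match a scaled-unit evaluation", {
  # Poiseuille evaluated in SI vs in a mm / mPa s / mmHg system
  q <- 2.3e-6; L <- 0.012; a <- 5.1e-6
  si <- poiseuille_drop(q, mu0, L, a)
  # scaled system: q in mm^3/s, lengths in mm, areas in mm^2; the length
  # and flow factors cancel the squared area factor exactly, so the same
  # formula yields Pa with no residual conversion
  scaled <- 8 * pi * mu0 * (L * 1e3) * (q * 1e9) / (a * 1e6)^2
  expect_lt(rel_err(si, scaled), 1e-12)
  expect_equal(133.322387415 * (si / 133.322387415), si, tolerance = 1e-15)
})

test_that("oracle matches closed forms on tubes and linear tapers", {
  tube <- make_straight_tube(20, 1.5, 0.1)$branches$root
  expect_lt(rel_err(oracle_pressure_drop(tube, list(), 1e-6),
                    poiseuille_drop(1e-6, mu0, 0.02, pi * 1.5e-3^2) /
                      133.322387415), 1e-9)
  s <- seq(0, 5, length.out = 2001)
  r <- 1.5 - 0.1 * s   # 1.5 -> 1.0 mm over 5 mm
  tap <- branch("t", s, pi * r^2)
  expect_lt(rel_err(oracle_pressure_drop(tap, list(), 1e-6),
                    taper_viscous_drop(1e-6, mu0, 1.5e-3, 1e-3, 5e-3) /
                      133.322387415), 1e-6)
})
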