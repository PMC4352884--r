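test_that("replicon classification follows pulse/chase block geometry", {
  # active replicon: BrdU core with EdU flanks bordering unlabeled DNA
  m <- molecule("a", 200, rbind(tracks_df(50, 60, "BrdU"),
                                tracks_df(c(42, 60), c(50, 68), "EdU")))
  rec <- classify_replicons(m)
  expect_equal(rec$class, "active")
  expect_equal(rec$left_status, "progressive")
  expect_equal(rec$right_status, "progressive")
  expect_equal(rec$v_left, 8 / 3)
  expect_equal(rec$v_right, 8 / 3)
  expect_equal(rec$origin_kb, 55)

  # exclusively-chase track: newly fired origin
  m2 <- molecule("n", 200, tracks_df(100, 106, "EdU"))
  expect_equal(classify_replicons(m2)$class, "newly_fired")
  expect_true(is.na(classify_replicons(m2)$v_left))

  # merged on both sides: terminated/ambiguous
  m3 <- molecule("t", 200, rbind(
    tracks_df(c(30, 50, 65), c(45, 60, 80), "BrdU"),
    tracks_df(c(45, 60), c(50, 65), "EdU")))
  expect_equal(classify_replicons(m3)$class, "terminated")

  # truncation at the molecule end is not progressive
  m4 <- molecule("tr", 100, rbind(tracks_df(0, 10, "BrdU"),
                                  tracks_df(10, 18, "EdU")))
  rec4 <- classify_replicons(m4)
  expect_equal(rec4$left_status, "truncated")
  expect_equal(rec4$class, "active")               # right fork progressive
  expect_error(classify_replicons(m, chase_min = 0), "chase_min")
})

test_that("velocity estimation uses only progressive forks", {
  m <- molecule("a", 300, rbind(tracks_df(100, 110, "BrdU"),
                                tracks_df(c(91.6, 110), c(100, 118.4), "EdU")))
  ev <- estimate_fork_velocities(classify_replicons(m, chase_min = 3))
  expect_equal(ev$mean_kb_min, 2.8)
  expect_equal(ev$n, 2)

  # a merged side contributes no velocity
  m2 <- molecule("b", 300, rbind(
    tracks_df(c(100, 130), c(110, 140), "BrdU"),
    tracks_df(c(92, 110, 140), c(100, 130, 148), "EdU")))
  ev2 <- estimate_fork_velocities(classify_replicons(m2))
  expect_equal(ev2$n, 2)                            # outer forks only
})

test_that("fork ends equal twice the active replicons without merging", {
  centers <- c(200, 500, 800)
  m <- molecule("k", 1000, rbind(
    tracks_df(centers - 5, centers + 5, "BrdU"),
    tracks_df(c(centers - 13, centers + 5), c(centers - 5, centers + 13),
              "EdU")))
  rec <- classify_replicons(m)
  expect_equal(sum(rec$class == "active"), 3)
  expect_equal(count_fork_ends(m), 2L * 3L)
})

test_that("classification is invariant under orientation flip", {
  m <- molecule("m", 400, rbind(tracks_df(c(50, 200), c(60, 210), "BrdU"),
                                tracks_df(c(42, 60, 210), c(50, 68, 218),
                                          "EdU")))
  a <- classify_replicons(m)
  b <- classify_replicons(flip_molecule(m))
  expect_equal(sort(a$class), sort(b$class))
  expect_equal(sort(c(a$v_left, a$v_right)), sort(c(b$v_left, b$v_right)))
})

test_that("the velocity estimator recovers the generative fork speed", {
  # short clean chase isolates the estimator from tip fusion with
  # chase-fired origins (a +4% bias of the 3-min protocol itself)
  vels <- numeric(0)
  for (s in 5:6) {
    sim <- simulate_genome_sphase(seed = s)
    tr <- sim$trajectory
    ts <- stats::approx(tr$f, tr$time_min, 0.3, ties = "ordered")$y
    mols <- label_pulse_chase(sim, 0, ts - 1, 1, clean_noise())
    frags <- fragment_and_stretch(mols, clean_noise(), seed = 100 + s)
    recs <- do.call(rbind, lapply(frags, classify_replicons, chase_min = 1))
    vels <- c(vels, estimate_fork_velocities(recs)$velocities)
  }
  expect_gt(length(vels), 300)
  expect_lt(abs(mean(vels) - 2.8) / 2.8, 0.05)
})

test_that("the firing-rate estimator recovers the generative ramp", {
  # short clean chase isolates the estimator from the detection floor
  per <- data.frame()
  for (s in 1:10) {
    sim <- simulate_genome_sphase(seed = s)
    tr <- sim$trajectory
    for (ft in c(0.15, 0.25, 0.35, 0.45)) {
      ts <- stats::approx(tr$f, tr$time_min, ft, ties = "ordered")$y
      mols <- label_pulse_chase(sim, 0, ts - 1, 1, clean_noise())
      frags <- fragment_and_stretch(mols, clean_noise(), seed = 1000 + s)
      per <- rbind(per,
                   firing_and_density_profiles(frags, chase_min = 1)$per_molecule)
    }
  }
  bins <- cut(per$f, seq(0.1, 0.5, by = 0.1))
  obs <- tapply(per$rate_per_min_mb, bins, mean, na.rm = TRUE)
  gen <- firing_rate(kinetic_profile(), tapply(per$f, bins, mean))
  ok <- !is.na(obs) & as.integer(table(bins)) >= 30
  expect_gte(sum(ok), 3)
  expect_lt(max(abs(obs[ok] / gen[ok] - 1)), 0.15)
})

test_that("fork velocity is uncorrelated with origin density when constant", {
  sim <- simulate_genome_sphase(seed = 3)
  tr <- sim$trajectory
  ts <- stats::approx(tr$f, tr$time_min, 0.4, ties = "ordered")$y
  mols <- label_pulse_chase(sim, 0, ts - 3, 3)
  frags <- fragment_and_stretch(mols, seed = 4)
  vd <- velocity_vs_density(frags, n_perm = 499, seed = 5)
  expect_lt(abs(vd$correlation), 0.25)
  expect_gt(vd$p, 0.01)
})

test_that("a constructed density-velocity dependence is detected", {
  mols <- lapply(1:8, function(k) {
    centers <- seq(30, 270, length.out = k + 1)[-1]
    molecule(paste0("w", k), 300, rbind(
      tracks_df(centers - 2, centers + 2, "BrdU"),
      tracks_df(c(centers - 2 - k, centers + 2),
                c(centers - 2, centers + 2 + k), "EdU")))
  })
  vd <- velocity_vs_density(mols, n_perm = 199, seed = 1)
  expect_gt(vd$correlation, 0.8)
  expect_lt(vd$p, 0.05)
})

test_that("region timing contrasts annotated regions with the molecule rest", {
  m <- make_mol("m", 1000, c(100, 350), c(200, 400),
                chrom = "chrI", offset_kb = 5000, strand = "+")
  regions <- data.frame(chrom = "chrI",
                        start_kb = c(5100, 5600, 5000),
                        end_kb = c(5200, 5800, 6000),
                        name = c("early", "late", "whole"))
  rt <- region_timing(list(m), regions)
  expect_equal(rt$region_fraction[rt$region == "early"], 1)
  expect_gt(rt$region_fraction[rt$region == "early"],
            rt$rest_fraction[rt$region == "early"])   # above the diagonal
  expect_equal(rt$region_fraction[rt$region == "late"], 0)
  expect_gt(rt$rest_fraction[rt$region == "late"], 0)
  expect_equal(rt$region_fraction[rt$region == "whole"],
               rt$rest_fraction[rt$region == "whole"])
})

test_that("memory overlap reproduces direct arithmetic and identity", {
  e1 <- data.frame(chrom = "chrI", pos_kb = seq(100, 3000, length.out = 30))
  shared <- e1[1:30, ]
  far <- data.frame(chrom = "chrI",
                    pos_kb = seq(3100, 5500, length.out = 205))
  e2 <- rbind(shared, far)
  mo <- memory_overlap(e1, e2, match_kb = 2, n_perm = 49, seed = 1)
  expect_equal(mo$n_second, 235)
  expect_equal(mo$overlap, 30)
  expect_equal(mo$fraction, 30 / 235)

  ident <- memory_overlap(e1, e1, match_kb = 1, n_perm = 49, seed = 2)
  expect_equal(ident$fraction, 1)

  scan <- memory_overlap(e1, e2, match_kb = c(2, 5, 10), n_perm = 49,
                         seed = 3)
  expect_equal(nrow(scan), 3)
  expect_true(all(diff(scan$overlap) >= 0))        # wider window, more hits
})

test_that("total-origin estimate counts merged blocks once and scales", {
  merged <- make_mol("m", 1000, 0, 900)
  expect_equal(total_origins_estimate(list(merged))$per_molecule$blocks, 1)
  starts <- seq(0, 900, by = 100)
  many <- make_mol("k", 1000, starts, starts + 90)
  est <- total_origins_estimate(list(many))
  expect_equal(est$per_molecule$blocks, 10)
  expect_equal(est$estimate, 10 * 13.6)
  low <- make_mol("lo", 1000, 0, 500)
  expect_equal(total_origins_estimate(list(low))$n_molecules, 0L)
})
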