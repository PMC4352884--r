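test_that("origins are called at track midpoints, merging pulse/chase blocks", {
  expect_equal(call_origins(make_mol("m", 100, 10, 14))$origin_kb, 12)
  m <- molecule("pc", 100, rbind(tracks_df(10, 14, "BrdU"),
                                 tracks_df(14, 20, "EdU")))
  expect_equal(call_origins(m)$origin_kb, 15)      # one origin per block
  expect_equal(call_origins(m, channels = "BrdU")$origin_kb, 12)
  expect_equal(nrow(call_origins(molecule("none", 50))), 0)
})

test_that("replication fraction counts labeled DNA once", {
  expect_equal(replication_fraction(make_mol("m", 100, c(10, 60), c(14, 68))), 0.12)
  expect_equal(replication_fraction(make_mol("m", 100, 0, 100)), 1)
  m <- molecule("pc", 100, rbind(tracks_df(10, 20, "BrdU"),
                                 tracks_df(20, 26, "EdU")))
  expect_equal(replication_fraction(m), 0.16)      # abutting, no double count
})

test_that("IOD measurement applies the track and extent filters strictly", {
  m <- make_mol("m", 100, c(10, 30, 58), c(14, 36, 62))
  iods <- measure_iods(list(m))
  expect_equal(iods$iod_kb, c(21, 27))             # midpoints 12, 33, 60
  expect_equal(nrow(iods), nrow(call_origins(m)) - 1)
  expect_true(all(iods$eligible))

  # a 25-kb middle track poisons both adjacent IODs
  m2 <- make_mol("m2", 300, c(10, 40, 80), c(14, 65, 84))
  expect_equal(eligible_iods(measure_iods(list(m2))), numeric(0))

  # a molecule at 60% replicated contributes no eligible IODs
  m3 <- make_mol("m3", 100, c(0, 30, 60, 85), c(15, 45, 75, 100))
  expect_equal(replication_fraction(m3), 0.6)
  expect_false(any(measure_iods(list(m3))$eligible))

  # exactly 20-kb flanking track is excluded (strict <)
  m4 <- make_mol("m4", 200, c(10, 60), c(30, 64))
  expect_false(any(measure_iods(list(m4))$eligible))
})

test_that("extent bins are right-closed with exclusion above 50%", {
  b <- bin_by_extent(c(0.03, 0.05, 0.051, 0.2, 0.21, 0.5, 0.7))
  expect_equal(as.character(b),
               c("0-5%", "0-5%", "5-20%", "5-20%", "20-50%", "20-50%", ">50%"))
})

test_that("moving-average profile integrates labeled DNA per window", {
  # single 20-kb track: peak value 0.1 when fully inside a 200-kb window
  m <- make_mol("m", 1000, 490, 510)
  prof <- moving_average_profile(m)
  expect_equal(max(prof$fraction), 0.1, tolerance = 1e-9)
  expect_equal(prof$fraction[prof$center_kb == 500], 0.1)
  expect_equal(min(prof$fraction), 0)

  # uniformly labeled molecule: constant profile at the overall fraction
  m2 <- make_mol("m2", 600, 0, 600)
  expect_true(all(abs(moving_average_profile(m2)$fraction - 1) < 1e-9))
  expect_error(moving_average_profile(make_mol("s", 100, 10, 20)), "window")

  # coarser windows smooth the profile (variance decreases)
  mols <- generate_two_regime_molecules(seed = 4, n_molecules = 1,
                                        mol_length_kb = 2000,
                                        replication_extent = 0.3)
  p100 <- moving_average_profile(mols[[1]], window_kb = 100)
  p500 <- moving_average_profile(mols[[1]], window_kb = 500)
  expect_lt(stats::sd(p500$fraction), stats::sd(p100$fraction))
})

test_that("fork-end counting ignores molecule-end truncation", {
  expect_equal(count_fork_ends(make_mol("m", 100, 40, 60)), 2L)
  expect_equal(count_fork_ends(make_mol("m", 100, 0, 60)), 1L)
  expect_equal(count_fork_ends(make_mol("m", 100, 0, 100)), 0L)
  m <- molecule("pc", 100, rbind(tracks_df(10, 20, "BrdU"),
                                 tracks_df(20, 30, "EdU")))
  expect_equal(count_fork_ends(m), 2L)             # one merged block
})

test_that("in-silico cutting loses boundary-spanning IODs", {
  m <- make_mol("m", 2000, c(340, 640), c(360, 660))
  pieces <- cut_in_silico(list(m), 500)
  expect_length(pieces, 4)
  expect_equal(vapply(pieces, function(p) p$length_kb, numeric(1)),
               rep(500, 4))
  expect_equal(measure_iods(list(m))$iod_kb, 300)
  expect_equal(nrow(measure_iods(pieces)), 0)      # straddling IOD gone
})

test_that("measurements are invariant under orientation flip", {
  m <- molecule("m", 500, rbind(tracks_df(c(40, 100, 300), c(52, 120, 310)),
                                tracks_df(120, 130, "EdU")))
  fm <- flip_molecule(m)
  expect_equal(replication_fraction(fm), replication_fraction(m))
  expect_equal(count_fork_ends(fm), count_fork_ends(m))
  expect_equal(sort(measure_iods(list(fm))$iod_kb),
               sort(measure_iods(list(m))$iod_kb))
  expect_equal(sort(500 - call_origins(fm)$origin_kb),
               sort(call_origins(m)$origin_kb))
})
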