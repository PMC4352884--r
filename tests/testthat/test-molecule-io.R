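test_that("molecule invariants are enforced", {
  expect_silent(make_mol("ok", 100, c(10, 30), c(14, 36)))
  expect_error(make_mol("bad", 100, 10, 8), "end_kb > start_kb")
  expect_error(make_mol("bad", 100, c(10, 12), c(20, 30)), "overlapping")
  expect_error(molecule("bad", 100, tracks_df(10, 20, "XdU")), "channel")
  expect_error(make_mol("bad", 100, 990, 1050), "within")
  # different channels may abut without overlapping
  m <- molecule("pc", 100, rbind(tracks_df(10, 14, "BrdU"),
                                 tracks_df(14, 20, "EdU")))
  expect_equal(nrow(m$tracks), 2)
})

test_that("write -> read round-trips molecule tables exactly", {
  mols <- list(
    make_mol("m1", 1000, c(10, 500.4), c(20, 520.8)),
    molecule("m2", 800, rbind(tracks_df(100, 110, "BrdU"),
                              tracks_df(110, 118, "EdU"))),
    molecule("empty", 500))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_molecules(mols, path)
  back <- read_molecules(path)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$id, mols[[i]]$id)
    expect_equal(back[[i]]$length_kb, mols[[i]]$length_kb)
    expect_equal(back[[i]]$tracks$start_kb, mols[[i]]$tracks$start_kb)
    expect_equal(back[[i]]$tracks$channel, mols[[i]]$tracks$channel)
  }
})

test_that("a large generated cohort round-trips losslessly", {
  mols <- generate_rdna_array(n_molecules = 400, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_molecules(mols, path)
  back <- read_molecules(path)
  expect_length(back, 400)
  expect_identical(
    do.call(rbind, lapply(back, `[[`, "tracks")),
    do.call(rbind, lapply(mols, `[[`, "tracks")))
})

test_that("empty table and malformed rows are handled with line numbers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("molecule_id\tmol_length_kb\ttrack_start_kb\ttrack_end_kb\tchannel",
             path)
  expect_length(read_molecules(path), 0)

  writeLines(c("molecule_id\tmol_length_kb\ttrack_start_kb\ttrack_end_kb\tchannel",
               "m1\t1000\t10\t20\tBrdU",
               "m1\t1000\t900\t1050\tBrdU"), path)
  expect_error(read_molecules(path), "line\\(s\\) 3")

  writeLines(c("molecule_id\tmol_length_kb\ttrack_start_kb\ttrack_end_kb\tchannel",
               "m1\t1000\t10\t20\tGFP"), path)
  expect_error(read_molecules(path), "unknown channel")

  expect_error(read_molecules(tempfile()), "no such file")
})

probe_library <- function() {
  rbind(
    data.frame(chrom = "chrII", start_kb = 1050, end_kb = 1080,
               probe_id = "a1", pair_id = "A"),
    data.frame(chrom = "chrII", start_kb = 1120, end_kb = 1200,
               probe_id = "a2", pair_id = "A"),
    data.frame(chrom = "chrI", start_kb = 200, end_kb = 260,
               probe_id = "b1", pair_id = "B"),
    data.frame(chrom = "chrI", start_kb = 300, end_kb = 310,
               probe_id = "b2", pair_id = "B"))
}

test_that("probe alignment assigns coordinates in both orientations", {
  m <- make_mol("mol", 300, 10, 14)
  probes <- data.frame(start_kb = c(50, 120), end_kb = c(80, 200))
  res <- align_by_probes(m, probes, probe_library())
  expect_equal(res$status, "matched")
  expect_equal(res$chrom, "chrII")
  expect_equal(res$offset_kb, 1000)
  expect_equal(res$strand, "+")

  # the same physical molecule combed in reverse
  fm <- flip_molecule(m)
  fprobes <- data.frame(start_kb = 300 - probes$end_kb,
                        end_kb = 300 - probes$start_kb)
  res2 <- align_by_probes(fm, fprobes, probe_library())
  expect_equal(res2$status, "matched")
  expect_equal(res2$strand, "-")
  expect_equal(res2$offset_kb, 1000)
  # flipping back restores the original track coordinates
  expect_equal(res2$molecule$tracks$start_kb, m$tracks$start_kb)
})

test_that("probe alignment flags ambiguity and non-matches", {
  lib <- probe_library()
  # a second pair whose signature collides with pair A within tolerance
  lib <- rbind(lib, data.frame(chrom = "chrIII",
                               start_kb = c(10, 82), end_kb = c(41, 164),
                               probe_id = c("c1", "c2"),
                               pair_id = c("C", "C")))
  m <- make_mol("mol", 300, 10, 14)
  probes <- data.frame(start_kb = c(50, 120), end_kb = c(80, 200))
  expect_equal(align_by_probes(m, probes, lib)$status, "ambiguous")
  far <- data.frame(start_kb = c(10, 200), end_kb = c(15, 290))
  expect_equal(align_by_probes(m, far, probe_library())$status, "no_match")
  expect_error(align_by_probes(m, probes[1, , drop = FALSE], lib),
               "two detected probe")
})
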