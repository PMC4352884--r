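test_that("cluster calling chains origins with gaps at most d_max", {
  o <- data.frame(molecule_id = "m", origin_kb = c(0, 30, 60, 90, 120))
  cc <- call_clusters(o)
  expect_equal(nrow(cc$clusters), 1)
  expect_equal(cc$clusters$n_origins, 5)
  expect_equal(cc$clusters$span_kb, 120)
  expect_equal(cc$clusters$mean_iod_kb, 30)

  # four origins never form a cluster
  o4 <- data.frame(molecule_id = "m", origin_kb = c(0, 30, 60, 90))
  expect_equal(nrow(call_clusters(o4)$clusters), 0)

  # a 41-kb gap splits a 10-origin run into two clusters of five
  pos <- c(0, 30, 60, 90, 120, 161, 191, 221, 251, 281)
  cc2 <- call_clusters(data.frame(molecule_id = "m", origin_kb = pos))
  expect_equal(cc2$clusters$n_origins, c(5, 5))

  # a gap of exactly 40 kb chains (inclusive rule)
  pos40 <- c(0, 40, 80, 120, 160)
  expect_equal(nrow(call_clusters(
    data.frame(molecule_id = "m", origin_kb = pos40))$clusters), 1)
})

test_that("cluster calling is deterministic and order-independent", {
  set.seed(1)
  o <- data.frame(molecule_id = sample(c("a", "b"), 60, replace = TRUE),
                  origin_kb = stats::runif(60, 0, 2000))
  cc1 <- call_clusters(o)
  cc2 <- call_clusters(o[sample(nrow(o)), ])
  expect_equal(cc1$clusters, cc2$clusters)
  expect_equal(call_clusters(cc1$origins[, 1:2])$clusters, cc1$clusters)
})

test_that("cluster counts are monotone in min_n and d_max", {
  mols <- generate_two_regime_molecules(seed = 5, n_molecules = 20)
  origins <- planted_truth(mols)[, c("molecule_id", "pos_kb")]
  names(origins)[2] <- "origin_kb"
  count <- function(d, k) nrow(call_clusters(origins,
                                             cluster_params(d, k))$clusters)
  members <- function(d, k) sum(!is.na(call_clusters(
    origins, cluster_params(d, k))$origins$cluster_id))
  for (d in c(20, 40, 60)) {
    counts <- vapply(2:8, function(k) count(d, k), numeric(1))
    expect_true(all(diff(counts) <= 0))            # min_n up, count down
  }
  # raising d_max grows every chain, so clustered-origin membership is
  # monotone (the cluster COUNT is not: two clusters of 5 can merge into 1)
  for (k in c(3, 5, 7)) {
    got <- vapply(c(20, 30, 40, 60), function(d) members(d, k), numeric(1))
    expect_true(all(diff(got) >= 0))
  }
})

test_that("the caller recovers planted clusters from origin positions", {
  counts_ratio <- frac_diff <- numeric(0)
  for (s in 1:20) {
    mols <- generate_two_regime_molecules(seed = s, n_molecules = 15)
    truth <- planted_truth(mols)
    o <- data.frame(molecule_id = truth$molecule_id, origin_kb = truth$pos_kb)
    cc <- call_clusters(o)
    planted <- sum(vapply(split(truth$cluster, truth$molecule_id),
                          function(z) length(unique(z[z > 0])), numeric(1)))
    counts_ratio <- c(counts_ratio, nrow(cc$clusters) / planted)
    frac_diff <- c(frac_diff, mean(!is.na(cc$origins$cluster_id)) -
                     mean(truth$cluster > 0))
  }
  expect_lt(abs(mean(counts_ratio) - 1), 0.2)      # count within 20%
  expect_lt(abs(mean(frac_diff)), 0.10)            # membership within 10 pts
})

test_that("membership survives track rendering at low replication extent", {
  prec <- rec <- numeric(0)
  for (s in 1:20) {
    mols <- generate_two_regime_molecules(replication_extent = c(0.1, 0.2),
                                          seed = s, n_molecules = 10)
    cc <- call_clusters(mols)
    matched <- match_to_truth(cc$origins, planted_truth(mols))
    called_in <- !is.na(matched$cluster_id)
    true_in <- matched$true_cluster > 0
    prec <- c(prec, sum(called_in & true_in) / max(sum(called_in), 1))
    rec <- c(rec, sum(called_in & true_in) / max(sum(true_in), 1))
  }
  expect_gte(mean(prec), 0.9)
  expect_gte(mean(rec), 0.9)
})

test_that("transition-point scan finds the planted cluster size", {
  set.seed(6)
  orig <- do.call(rbind, lapply(1:40, function(i) {
    starts <- sort(stats::runif(3, 100, 1500))
    data.frame(molecule_id = sprintf("m%02d", i),
               origin_kb = as.vector(vapply(starts, function(s)
                 s + cumsum(c(0, stats::rexp(7, 1 / 15))), numeric(8))))
  }))
  scan <- transition_point_scan(orig, analyzed_kb = 40 * 1800)
  expect_lte(abs(scan$elbow - 8), 1)               # clusters of exactly 8
  expect_true(all(diff(scan$curve$clusters_per_genome) <= 1e-9))

  # uniform origins: smoothly decaying curve, weaker two-segment improvement
  set.seed(7)
  unif <- data.frame(molecule_id = rep(sprintf("u%02d", 1:40), each = 60),
                     origin_kb = stats::runif(2400, 0, 1800))
  scan_u <- transition_point_scan(unif, analyzed_kb = 40 * 1800)
  expect_lt(scan_u$improvement, scan$improvement)
})

test_that("cluster statistics summarize planted structure", {
  o <- data.frame(molecule_id = "m", origin_kb = c(100, 120, 140, 160, 180))
  cc <- call_clusters(o)
  mol <- list(make_mol("m", 1000, c(98, 118, 138, 158, 178),
                       c(102, 122, 142, 162, 182)))
  cs <- cluster_statistics(cc, mol)
  expect_equal(cs$within_mean_iod_kb, 20)
  expect_equal(cs$mean_span_kb, 80)
  expect_equal(cs$origins_per_cluster, 5)
  expect_equal(cs$fraction_origins_in_clusters, 1)

  # no clusters: empty fields, zero fraction
  cc0 <- call_clusters(data.frame(molecule_id = "m",
                                  origin_kb = c(100, 300, 500)))
  cs0 <- cluster_statistics(cc0, mol)
  expect_equal(cs0$n_clusters, 0)
  expect_equal(cs0$fraction_origins_in_clusters, 0)
  expect_true(is.na(cs0$within_mean_iod_kb))

  # default-calibrated generator: ~25 clusters/genome and ~12 origins per
  # cluster recovered from planted origin positions (within 20%)
  mols <- generate_two_regime_molecules(seed = 8, n_molecules = 40)
  truth <- planted_truth(mols)
  cc2 <- call_clusters(data.frame(molecule_id = truth$molecule_id,
                                  origin_kb = truth$pos_kb))
  cs2 <- cluster_statistics(cc2, mols)
  expect_lt(abs(cs2$clusters_per_genome - 25) / 25, 0.2)
  expect_lt(abs(cs2$origins_per_cluster - 12) / 12, 0.2)
})

test_that("cluster extension detects adjacency enrichment of new origins", {
  mols <- lapply(1:6, function(i)
    make_mol(paste0("m", i), 2000, seq(500, 580, 20), seq(504, 584, 20)))
  cc <- call_clusters(mols)
  edges <- do.call(rbind, lapply(1:6, function(i)
    data.frame(molecule_id = paste0("m", i), origin_kb = c(460, 620))))
  enriched <- cluster_extension(cc, edges, mols, n_perm = 199, seed = 1)
  expect_gt(enriched$enrichment, 2)
  expect_lt(enriched$p, 0.05)

  set.seed(2)
  unif <- do.call(rbind, lapply(1:6, function(i)
    data.frame(molecule_id = paste0("m", i),
               origin_kb = stats::runif(8, 0, 2000))))
  flat <- cluster_extension(cc, unif, mols, n_perm = 199, seed = 3)
  expect_gt(flat$p, 0.05)

  none <- cluster_extension(cc, edges[0, ], mols, n_perm = 19, seed = 4)
  expect_equal(none$observed, 0L)
  expect_equal(none$n_new, 0L)
})

test_that("positional overlap counts molecules with clusters at a reference", {
  mols <- lapply(1:8, function(i)
    make_mol(paste0("m", i), 1000, seq(300, 380, 20), seq(304, 384, 20),
             chrom = "chrII", offset_kb = 2000, strand = "+"))
  cc <- call_clusters(mols)
  ref <- data.frame(chrom = "chrII", start_kb = 2320, end_kb = 2360,
                    name = "A")
  ov <- positional_overlap(mols, cc, ref, n_perm = 99, seed = 1)
  expect_equal(ov$fraction, 1)                     # identical clusters
  expect_lt(ov$p_perm, 0.05)

  ref_off <- data.frame(chrom = "chrII", start_kb = 2800, end_kb = 2840,
                        name = "B")
  ov2 <- positional_overlap(mols, cc, ref_off, n_perm = 99, seed = 2)
  expect_equal(ov2$fraction, 0)
})
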