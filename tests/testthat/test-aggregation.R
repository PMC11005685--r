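chain_state <- function(coms, box = 100) {
  # single-bead molecules at given centres
  n <- nrow(coms)
  beads <- data.frame(
    bead_id = seq_len(n), molecule_id = seq_len(n), group = "CTD",
    residue_code = "CHOL", charge = 0, lj_epsilon = 1.5, lj_sigma = 6,
    radius = 3, mass = 40, stringsAsFactors = FALSE
  )
  system_state(beads, coms, box)
}

test_that("contact clustering is transitive along chains of contacts", {
  # A-B and B-C in contact, A-C not: one cluster of three
  st <- chain_state(rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)))
  cl <- cluster_molecules(st, contact_cutoff = 4.5)
  expect_equal(unname(cl), c(1L, 1L, 1L))
  # no contacts: all singletons
  st2 <- chain_state(rbind(c(0, 0, 0), c(30, 0, 0), c(0, 30, 0)))
  expect_equal(unname(cluster_molecules(st2, 4.5)), 1:3)
})

test_that("cluster partitions equal BFS over the brute-force contact matrix", {
  for (seed in 1:8) {
    st <- make_random_state(8, 3, box = 30, seed = seed + 50)
    got <- cluster_molecules(st, 4.5)
    want <- oracle_clusters(st, 4.5)
    # same partition: equal co-membership for every molecule pair
    expect_identical(outer(got, got, "=="), outer(want, want, "=="))
  }
  st16 <- make_random_state(16, 4, box = 42, seed = 77)
  got <- cluster_molecules(st16, 4.5)
  want <- oracle_clusters(st16, 4.5)
  expect_identical(outer(got, got, "=="), outer(want, want, "=="))
})

test_that("cluster labels are canonical by lowest molecule id", {
  st <- chain_state(rbind(c(0, 0, 0), c(40, 0, 0), c(2, 0, 0), c(41, 0, 0)))
  cl <- cluster_molecules(st, 4.5)
  # molecule 1's cluster must be labelled 1, molecule 2's labelled 2
  expect_equal(unname(cl), c(1L, 2L, 1L, 2L))
})

test_that("partitions are invariant to relabeling and rigid translation", {
  st <- make_random_state(7, 3, box = 32, seed = 61)
  base <- cluster_molecules(st, 4.5)
  tr <- st; tr$coords <- tr$coords + c(5.1)
  expect_identical(cluster_molecules(tr, 4.5), base)
  perm <- sample(7)
  rl <- st; rl$beads$molecule_id <- perm[rl$beads$molecule_id]
  got <- cluster_molecules(rl, 4.5)
  # co-membership must be preserved under the permutation
  expect_identical(unname(outer(got[perm], got[perm], "==")),
                   unname(outer(base, base, "==")))
})

test_that("largest-cluster fraction is monotone in the contact cutoff", {
  for (seed in 1:5) {
    st <- make_random_state(8, 3, box = 30, seed = seed + 80)
    fracs <- sapply(c(2, 4, 6, 9, 14), function(cut) {
      cl <- cluster_molecules(st, cut)
      max(tabulate(cl)) / length(cl)
    })
    expect_true(all(diff(fracs) >= 0))
  }
})

test_that("timelines report coincident and dispersed extremes correctly", {
  blob <- chain_state(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)))
  blob2 <- blob; blob2$time <- 10
  tl <- build_timeline(list(blob, blob2))
  expect_equal(tl$largest_cluster_fraction, c(1, 1))
  expect_equal(tl$n_clusters, c(1, 1))
  far <- chain_state(rbind(c(0, 0, 0), c(30, 0, 0), c(0, 30, 0),
                           c(30, 30, 0)))
  far2 <- far; far2$time <- 10
  tl2 <- build_timeline(list(far, far2))
  expect_equal(tl2$largest_cluster_fraction, c(0.25, 0.25))
  expect_error(build_timeline(list(blob)), "2 frames")
})

test_that("shape anisotropy separates linear from isotropic clusters", {
  line <- cbind(seq(0, 10, length.out = 8), 0, 0)
  expect_equal(shape_anisotropy(line), 1.0, tolerance = 1e-12)
  octa <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  expect_equal(shape_anisotropy(octa), 0, tolerance = 1e-12)
  expect_equal(shape_anisotropy(rbind(c(1, 1, 1))), 0)
})

test_that("kinetic classes follow the window rules", {
  mk <- function(frac, k2) {
    data.frame(time = seq_along(frac), largest_cluster_fraction = frac,
               n_clusters = 1, kappa_sq = k2)
  }
  n <- 40
  expect_equal(classify_kinetics(mk(rep(1, n), rep(0.05, n))), "fast_stable")
  expect_equal(classify_kinetics(mk(rep(1 / 16, n), rep(0.5, n))),
               "non_aggregator")
  # early assembly that decays by the end: transient narrative
  decay <- seq(0.9, 0.3, length.out = n)
  expect_equal(classify_kinetics(mk(decay, rep(0.1, n))), "non_aggregator")
  decay2 <- seq(0.9, 0.35, length.out = n)
  expect_equal(classify_kinetics(mk(decay2, rep(0.1, n))), "transient")
  # assembled but never sphere-like: transient
  expect_equal(classify_kinetics(mk(rep(1, n), rep(0.8, n))), "transient")
})

test_that("rank-sum screening orders a dominating system first", {
  rep0 <- data.frame(
    name = c("A", "B", "C"),
    mean_sasa = c(100, 200, 300), mean_rg = c(10, 20, 30),
    mean_vdw = c(-500, -100, -50), mean_ele = c(-100, 10, 500),
    mean_sat_max = c(8, 3, 1), net_charge = c(2, 3, 8)
  )
  out <- rank_candidates(rep0, k = 2)
  expect_s3_class(out, "screening_report")
  expect_equal(out$name[1], "A")
  expect_equal(out$rank, 1:3)
  expect_true(out$selected[1])
  expect_equal(out$excluded, c(FALSE, FALSE, TRUE))
  expect_equal(out$exclusion_reason[3], "excess cationic charge")
  expect_false(out$selected[3])
})

test_that("ties break lexicographically and exclusion does not unrank", {
  rep0 <- data.frame(
    name = c("B", "A"),
    mean_sasa = 1, mean_rg = 1, mean_vdw = -1, mean_ele = -1,
    mean_sat_max = 2, net_charge = c(8, 8)
  )
  out <- rank_candidates(rep0, k = 5)
  expect_equal(out$name, c("A", "B"))
  expect_true(all(out$excluded))
  expect_false(any(out$selected))
  expect_equal(sort(out$rank), 1:2)
})

test_that("ranks are scale-free in any single metric", {
  set.seed(5)
  rep0 <- data.frame(
    name = sprintf("S%02d", 1:8),
    mean_sasa = runif(8, 100, 300), mean_rg = runif(8, 5, 30),
    mean_vdw = -runif(8, 10, 700), mean_ele = runif(8, -300, 300),
    mean_sat_max = runif(8, 0, 8), net_charge = sample(0:8, 8, TRUE)
  )
  base <- rank_candidates(rep0)
  for (m in c("mean_sasa", "mean_rg", "mean_vdw", "mean_ele",
              "mean_sat_max")) {
    sc <- rep0
    sc[[m]] <- sc[[m]] * 3.7
    expect_equal(rank_candidates(sc)$name, base$name)
  }
})

test_that("a planted library is recovered against an independent recompute", {
  set.seed(9)
  nsys <- 10
  # planted dominant aggregator "P01"; three high-charge systems
  rep0 <- data.frame(
    name = sprintf("P%02d", 1:nsys),
    mean_sasa = c(100, runif(nsys - 1, 150, 400)),
    mean_rg = c(8, runif(nsys - 1, 10, 40)),
    mean_vdw = c(-900, runif(nsys - 1, -500, -10)),
    mean_ele = c(-200, runif(nsys - 1, -100, 800)),
    mean_sat_max = c(9, runif(nsys - 1, 0, 6)),
    net_charge = c(2, 3, 3, 4, 4, 5, 5, 8, 7, 9)
  )
  out <- rank_candidates(rep0)
  expect_equal(out$name[1], "P01")
  expect_true(out$selected[out$name == "P01"])
  expect_equal(sort(out$name[out$excluded]), c("P08", "P09", "P10"))
  # independent recompute of the composite from first principles
  comp <- rank(rep0$mean_sasa) + rank(rep0$mean_rg) + rank(rep0$mean_vdw) +
    rank(rep0$mean_ele) + rank(-rep0$mean_sat_max)
  want <- rep0$name[order(comp, rep0$name)]
  expect_equal(out$name, want)
  # inconsistent metric sets are rejected
  bad <- rep0; bad$mean_rg[2] <- NA
  expect_error(rank_candidates(bad), "inconsistent|NA")
})
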