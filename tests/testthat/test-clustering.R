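# RMSD matrices, hierarchical clustering, cuts, medoids, timelines.

test_that("rmsd_matrix vanishes for duplicates and rigid motions", {
  # all states in one basin with zero noise: identical coordinates
  one_basin <- make_two_basin_ensemble(3, noise_sd = 0, seed = 1,
                                       switch_script = c(1, 1, 1))
  m0 <- rmsd_matrix(one_basin$ensemble, "CA")
  expect_equal(unname(m0), matrix(0, 3, 3), tolerance = 1e-9)

  # a rigidly moved state stays at zero distance
  ens <- one_basin$ensemble
  r <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  a <- ens$states[[2]]$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(r)
  ens$states[[2]]$atoms$x <- xyz[, 1] + 5
  ens$states[[2]]$atoms$y <- xyz[, 2] - 3
  ens$states[[2]]$atoms$z <- xyz[, 3]
  m1 <- rmsd_matrix(ens, "CA")
  expect_lt(max(m1), 1e-9)
})

test_that("rmsd_matrix equals entrywise independent kabsch calls", {
  tb <- make_two_basin_ensemble(5, seed = 6)$ensemble
  m <- rmsd_matrix(tb, "CA")
  expect_true(isSymmetric(unname(m)))
  expect_equal(unname(diag(m)), rep(0, 5))
  coords <- lapply(tb$states, function(s)
    coordinate_matrix(s, "CA")$coords)
  for (a in 1:4) for (b in (a + 1):5) {
    expect_equal(m[a, b], kabsch(coords[[a]], coords[[b]])$rmsd,
                 tolerance = 1e-12)
  }
})

test_that("rmsd_matrix entries are invariant to rigid motion of one state", {
  tb <- make_two_basin_ensemble(4, seed = 7)$ensemble
  m <- rmsd_matrix(tb, "CA")
  r <- rbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0))
  a <- tb$states[[3]]$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(r)
  tb$states[[3]]$atoms$x <- xyz[, 1] + 11
  tb$states[[3]]$atoms$y <- xyz[, 2]
  tb$states[[3]]$atoms$z <- xyz[, 3] - 4
  m2 <- rmsd_matrix(tb, "CA")
  expect_equal(m, m2, tolerance = 1e-6)
})

test_that("reference-based mode agrees with pairwise mode on rigid ensembles", {
  one <- make_two_basin_ensemble(3, noise_sd = 0, seed = 2,
                                 switch_script = c(1, 1, 1))$ensemble
  mp <- rmsd_matrix(one, "CA")
  mr <- rmsd_matrix(one, "CA", reference = 0)
  expect_equal(mp, mr, tolerance = 1e-9)
  # reference mode measures in a common frame: never below pairwise-optimal
  tb <- make_two_basin_ensemble(4, seed = 3)$ensemble
  mp2 <- rmsd_matrix(tb, "CA")
  mr2 <- rmsd_matrix(tb, "CA", reference = 0)
  expect_true(all(mr2 - mp2 >= -1e-9))
})

test_that("rmsd_matrix validates its inputs", {
  tb <- make_two_basin_ensemble(2, seed = 1)$ensemble
  expect_error(rmsd_matrix(rinens:::new_ensemble(tb$states[1])),
               "2 states")
  expect_error(rmsd_matrix(tb, "XX"), "selection")
})

test_that("two states merge at exactly their RMSD", {
  tb <- make_two_basin_ensemble(2, seed = 5)$ensemble
  m <- rmsd_matrix(tb, "CA")
  for (linkage in c("average", "complete", "single")) {
    d <- hierarchical_cluster(m, linkage)
    expect_equal(d$hclust$height, m[1, 2])
  }
})

test_that("linkage heights are monotone and match a naive implementation", {
  set.seed(13)
  for (linkage in c("average", "complete", "single")) {
    # random symmetric distance matrix
    n <- 8
    p <- matrix(runif(n * 3, 0, 10), ncol = 3)
    m <- as.matrix(dist(p))
    d <- hierarchical_cluster(m, linkage)
    expect_true(all(diff(d$hclust$height) >= -1e-12))
    naive <- naive_agglomerative(m, linkage)
    expect_equal(sort(d$hclust$height), sort(naive$heights),
                 tolerance = 1e-9)
    # flat partitions agree at several cutoffs
    for (cutoff in quantile(naive$heights, c(0.25, 0.5, 0.9))) {
      ours <- cut_dendrogram(d, cutoff)$cluster
      theirs <- naive_agglomerative(m, linkage, cutoff)$partition
      expect_true(same_partition(ours, theirs))
    }
  }
})

test_that("two tight groups split at the inter-group distance", {
  tb <- make_two_basin_ensemble(8, basin_shift = 6, noise_sd = 0.1,
                                seed = 17)
  m <- rmsd_matrix(tb$ensemble, "CA")
  d <- hierarchical_cluster(m, "average")
  lab <- tb$truth$labels
  inter <- mean(m[lab == 1, lab == 2])
  expect_equal(max(d$hclust$height), inter, tolerance = 0.05)
  cl <- cut_dendrogram(d, 3)
  expect_equal(cl$n_clusters, 2)
  expect_true(same_partition(cl$cluster, lab))
})

test_that("hierarchical_cluster rejects malformed matrices", {
  m <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(hierarchical_cluster(m), "symmetric")
  m2 <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(hierarchical_cluster(m2), "diagonal")
})

test_that("dendrogram cut semantics are strict at the cutoff", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 1
  m[1, 3] <- m[3, 1] <- 5
  m[2, 3] <- m[3, 2] <- 5
  d <- hierarchical_cluster(m, "complete")
  expect_equal(cut_dendrogram(d, 10)$n_clusters, 1)   # above root
  expect_equal(cut_dendrogram(d, 0.5)$n_clusters, 3)  # below all merges
  # cutoff equal to a merge height splits that merge
  expect_equal(cut_dendrogram(d, 1)$n_clusters, 3)
  expect_equal(cut_dendrogram(d, 1.001)$n_clusters, 2)
  expect_error(cut_dendrogram(d, 0), "cutoff")
})

test_that("cluster count is non-increasing in the cutoff", {
  tb <- make_two_basin_ensemble(10, seed = 19)$ensemble
  d <- hierarchical_cluster(rmsd_matrix(tb, "CA"))
  sweep_counts <- vapply(seq(0.01, 8, length.out = 40), function(h)
    cut_dendrogram(d, h)$n_clusters, integer(1))
  expect_true(all(diff(sweep_counts) <= 0))
  expect_equal(sweep_counts[1], 10L)
  expect_equal(sweep_counts[40], 1L)
})

test_that("medoids minimize summed intra-cluster RMSD", {
  # 3 states on a path: the middle one is the medoid
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 1
  m[2, 3] <- m[3, 2] <- 1
  m[1, 3] <- m[3, 1] <- 2
  d <- hierarchical_cluster(m, "single")
  cl <- cut_dendrogram(d, 100)
  reps <- representatives(cl, m)
  expect_equal(nrow(reps), 1)
  expect_equal(reps$representative, 1L)   # middle state, 0-based
  expect_equal(reps$size, 3)

  # brute-force oracle on a random instance
  set.seed(23)
  p <- matrix(runif(21, 0, 5), ncol = 3)
  m2 <- as.matrix(dist(p))
  d2 <- hierarchical_cluster(m2)
  cl2 <- cut_dendrogram(d2, median(d2$hclust$height))
  reps2 <- representatives(cl2, m2)
  for (k in seq_len(nrow(reps2))) {
    members <- which(cl2$cluster == reps2$cluster[k])
    sums <- vapply(members, function(s)
      sum(m2[s, members]), numeric(1))
    expect_equal(reps2$representative[k],
                 members[which.min(sums)] - 1L)
  }
  # singleton clusters represent themselves
  single <- cut_dendrogram(d2, 1e-9)
  reps3 <- representatives(single, m2)
  expect_equal(reps3$representative, seq_len(nrow(m2)) - 1L)
  expect_equal(reps3$mean_intra_rmsd, rep(0, nrow(m2)))
})

test_that("cluster timeline counts transitions in time order", {
  fake <- function(cl) structure(list(cluster = cl, cutoff_used = 1,
                                      n_clusters = max(cl)),
                                 class = "rin_clusters")
  expect_equal(cluster_timeline(fake(c(1, 1, 1)))$transitions, 0L)
  expect_equal(cluster_timeline(fake(c(1, 2, 1, 2)))$transitions, 3L)
  tl <- cluster_timeline(fake(c(1, 1, 2)))$timeline
  expect_equal(tl$state, 0:2)

  # scripted basin switches reproduce the scripted transition count
  script <- c(1, 1, 2, 2, 1, 1)
  tb <- make_two_basin_ensemble(6, switch_script = script, seed = 29)
  d <- hierarchical_cluster(rmsd_matrix(tb$ensemble, "CA"))
  cl <- cut_dendrogram(d, 3)
  expect_equal(cluster_timeline(cl)$transitions,
               sum(diff(script) != 0))
})

test_that("Newick export round-trips through ape", {
  tb <- make_two_basin_ensemble(7, seed = 31)$ensemble
  d <- hierarchical_cluster(rmsd_matrix(tb, "CA"))
  txt <- dendrogram_newick(d)
  phy <- ape::read.tree(text = txt)
  expect_equal(length(phy$tip.label), 7)
  expect_setequal(phy$tip.label, paste0("S", 0:6))
  # tree distance between two leaves equals their merge height
  two <- make_two_basin_ensemble(2, seed = 32)$ensemble
  m2 <- rmsd_matrix(two, "CA")
  d2 <- hierarchical_cluster(m2)
  phy2 <- ape::read.tree(text = dendrogram_newick(d2))
  expect_equal(sum(phy2$edge.length), m2[1, 2], tolerance = 1e-9)
})
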