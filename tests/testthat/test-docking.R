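test_that("nonbonded energy reproduces LJ landmarks and Coulomb", {
  z <- function(r) matrix(c(0, 0, 0, r, 0, 0), ncol = 3, byrow = TRUE)
  one <- function(r, q = c(0, 0), sig = c(3.4, 3.4), eps = c(0.3, 0.3)) {
    nonbonded_energy(z(r)[1, , drop = FALSE], q[1], sig[1], eps[1],
                     z(r)[2, , drop = FALSE], q[2], sig[2], eps[2],
                     cutoff = 100)
  }
  expect_equal(one(3.4), 0, tolerance = 1e-12)
  expect_equal(one(2^(1 / 6) * 3.4), -0.3, tolerance = 1e-12)
  # pure Coulomb at 5 A (epsilon 0)
  e <- nonbonded_energy(matrix(0, 1, 3), 0.5, 0, 0,
                        matrix(c(5, 0, 0), 1, 3), -0.4, 0, 0, cutoff = 10)
  expect_equal(e, 1389.35458 * 0.5 * -0.4 / 5, tolerance = 1e-12)
})

test_that("nonbonded energy equals the O(N^2) oracle and is symmetric", {
  set.seed(11)
  na <- 10; nb <- 8
  xa <- matrix(rnorm(na * 3, sd = 4), ncol = 3)
  xb <- matrix(rnorm(nb * 3, sd = 4), ncol = 3) + 5
  qa <- runif(na, -0.5, 0.5); qb <- runif(nb, -0.5, 0.5)
  sa <- runif(na, 3, 3.6); sb <- runif(nb, 3, 3.6)
  ea <- runif(na, 0.1, 0.6); eb <- runif(nb, 0.1, 0.6)
  got <- nonbonded_energy(xa, qa, sa, ea, xb, qb, sb, eb, cutoff = 1e6)
  want <- oracle_energy(xa, qa, sa, ea, xb, qb, sb, eb)
  expect_equal(got, want, tolerance = 1e-10)
  expect_equal(nonbonded_energy(xb, qb, sb, eb, xa, qa, sa, ea, cutoff = 1e6),
               got, tolerance = 1e-10)
  # with a finite cutoff the oracle restricted to <= cutoff pairs agrees
  got_c <- nonbonded_energy(xa, qa, sa, ea, xb, qb, sb, eb, cutoff = 6)
  want_c <- oracle_energy(xa, qa, sa, ea, xb, qb, sb, eb, cutoff = 6)
  expect_equal(got_c, want_c, tolerance = 1e-10)
})

test_that("unassigned parameters raise an error", {
  expect_error(
    nonbonded_energy(matrix(0, 1, 3), NA, 3.4, 0.3,
                     matrix(1, 1, 3), 0, 3.4, 0.3),
    "assign_nonbonded")
})

channel <- make_toy_complex("channel", seed = 1)
spec2 <- oligomer_spec(2, "Ace", "COO-", 1)
olig2 <- build_oligomer(spec2)
olig2$structure <- assign_nonbonded(olig2$structure, channel$table)

test_that("seed placement is deterministic, sorted and clash-free", {
  cfg <- dock_config(n_samples = 150, keep_k = 10, n_dihedral_samples = 2)
  p1 <- seed_placement(channel$structure, olig2, cfg, seed = 5)
  p2 <- seed_placement(channel$structure, olig2, cfg, seed = 5)
  expect_identical(lapply(p1, `[[`, "xyz"), lapply(p2, `[[`, "xyz"))
  s <- vapply(p1, `[[`, 0, "score")
  expect_true(all(diff(s) >= 0))
  e_heavy <- coords(channel$structure,
                    which(channel$structure$atoms$element != "H"))
  hv <- intersect(heavy_atoms(olig2), p1[[1]]$placed)
  for (p in p1) {
    expect_gte(min(cross_dist(p$xyz[hv, , drop = FALSE], e_heavy)), 2.0)
  }
})

test_that("a solid wall rejects every placement with a helpful error", {
  wall <- make_toy_complex("wall", seed = 1)
  olw <- build_oligomer(spec2)
  olw$structure <- assign_nonbonded(olw$structure, wall$table)
  cfg <- dock_config(n_samples = 200, keep_k = 10)
  expect_error(seed_placement(wall$structure, olw, cfg, seed = 1),
               "seed_radius")
  expect_error(dock_oligomer(wall$structure, spec2, wall$table, cfg, seed = 1),
               "200 seed placements clash")
})

test_that("extension keeps global top-k sorted and placed-atom clash rules", {
  cfg <- dock_config(n_samples = 150, keep_k = 6, n_dihedral_samples = 2,
                     jitter = 0)
  seeds <- seed_placement(channel$structure, olig2, cfg, seed = 2)
  ext <- extend_increment(channel$structure, olig2, seeds, cfg, seed = 2)
  s <- vapply(ext, `[[`, 0, "score")
  expect_true(all(diff(s) >= 0))
  expect_lte(length(ext), cfg$keep_k)
  expect_true(all(vapply(ext, `[[`, 0L, "increment") == 2L))
  expect_error(extend_increment(channel$structure, olig2, ext, cfg, seed = 2),
               "complete")
})

test_that("docking equals exhaustive enumeration of the same samples", {
  cfg <- dock_config(n_samples = 80, keep_k = 4, n_dihedral_samples = 3,
                     jitter = 0)
  res <- dock_oligomer(channel$structure, spec2, channel$table, cfg, seed = 9)

  # oracle: re-enumerate every (kept seed) x (3^6 dihedral grid) completion
  seeds <- seed_placement(channel$structure, olig2, cfg, seed = 9)
  rows <- which(olig2$rotatable$unit == 2)
  grid <- as.matrix(expand.grid(rep(list(c(180, 60, -60)), length(rows)),
                                KEEP.OUT.ATTRS = FALSE))
  eidx <- group_idx(channel$structure, "enzyme")
  eat <- channel$structure$atoms[eidx, ]
  e_xyz <- as.matrix(eat[, c("x", "y", "z")])
  e_heavy <- e_xyz[eat$element != "H", , drop = FALSE]
  sat <- olig2$structure$atoms
  placed <- which(olig2$unit_of %in% c(0L, 1L, 2L, 3L))
  hv_pl <- intersect(which(sat$element != "H"), placed)
  best <- Inf
  for (p in seeds) {
    for (g in seq_len(nrow(grid))) {
      dh <- p$dihedrals
      dh[rows] <- grid[g, ]
      cand <- build_oligomer(spec2, dihedrals = dh)
      m <- coords(cand$structure)
      xyz <- sweep(sweep(m, 2, p$ref) %*% t(p$rot), 2, p$trans, "+")
      if (has_internal_clash(cand, 2.0, xyz = xyz, idx = placed)) next
      if (min(cross_dist(xyz[hv_pl, , drop = FALSE], e_heavy)) < 2.0) next
      sc <- oracle_energy(e_xyz, eat$charge, eat$sigma, eat$epsilon,
                          xyz, sat$charge, sat$sigma, sat$epsilon,
                          cutoff = cfg$cutoff)
      if (sc < best) best <- sc
    }
  }
  expect_equal(res$best_score, best, tolerance = 1e-9)
})

test_that("full docking is bit-identical under a fixed seed", {
  cfg <- dock_config(n_samples = 120, keep_k = 5, n_dihedral_samples = 2)
  r1 <- dock_oligomer(channel$structure, spec2, channel$table, cfg, seed = 4)
  r2 <- dock_oligomer(channel$structure, spec2, channel$table, cfg, seed = 4)
  expect_identical(r1$clusters, r2$clusters)
  expect_identical(lapply(r1$poses, `[[`, "xyz"),
                   lapply(r2$poses, `[[`, "xyz"))
  expect_identical(r1$binding_energy_estimate, r2$binding_energy_estimate)
})

test_that("the channel pocket yields a negative best score", {
  cfg <- dock_config(n_samples = 250, keep_k = 12, n_dihedral_samples = 2)
  res <- dock_oligomer(channel$structure, spec2, channel$table, cfg, seed = 1)
  expect_lt(res$best_score, 0)
  expect_equal(sum(res$clusters$population), length(res$poses))
  expect_lte(res$binding_energy_estimate,
             max(vapply(res$poses, `[[`, 0, "score")))
  expect_identical(generics::tidy(res), res$clusters)
  g <- generics::glance(res)
  expect_equal(g$best_score, res$best_score)
  expect_equal(g$n_clusters, nrow(res$clusters))
})

test_that("clustering matches hand-built bundles and tie-breaks by score", {
  cfg <- dock_config(n_samples = 100, keep_k = 2, n_dihedral_samples = 3,
                     jitter = 0)
  seeds <- seed_placement(channel$structure, olig2, cfg, seed = 3)
  ext <- extend_increment(channel$structure, olig2, seeds, cfg, seed = 3)
  p <- ext[[1]]
  # identical poses collapse to one cluster of population n
  res1 <- cluster_and_rank(list(p, p, p), olig2, rmsd_cutoff = 2.0)
  expect_equal(nrow(res1$clusters), 1)
  expect_equal(res1$clusters$population, 3L)
  expect_identical(res1$binding_energy_estimate, p$score)

  # two separated bundles of equal population: lower mean score ranks first
  q <- p
  q$xyz <- p$xyz + 50  # far away: its own cluster
  q$score <- p$score + 10
  res2 <- cluster_and_rank(list(p, p, q, q), olig2, rmsd_cutoff = 2.0)
  expect_equal(nrow(res2$clusters), 2)
  expect_equal(res2$clusters$population, c(2L, 2L))
  expect_equal(res2$clusters$mean_score[1], p$score, tolerance = 1e-12)
  expect_identical(res2$binding_energy_estimate, p$score)

  # cluster assignment equals all-pairs single-link on separated bundles
  poses <- list(p, p, q, q, q)
  res3 <- cluster_and_rank(poses, olig2, rmsd_cutoff = 2.0)
  hv <- heavy_atoms(olig2)
  mats <- lapply(poses, function(z) z$xyz[hv, , drop = FALSE])
  n <- length(poses)
  lab <- seq_len(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (sqrt(mean(rowSums((mats[[i]] - mats[[j]])^2))) <= 2.0) {
      lab[lab == lab[j]] <- lab[i]
    }
  }
  expect_equal(length(unique(lab)), nrow(res3$clusters))
  expect_error(cluster_and_rank(list(), olig2), "empty")
})

test_that("a 1-unit dock reduces to seeding plus clustering", {
  sp1 <- oligomer_spec(1, "Ace", "COO-", 1)
  ol1 <- build_oligomer(sp1)
  ol1$structure <- assign_nonbonded(ol1$structure, channel$table)
  cfg <- dock_config(n_samples = 120, keep_k = 8)
  res <- dock_oligomer(channel$structure, sp1, channel$table, cfg, seed = 6)
  seeds <- seed_placement(channel$structure, ol1, cfg, seed = 6)
  ref <- cluster_and_rank(seeds, ol1, cfg$rmsd_cutoff)
  expect_equal(res$binding_energy_estimate, ref$binding_energy_estimate,
               tolerance = 1e-12)
  expect_equal(res$clusters, ref$clusters)
})

test_that("both orientations dock independently and deterministically", {
  cfg <- dock_config(n_samples = 120, keep_k = 5, n_dihedral_samples = 2)
  runs <- lapply(enumerate_orientations(spec2), function(sp)
    dock_oligomer(channel$structure, sp, channel$table, cfg, seed = 7))
  expect_equal(vapply(runs, `[[`, 0L, "orientation"), 1:2)
  expect_equal(length(unique(vapply(runs, `[[`, "", "label"))), 2)
  expect_false(identical(runs[[1]]$binding_energy_estimate,
                         runs[[2]]$binding_energy_estimate))
})
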