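random_traj <- function(n_frames = 8, seed = 1) {
  set.seed(seed)
  # 6 enzyme atoms in 3 residues + 2 substrate atoms
  xyz <- matrix(rnorm(24), ncol = 3)
  st <- tiny_structure(xyz, resno = c(1, 1, 2, 2, 3, 3, 9, 9),
                       resid = c(rep("ENZ", 6), "SUB", "SUB"),
                       groups = list(enzyme = 1:6, substrate = 7:8))
  frames <- lapply(seq_len(n_frames), function(k)
    matrix(rnorm(24, sd = 2), ncol = 3))
  pa_trajectory(st, frames)
}

test_that("contact frequencies agree frame-exactly with the O(N^2) oracle", {
  tr <- random_traj(10, seed = 3)
  got <- contact_frequencies(tr, cutoff = 2.5)
  want <- oracle_contacts(tr, cutoff = 2.5)
  expect_equal(got$resno, want$resno)
  expect_equal(got$f, want$f, tolerance = 1e-12)
  # larger cutoff: frequencies can only grow (monotonicity)
  got4 <- contact_frequencies(tr, cutoff = 4.0)
  expect_true(all(got4$f >= got$f))
})

test_that("the contact cutoff is inclusive", {
  st <- tiny_structure(matrix(c(0, 0, 0, 2.5, 0, 0), ncol = 3, byrow = TRUE),
                       resno = c(1, 9), resid = c("ENZ", "SUB"),
                       groups = list(enzyme = 1L, substrate = 2L))
  tr <- pa_trajectory(st, list(coords(st)))
  expect_equal(contact_frequencies(tr, cutoff = 2.5)$f, 100)
  st2 <- set_coords(st, matrix(c(0, 0, 0, 2.5001, 0, 0), ncol = 3,
                               byrow = TRUE))
  tr2 <- pa_trajectory(st2, list(coords(st2)))
  expect_equal(contact_frequencies(tr2, cutoff = 2.5)$f, 0)
})

test_that("replica aggregation uses mean +/- SEM and guards the cutoff", {
  trs <- lapply(1:3, function(s) random_traj(6, seed = s))
  profs <- lapply(trs, contact_frequencies)
  agg <- aggregate_contacts(profs)
  f1 <- vapply(profs, function(p) p$f[p$resno == 1], 0)
  expect_equal(agg$mean_f[agg$resno == 1], mean(f1), tolerance = 1e-12)
  expect_equal(agg$sem_f[agg$resno == 1], sd(f1) / sqrt(3), tolerance = 1e-12)
  p2 <- contact_frequencies(trs[[2]], cutoff = 3.0)
  expect_error(aggregate_contacts(list(profs[[1]], p2)), "cutoff")
})

test_that("hotspot selection is inclusive, sorted, and honours exclusions", {
  trajs <- make_trajectory(planted_truth(contact_f = c(`10` = 80, `20` = 50,
                                                       `30` = 20),
                                         hbond_occupancy = 40,
                                         donor_resno = 99L),
                           n_frames = 400, n_replicas = 2, seed = 2)
  profs <- lapply(trajs, contact_frequencies)
  hs <- select_hotspots(profs, threshold = 50)
  expect_true(all(hs$mean_f >= 50))
  expect_equal(hs$mean_f, sort(hs$mean_f, decreasing = TRUE))
  expect_true(10 %in% hs$resno)
  hs2 <- select_hotspots(profs, threshold = 50, exclude = 10)
  expect_false(10 %in% hs2$resno)
})

test_that("contact deltas combine uncertainties in quadrature", {
  trs_a <- lapply(1:3, function(s) random_traj(6, seed = s))
  trs_b <- lapply(4:6, function(s) random_traj(6, seed = s))
  a <- aggregate_contacts(lapply(trs_a, contact_frequencies))
  b <- aggregate_contacts(lapply(trs_b, contact_frequencies))
  d <- contact_delta(a, b)
  i <- 1
  expect_equal(d$delta_f[i], a$mean_f[i] - b$mean_f[i], tolerance = 1e-12)
  expect_equal(d$uncertainty[i], sqrt(a$sem_f[i]^2 + b$sem_f[i]^2),
               tolerance = 1e-12)
  b2 <- aggregate_contacts(lapply(trs_b, contact_frequencies, cutoff = 3))
  expect_error(contact_delta(a, b2), "cutoff")
})

hbond_fixture <- function(d, angle_deg) {
  # exact construction: H at the origin, N 1 A away, acceptor placed so the
  # N-H-A angle is angle_deg and the N-A distance is d (law of cosines)
  ang <- pi * angle_deg / 180
  r2 <- cos(ang) + sqrt(d^2 - sin(ang)^2)
  acc <- r2 * c(cos(ang), sin(ang), 0)
  xyz <- rbind(c(1, 0, 0), c(0, 0, 0), acc)
  st <- tiny_structure(xyz, element = c("N", "H", "O"),
                       charge = c(0.4, 0, -0.5),
                       resno = c(1, 1, 9), resid = c("DON", "DON", "ACC"),
                       groups = list(donor = 1:2, acceptor = 3L))
  pa_trajectory(st, list(coords(st)))
}

test_that("hydrogen bonds respect the distance and angle gates", {
  expect_equal(occupancy(detect_interactions(hbond_fixture(2.9, 180),
                                             "donor", "acceptor", "hbond")), 100)
  expect_equal(occupancy(detect_interactions(hbond_fixture(3.5, 180),
                                             "donor", "acceptor", "hbond")), 100)
  expect_equal(occupancy(detect_interactions(hbond_fixture(3.51, 180),
                                             "donor", "acceptor", "hbond")), 0)
  expect_equal(occupancy(detect_interactions(hbond_fixture(2.9, 150),
                                             "donor", "acceptor", "hbond")), 100)
  expect_equal(occupancy(detect_interactions(hbond_fixture(2.9, 149),
                                             "donor", "acceptor", "hbond")), 0)
})

test_that("hydrogen-bond detection demands explicit hydrogens", {
  st <- tiny_structure(matrix(rnorm(6), ncol = 3), element = c("N", "O"),
                       resno = c(1, 9), groups = list(donor = 1L,
                                                      acceptor = 2L))
  tr <- pa_trajectory(st, list(coords(st)))
  expect_error(detect_interactions(tr, "donor", "acceptor", "hbond"),
               "hydrogen")
})

test_that("salt bridges gate on distance and ionic charge", {
  fix <- function(d, qn = 0.6, qo = -0.5) {
    xyz <- rbind(c(0, 0, 0), c(d, 0, 0))
    st <- tiny_structure(xyz, element = c("N", "O"), charge = c(qn, qo),
                         resno = c(1, 9), groups = list(donor = 1L,
                                                        acceptor = 2L))
    pa_trajectory(st, list(coords(st)))
  }
  occ <- function(tr) occupancy(detect_interactions(tr, "donor", "acceptor",
                                                    "salt_bridge"))
  expect_equal(occ(fix(4.0)), 100)
  expect_equal(occ(fix(4.01)), 0)
  expect_equal(occ(fix(3.0, qn = 0.25)), 100)   # inclusive charge gate
  expect_equal(occ(fix(3.0, qn = 0.24)), 0)
  expect_equal(occ(fix(3.0, qo = -0.2)), 0)
})

test_that("conditional energies conserve the weighted mean to 1e-9", {
  trajs <- make_trajectory(planted_truth(), n_frames = 150, n_replicas = 1,
                           seed = 8)
  tr <- trajs[[1]]
  es <- interaction_energy_series(tr)
  hb <- detect_interactions(tr, "donor", "acceptor", "hbond")
  ce <- conditional_energy(es, hb)
  recon <- (ce$n_bound * ce$e_bound + ce$n_unbound * ce$e_unbound) /
    (ce$n_bound + ce$n_unbound)
  expect_equal(recon, mean(es$energy), tolerance = 1e-9)
  expect_equal(ce$delta_sd, sqrt(ce$sd_bound^2 + ce$sd_unbound^2),
               tolerance = 1e-12)
})

test_that("sparse states flag the conditional delta as undefined", {
  trajs <- make_trajectory(planted_truth(hbond_occupancy = 100),
                           n_frames = 30, n_replicas = 1, seed = 1)
  tr <- trajs[[1]]
  es <- interaction_energy_series(tr)
  hb <- detect_interactions(tr, "donor", "acceptor", "hbond")
  ce <- conditional_energy(es, hb, min_frames = 5)
  expect_false(ce$defined)
  expect_true(is.na(ce$delta_e))
  expect_error(conditional_energy(es[1:10, ], hb), "frame")
})

test_that("side-chain states split at the 45 degree boundary", {
  ring_at <- function(theta_deg) {
    # CB at origin, centroid along theta from the +z axis (pocket axis)
    dir <- c(sin(pi * theta_deg / 180), 0, cos(pi * theta_deg / 180))
    cen <- 2.1 * dir
    ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- ref - sum(ref * dir) * dir; u <- u / sqrt(sum(u^2))
    v <- c(dir[2] * u[3] - dir[3] * u[2], dir[3] * u[1] - dir[1] * u[3],
           dir[1] * u[2] - dir[2] * u[1])
    ring <- t(vapply(seq(0, 300, by = 60) * pi / 180,
                     function(a) cen + 1.4 * (cos(a) * u + sin(a) * v),
                     numeric(3)))
    xyz <- rbind(c(0, 0, 0), ring, c(0, -5, 0), c(0, -5, 10))
    at <- tibble::tibble(
      serial = 1:9,
      name = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "ORI", "MOU"),
      element = "C", resid = c(rep("PHE", 7), "X", "X"),
      resno = c(rep(134L, 7), 900L, 901L),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    st <- pa_structure(at, groups = list(axis_origin = 8L, axis_mouth = 9L))
    pa_trajectory(st, list(coords(st)))
  }
  s30 <- classify_sidechain(ring_at(30), 134, "axis_origin", "axis_mouth")
  expect_equal(s30$state, "conformation_1")
  expect_equal(s30$theta, 30, tolerance = 1e-6)
  s449 <- classify_sidechain(ring_at(44.9), 134, "axis_origin", "axis_mouth")
  expect_equal(s449$state, "conformation_1")
  s451 <- classify_sidechain(ring_at(45.1), 134, "axis_origin", "axis_mouth")
  expect_equal(s451$state, "conformation_2")
  s60 <- classify_sidechain(ring_at(60), 134, "axis_origin", "axis_mouth")
  expect_equal(s60$state, "conformation_2")
  expect_error(classify_sidechain(random_traj(2), 1, "enzyme", "substrate"),
               "aromatic")
})

test_that("aggregate_replicas reports mean, SEM and flags single replicas", {
  x <- c(10, 12, 14)
  a <- aggregate_replicas(x)
  expect_equal(a$mean, 12)
  expect_equal(a$sem, sd(x) / sqrt(3), tolerance = 1e-12)
  expect_equal(a$n, 3L)
  expect_message(a1 <- aggregate_replicas(5), "replica")
  expect_true(is.na(a1$sem))
})
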