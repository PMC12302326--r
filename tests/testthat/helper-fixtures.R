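# Shared small fixtures for the test suite.

# minimal parameterised structure: `n` atoms at given coordinates
tiny_structure <- function(xyz, element = rep("C", nrow(xyz)),
                           charge = rep(0, nrow(xyz)),
                           sigma = rep(3.4, nrow(xyz)),
                           eps = rep(0.3, nrow(xyz)),
                           resno = seq_len(nrow(xyz)),
                           resid = rep("RES", nrow(xyz)),
                           groups = list()) {
  at <- tibble::tibble(
    serial = seq_len(nrow(xyz)), name = paste0(element, seq_len(nrow(xyz))),
    element = element, resid = resid, resno = as.integer(resno),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = charge, sigma = sigma, epsilon = eps
  )
  pa_structure(at, groups = groups)
}

# independent O(N^2) double-loop LJ + Coulomb energy (oracle)
oracle_energy <- function(xyz_a, q_a, sig_a, eps_a, xyz_b, q_b, sig_b, eps_b,
                          cutoff = Inf) {
  ke <- 1389.35458
  e <- 0
  for (i in seq_len(nrow(xyz_a))) {
    for (j in seq_len(nrow(xyz_b))) {
      r <- sqrt(sum((xyz_a[i, ] - xyz_b[j, ])^2))
      if (r > cutoff || r == 0) next
      sij <- (sig_a[i] + sig_b[j]) / 2
      eij <- sqrt(eps_a[i] * eps_b[j])
      sr6 <- (sij / r)^6
      e <- e + 4 * eij * (sr6^2 - sr6) + ke * q_a[i] * q_b[j] / r
    }
  }
  e
}

# independent per-frame, per-residue contact oracle (any-atom minimum
# distance, inclusive cutoff)
oracle_contacts <- function(traj, cutoff = 2.5) {
  st <- traj$structure
  eidx <- st$groups$enzyme
  sidx <- st$groups$substrate
  resnos <- sort(unique(st$atoms$resno[eidx]))
  hits <- matrix(FALSE, nrow = length(traj$frames), ncol = length(resnos))
  for (k in seq_along(traj$frames)) {
    m <- traj$frames[[k]]
    for (ri in seq_along(resnos)) {
      ats <- eidx[st$atoms$resno[eidx] == resnos[ri]]
      dmin <- Inf
      for (a in ats) for (b in sidx) {
        d <- sqrt(sum((m[a, ] - m[b, ])^2))
        if (d < dmin) dmin <- d
      }
      hits[k, ri] <- dmin <= cutoff
    }
  }
  tibble::tibble(resno = resnos, f = 100 * colMeans(hits))
}

# graph scan for rotatable bonds: single, non-amide, both endpoints heavy
# with heavy-degree >= 2 (an independent reading of the rotatability rule)
oracle_rotatable <- function(olig) {
  at <- olig$structure$atoms
  bonds <- olig$bonds
  deg_heavy <- function(i) {
    nb <- c(bonds$j[bonds$i == i], bonds$i[bonds$j == i])
    sum(at$element[nb] != "H")
  }
  sel <- bonds$kind == "single" &
    at$element[bonds$i] != "H" & at$element[bonds$j] != "H"
  keep <- which(sel)
  keep[vapply(keep, function(r)
    deg_heavy(bonds$i[r]) >= 2 && deg_heavy(bonds$j[r]) >= 2, TRUE)]
}

quiet_pipeline <- function(...) suppressMessages(run_pipeline(...))
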