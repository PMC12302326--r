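#' Per-residue contact frequencies along a trajectory
#'
#' A residue is in contact with the substrate in a frame when the minimum
#' distance over all (residue atom, substrate atom) pairs - hydrogens
#' included - is less than or equal to `cutoff` (default 2.5 Angstrom,
#' inclusive). The frequency is the percentage of frames in contact.
#'
#' @param traj A [pa_trajectory()].
#' @param enzyme_group,substrate_group Group names on the topology.
#' @param cutoff Contact distance in Angstrom.
#' @return A tibble of class `pa_contact_profile` with columns `resno`,
#'   `resid`, `f` (percent of frames) and attributes `cutoff`, `n_frames`,
#'   `replica_id`.
#' @export
contact_frequencies <- function(traj, enzyme_group = "enzyme",
                                substrate_group = "substrate", cutoff = 2.5) {
  st <- traj$structure
  eidx <- group_idx(st, enzyme_group)
  sidx <- group_idx(st, substrate_group)
  if (length(eidx) == 0 || length(sidx) == 0) {
    stop("enzyme and substrate groups must be non-empty")
  }
  nf <- n_frames(traj)
  res <- split(eidx, st$atoms$resno[eidx])
  hits <- matrix(0L, nrow = length(res), ncol = nf)
  for (k in seq_len(nf)) {
    m <- traj$frames[[k]]
    d <- cross_dist(m[eidx, , drop = FALSE], m[sidx, , drop = FALSE])
    mind <- apply(d, 1, min)
    per_res <- tapply(mind, st$atoms$resno[eidx], min)
    hits[, k] <- as.integer(per_res <= cutoff)
  }
  resno <- as.integer(names(res))
  out <- tibble::tibble(
    resno = resno,
    resid = st$atoms$resid[vapply(res, `[[`, 0L, 1)],
    f = 100 * rowMeans(hits)
  )
  attr(out, "cutoff") <- cutoff
  attr(out, "n_frames") <- nf
  attr(out, "replica_id") <- traj$replica_id
  class(out) <- c("pa_contact_profile", class(out))
  out
}

#' Aggregate contact profiles across replicas
#'
#' @param profiles List of [contact_frequencies()] outputs computed with the
#'   same cutoff.
#' @return Tibble of class `pa_contact_profile_mean` with `resno`, `resid`,
#'   `mean_f`, `sem_f`, `n_replicas`; attribute `cutoff`.
#' @export
aggregate_contacts <- function(profiles) {
  cuts <- vapply(profiles, attr, 0, "cutoff")
  if (length(unique(cuts)) != 1) stop("profiles use different cutoffs")
  all <- dplyr::bind_rows(lapply(seq_along(profiles), function(i) {
    dplyr::mutate(tibble::as_tibble(profiles[[i]]), replica = i)
  }))
  out <- all |>
    dplyr::group_by(.data$resno, .data$resid) |>
    dplyr::summarise(mean_f = mean(.data$f),
                     sem_f = if (dplyr::n() > 1)
                       stats::sd(.data$f) / sqrt(dplyr::n()) else NA_real_,
                     n_replicas = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$resno)
  attr(out, "cutoff") <- cuts[1]
  class(out) <- c("pa_contact_profile_mean", class(out))
  out
}

#' Select hotspot residues from replica contact profiles
#'
#' Nominates residues whose replica-mean contact frequency is at least
#' `threshold` percent (inclusive), minus an exclusion set (typically the
#' catalytic nucleophile, which is indispensable and not mutated). Sorted by
#' descending mean frequency.
#'
#' @param profiles List of per-replica [contact_frequencies()] profiles, or
#'   an [aggregate_contacts()] result.
#' @param threshold Selection threshold in percent of simulation time.
#' @param exclude Integer residue numbers to drop from the nomination.
#' @return Tibble with `resno`, `resid`, `mean_f`, ordered by `mean_f`
#'   descending.
#' @export
select_hotspots <- function(profiles, threshold = 50, exclude = integer(0)) {
  agg <- if (inherits(profiles, "pa_contact_profile_mean")) profiles
         else aggregate_contacts(profiles)
  agg |>
    dplyr::filter(.data$mean_f >= threshold, !.data$resno %in% exclude) |>
    dplyr::arrange(dplyr::desc(.data$mean_f)) |>
    dplyr::select("resno", "resid", "mean_f")
}

#' Contact-frequency difference between two systems
#'
#' Delta f = mean_a - mean_b per residue, with uncertainty combined in
#' quadrature from the replica standard errors.
#'
#' @param a,b [aggregate_contacts()] results (same cutoff).
#' @param resno Optional residue subset.
#' @return Tibble with `resno`, `delta_f`, `uncertainty`.
#' @export
contact_delta <- function(a, b, resno = NULL) {
  if (!isTRUE(all.equal(attr(a, "cutoff"), attr(b, "cutoff")))) {
    stop("contact profiles were computed with different cutoffs (",
         attr(a, "cutoff"), " vs ", attr(b, "cutoff"), " Angstrom)")
  }
  j <- dplyr::inner_join(tibble::as_tibble(a), tibble::as_tibble(b),
                         by = "resno", suffix = c("_a", "_b"))
  out <- tibble::tibble(
    resno = j$resno,
    delta_f = j$mean_f_a - j$mean_f_b,
    uncertainty = sqrt(j$sem_f_a^2 + j$sem_f_b^2)
  )
  if (!is.null(resno)) out <- out[out$resno %in% resno, ]
  out
}

# map hydrogens to their donor heavy atom by distance in a reference frame
donor_hydrogens <- function(st, idx, ref_xyz, hd_max = 1.25) {
  heavies <- idx[st$atoms$element[idx] %in% c("N", "O")]
  hs <- which(st$atoms$element == "H")
  hs <- intersect(hs, idx)
  if (length(hs) == 0 || length(heavies) == 0) {
    return(tibble::tibble(donor = integer(0), h = integer(0)))
  }
  d <- cross_dist(ref_xyz[heavies, , drop = FALSE], ref_xyz[hs, , drop = FALSE])
  hit <- which(d <= hd_max, arr.ind = TRUE)
  tibble::tibble(donor = heavies[hit[, 1]], h = hs[hit[, 2]])
}

#' Detect hydrogen bonds or salt bridges per frame
#'
#' Hydrogen bond: donor-acceptor heavy-atom distance <= `dist_cutoff`
#' (default 3.5 Angstrom) and donor-H-acceptor angle >= `angle_cutoff`
#' (default 150 degrees). Salt bridge: any (cationic N, anionic O) pair
#' within 4.0 Angstrom; ionic atoms are recognised by their partial charge
#' (N with charge >= `q_ion`, O with charge <= -`q_ion`). The occupancy is
#' the percentage of frames with at least one qualifying interaction.
#'
#' @param traj A [pa_trajectory()] with hydrogens (hbond) or charges
#'   (salt_bridge) on the topology.
#' @param donor_group,acceptor_group Group names; for salt bridges the donor
#'   group supplies the cationic nitrogens.
#' @param kind `"hbond"` or `"salt_bridge"`.
#' @param dist_cutoff Heavy-atom distance cutoff (Angstrom); default 3.5 for
#'   hbond, 4.0 for salt_bridge.
#' @param angle_cutoff Donor-H-acceptor angle gate in degrees (hbond only).
#' @param q_ion Partial-charge magnitude above which an atom counts as ionic.
#' @return Tibble of class `pa_interaction_series` with `frame`, `count`;
#'   attributes `occupancy` (percent) and `kind`.
#' @export
detect_interactions <- function(traj, donor_group, acceptor_group,
                                kind = c("hbond", "salt_bridge"),
                                dist_cutoff = NULL, angle_cutoff = 150,
                                q_ion = 0.25) {
  kind <- match.arg(kind)
  if (is.null(dist_cutoff)) dist_cutoff <- if (kind == "hbond") 3.5 else 4.0
  st <- traj$structure
  didx <- group_idx(st, donor_group)
  aidx <- group_idx(st, acceptor_group)
  nf <- n_frames(traj)
  counts <- integer(nf)
  if (kind == "hbond") {
    dh <- donor_hydrogens(st, didx, traj$frames[[1]])
    if (nrow(dh) == 0) {
      stop("no donor hydrogens found in group '", donor_group,
           "'; hydrogen-bond detection needs explicit hydrogens")
    }
    acc <- aidx[st$atoms$element[aidx] %in% c("N", "O")]
    if (length(acc) == 0) stop("no N/O acceptors in group '", acceptor_group, "'")
    for (k in seq_len(nf)) {
      m <- traj$frames[[k]]
      dda <- cross_dist(m[dh$donor, , drop = FALSE], m[acc, , drop = FALSE])
      cnt <- 0L
      seen <- character(0)
      pair <- which(dda <= dist_cutoff, arr.ind = TRUE)
      for (r in seq_len(nrow(pair))) {
        i <- pair[r, 1]; j <- pair[r, 2]
        key <- paste(dh$donor[i], acc[j])
        if (key %in% seen) next
        ang <- point_angle(m[dh$donor[i], ], m[dh$h[i], ], m[acc[j], ])
        if (ang >= angle_cutoff) { cnt <- cnt + 1L; seen <- c(seen, key) }
      }
      counts[k] <- cnt
    }
  } else {
    if (all(is.na(st$atoms$charge))) {
      stop("salt-bridge detection needs charges; call assign_nonbonded() first")
    }
    cat_n <- didx[st$atoms$element[didx] == "N" &
                    !is.na(st$atoms$charge[didx]) &
                    st$atoms$charge[didx] >= q_ion]
    ani_o <- aidx[st$atoms$element[aidx] == "O" &
                    !is.na(st$atoms$charge[aidx]) &
                    st$atoms$charge[aidx] <= -q_ion]
    for (k in seq_len(nf)) {
      if (length(cat_n) == 0 || length(ani_o) == 0) { counts[k] <- 0L; next }
      m <- traj$frames[[k]]
      d <- cross_dist(m[cat_n, , drop = FALSE], m[ani_o, , drop = FALSE])
      counts[k] <- sum(d <= dist_cutoff)
    }
  }
  out <- tibble::tibble(frame = seq_len(nf), count = counts)
  attr(out, "occupancy") <- 100 * mean(counts >= 1)
  attr(out, "kind") <- kind
  class(out) <- c("pa_interaction_series", class(out))
  out
}

#' Occupancy of an interaction series
#' @param series A [detect_interactions()] result.
#' @return Percent of frames with at least one interaction.
#' @export
occupancy <- function(series) attr(series, "occupancy")

#' Enzyme-substrate interaction energy per frame
#'
#' Evaluates the short-range Lennard-Jones + Coulomb energy between the two
#' groups on every trajectory frame (see [nonbonded_energy()]).
#'
#' @param traj A [pa_trajectory()] with parameters assigned on the topology.
#' @param enzyme_group,substrate_group Group names.
#' @param cutoff Pair cutoff in Angstrom.
#' @return Tibble of class `pa_energy_series` with `frame`, `energy`
#'   (kJ/mol).
#' @export
interaction_energy_series <- function(traj, enzyme_group = "enzyme",
                                      substrate_group = "substrate",
                                      cutoff = 10) {
  st <- traj$structure
  eidx <- group_idx(st, enzyme_group)
  sidx <- group_idx(st, substrate_group)
  at <- st$atoms
  e <- vapply(seq_len(n_frames(traj)), function(k) {
    m <- traj$frames[[k]]
    nonbonded_energy(m[eidx, , drop = FALSE], at$charge[eidx],
                     at$sigma[eidx], at$epsilon[eidx],
                     m[sidx, , drop = FALSE], at$charge[sidx],
                     at$sigma[sidx], at$epsilon[sidx], cutoff)
  }, 0)
  out <- tibble::tibble(frame = seq_len(n_frames(traj)), energy = e)
  class(out) <- c("pa_energy_series", class(out))
  out
}

#' Interaction energy conditioned on a bond state
#'
#' Splits the per-frame energies by whether the interaction series records
#' at least one bond in that frame, and reports the mean energy in each
#' state, their standard deviations, and the drop upon bond formation
#' delta_E = E_bound - E_unbound with the state spreads combined in
#' quadrature. The delta is flagged undefined when either state has fewer
#' than `min_frames` frames.
#'
#' @param energy A [interaction_energy_series()] result.
#' @param series A [detect_interactions()] result of equal length.
#' @param min_frames Minimum frames per state for a defined delta.
#' @return List of class `pa_conditional_energy` with `frames` (tibble),
#'   `e_bound`, `e_unbound`, `sd_bound`, `sd_unbound`, `n_bound`,
#'   `n_unbound`, `delta_e`, `delta_sd`, `defined`.
#' @export
conditional_energy <- function(energy, series, min_frames = 5) {
  if (nrow(energy) != nrow(series)) {
    stop("energy and interaction series have different frame counts")
  }
  bound <- series$count >= 1
  eb <- energy$energy[bound]; eu <- energy$energy[!bound]
  defined <- length(eb) >= min_frames && length(eu) >= min_frames
  out <- list(
    frames = tibble::tibble(frame = energy$frame, energy = energy$energy,
                            bound = bound),
    e_bound = if (length(eb)) mean(eb) else NA_real_,
    e_unbound = if (length(eu)) mean(eu) else NA_real_,
    sd_bound = if (length(eb) > 1) stats::sd(eb) else NA_real_,
    sd_unbound = if (length(eu) > 1) stats::sd(eu) else NA_real_,
    n_bound = length(eb), n_unbound = length(eu),
    defined = defined
  )
  out$delta_e <- if (defined) out$e_bound - out$e_unbound else NA_real_
  out$delta_sd <- if (defined) sqrt(out$sd_bound^2 + out$sd_unbound^2) else NA_real_
  class(out) <- "pa_conditional_energy"
  out
}

#' @export
print.pa_conditional_energy <- function(x, ...) {
  cat("<pa_conditional_energy> E_bound =", round(x$e_bound, 1),
      "( n =", x$n_bound, "), E_unbound =", round(x$e_unbound, 1),
      "( n =", x$n_unbound, ")\n")
  if (x$defined) {
    cat("delta_E =", round(x$delta_e, 1), "+/-", round(x$delta_sd, 1), "kJ/mol\n")
  } else {
    cat("delta_E undefined (a state has too few frames)\n")
  }
  invisible(x)
}

#' Classify an aromatic side chain into pocket-axis conformations
#'
#' Per frame, the angle theta between the CB-to-ring-centroid vector of the
#' residue and the pocket axis (origin-group centroid toward mouth-group
#' centroid) is computed; frames with theta <= `boundary` are labelled
#' `conformation_1` (vertical, pointing toward the active site), others
#' `conformation_2` (horizontal or pointing out of the enzyme).
#'
#' @param traj A [pa_trajectory()].
#' @param resno Residue number of an aromatic residue (Phe/Tyr/Trp).
#' @param origin_group,mouth_group Group names defining the pocket axis.
#' @param boundary Classification boundary in degrees.
#' @return Tibble of class `pa_sidechain_states` with `frame`, `theta`,
#'   `state`; attribute `fractions` (named numeric summing to 1).
#' @export
classify_sidechain <- function(traj, resno, origin_group, mouth_group,
                               boundary = 45) {
  st <- traj$structure
  at <- st$atoms
  ridx <- which(at$resno == resno)
  if (length(ridx) == 0) stop("residue ", resno, " not found")
  arom <- ridx[at$resid[ridx] %in% c("PHE", "TYR", "TRP")]
  if (length(arom) == 0) {
    stop("residue ", resno, " (", paste(unique(at$resid[ridx]), collapse = "/"),
         ") is not aromatic (Phe/Tyr/Trp)")
  }
  ridx <- arom
  resid <- at$resid[ridx[1]]
  cb <- ridx[at$name[ridx] == "CB"]
  ring_names <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ",
                  "NE1", "CE3", "CZ2", "CZ3", "CH2")
  ring <- ridx[at$name[ridx] %in% ring_names]
  if (length(cb) != 1 || length(ring) < 3) {
    stop("residue ", resno, " lacks CB/ring atoms for classification")
  }
  o_idx <- group_idx(st, origin_group)
  m_idx <- group_idx(st, mouth_group)
  nf <- n_frames(traj)
  theta <- vapply(seq_len(nf), function(k) {
    m <- traj$frames[[k]]
    axis <- colMeans(m[m_idx, , drop = FALSE]) - colMeans(m[o_idx, , drop = FALSE])
    v <- colMeans(m[ring, , drop = FALSE]) - m[cb, ]
    acos(max(-1, min(1, sum(vunit(axis) * vunit(v))))) * 180 / pi
  }, 0)
  state <- ifelse(theta <= boundary, "conformation_1", "conformation_2")
  out <- tibble::tibble(frame = seq_len(nf), theta = theta, state = state)
  attr(out, "fractions") <- c(
    conformation_1 = mean(state == "conformation_1"),
    conformation_2 = mean(state == "conformation_2")
  )
  class(out) <- c("pa_sidechain_states", class(out))
  out
}

#' Mean and standard error across replicas
#'
#' The package follows the convention of reporting replica statistics as
#' mean plus/minus the standard error of the mean (SEM = sd / sqrt(n)).
#'
#' @param x Numeric vector of per-replica scalars.
#' @return Tibble with `mean`, `sem` (`NA` with a message when n = 1), `n`.
#' @export
aggregate_replicas <- function(x) {
  if (length(x) < 1) stop("need at least one replica")
  sem <- if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else {
    message("single replica: SEM not defined")
    NA_real_
  }
  tibble::tibble(mean = mean(x), sem = sem, n = length(x))
}
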