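# Coulomb constant in kJ mol^-1 Angstrom e^-2
KE_COULOMB <- 1389.35458

#' Short-range Lennard-Jones + Coulomb interaction energy between two atom sets
#'
#' Pairwise sum of 4*eps*((sigma/r)^12 - (sigma/r)^6) + ke*qi*qj/r over all
#' inter-set pairs within `cutoff`, with Lorentz-Berthelot combination
#' (arithmetic sigma, geometric epsilon). Symmetric in the two sets.
#'
#' @param xyz_a,xyz_b Coordinate matrices (n x 3, Angstrom).
#' @param q_a,q_b Partial charges (e).
#' @param sig_a,sig_b Lennard-Jones sigma (Angstrom).
#' @param eps_a,eps_b Lennard-Jones epsilon (kJ/mol).
#' @param cutoff Pair distance cutoff in Angstrom.
#' @return Energy in kJ/mol.
#' @export
nonbonded_energy <- function(xyz_a, q_a, sig_a, eps_a,
                             xyz_b, q_b, sig_b, eps_b, cutoff = 10) {
  if (anyNA(q_a) || anyNA(q_b) || anyNA(sig_a) || anyNA(sig_b) ||
      anyNA(eps_a) || anyNA(eps_b)) {
    stop("nonbonded parameters unassigned; call assign_nonbonded() first")
  }
  d <- cross_dist(xyz_a, xyz_b)
  sel <- d <= cutoff & d > 0
  if (!any(sel)) return(0)
  r <- d[sel]
  sij <- outer(sig_a, sig_b, function(a, b) (a + b) / 2)[sel]
  eij <- sqrt(outer(eps_a, eps_b))[sel]
  qq <- outer(q_a, q_b)[sel]
  sr6 <- (sij / r)^6
  sum(4 * eij * (sr6^2 - sr6) + KE_COULOMB * qq / r)
}

#' Docking configuration
#'
#' Tunables of the incremental fragment-growth docking. Defaults: 10 A
#' energy cutoff, 2.0 A heavy-atom clash threshold, 8 A seeding radius,
#' 5000 seed samples, 50 retained poses per increment, 2.0 A RMSD cluster
#' cutoff, 3 dihedral samples per rotatable bond drawn from
#' {60, 180, -60} degrees with +/-15 degree uniform jitter.
#'
#' @param cutoff Energy cutoff (Angstrom).
#' @param clash_threshold Heavy-atom clash distance (Angstrom).
#' @param seed_radius Seeding sphere radius around the site centroid (Angstrom).
#' @param n_samples Number of rigid-body seed samples.
#' @param keep_k Poses retained per increment.
#' @param rmsd_cutoff Leader-clustering RMSD cutoff (Angstrom).
#' @param n_dihedral_samples Dihedral samples per rotatable bond (1-3).
#' @param jitter Uniform dihedral jitter half-width (degrees).
#' @param site Group name used as the docking site.
#' @return A list of class `pa_dock_config`.
#' @export
dock_config <- function(cutoff = 10, clash_threshold = 2.0, seed_radius = 8,
                        n_samples = 5000, keep_k = 50, rmsd_cutoff = 2.0,
                        n_dihedral_samples = 3, jitter = 15,
                        site = "catalytic_triad") {
  structure(list(cutoff = cutoff, clash_threshold = clash_threshold,
                 seed_radius = seed_radius, n_samples = n_samples,
                 keep_k = keep_k, rmsd_cutoff = rmsd_cutoff,
                 n_dihedral_samples = n_dihedral_samples, jitter = jitter,
                 site = site),
            class = "pa_dock_config")
}

# pose coordinates: conformer rebuilt at the pose's dihedrals, then the
# seeding rigid-body transform applied
pose_coords <- function(pose, idx = NULL) {
  base <- build_oligomer(pose$spec, dihedrals = pose$dihedrals)
  m <- coords(base$structure)
  m <- sweep(m, 2, pose$ref) %*% t(pose$rot)
  m <- sweep(m, 2, pose$trans, "+")
  if (!is.null(idx)) m[idx, , drop = FALSE] else m
}

new_pose <- function(spec, dihedrals, ref, rot, trans, increment, placed,
                     score = NA_real_, xyz = NULL) {
  structure(list(spec = spec, dihedrals = dihedrals, ref = ref, rot = rot,
                 trans = trans, increment = increment, placed = placed,
                 score = score, xyz = xyz, cluster_id = NA_integer_),
            class = "pa_pose")
}

enzyme_params <- function(enzyme, idx) {
  at <- enzyme$atoms[idx, ]
  list(xyz = as.matrix(at[, c("x", "y", "z")]), q = at$charge,
       sig = at$sigma, eps = at$epsilon)
}

#' Score a pose against a parameterised enzyme
#'
#' The docking score is the short-range enzyme-substrate interaction energy
#' (Lennard-Jones + Coulomb, see [nonbonded_energy()]) over the atoms placed
#' so far; it doubles as the binding-affinity proxy reported for final poses.
#'
#' @param enzyme A [pa_structure()] with nonbonded parameters assigned and an
#'   `"enzyme"` group (all atoms if absent).
#' @param pose A `pa_pose` or a `pa_oligomer` with parameters assigned.
#' @param cutoff Pair cutoff in Angstrom.
#' @param olig Reference `pa_oligomer` carrying the substrate parameters
#'   (required for `pa_pose` input).
#' @return Energy in kJ/mol.
#' @export
score_pose <- function(enzyme, pose, cutoff = 10, olig = NULL) {
  eidx <- if ("enzyme" %in% names(enzyme$groups)) group_idx(enzyme, "enzyme")
          else seq_len(n_atoms(enzyme))
  ep <- enzyme_params(enzyme, eidx)
  if (inherits(pose, "pa_oligomer")) {
    at <- pose$structure$atoms
    nonbonded_energy(ep$xyz, ep$q, ep$sig, ep$eps,
                     as.matrix(at[, c("x", "y", "z")]), at$charge, at$sigma,
                     at$epsilon, cutoff)
  } else {
    if (is.null(olig)) stop("scoring a pa_pose needs the reference oligomer")
    at <- olig$structure$atoms[pose$placed, ]
    xyz <- if (!is.null(pose$xyz)) pose$xyz[pose$placed, , drop = FALSE]
           else pose_coords(pose, pose$placed)
    nonbonded_energy(ep$xyz, ep$q, ep$sig, ep$eps,
                     xyz, at$charge, at$sigma, at$epsilon, cutoff)
  }
}

clashes_enzyme <- function(enz_heavy_xyz, pose_xyz_heavy, threshold) {
  if (nrow(enz_heavy_xyz) == 0 || nrow(pose_xyz_heavy) == 0) return(FALSE)
  min(cross_dist(pose_xyz_heavy, enz_heavy_xyz)) < threshold
}

placed_atoms <- function(olig, increment) {
  n <- olig$spec$n_units
  units <- c(0L, seq_len(increment))
  if (increment >= n) units <- c(units, n + 1L)  # include the far cap
  which(olig$unit_of %in% units)
}

#' Rigid-body seeding of the first oligomer increment
#'
#' Samples rigid-body placements of the first repeat unit (plus its cap and
#' leading amide) uniformly in a sphere around the docking-site centroid,
#' with uniform random orientations. Placements with any heavy-atom overlap
#' below the clash threshold are discarded; survivors are scored and the
#' best `keep_k` retained.
#'
#' @param enzyme Parameterised [pa_structure()] with the site group.
#' @param olig A parameterised `pa_oligomer` (full chain; only increment 1 is
#'   placed).
#' @param config A [dock_config()].
#' @param seed Integer RNG seed (placements are deterministic given it).
#' @return List of `pa_pose` objects sorted by score.
#' @export
seed_placement <- function(enzyme, olig, config = dock_config(), seed = 1L) {
  set.seed(seed)
  site <- group_idx(enzyme, config$site)
  if (length(site) == 0) stop("docking site group is empty")
  centre <- colMeans(coords(enzyme, site))
  eidx <- if ("enzyme" %in% names(enzyme$groups)) group_idx(enzyme, "enzyme")
          else seq_len(n_atoms(enzyme))
  e_heavy <- coords(enzyme, eidx[enzyme$atoms$element[eidx] != "H"])
  placed <- placed_atoms(olig, 1L)
  base <- coords(olig$structure)
  ref <- colMeans(base[placed, , drop = FALSE])
  hv_pl <- intersect(heavy_atoms(olig), placed)
  poses <- list()
  for (s in seq_len(config$n_samples)) {
    rot <- random_rotation()
    u <- stats::runif(1)^(1 / 3) * config$seed_radius
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    trans <- centre + u * dir
    xyz <- sweep(base, 2, ref) %*% t(rot)
    xyz <- sweep(xyz, 2, trans, "+")
    if (clashes_enzyme(e_heavy, xyz[hv_pl, , drop = FALSE],
                       config$clash_threshold)) next
    p <- new_pose(olig$spec, olig$dihedrals, ref, rot, trans, 1L, placed,
                  xyz = xyz)
    p$score <- score_pose(enzyme, p, config$cutoff, olig)
    poses[[length(poses) + 1]] <- p
  }
  if (length(poses) == 0) {
    stop("all ", config$n_samples, " seed placements clash with the enzyme; ",
         "increase seed_radius or use a smaller fragment")
  }
  poses <- poses[order(vapply(poses, `[[`, 0, "score"))]
  poses[seq_len(min(config$keep_k, length(poses)))]
}

dihedral_candidates <- function(n_samples, jitter) {
  base <- c(180, 60, -60)  # trans first so reduced sampling keeps it
  picks <- if (n_samples >= 3) base else base[seq_len(n_samples)]
  picks + stats::runif(length(picks), -jitter, jitter)
}

#' Grow retained poses by one repeat unit
#'
#' For every retained pose the next 6-AHA unit is appended; its backbone
#' torsions are sampled from {60, 180, -60} degrees (plus uniform jitter) in
#' full factorial combination, every completion is scored, and the global
#' best `keep_k` non-clashing completions survive.
#'
#' @param enzyme Parameterised [pa_structure()].
#' @param olig The reference parameterised `pa_oligomer`.
#' @param poses List of `pa_pose` at a common increment.
#' @param config A [dock_config()].
#' @param seed Integer RNG seed (controls jitter).
#' @return List of `pa_pose` at increment + 1, sorted by score.
#' @export
extend_increment <- function(enzyme, olig, poses, config = dock_config(),
                             seed = 1L) {
  if (length(poses) == 0) stop("no poses to extend")
  inc <- poses[[1]]$increment
  if (inc >= olig$spec$n_units) stop("poses are already complete")
  set.seed(seed)
  unit <- inc + 1L
  rows <- which(olig$rotatable$unit == unit)
  cand <- lapply(rows, function(r) dihedral_candidates(config$n_dihedral_samples,
                                                       config$jitter))
  grid <- as.matrix(expand.grid(cand, KEEP.OUT.ATTRS = FALSE))
  placed <- placed_atoms(olig, unit)
  hv_pl <- intersect(heavy_atoms(olig), placed)
  eidx <- if ("enzyme" %in% names(enzyme$groups)) group_idx(enzyme, "enzyme")
          else seq_len(n_atoms(enzyme))
  e_heavy <- coords(enzyme, eidx[enzyme$atoms$element[eidx] != "H"])
  out <- list()
  for (p in poses) {
    for (gi in seq_len(nrow(grid))) {
      dh <- p$dihedrals
      dh[rows] <- grid[gi, ]
      cand_olig <- build_oligomer(olig$spec, dihedrals = dh)
      m <- coords(cand_olig$structure)
      xyz <- sweep(sweep(m, 2, p$ref) %*% t(p$rot), 2, p$trans, "+")
      if (has_internal_clash(cand_olig, config$clash_threshold, xyz = xyz,
                             idx = placed)) next
      if (clashes_enzyme(e_heavy, xyz[hv_pl, , drop = FALSE],
                         config$clash_threshold)) next
      np <- new_pose(olig$spec, dh, p$ref, p$rot, p$trans, unit, placed,
                     xyz = xyz)
      np$score <- score_pose(enzyme, np, config$cutoff, olig)
      out[[length(out) + 1]] <- np
    }
  }
  if (length(out) == 0) {
    stop("no non-clashing extension found at increment ", unit)
  }
  out <- out[order(vapply(out, `[[`, 0, "score"))]
  out[seq_len(min(config$keep_k, length(out)))]
}

rmsd_no_superposition <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Cluster completed poses and rank by population and affinity
#'
#' Greedy leader clustering on substrate heavy-atom RMSD without
#' superposition (all poses share the enzyme frame). Clusters are ranked by
#' population (descending), ties broken by mean score (ascending); the best
#' pose is the lowest-score member of the top cluster and its score is
#' reported as the binding-energy estimate.
#'
#' @param poses List of complete `pa_pose` objects.
#' @param olig Reference `pa_oligomer`.
#' @param rmsd_cutoff Cluster assignment cutoff in Angstrom.
#' @return A `pa_docking_result` with elements `clusters` (tibble), `poses`,
#'   `best_pose`, `binding_energy_estimate`.
#' @export
cluster_and_rank <- function(poses, olig, rmsd_cutoff = 2.0) {
  if (length(poses) == 0) stop("cannot cluster an empty pose list")
  n_units <- olig$spec$n_units
  if (any(vapply(poses, `[[`, 0L, "increment") != n_units)) {
    stop("all poses must be complete (increment = n_units)")
  }
  hv <- heavy_atoms(olig)
  mats <- lapply(poses, function(p) {
    if (!is.null(p$xyz)) p$xyz[hv, , drop = FALSE] else pose_coords(p, hv)
  })
  ord <- order(vapply(poses, `[[`, 0, "score"))
  leaders <- integer(0)
  cl <- integer(length(poses))
  for (i in ord) {
    hit <- 0L
    for (j in seq_along(leaders)) {
      if (rmsd_no_superposition(mats[[i]], mats[[leaders[j]]]) <= rmsd_cutoff) {
        hit <- j; break
      }
    }
    if (hit == 0L) { leaders <- c(leaders, i); hit <- length(leaders) }
    cl[i] <- hit
  }
  scores <- vapply(poses, `[[`, 0, "score")
  clusters <- tibble::tibble(cluster_id = seq_along(leaders)) |>
    dplyr::mutate(population = vapply(.data$cluster_id,
                                      function(k) sum(cl == k), 0L),
                  mean_score = vapply(.data$cluster_id,
                                      function(k) mean(scores[cl == k]), 0)) |>
    dplyr::arrange(dplyr::desc(.data$population), .data$mean_score) |>
    dplyr::mutate(rank = dplyr::row_number())
  top <- clusters$cluster_id[1]
  members <- which(cl == top)
  best <- members[which.min(scores[members])]
  for (i in seq_along(poses)) poses[[i]]$cluster_id <- cl[i]
  structure(list(clusters = clusters, poses = poses,
                 best_pose = poses[[best]],
                 binding_energy_estimate = scores[best],
                 best_score = min(scores),
                 orientation = olig$spec$orientation,
                 label = oligomer_label(olig$spec)),
            class = "pa_docking_result")
}

#' @export
print.pa_docking_result <- function(x, ...) {
  cat("<pa_docking_result>", x$label, "\n")
  cat("binding energy estimate:",
      round(x$binding_energy_estimate, 2), "kJ/mol\n")
  print(x$clusters)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy summary of a docking result
#' @param x A `pa_docking_result`.
#' @param ... Unused.
#' @return A tibble of clusters with population, mean score and rank.
#' @export
#' @exportS3Method generics::tidy
tidy.pa_docking_result <- function(x, ...) x$clusters

#' One-row summary of a docking result
#' @param x A `pa_docking_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
#' @exportS3Method generics::glance
glance.pa_docking_result <- function(x, ...) {
  tibble::tibble(label = x$label, orientation = x$orientation,
                 n_poses = length(x$poses), n_clusters = nrow(x$clusters),
                 binding_energy_estimate = x$binding_energy_estimate,
                 best_score = x$best_score)
}

#' Incremental fragment-growth docking of a flexible oligomer
#'
#' Places the first repeat unit by rigid-body sampling around the catalytic
#' site ([seed_placement()]), grows the chain one 6-AHA unit at a time with
#' factorial dihedral sampling ([extend_increment()]) and finally clusters
#' and ranks completed poses by population and affinity
#' ([cluster_and_rank()]). The receptor is rigid. Deterministic under a
#' fixed seed.
#'
#' @param enzyme Parameterised [pa_structure()] with a `"catalytic_triad"`
#'   group.
#' @param spec An [oligomer_spec()].
#' @param table A [pa_nonbonded()] table covering the oligomer atoms.
#' @param config A [dock_config()].
#' @param seed Integer RNG seed.
#' @return A `pa_docking_result`, with `per_increment_counts` recording
#'   survivor counts for audit.
#' @export
dock_oligomer <- function(enzyme, spec, table, config = dock_config(),
                          seed = 1L) {
  olig <- build_oligomer(spec)
  olig$structure <- assign_nonbonded(olig$structure, table)
  # orientation 2 mirrors the substrate termini; with isotropic rigid-body
  # seeding the two orientations are equivalent up to the random stream,
  # so each gets an independent deterministic substream
  seed_o <- seed + (spec$orientation - 1L) * 10007L
  poses <- seed_placement(enzyme, olig, config, seed = seed_o)
  counts <- length(poses)
  if (spec$n_units > 1) {
    for (u in 2:spec$n_units) {
      poses <- extend_increment(enzyme, olig, poses, config,
                                seed = seed_o + u)
      counts <- c(counts, length(poses))
    }
  }
  res <- cluster_and_rank(poses, olig, config$rmsd_cutoff)
  res$per_increment_counts <- counts
  res$config <- config
  res$seed <- seed
  res
}
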