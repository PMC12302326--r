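# Synthetic-data generators with planted ground truth. They plant the target
# statistics directly at frame level (Bernoulli/Gaussian construction)
# rather than simulating physics: the surface under test is the analysis
# code, not an MD engine.

#' Serialize a planted-truth record next to a generated dataset
#' @param truth Named list of planted parameters.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Build a rigid toy enzyme with a labelled pocket
#'
#' Constructs a pseudo-enzyme of a few hundred atoms with a
#' `catalytic_triad` group and one of three pocket geometries: an open
#' cylindrical `channel` that admits an extended oligomer, a shallow
#' `cleft` between two walls, or a solid `wall` that rejects every seed
#' placement. A nonbonded table covering the pocket and all oligomer
#' residues is returned alongside.
#'
#' @param pocket `"channel"`, `"cleft"` or `"wall"`.
#' @param seed RNG seed (atom placement jitter).
#' @return List with `structure` (a [pa_structure()] with groups `enzyme`
#'   and `catalytic_triad`) and `table` (a [pa_nonbonded()]).
#' @export
make_toy_complex <- function(pocket = c("channel", "cleft", "wall"),
                             seed = 1L) {
  pocket <- match.arg(pocket)
  set.seed(seed)
  pts <- switch(pocket,
    channel = {
      # tube of radius 7 A along x, length 34 A
      xs <- seq(-2, 32, by = 2)
      ang <- seq(0, 2 * pi, length.out = 13)[-13]
      do.call(rbind, lapply(xs, function(x)
        cbind(x, 7 * cos(ang), 7 * sin(ang))))
    },
    cleft = {
      g <- expand.grid(x = seq(-2, 22, by = 2), y = seq(-8, 8, by = 2))
      rbind(cbind(g$x, g$y, rep(5, nrow(g))), cbind(g$x, g$y, rep(-5, nrow(g))))
    },
    wall = {
      # solid lattice blanketing the whole seeding sphere plus fragment
      # extent: every point inside is < 1.4 A from a lattice atom
      g <- expand.grid(x = seq(-10, 21, by = 1.6), y = seq(-15, 15, by = 1.6),
                       z = seq(-15, 15, by = 1.6))
      m <- as.matrix(g)
      m[sqrt(rowSums(sweep(m, 2, c(5.8, 0, 0))^2)) < 15, ]
    })
  pts <- pts + matrix(stats::rnorm(length(pts), sd = 0.05), ncol = 3)
  n_wall <- nrow(pts)
  # catalytic triad: three marker atoms near the pocket mouth
  triad <- rbind(c(5, 0, 0), c(6.2, 1.0, 0), c(6.2, -1.0, 0))
  at <- tibble::tibble(
    serial = seq_len(n_wall + 3),
    name = c(rep("CW", n_wall), c("OG1", "OD1", "OD2")),
    element = c(rep("C", n_wall), "O", "O", "O"),
    resid = c(rep("POC", n_wall), "THR", "ASP", "ASP"),
    resno = c(rep(1L, n_wall), 267L, 306L, 308L),
    x = c(pts[, 1], triad[, 1]),
    y = c(pts[, 2], triad[, 2]),
    z = c(pts[, 3], triad[, 3])
  )
  st <- pa_structure(at, groups = list(
    enzyme = seq_len(n_wall + 3),
    catalytic_triad = n_wall + 1:3
  ))
  tb <- toy_nonbonded_table()
  st <- assign_nonbonded(st, tb)
  list(structure = st, table = tb)
}

#' Toy nonbonded parameter table for the pocket and oligomer residues
#'
#' A self-contained stand-in parameter set (the analyses only need sane
#' magnitudes): mildly attractive pocket carbons, standard-sized heavy
#' atoms, small hydrogens, and per-residue partial charges that sum to each
#' residue's formal charge (0 for ACE/AHA/NME/POC/THR/ASP here, -1 for the
#' carboxylate unit AHC, +1 for the ammonium unit AHN).
#'
#' @return A [pa_nonbonded()] table.
#' @export
toy_nonbonded_table <- function() {
  row <- function(res, atom, q, s, e) {
    data.frame(residue = res, atom = atom, charge = q, sigma = s, epsilon = e)
  }
  ch2 <- function(res, k) {
    rbind(row(res, paste0("C", k), 0, 3.5, 0.3),
          row(res, paste0("H", k, "1"), 0, 1.2, 0.05),
          row(res, paste0("H", k, "2"), 0, 1.2, 0.05))
  }
  aha_core <- function(res) do.call(rbind, lapply(2:6, function(k) ch2(res, k)))
  tb <- rbind(
    row("POC", "CW", 0, 3.4, 0.8),
    row("THR", "OG1", 0, 3.1, 0.5),
    row("ASP", "OD1", 0, 3.1, 0.5),
    row("ASP", "OD2", 0, 3.1, 0.5),
    # acetyl cap, neutral
    row("ACE", "CH3", -0.10, 3.5, 0.3),
    row("ACE", "HH31", 0.05, 1.2, 0.05),
    row("ACE", "HH32", 0.05, 1.2, 0.05),
    row("ACE", "HH33", 0.05, 1.2, 0.05),
    row("ACE", "C", 0.45, 3.4, 0.35),
    row("ACE", "O", -0.50, 3.0, 0.5),
    # interior 6-AHA unit, neutral
    row("AHA", "N", -0.45, 3.3, 0.5),
    row("AHA", "H", 0.25, 1.0, 0.05),
    aha_core("AHA"),
    row("AHA", "C", 0.50, 3.4, 0.35),
    row("AHA", "O", -0.30, 3.0, 0.5),
    # carboxylate-terminal unit, formal charge -1
    row("AHC", "N", -0.45, 3.3, 0.5),
    row("AHC", "H", 0.25, 1.0, 0.05),
    aha_core("AHC"),
    row("AHC", "C", 0.70, 3.4, 0.35),
    row("AHC", "O", -0.75, 3.0, 0.5),
    row("AHC", "OXT", -0.75, 3.0, 0.5),
    # ammonium-terminal unit, formal charge +1
    row("AHN", "N", -0.30, 3.3, 0.5),
    row("AHN", "H1", 0.33, 1.0, 0.05),
    row("AHN", "H2", 0.33, 1.0, 0.05),
    row("AHN", "H3", 0.33, 1.0, 0.05),
    aha_core("AHN"),
    row("AHN", "C", 0.50, 3.4, 0.35),
    row("AHN", "O", -0.40, 3.0, 0.5)
  )
  # AHN C2 carries the residual to close the +1 formal charge
  tb$charge[tb$residue == "AHN" & tb$atom == "C2"] <- 1 -
    sum(tb$charge[tb$residue == "AHN" & tb$atom != "C2"])
  tb <- rbind(tb,
    row("NME", "N", -0.45, 3.3, 0.5),
    row("NME", "H", 0.25, 1.0, 0.05),
    row("NME", "CH3", 0.05, 3.5, 0.3),
    row("NME", "HH31", 0.05, 1.2, 0.05),
    row("NME", "HH32", 0.05, 1.2, 0.05),
    row("NME", "HH33", 0.05, 1.2, 0.05)
  )
  pa_nonbonded(tibble::as_tibble(tb),
               formal_charges = c(POC = 0, ACE = 0, AHA = 0, AHC = -1,
                                  AHN = 1, NME = 0))
}

#' Planted-truth record for synthetic trajectories
#'
#' @param contact_f Named numeric: target contact frequency (percent) per
#'   enzyme residue number.
#' @param hbond_occupancy Target hydrogen-bond occupancy (percent) between
#'   the donor residue and the substrate terminus.
#' @param e_bound,e_unbound Target enzyme-substrate interaction energy
#'   (kJ/mol) in bonded and unbonded frames.
#' @param noise_sd Gaussian sd of the per-frame energy (kJ/mol).
#' @param state_fractions Length-2 numeric summing to 1: planted fractions
#'   of the aromatic side chain's two conformations.
#' @param donor_resno,aromatic_resno Residue numbers of the planted donor
#'   and aromatic residues.
#' @return A list of class `pa_planted_truth`.
#' @export
planted_truth <- function(contact_f = c(`91` = 60, `98` = 55, `134` = 80,
                                        `267` = 90, `305` = 52, `144` = 30),
                          hbond_occupancy = 67,
                          e_bound = -200, e_unbound = -102, noise_sd = 5,
                          state_fractions = c(0.7, 0.3),
                          donor_resno = 330L, aromatic_resno = 134L) {
  if (any(contact_f < 0 | contact_f > 100)) stop("contact_f must be in [0, 100]")
  if (hbond_occupancy < 0 || hbond_occupancy > 100) {
    stop("hbond_occupancy must be in [0, 100]")
  }
  if (abs(sum(state_fractions) - 1) > 1e-9) {
    stop("state_fractions must sum to 1")
  }
  if (as.character(donor_resno) %in% names(contact_f) &&
      contact_f[[as.character(donor_resno)]] < hbond_occupancy) {
    stop("conflicting targets: the donor residue's contact frequency (",
         contact_f[[as.character(donor_resno)]],
         "%) cannot be below its hydrogen-bond occupancy (",
         hbond_occupancy, "%)")
  }
  structure(list(contact_f = contact_f, hbond_occupancy = hbond_occupancy,
                 e_bound = e_bound, e_unbound = e_unbound,
                 noise_sd = noise_sd, state_fractions = state_fractions,
                 donor_resno = donor_resno, aromatic_resno = aromatic_resno),
            class = "pa_planted_truth")
}

#' Generate synthetic trajectories realising a planted truth
#'
#' Builds a minimal enzyme-substrate system and toggles its parts frame by
#' frame with independent Bernoulli draws so that the analysis stack should
#' recover the planted statistics: contact probes sit at 2.0 A (contact) or
#' 6.0 A (apart) from a substrate hub atom; in hydrogen-bonded frames the
#' donor realises compliant geometry (2.9 A, collinear H) against the
#' substrate's carboxylate oxygen, else it retreats to 8 A; partial charges
#' are chosen so the short-range interaction energy equals the planted
#' bound/unbound levels, with Gaussian noise injected through a baseline
#' charge pair; the aromatic side chain alternates between an axis-aligned
#' and a perpendicular orientation at the planted fractions.
#'
#' @param truth A [planted_truth()].
#' @param n_frames Frames per replica.
#' @param n_replicas Number of independent replicas.
#' @param seed RNG seed.
#' @param dt Frame spacing (ps).
#' @return List of [pa_trajectory()] objects with groups `enzyme`,
#'   `substrate`, `donor`, `acceptor`, `axis_origin`, `axis_mouth`.
#' @export
make_trajectory <- function(truth = planted_truth(), n_frames = 200,
                            n_replicas = 3, seed = 1L, dt = 100) {
  ke <- KE_COULOMB
  r_b <- 2.9; r_u <- 8.0; r_base <- 4.0
  q_acc <- -0.5
  qq_h <- (truth$e_bound - truth$e_unbound) / (ke * (1 / r_b - 1 / r_u))
  q_don <- qq_h / q_acc
  e_base <- truth$e_unbound - ke * qq_h / r_u
  q_bsub <- -0.5
  qq_b <- e_base * r_base / ke
  q_benz <- qq_b / q_bsub

  resnos <- as.integer(names(truth$contact_f))
  n_probe <- length(resnos)
  # probe directions fan out in the xy-plane around the substrate hub
  ang <- 2 * pi * seq_len(n_probe) / n_probe
  hub <- c(0, 0, 0)
  hb_centre <- c(0, 30, 0)   # acceptor O position
  base_enz <- c(0, 60, 0)
  arom_cb <- c(2, 90, 5)
  axis_o <- c(0, 88, 0); axis_m <- c(0, 88, 10)

  ring_local <- function(dir) {
    # hexagon of radius 1.4 A centred 2.1 A from CB along dir
    dir <- vunit(dir)
    ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- vunit(vcross(dir, ref)); v <- vcross(dir, u)
    cen <- arom_cb + 2.1 * dir
    t(vapply(seq(0, 300, by = 60) * pi / 180,
             function(a) cen + 1.4 * (cos(a) * u + sin(a) * v), numeric(3)))
  }

  at <- tibble::tibble(
    name = c(paste0("CP", seq_len(n_probe)),      # contact probes (enzyme)
             "NE", "HE",                          # donor N-H (enzyme)
             "CB0",                               # baseline partner (enzyme)
             "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ",  # aromatic (enzyme)
             "ORI", "MOU",                        # axis markers (enzyme)
             "C1", "OXT", "OB"),                  # substrate hub/acceptor/baseline
    element = c(rep("C", n_probe), "N", "H", "C",
                rep("C", 7), "C", "C", "C", "O", "O"),
    resid = c(rep("CNT", n_probe), "ARG", "ARG", "BAS",
              rep("PHE", 7), "AXO", "AXM", "SUB", "SUB", "SUB"),
    resno = c(resnos, truth$donor_resno, truth$donor_resno, 900L,
              rep(truth$aromatic_resno, 7), 901L, 902L, 999L, 999L, 999L),
    x = 0, y = 0, z = 0,
    charge = c(rep(0, n_probe), q_don, 0, q_benz,
               rep(0, 7), 0, 0, 0, q_acc, q_bsub),
    sigma = 0, epsilon = 0
  )
  at$serial <- seq_len(nrow(at))
  n_tot <- nrow(at)
  i_probe <- seq_len(n_probe)
  i_don <- n_probe + 1L; i_h <- n_probe + 2L; i_base <- n_probe + 3L
  i_cb <- n_probe + 4L; i_ring <- n_probe + 4L + 1:6
  i_axo <- n_probe + 11L; i_axm <- n_probe + 12L
  i_hub <- n_probe + 13L; i_acc <- n_probe + 14L; i_bsub <- n_probe + 15L
  st <- pa_structure(
    at[, c("serial", "name", "element", "resid", "resno", "x", "y", "z",
           "charge", "sigma", "epsilon")],
    groups = list(
      enzyme = c(i_probe, i_don, i_h, i_base, i_cb, i_ring),
      substrate = c(i_hub, i_acc, i_bsub),
      donor = c(i_don, i_h), acceptor = i_acc,
      axis_origin = i_axo, axis_mouth = i_axm
    ))

  lapply(seq_len(n_replicas), function(rep_i) {
    set.seed(seed + 7919L * rep_i)
    frames <- vector("list", n_frames)
    contact_draw <- matrix(stats::runif(n_probe * n_frames) <
                             rep(truth$contact_f / 100, n_frames),
                           nrow = n_probe)
    hb_draw <- stats::runif(n_frames) < truth$hbond_occupancy / 100
    state1 <- stats::runif(n_frames) < truth$state_fractions[1]
    e_noise <- stats::rnorm(n_frames, 0, truth$noise_sd)
    for (k in seq_len(n_frames)) {
      m <- matrix(0, nrow = n_tot, ncol = 3)
      m[i_hub, ] <- hub
      d_probe <- ifelse(contact_draw[, k], 2.0, 6.0)
      m[i_probe, ] <- hub + cbind(d_probe * cos(ang), d_probe * sin(ang), 0)
      m[i_acc, ] <- hb_centre
      r_dn <- if (hb_draw[k]) r_b else r_u
      m[i_don, ] <- hb_centre + c(0, r_dn, 0)
      m[i_h, ] <- hb_centre + c(0, r_dn - 1.0, 0)
      # baseline pair: Gaussian energy noise mapped through 1/r
      e_k <- e_base + e_noise[k]
      r_k <- ke * qq_b / e_k
      m[i_bsub, ] <- base_enz + c(0, 0, 0)
      m[i_base, ] <- base_enz + c(r_k, 0, 0)
      m[i_cb, ] <- arom_cb
      m[i_ring, ] <- ring_local(if (state1[k]) c(0, 0, 1) else c(1, 0, 0))
      m[i_axo, ] <- axis_o
      m[i_axm, ] <- axis_m
      frames[[k]] <- m
    }
    pa_trajectory(st, frames, dt = dt, replica_id = rep_i)
  })
}

#' Simulate a variant screening plate with known fold-changes
#'
#' Draws replicate activity measurements with lognormal noise (mean equal to
#' the true activity) for each variant, plus background wells, in the layout
#' consumed by [specific_activity()] and [fold_change()].
#'
#' @param true_folds Named numeric of true fold-changes over the parent.
#' @param parent_activity True parent specific activity
#'   (umol/(h mg); plate default 77).
#' @param noise_cv Coefficient of variation of the measurement noise.
#' @param n_replicates Replicates per variant.
#' @param seed RNG seed.
#' @param enzyme_nM,loading_g_per_L,time_h Assay conditions.
#' @param background_uM Mean amine background of blank wells.
#' @return Tibble of activity records (`variant`, `substrate`, `enzyme_nM`,
#'   `enzyme_mg_per_L`, `loading_g_per_L`, `time_h`, `amine_uM`,
#'   `replicate`) with attribute `truth`.
#' @export
make_screen_plate <- function(true_folds, parent_activity = 77,
                              noise_cv = 0.05, n_replicates = 2, seed = 1L,
                              enzyme_nM = 50, loading_g_per_L = 456,
                              time_h = 2, background_uM = 2) {
  if (any(true_folds <= 0)) stop("fold-changes must be positive")
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  set.seed(seed)
  mg <- enzyme_mg_per_L(enzyme_nM)
  variants <- c(parent = 1, true_folds)
  sdlog <- sqrt(log(1 + noise_cv^2))
  rows <- purrr::map_dfr(names(variants), function(v) {
    act_true <- parent_activity * variants[[v]]
    act <- if (noise_cv > 0) {
      stats::rlnorm(n_replicates, log(act_true) - sdlog^2 / 2, sdlog)
    } else rep(act_true, n_replicates)
    tibble::tibble(variant = v, substrate = "PA6", enzyme_nM = enzyme_nM,
                   enzyme_mg_per_L = mg, loading_g_per_L = loading_g_per_L,
                   time_h = time_h,
                   amine_uM = pmax(act * time_h * mg, 0),
                   replicate = seq_len(n_replicates))
  })
  blanks <- tibble::tibble(variant = "blank", substrate = "PA6",
                           enzyme_nM = 0, enzyme_mg_per_L = 0,
                           loading_g_per_L = loading_g_per_L, time_h = time_h,
                           amine_uM = pmax(stats::rnorm(n_replicates,
                                                        background_uM,
                                                        background_uM * noise_cv), 0),
                           replicate = seq_len(n_replicates))
  out <- dplyr::bind_rows(rows, blanks)
  attr(out, "truth") <- list(true_folds = as.list(true_folds),
                             parent_activity = parent_activity,
                             noise_cv = noise_cv, seed = seed)
  out
}

#' Simulate a two-state thermal melt curve
#'
#' @param tm True melting temperature (deg C).
#' @param slope Transition width parameter (deg C).
#' @param noise Gaussian noise sd on the unit-amplitude signal.
#' @param seed RNG seed.
#' @param trange Scanned temperature range (deg C).
#' @param step Grid spacing (deg C).
#' @return Tibble `temperature_C`, `signal` with attribute `truth`.
#' @export
make_melt_curve <- function(tm = 85.7, slope = 1.2, noise = 0.01, seed = 1L,
                            trange = c(60, 100), step = 0.5) {
  set.seed(seed)
  t <- seq(trange[1], trange[2], by = step)
  s <- 1 / (1 + exp((tm - t) / slope)) + stats::rnorm(length(t), 0, noise)
  out <- tibble::tibble(temperature_C = t, signal = s)
  attr(out, "truth") <- list(tm = tm, slope = slope, noise = noise, seed = seed)
  out
}

#' Planted column-frequency profile for a synthetic family alignment
#'
#' Background columns mix a majority residue with a few alternatives
#' (moderate conservation); `conserved` columns are single-residue
#' (full conservation); `variable` columns are uniform over the 20 amino
#' acids (no conservation).
#'
#' @param length Alignment length (columns).
#' @param conserved Positions fixed to a single residue.
#' @param variable Positions drawn uniformly over all amino acids.
#' @param seed RNG seed for assigning majority residues.
#' @return A `length` x 20 frequency matrix (rows sum to 1).
#' @export
make_msa_profile <- function(length = 320, conserved = setdiff(300:308, 304:305),
                             variable = 304:305, seed = 1L) {
  set.seed(seed)
  freq <- matrix(0, nrow = length, ncol = 20,
                 dimnames = list(NULL, AA_ALPHABET))
  for (j in seq_len(length)) {
    if (j %in% variable) {
      freq[j, ] <- 1 / 20
    } else if (j %in% conserved) {
      freq[j, sample.int(20, 1)] <- 1
    } else {
      picks <- sample.int(20, 4)
      freq[j, picks] <- c(0.55, 0.15, 0.15, 0.15)
    }
  }
  freq
}

#' Sample a synthetic alignment column-wise from a frequency profile
#'
#' @param profile Frequency matrix from [make_msa_profile()].
#' @param n_seqs Number of sequences.
#' @param seed RNG seed.
#' @param path Optional FASTA output path.
#' @return Character vector of aligned sequences (named), invisibly written
#'   to `path` when given; attribute `truth` holds the profile.
#' @export
make_msa <- function(profile, n_seqs = 50, seed = 1L, path = NULL) {
  set.seed(seed)
  L <- nrow(profile)
  cols <- vapply(seq_len(L), function(j) {
    sample(AA_ALPHABET, n_seqs, replace = TRUE, prob = profile[j, ])
  }, character(n_seqs))
  seqs <- apply(cols, 1, paste0, collapse = "")
  names(seqs) <- paste0("seq", seq_len(n_seqs))
  if (!is.null(path)) {
    writeLines(paste0(">", names(seqs), "\n", seqs), path)
  }
  attr(seqs, "truth") <- list(seed = seed, n_seqs = n_seqs)
  seqs
}

#' Simulate an amine-release time course with background
#'
#' Integrates a saturating release model: enzymatic release
#' A * (1 - exp(-k t)) scaled by enzyme load, plus a linear non-enzymatic
#' background, plus Gaussian noise. With zero enzyme the sample reproduces
#' the background series.
#'
#' @param times Time points (h).
#' @param enzyme_mg_per_L Enzyme mass concentration; 0 gives pure background.
#' @param rate_uM_h Initial enzymatic release rate at the reference load.
#' @param ref_mg_per_L Reference enzyme load for `rate_uM_h`.
#' @param k_sat Saturation rate constant (1/h).
#' @param background_uM_h Linear background release rate.
#' @param noise_sd Gaussian noise sd (uM).
#' @param seed RNG seed.
#' @return List with `sample` and `blank` tibbles (`time_h`, `amine_uM`) and
#'   `truth`.
#' @export
make_timecourse <- function(times = c(0, 2, 4, 8, 24, 48, 96, 120),
                            enzyme_mg_per_L = 1.9, rate_uM_h = 50,
                            ref_mg_per_L = 1.9, k_sat = 0.05,
                            background_uM_h = 0.5, noise_sd = 0,
                            seed = 1L) {
  set.seed(seed)
  scale <- enzyme_mg_per_L / ref_mg_per_L
  enz <- scale * (rate_uM_h / k_sat) * (1 - exp(-k_sat * times))
  bg <- background_uM_h * times
  noise <- function(n) if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  list(
    sample = tibble::tibble(time_h = times,
                            amine_uM = pmax(enz + bg + noise(length(times)), 0)),
    blank = tibble::tibble(time_h = times,
                           amine_uM = pmax(bg + noise(length(times)), 0)),
    truth = list(rate_uM_h = rate_uM_h, k_sat = k_sat,
                 background_uM_h = background_uM_h,
                 enzyme_mg_per_L = enzyme_mg_per_L, seed = seed)
  )
}

#' Simulate Michaelis-Menten rate data
#'
#' @param vmax,km True parameters.
#' @param x Predictor values (substrate loading or enzyme concentration).
#' @param noise_cv Relative Gaussian noise on the rates.
#' @param seed RNG seed.
#' @return Tibble `x`, `rate` with attribute `truth`.
#' @export
make_mm_data <- function(vmax = 10, km = 100,
                         x = c(19, 38, 76, 152, 228, 304, 456, 608),
                         noise_cv = 0.05, seed = 1L) {
  set.seed(seed)
  v <- vmax * x / (km + x)
  rate <- v * (1 + stats::rnorm(length(x), 0, noise_cv))
  out <- tibble::tibble(x = x, rate = rate)
  attr(out, "truth") <- list(vmax = vmax, km = km, noise_cv = noise_cv,
                             seed = seed)
  out
}
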