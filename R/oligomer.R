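#' Oligomer substrate specification
#'
#' Describes a polyamide-6 oligomer proxy with `n_units` repeating
#' 6-aminohexanoic-acid (6-AHA) units, one capped terminus mimicking the
#' continuation of the polymer chain and one charged terminus. An acetyl cap
#' (`"Ace"`) pairs with a carboxylate terminus (`"COO-"`, the carboxy-
#' terminus proxy); an N-methylamide cap (`"NMe"`) pairs with an ammonium
#' terminus (`"NH3+"`, the amine-terminus proxy).
#'
#' @param n_units Number of 6-AHA repeat units (>= 1).
#' @param terminus_a Cap: `"Ace"` or `"NMe"`.
#' @param terminus_b Charged terminus: `"COO-"` or `"NH3+"`.
#' @param orientation Orientation label 1 or 2 (mirrored termini during
#'   docking; composition is identical).
#' @return An object of class `pa_oligomer_spec`.
#' @export
oligomer_spec <- function(n_units = 4, terminus_a = c("Ace", "NMe"),
                          terminus_b = c("COO-", "NH3+"), orientation = 1) {
  terminus_a <- match.arg(terminus_a)
  terminus_b <- match.arg(terminus_b)
  if (n_units < 1) stop("n_units must be >= 1")
  ok <- (terminus_a == "Ace" && terminus_b == "COO-") ||
    (terminus_a == "NMe" && terminus_b == "NH3+")
  if (!ok) {
    stop("invalid cap/terminus pairing: Ace pairs with COO- and NMe with ",
         "NH3+ (one capped chain continuation, one charged chain terminus)")
  }
  if (!orientation %in% c(1, 2)) stop("orientation must be 1 or 2")
  structure(list(n_units = as.integer(n_units), terminus_a = terminus_a,
                 terminus_b = terminus_b, orientation = as.integer(orientation)),
            class = "pa_oligomer_spec")
}

#' @export
print.pa_oligomer_spec <- function(x, ...) {
  cat("<pa_oligomer_spec>", oligomer_label(x), "(orientation", x$orientation, ")\n")
  invisible(x)
}

#' Human-readable oligomer label
#'
#' Orientation 2 of the carboxy-terminus proxy is reported with mirrored
#' termini, e.g. `-OOC-[6-AHA]4-Ace`.
#'
#' @param spec A [oligomer_spec()].
#' @return Character label.
#' @export
oligomer_label <- function(spec) {
  core <- paste0("[6-AHA]", spec$n_units)
  if (spec$terminus_a == "Ace") {
    if (spec$orientation == 1) paste0("Ace-", core, "-COO-")
    else paste0("-OOC-", core, "-Ace")
  } else {
    if (spec$orientation == 1) paste0("NMe-", core, "-NH3+")
    else paste0("+H3N-", core, "-NMe")
  }
}

#' Enumerate the two docking orientations of an oligomer
#'
#' Returns the same chemistry with the two orientation labels, i.e. the
#' tetramer entering the pocket with either terminus first.
#'
#' @param spec A [oligomer_spec()].
#' @return List of two specs differing only in `orientation`.
#' @export
enumerate_orientations <- function(spec) {
  lapply(1:2, function(o) {
    s <- spec; s$orientation <- as.integer(o); s
  })
}

# Ideal internal coordinates (Angstrom / degrees), standard amide and
# alkane geometry.
.geom <- list(
  b_cc = 1.52, b_cn_amide = 1.33, b_cn_sp3 = 1.46, b_co = 1.23,
  b_coo = 1.25, b_nh = 1.01, b_ch = 1.09,
  a_sp3 = 111, a_amide_n = 122, a_c_n = 116, a_c_o = 121, a_coo = 117,
  a_h = 109.5, a_nh = 119
)

#' Build an oligomer conformer in 3D
#'
#' Constructs the full-atom oligomer (hydrogens included) from ideal amide
#' and alkane internal coordinates. Amide torsions are frozen trans
#' (omega = 180 degrees); all other backbone torsions are free parameters
#' with an extended all-anti default. The attack-site amide (the bond placed
#' near the catalytic threonine during docking) is the amide closest to the
#' chain centre.
#'
#' @param spec A [oligomer_spec()].
#' @param dihedrals Optional numeric vector of torsions (degrees), one per
#'   rotatable bond in backbone order; default all 180 (extended).
#' @return An object of class `pa_oligomer` with elements `spec`,
#'   `structure` (a [pa_structure()] with group `"substrate"`), `bonds`
#'   (tibble `i`, `j`, `kind`), `rotatable` (tibble with torsion quadruples),
#'   `formal_charge`, `unit_of` (per-atom unit index, 0 for the cap),
#'   `attack_amide` (atom indices of the attack-site C and N) and
#'   `dihedrals` used.
#' @export
build_oligomer <- function(spec, dihedrals = NULL) {
  g <- .geom
  n <- spec$n_units
  ace <- spec$terminus_a == "Ace"

  # --- backbone blueprint: one row per backbone heavy atom -----------------
  bb <- list()
  push <- function(name, resid, resno, unit, r, theta, kind) {
    bb[[length(bb) + 1]] <<- list(name = name, resid = resid, resno = resno,
                                  unit = unit, r = r, theta = theta,
                                  kind = kind)
  }
  if (ace) {
    push("CH3", "ACE", 1L, 0L, NA, NA, NA)
    push("C", "ACE", 1L, 0L, g$b_cc, NA, "single")
    for (i in seq_len(n)) {
      resid <- if (i == n) "AHC" else "AHA"
      rn <- i + 1L
      push("N", resid, rn, i, g$b_cn_amide, g$a_c_n, "amide")
      push("C2", resid, rn, i, g$b_cn_sp3, g$a_amide_n, "single")
      for (k in 3:6) push(paste0("C", k), resid, rn, i, g$b_cc, g$a_sp3, "single")
      push("C", resid, rn, i, g$b_cc, g$a_sp3, "single")
    }
  } else {
    for (i in seq_len(n)) {
      resid <- if (i == 1) "AHN" else "AHA"
      rn <- i
      if (i == 1) {
        push("N", resid, rn, i, NA, NA, NA)
        push("C2", resid, rn, i, g$b_cn_sp3, NA, "single")
      } else {
        push("N", resid, rn, i, g$b_cn_amide, g$a_c_n, "amide")
        push("C2", resid, rn, i, g$b_cn_sp3, g$a_amide_n, "single")
      }
      for (k in 3:6) push(paste0("C", k), resid, rn, i, g$b_cc, g$a_sp3, "single")
      push("C", resid, rn, i, g$b_cc, g$a_sp3, "single")
    }
    push("N", "NME", n + 1L, n + 1L, g$b_cn_amide, g$a_c_n, "amide")
    push("CH3", "NME", n + 1L, n + 1L, g$b_cn_sp3, g$a_amide_n, "single")
  }
  K <- length(bb)
  nm <- vapply(bb, `[[`, "", "name")

  # rotatable backbone bonds: single bonds whose two ends both have heavy
  # degree >= 2 in the final graph (excludes methyl rotors and chain ends)
  heavy_deg_lo <- c(1, rep(2, K - 2), 1)  # backbone-internal degree
  # terminal backbone atoms gain decorations: last C of COO- gets two O
  kind_k <- vapply(bb, function(b) if (is.null(b$kind) || is.na(b$kind)) "seed" else b$kind, "")
  rot_k <- logical(K)  # bond (k-1, k) rotatable?
  for (k in 2:K) {
    if (kind_k[k] != "single") next
    deg_a <- heavy_deg_lo[k - 1] + (nm[k - 1] == "C")  # carbonyl C gains O
    if (k - 1 == K - 1 && !ace) deg_a <- heavy_deg_lo[k - 1] + 0
    deg_b <- heavy_deg_lo[k] + (nm[k] == "C") +
      (k == K && ace)  # terminal carboxylate C gains OXT
    if (deg_a >= 2 && deg_b >= 2) rot_k[k] <- TRUE
  }
  rot_bond_ks <- which(rot_k)  # atom index k: bond between k-1 and k
  n_rot <- length(rot_bond_ks)
  if (is.null(dihedrals)) dihedrals <- rep(180, n_rot)
  if (length(dihedrals) != n_rot) {
    stop("expected ", n_rot, " dihedral values, got ", length(dihedrals))
  }
  phi_of_bond <- rep(180, K)  # phi for axis bond (k-1, k); amide stays 180
  phi_of_bond[rot_bond_ks] <- dihedrals

  # --- place backbone heavy atoms ------------------------------------------
  r2 <- bb[[2]]$r
  th3 <- if (!is.na(bb[[3]]$theta)) bb[[3]]$theta else g$a_sp3
  P <- matrix(0, nrow = K, ncol = 3)
  P[2, ] <- c(r2, 0, 0)
  P[3, ] <- P[2, ] + bb[[3]]$r * c(-cospi(th3 / 180), sinpi(th3 / 180), 0)
  if (K >= 4) {
    for (k in 4:K) {
      # torsion axis is bond (k-2, k-1)
      P[k, ] <- nerf_place(P[k - 3, ], P[k - 2, ], P[k - 1, ],
                           bb[[k]]$r, bb[[k]]$theta, phi_of_bond[k - 1])
    }
  }

  # --- decorations (O, OXT, H) ---------------------------------------------
  atoms <- list(); bonds <- list()
  idx_of_bb <- integer(K)
  add_atom <- function(name, elem, resid, resno, unit, p) {
    atoms[[length(atoms) + 1]] <<- list(name = name, element = elem,
                                        resid = resid, resno = resno,
                                        unit = unit, x = p[1], y = p[2], z = p[3])
    length(atoms)
  }
  add_bond <- function(i, j, kind) {
    bonds[[length(bonds) + 1]] <<- list(i = i, j = j, kind = kind)
  }
  for (k in seq_len(K)) {
    b <- bb[[k]]
    elem <- if (substr(b$name, 1, 1) == "N") "N" else "C"
    idx_of_bb[k] <- add_atom(b$name, elem, b$resid, b$resno, b$unit, P[k, ])
    if (k > 1) add_bond(idx_of_bb[k - 1], idx_of_bb[k], kind_k[k])
  }
  for (k in seq_len(K)) {
    b <- bb[[k]]; me <- idx_of_bb[k]
    if (b$name == "C" && b$resid != "NME") {            # carbonyl / carboxylate C
      if (b$resid != "ACE" && k < K && nm[k + 1] == "N") {  # interior amide C=O
        p <- nerf_place(P[k - 2, ], P[k - 1, ], P[k, ], g$b_co, g$a_c_o,
                        phi_of_bond[k] + 180)
        o <- add_atom("O", "O", b$resid, b$resno, b$unit, p)
        add_bond(me, o, "double")
      } else if (b$resid == "ACE") {                    # acetyl C=O
        p <- nerf_place(P[1, ], P[3, ], P[2, ], g$b_co, 123, 180)
        o <- add_atom("O", "O", b$resid, b$resno, b$unit, p)
        add_bond(me, o, "double")
      } else {                                          # terminal carboxylate
        phi <- phi_of_bond[k]
        p1 <- nerf_place(P[k - 2, ], P[k - 1, ], P[k, ], g$b_coo, g$a_coo, phi)
        p2 <- nerf_place(P[k - 2, ], P[k - 1, ], P[k, ], g$b_coo, g$a_coo, phi + 180)
        o1 <- add_atom("O", "O", b$resid, b$resno, b$unit, p1)
        o2 <- add_atom("OXT", "O", b$resid, b$resno, b$unit, p2)
        add_bond(me, o1, "partial"); add_bond(me, o2, "partial")
      }
    }
    if (b$name == "N") {
      if (b$resid == "AHN") {                           # ammonium NH3+
        for (h in 1:3) {
          p <- nerf_place(P[3, ], P[2, ], P[1, ], g$b_nh, g$a_h, 60 + (h - 1) * 120)
          hi <- add_atom(paste0("H", h), "H", b$resid, b$resno, b$unit, p)
          add_bond(me, hi, "single")
        }
      } else {                                          # planar amide H
        p <- nerf_place(P[k - 2, ], P[k - 1, ], P[k, ], g$b_nh, g$a_nh, 0)
        hi <- add_atom("H", "H", b$resid, b$resno, b$unit, p)
        add_bond(me, hi, "single")
      }
    }
    if (grepl("^C[2-6]$", b$name)) {                    # methylene H pair
      if (k >= 3) {
        refs <- list(P[k - 2, ], P[k - 1, ])
        phi_next <- phi_of_bond[k]  # torsion about bond (k-1, k), as for B[k+1]
      } else {
        # chain-initial CH2 (ammonium terminus): reference down-chain instead
        refs <- list(P[k + 2, ], P[k + 1, ])
        phi_next <- dihedral_angle(P[k + 2, ], P[k + 1, ], P[k, ], P[k - 1, ])
      }
      for (s in c(120, -120)) {
        p <- nerf_place(refs[[1]], refs[[2]], P[k, ], g$b_ch, g$a_h,
                        phi_next + s)
        hi <- add_atom(paste0("H", substr(b$name, 2, 2),
                              if (s > 0) "1" else "2"),
                       "H", b$resid, b$resno, b$unit, p)
        add_bond(me, hi, "single")
      }
    }
    if (b$name == "CH3") {                              # methyl H x3
      if (k == 1) { a <- P[3, ]; bref <- P[2, ] } else { a <- P[k - 2, ]; bref <- P[k - 1, ] }
      for (h in 1:3) {
        p <- nerf_place(a, bref, P[k, ], g$b_ch, g$a_h, 60 + (h - 1) * 120)
        hi <- add_atom(paste0("HH3", h), "H", b$resid, b$resno, b$unit, p)
        add_bond(me, hi, "single")
      }
    }
  }

  at <- dplyr::bind_rows(lapply(atoms, tibble::as_tibble))
  at$serial <- seq_len(nrow(at))
  st <- pa_structure(at[, c("serial", "name", "element", "resid", "resno",
                            "x", "y", "z")],
                     groups = list(substrate = seq_len(nrow(at))))
  bd <- dplyr::bind_rows(lapply(bonds, tibble::as_tibble))

  rot <- tibble::tibble(
    k = rot_bond_ks,
    i = idx_of_bb[rot_bond_ks - 1], j = idx_of_bb[rot_bond_ks],
    a = idx_of_bb[pmax(rot_bond_ks - 2, 1)],
    d = idx_of_bb[pmin(rot_bond_ks + 1, K)],
    unit = vapply(rot_bond_ks, function(k) bb[[k]]$unit, 0L),
    value = dihedrals
  )

  # attack-site amide: the amide bond nearest the chain centre
  amide_rows <- which(bd$kind == "amide")
  unit_of <- at$unit
  if (length(amide_rows) > 0) {
    # central amide: between units n/2 and n/2 + 1 (cap amide for n = 1)
    target <- floor(n / 2) + 1
    cen <- amide_rows[which.min(abs(unit_of[bd$j[amide_rows]] - target))]
    attack <- c(C = bd$i[cen], N = bd$j[cen])
  } else {
    attack <- c(C = NA_integer_, N = NA_integer_)
  }

  structure(list(
    spec = spec, structure = st,
    bonds = bd, rotatable = rot,
    formal_charge = if (spec$terminus_b == "COO-") -1L else 1L,
    unit_of = unit_of, backbone = idx_of_bb,
    attack_amide = attack, dihedrals = dihedrals
  ), class = "pa_oligomer")
}

#' @export
print.pa_oligomer <- function(x, ...) {
  cat("<pa_oligomer>", oligomer_label(x$spec), "-", n_atoms(x$structure),
      "atoms,", nrow(x$rotatable), "rotatable bonds, formal charge",
      x$formal_charge, "\n")
  invisible(x)
}

#' Heavy-atom indices of an oligomer
#' @param olig A `pa_oligomer`.
#' @return Integer atom indices of non-hydrogen atoms.
#' @export
heavy_atoms <- function(olig) which(olig$structure$atoms$element != "H")

# pairs of atoms separated by >= 3 bonds ("nonbonded" for clash purposes)
bonded_exclusions <- function(olig) {
  n <- n_atoms(olig$structure)
  adj <- vector("list", n)
  for (r in seq_len(nrow(olig$bonds))) {
    i <- olig$bonds$i[r]; j <- olig$bonds$j[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  excl <- new.env()
  for (i in seq_len(n)) {
    one <- adj[[i]]
    two <- unique(unlist(adj[one]))
    for (j in unique(c(one, two))) {
      if (j != i) assign(paste(min(i, j), max(i, j)), TRUE, envir = excl)
    }
  }
  excl
}

#' Check an oligomer conformer for internal steric clash
#'
#' @param olig A `pa_oligomer`.
#' @param threshold Heavy-atom clash distance in Angstrom.
#' @param xyz Optional replacement coordinates (n x 3).
#' @param idx Optional atom subset to restrict the check to.
#' @return TRUE if any nonbonded heavy-atom pair (separated by three or more
#'   bonds) is closer than `threshold`.
#' @export
has_internal_clash <- function(olig, threshold = 2.0, xyz = NULL, idx = NULL) {
  hv <- heavy_atoms(olig)
  if (!is.null(idx)) hv <- intersect(hv, idx)
  m <- if (is.null(xyz)) coords(olig$structure, hv) else xyz[hv, , drop = FALSE]
  excl <- bonded_exclusions(olig)
  d <- cross_dist(m, m)
  close <- which(d < threshold & upper.tri(d), arr.ind = TRUE)
  for (r in seq_len(nrow(close))) {
    i <- hv[close[r, 1]]; j <- hv[close[r, 2]]
    if (!exists(paste(min(i, j), max(i, j)), envir = excl)) return(TRUE)
  }
  FALSE
}
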