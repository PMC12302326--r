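#' Molecular structure container
#'
#' A `pa_structure` bundles an atom table with named atom-index groups
#' (e.g. `"enzyme"`, `"substrate"`, `"catalytic_triad"`). The atom table is a
#' tibble with one row per atom and columns `serial`, `name`, `element`,
#' `resid` (residue name), `resno` (1-based residue number, kept verbatim
#' from the input file so positions such as T267 or F134 address correctly),
#' `chain`, `x`, `y`, `z` (Angstrom), `charge` (e), `sigma` (Angstrom) and
#' `epsilon` (kJ/mol). Charges and Lennard-Jones parameters are `NA` until
#' [assign_nonbonded()] is called.
#'
#' @param atoms A data frame with at least `serial`, `name`, `resid`,
#'   `resno`, `x`, `y`, `z`. Missing optional columns are filled.
#' @param groups Named list of integer atom indices (rows of `atoms`).
#' @return An object of class `pa_structure`.
#' @export
pa_structure <- function(atoms, groups = list()) {
  atoms <- tibble::as_tibble(atoms)
  defaults <- list(element = NA_character_, chain = "A",
                   charge = NA_real_, sigma = NA_real_, epsilon = NA_real_)
  for (nm in names(defaults)) {
    if (!nm %in% names(atoms)) atoms[[nm]] <- defaults[[nm]]
  }
  atoms$element <- ifelse(is.na(atoms$element) | atoms$element == "",
                          guess_element(atoms$name), atoms$element)
  req <- c("serial", "name", "resid", "resno", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(atoms$serial)) stop("atom serials must be unique")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("atom coordinates must be finite")
  }
  if (any(atoms$resno < 1)) stop("residue numbers must be >= 1")
  atoms <- atoms[, c("serial", "name", "element", "resid", "resno", "chain",
                     "x", "y", "z", "charge", "sigma", "epsilon")]
  n <- nrow(atoms)
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (length(idx) && (any(idx < 1) || any(idx > n))) {
      stop("group '", g, "' has out-of-range atom indices")
    }
  }
  if (all(c("enzyme", "substrate") %in% names(groups)) &&
      length(intersect(groups$enzyme, groups$substrate)) > 0) {
    stop("'enzyme' and 'substrate' groups must be disjoint")
  }
  structure(list(atoms = atoms, groups = groups), class = "pa_structure")
}

#' @export
print.pa_structure <- function(x, ...) {
  cat("<pa_structure> ", nrow(x$atoms), " atoms, ",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), " residues\n", sep = "")
  if (length(x$groups)) {
    cat("groups:", paste0(names(x$groups), " (", lengths(x$groups), ")",
                          collapse = ", "), "\n")
  }
  print(x$atoms, n = 5)
  invisible(x)
}

#' Number of atoms in a structure
#' @param x A `pa_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' Coordinates of a structure as a matrix
#' @param x A `pa_structure`.
#' @param idx Optional atom indices.
#' @return Numeric matrix n x 3 (Angstrom).
#' @export
coords <- function(x, idx = NULL) {
  m <- as.matrix(x$atoms[, c("x", "y", "z")])
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

#' Replace coordinates of a structure
#' @param x A `pa_structure`.
#' @param m Numeric n x 3 matrix.
#' @return The structure with updated coordinates.
#' @export
set_coords <- function(x, m) {
  stopifnot(nrow(m) == n_atoms(x), ncol(m) == 3)
  x$atoms$x <- m[, 1]; x$atoms$y <- m[, 2]; x$atoms$z <- m[, 3]
  x
}

#' Atom indices of a named group
#' @param x A `pa_structure`.
#' @param name Group name.
#' @return Integer vector of atom indices.
#' @export
group_idx <- function(x, name) {
  if (!name %in% names(x$groups)) {
    stop("structure has no group '", name, "' (available: ",
         paste(names(x$groups), collapse = ", "), ")")
  }
  x$groups[[name]]
}

#' Define a group from residue numbers
#' @param x A `pa_structure`.
#' @param name Group name to create.
#' @param resno Residue numbers to include.
#' @return The structure with the group added.
#' @export
add_group <- function(x, name, resno) {
  x$groups[[name]] <- which(x$atoms$resno %in% resno)
  x
}

guess_element <- function(name) {
  # PDB convention: strip digits and take the leading letter(s)
  core <- sub("^[0-9 ]*", "", name)
  two <- toupper(substr(core, 1, 2))
  el <- ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "CA"),
               two, toupper(substr(core, 1, 1)))
  substr(el, 1, 1) <- toupper(substr(el, 1, 1))
  ifelse(nchar(el) == 2,
         paste0(substr(el, 1, 1), tolower(substr(el, 2, 2))), el)
}

# ---- PDB / XYZ readers -----------------------------------------------------

parse_pdb_atom_lines <- function(lines, line_no) {
  num <- function(s, what, ln) {
    v <- suppressWarnings(as.numeric(s))
    bad <- is.na(v) & !grepl("^\\s*$", s)
    bad <- bad | is.na(v)
    if (any(is.na(v))) {
      stop("malformed PDB ", what, " field at line ", ln[which(is.na(v))[1]])
    }
    v
  }
  pad <- function(l) formatC(l, width = 80, flag = "-")
  lines <- vapply(lines, pad, "", USE.NAMES = FALSE)
  tibble::tibble(
    serial = as.integer(num(substr(lines, 7, 11), "serial", line_no)),
    name = trimws(substr(lines, 13, 16)),
    resid = trimws(substr(lines, 18, 20)),
    chain = trimws(substr(lines, 22, 22)),
    resno = as.integer(num(substr(lines, 23, 26), "residue number", line_no)),
    x = num(substr(lines, 31, 38), "x", line_no),
    y = num(substr(lines, 39, 46), "y", line_no),
    z = num(substr(lines, 47, 54), "z", line_no),
    element = trimws(substr(lines, 77, 78))
  )
}

#' Read a structure from PDB or XYZ
#'
#' Atom order and residue numbering are preserved verbatim; no renumbering is
#' performed. For multi-model PDB files the first model is returned (use
#' [read_trajectory()] for all frames). Unknown elements are inferred from
#' atom names with a warning.
#'
#' @param path File path.
#' @param format `"pdb"`, `"xyz"` or `"auto"` (by extension).
#' @return A [pa_structure()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") {
    lines <- readLines(path)
    is_atom <- grepl("^(ATOM  |HETATM)", lines)
    end1 <- c(which(grepl("^ENDMDL", lines)), length(lines) + 1L)[1]
    sel <- which(is_atom & seq_along(lines) < end1)
    if (length(sel) == 0) stop("no ATOM/HETATM records in ", path)
    atoms <- parse_pdb_atom_lines(lines[sel], sel)
    if (any(atoms$element == "")) {
      warning("element column empty for some atoms; inferred from atom names")
      atoms$element[atoms$element == ""] <- NA_character_
    }
    pa_structure(atoms)
  } else {
    fr <- read_xyz_frames(path)
    at <- fr$atoms
    tb <- tibble::tibble(serial = seq_len(nrow(at)), name = at$name,
                         resid = "UNK", resno = 1L, chain = "A",
                         x = fr$frames[[1]][, 1], y = fr$frames[[1]][, 2],
                         z = fr$frames[[1]][, 3])
    pa_structure(tb)
  }
}

read_xyz_frames <- function(path) {
  lines <- readLines(path)
  i <- 1L; frames <- list(); names_ref <- NULL; fidx <- 0L
  while (i <= length(lines)) {
    if (grepl("^\\s*$", lines[i])) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    fidx <- fidx + 1L
    if (is.na(n)) stop("malformed XYZ atom-count at line ", i)
    if (i + 1L + n > length(lines)) stop("truncated XYZ frame ", fidx)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    if (any(lengths(parts) < 4)) {
      stop("malformed XYZ record at line ", i + 1L + which(lengths(parts) < 4)[1])
    }
    nm <- vapply(parts, `[[`, "", 1)
    m <- matrix(as.numeric(unlist(lapply(parts, function(p) p[2:4]))),
                ncol = 3, byrow = TRUE)
    if (is.null(names_ref)) names_ref <- nm
    frames[[fidx]] <- m
    i <- i + 2L + n
  }
  list(atoms = tibble::tibble(name = names_ref), frames = frames)
}

#' Write a structure to PDB or XYZ
#'
#' @param x A `pa_structure`.
#' @param path Output path.
#' @param format `"pdb"`, `"xyz"` or `"auto"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  if (format == "pdb") {
    writeLines(format_pdb_lines(x$atoms), path)
  } else {
    writeLines(format_xyz_block(x$atoms$name, coords(x)), path)
  }
  invisible(path)
}

format_pdb_lines <- function(atoms, end = TRUE) {
  nm <- ifelse(nchar(atoms$name) <= 3, paste0(" ", atoms$name), atoms$name)
  out <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 atoms$serial, nm, atoms$resid, atoms$chain, atoms$resno,
                 atoms$x, atoms$y, atoms$z, 1, 0, atoms$element)
  if (end) c(out, "END") else out
}

format_xyz_block <- function(names, m, comment = "") {
  c(as.character(nrow(m)), comment,
    sprintf("%-4s %12.6f %12.6f %12.6f", names, m[, 1], m[, 2], m[, 3]))
}

# ---- Trajectories ----------------------------------------------------------

#' Trajectory container
#'
#' An ordered stack of coordinate frames over a fixed topology.
#'
#' @param structure A [pa_structure()] giving the topology (frame 1 need not
#'   equal its coordinates).
#' @param frames List of n_atoms x 3 matrices (Angstrom).
#' @param dt Frame spacing in ps.
#' @param replica_id Integer replica label.
#' @return An object of class `pa_trajectory`.
#' @export
pa_trajectory <- function(structure, frames, dt = 1, replica_id = 1L) {
  if (length(frames) < 1) stop("a trajectory needs at least one frame")
  if (dt <= 0) stop("dt must be positive")
  n <- n_atoms(structure)
  for (k in seq_along(frames)) {
    if (nrow(frames[[k]]) != n) {
      stop("frame ", k, " has ", nrow(frames[[k]]), " atoms, topology has ", n)
    }
  }
  structure(list(structure = structure, frames = frames, dt = dt,
                 replica_id = as.integer(replica_id)),
            class = "pa_trajectory")
}

#' @export
print.pa_trajectory <- function(x, ...) {
  cat("<pa_trajectory> ", length(x$frames), " frames x ",
      n_atoms(x$structure), " atoms, dt = ", x$dt, " ps, replica ",
      x$replica_id, "\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param x A `pa_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) length(x$frames)

#' Read a trajectory from a multi-model PDB or concatenated XYZ stack
#'
#' @param path File path.
#' @param topology A [pa_structure()] whose atom count every frame must match.
#' @param dt Frame spacing in ps.
#' @param replica_id Replica label.
#' @param format `"pdb"`, `"xyz"` or `"auto"`.
#' @return A [pa_trajectory()].
#' @export
read_trajectory <- function(path, topology, dt = 1, replica_id = 1L,
                            format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  n <- n_atoms(topology)
  if (format == "pdb") {
    lines <- readLines(path)
    model_starts <- which(grepl("^MODEL", lines))
    is_atom <- grepl("^(ATOM  |HETATM)", lines)
    if (length(model_starts) == 0) {
      frames <- list(as.matrix(parse_pdb_atom_lines(lines[is_atom],
                                                    which(is_atom))[, c("x", "y", "z")]))
    } else {
      ends <- which(grepl("^ENDMDL", lines))
      if (length(ends) < length(model_starts)) ends <- c(ends, length(lines))
      frames <- vector("list", length(model_starts))
      for (k in seq_along(model_starts)) {
        sel <- which(is_atom & seq_along(lines) > model_starts[k] &
                       seq_along(lines) < ends[k])
        frames[[k]] <- as.matrix(parse_pdb_atom_lines(lines[sel], sel)[, c("x", "y", "z")])
      }
    }
  } else {
    frames <- read_xyz_frames(path)$frames
  }
  for (k in seq_along(frames)) {
    if (nrow(frames[[k]]) != n) {
      stop("frame ", k, " has ", nrow(frames[[k]]),
           " atoms but topology has ", n)
    }
  }
  pa_trajectory(topology, frames, dt = dt, replica_id = replica_id)
}

#' Write a trajectory as multi-model PDB or concatenated XYZ
#'
#' @param traj A `pa_trajectory`.
#' @param path Output path.
#' @param format `"pdb"`, `"xyz"` or `"auto"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  at <- traj$structure$atoms
  if (format == "pdb") {
    out <- unlist(lapply(seq_along(traj$frames), function(k) {
      a2 <- at
      a2$x <- traj$frames[[k]][, 1]; a2$y <- traj$frames[[k]][, 2]
      a2$z <- traj$frames[[k]][, 3]
      c(sprintf("MODEL     %4d", k), format_pdb_lines(a2, end = FALSE), "ENDMDL")
    }))
    writeLines(c(out, "END"), path)
  } else {
    out <- unlist(lapply(seq_along(traj$frames), function(k) {
      format_xyz_block(at$name, traj$frames[[k]], comment = paste("frame", k))
    }))
    writeLines(out, path)
  }
  invisible(path)
}

# ---- Nonbonded parameter tables --------------------------------------------

#' Read a nonbonded parameter table
#'
#' A delimited text file with header `residue,atom,charge,sigma,epsilon`
#' mapping (residue name, atom name) to partial charge (e), Lennard-Jones
#' sigma (Angstrom) and epsilon (kJ/mol). Lorentz-Berthelot combination is
#' assumed throughout the package.
#'
#' @param path File path (comma-, tab- or whitespace-delimited).
#' @param formal_charges Optional named numeric vector of formal charges per
#'   residue name; when given, each residue's summed partial charge is
#'   checked against it (tolerance 1e-6 e).
#' @return A tibble of class `pa_nonbonded`.
#' @export
read_nonbonded <- function(path, formal_charges = NULL) {
  tb <- utils::read.table(path, header = TRUE, sep = "",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tb) == 1) {  # comma-delimited
    tb <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  }
  names(tb) <- tolower(names(tb))
  pa_nonbonded(tibble::as_tibble(tb), formal_charges = formal_charges)
}

#' Construct a nonbonded parameter table
#' @param tb Data frame with columns `residue`, `atom`, `charge`, `sigma`,
#'   `epsilon`.
#' @param formal_charges Optional named vector of per-residue formal charges
#'   to validate against.
#' @return A tibble of class `pa_nonbonded`.
#' @export
pa_nonbonded <- function(tb, formal_charges = NULL) {
  req <- c("residue", "atom", "charge", "sigma", "epsilon")
  if (!all(req %in% names(tb))) {
    stop("nonbonded table needs columns: ", paste(req, collapse = ", "))
  }
  if (any(tb$sigma < 0) || any(tb$epsilon < 0)) {
    stop("sigma and epsilon must be non-negative")
  }
  if (anyDuplicated(tb[, c("residue", "atom")])) {
    stop("duplicate (residue, atom) entries in nonbonded table")
  }
  if (!is.null(formal_charges)) {
    sums <- tapply(tb$charge, tb$residue, sum)
    for (res in names(formal_charges)) {
      if (res %in% names(sums) &&
          abs(sums[[res]] - formal_charges[[res]]) > 1e-6) {
        stop("residue ", res, " partial charges sum to ",
             format(sums[[res]]), ", expected formal charge ",
             formal_charges[[res]])
      }
    }
  }
  class(tb) <- c("pa_nonbonded", class(tibble::as_tibble(tb)))
  tb
}

#' Write a nonbonded table as TSV
#' @param tb A `pa_nonbonded` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nonbonded <- function(tb, path) {
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign charges and Lennard-Jones parameters to a structure
#'
#' Looks every atom up by (residue name, atom name) in a nonbonded table and
#' sets `charge`, `sigma` and `epsilon`. All missing keys are collected and
#' reported in a single error.
#'
#' @param x A [pa_structure()].
#' @param table A [pa_nonbonded()] table.
#' @return The structure with parameters assigned.
#' @export
assign_nonbonded <- function(x, table) {
  key_s <- paste(x$atoms$resid, x$atoms$name, sep = "/")
  key_t <- paste(table$residue, table$atom, sep = "/")
  hit <- match(key_s, key_t)
  if (anyNA(hit)) {
    miss <- sort(unique(key_s[is.na(hit)]))
    stop("nonbonded table is missing ", length(miss), " (residue/atom) key(s): ",
         paste(miss, collapse = ", "))
  }
  x$atoms$charge <- table$charge[hit]
  x$atoms$sigma <- table$sigma[hit]
  x$atoms$epsilon <- table$epsilon[hit]
  x
}
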