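#' @useDynLib nbens, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif sd setNames convolve
#' @importFrom utils read.table write.table
NULL

# ---- core containers ------------------------------------------------------

#' Construct a single structure model
#'
#' A `structure_model` holds an atom table (PDB naming conventions) and an
#' n_atoms x 3 coordinate matrix in Angstrom. Residue numbering is 1-based and
#' taken verbatim from the source records; no renumbering is ever applied.
#'
#' @param atoms data.frame with columns `name`, `element`, `residue_index`
#'   (integer, >= 1), `residue_name` (3-letter code).
#' @param coords numeric matrix, `nrow(atoms)` x 3, Angstrom.
#' @param model_id integer model identifier.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, coords, model_id = 1L) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "residue_index", "residue_name") %in% names(atoms)))
  if (is.null(atoms$element)) {
    atoms$element <- guess_element(atoms$name)
  }
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(atoms) || ncol(coords) != 3) {
    stop("coords must be an n_atoms x 3 matrix matching the atom table")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (any(atoms$residue_index < 1)) stop("residue_index must be >= 1")
  key <- paste(atoms$residue_index, atoms$name)
  if (anyDuplicated(key)) {
    stop("duplicate (residue_index, atom_name) pair: ",
         key[duplicated(key)][1L])
  }
  structure(list(atoms = atoms, coords = coords,
                 model_id = as.integer(model_id)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> model %d: %d atoms, residues %d-%d\n",
              x$model_id, nrow(x$atoms), min(x$atoms$residue_index),
              max(x$atoms$residue_index)))
  invisible(x)
}

#' Construct an ensemble of structure models
#'
#' All models must share one atom count and ordering (the invariant that makes
#' per-atom comparison across an NMR-style multi-model ensemble meaningful).
#'
#' @param models list of [structure_model()] objects.
#' @param source_label free-text provenance label.
#' @return object of class `ensemble`.
#' @export
ensemble <- function(models, source_label = "") {
  stopifnot(length(models) >= 1)
  ref <- models[[1L]]$atoms
  for (i in seq_along(models)) {
    m <- models[[i]]
    if (nrow(m$atoms) != nrow(ref)) {
      stop(sprintf("model %d has %d atoms but model %d has %d",
                   m$model_id, nrow(m$atoms), models[[1L]]$model_id,
                   nrow(ref)))
    }
    if (!identical(m$atoms$name, ref$name) ||
        !identical(m$atoms$residue_index, ref$residue_index)) {
      stop(sprintf("model %d atom ordering differs from model %d",
                   m$model_id, models[[1L]]$model_id))
    }
  }
  structure(list(models = models, source_label = source_label),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> '%s': %d models x %d atoms\n", x$source_label,
              length(x$models), nrow(x$models[[1L]]$atoms)))
  invisible(x)
}

#' Number of models in an ensemble
#' @param ens an [ensemble()].
#' @return integer count.
#' @export
n_models <- function(ens) length(ens$models)

#' Construct a trajectory
#'
#' The substrate of every observable: ordered frames with a fixed time step.
#' Four payload kinds are supported: `cartesian` (n_frames x n_atoms x 3,
#' Angstrom), `torsion` (n_frames x k, degrees), `vector` (n_frames x n_vec x
#' 3 unit vectors), `scalar` (n_frames x k numeric, e.g. a collective
#' variable or a 1-D particle position).
#'
#' @param data array/matrix as described above.
#' @param dt time per frame, ps (> 0).
#' @param kind one of `"cartesian"`, `"torsion"`, `"vector"`, `"scalar"`.
#' @param topology optional reference [structure_model()] (cartesian kind).
#' @param labels optional column/vector labels (torsion / vector kinds).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(data, dt = 1, kind = c("cartesian", "torsion",
                                              "vector", "scalar"),
                       topology = NULL, labels = NULL) {
  kind <- match.arg(kind)
  if (dt <= 0) stop("dt must be > 0")
  if (kind %in% c("cartesian", "vector")) {
    if (length(dim(data)) == 2L && ncol(data) == 3L) {
      data <- array(data, dim = c(nrow(data), 1L, 3L))
    }
    stopifnot(length(dim(data)) == 3L, dim(data)[3L] == 3L)
    if (kind == "cartesian" && !is.null(topology) &&
        dim(data)[2L] != nrow(topology$atoms)) {
      stop("frame atom count does not match topology atom count")
    }
  } else {
    data <- as.matrix(data)
  }
  n <- dim(data)[1L]
  if (n < 1) stop("trajectory needs at least one frame")
  structure(list(data = data, dt = dt, kind = kind, topology = topology,
                 labels = labels),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> kind=%s: %d frames, dt=%g ps\n", x$kind,
              n_frames(x), x$dt))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$data)[1L]

#' Extract one frame of a cartesian trajectory as a structure model
#' @param traj cartesian [trajectory()] with a topology.
#' @param i frame index.
#' @return a [structure_model()].
#' @export
frame_model <- function(traj, i) {
  stopifnot(traj$kind == "cartesian", !is.null(traj$topology))
  structure_model(traj$topology$atoms, traj$data[i, , , drop = TRUE],
                  model_id = i)
}

#' Convert an ensemble to a cartesian trajectory (dt = 1 frame)
#' @param ens an [ensemble()].
#' @return a cartesian [trajectory()] whose topology is the first model.
#' @export
ensemble_to_trajectory <- function(ens) {
  nm <- length(ens$models)
  na <- nrow(ens$models[[1L]]$atoms)
  arr <- array(0, dim = c(nm, na, 3L))
  for (i in seq_len(nm)) arr[i, , ] <- ens$models[[i]]$coords
  trajectory(arr, dt = 1, kind = "cartesian", topology = ens$models[[1L]])
}

guess_element <- function(name) {
  stripped <- sub("^[0-9']+", "", name)
  el <- substr(stripped, 1L, 1L)
  el[el == ""] <- "X"
  el
}

# ---- PDB I/O --------------------------------------------------------------

#' Read a multi-model PDB file
#'
#' Parses ATOM records from a wwPDB v3.3 fixed-width file. MODEL/ENDMDL blocks
#' become one [structure_model()] each; a file without MODEL records yields a
#' single-model ensemble. Alternate locations: 'A' or blank are kept, others
#' dropped (count reported via message).
#'
#' @param path file path.
#' @param source_label label stored on the returned ensemble (default: path).
#' @return an [ensemble()].
#' @export
read_multimodel_pdb <- function(path, source_label = path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  models <- list()
  cur_lines <- integer(0)
  cur_id <- NA_integer_
  n_alt_dropped <- 0L
  flush_model <- function(line_idx, model_id) {
    if (length(line_idx) == 0L) return(NULL)
    ll <- lines[line_idx]
    alt <- substr(ll, 17L, 17L)
    keep <- alt %in% c(" ", "", "A")
    n_alt_dropped <<- n_alt_dropped + sum(!keep)
    ll <- ll[keep]; line_idx <- line_idx[keep]
    name <- trimws(substr(ll, 13L, 16L))
    resname <- trimws(substr(ll, 18L, 20L))
    resi <- suppressWarnings(as.integer(substr(ll, 23L, 26L)))
    xyz <- cbind(suppressWarnings(as.numeric(substr(ll, 31L, 38L))),
                 suppressWarnings(as.numeric(substr(ll, 39L, 46L))),
                 suppressWarnings(as.numeric(substr(ll, 47L, 54L))))
    bad <- which(!is.finite(rowSums(xyz)) | is.na(resi))
    if (length(bad) > 0L) {
      stop(sprintf("unreadable coordinates at line %d of %s",
                   line_idx[bad[1L]], path))
    }
    element <- trimws(substr(ll, 77L, 78L))
    element[element == ""] <- guess_element(name[element == ""])
    structure_model(
      data.frame(name = name, element = element, residue_index = resi,
                 residue_name = resname, stringsAsFactors = FALSE),
      xyz, model_id = model_id)
  }
  next_id <- 1L
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (r == "MODEL ") {
      cur_id <- suppressWarnings(as.integer(trimws(substr(lines[i], 7L, 14L))))
      if (is.na(cur_id)) cur_id <- next_id
      cur_lines <- integer(0)
    } else if (r == "ENDMDL") {
      m <- flush_model(cur_lines, cur_id)
      if (!is.null(m)) { models[[length(models) + 1L]] <- m; next_id <- next_id + 1L }
      cur_lines <- integer(0); cur_id <- NA_integer_
    } else if (r %in% c("ATOM  ", "HETATM")) {
      cur_lines <- c(cur_lines, i)
      if (is.na(cur_id)) cur_id <- next_id
    }
  }
  m <- flush_model(cur_lines, if (is.na(cur_id)) next_id else cur_id)
  if (!is.null(m)) models[[length(models) + 1L]] <- m
  if (length(models) == 0L) stop("no ATOM records found in ", path)
  if (n_alt_dropped > 0L) {
    message(sprintf("dropped %d alternate-location records", n_alt_dropped))
  }
  nat <- vapply(models, function(m) nrow(m$atoms), integer(1))
  if (length(unique(nat)) != 1L) {
    off <- which(nat != nat[1L])[1L]
    stop(sprintf("inconsistent atom count across models: model %d has %d atoms, model %d has %d",
                 models[[off]]$model_id, nat[off], models[[1L]]$model_id, nat[1L]))
  }
  ensemble(models, source_label = source_label)
}

#' Write an ensemble (or single model) as a multi-model PDB file
#'
#' @param x an [ensemble()] or [structure_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(x, path) {
  if (inherits(x, "structure_model")) x <- ensemble(list(x))
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(x$models) > 1L
  for (m in x$models) {
    if (multi) writeLines(sprintf("MODEL     %4d", m$model_id), con)
    nm <- m$atoms$name
    nm4 <- ifelse(nchar(nm) < 4L, sprintf(" %-3s", nm), substr(nm, 1L, 4L))
    lines <- sprintf(
      "ATOM  %5d %4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(m$atoms)), nm4, m$atoms$residue_name, "A",
      m$atoms$residue_index, m$coords[, 1L], m$coords[, 2L], m$coords[, 3L],
      1.00, 0.00, m$atoms$element)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- trajectory table I/O -------------------------------------------------

#' Write a cartesian trajectory as a plain coordinate table
#'
#' Minimal interchange format: whitespace-separated columns
#' `frame atom x y z`, one row per atom per frame, plus a `# dt=<ps>` header.
#'
#' @param traj cartesian [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_traj_table <- function(traj, path) {
  stopifnot(traj$kind == "cartesian")
  nf <- n_frames(traj); na <- dim(traj$data)[2L]
  comp <- function(k) as.vector(t(matrix(traj$data[, , k], nrow = nf)))
  df <- data.frame(frame = rep(seq_len(nf), each = na),
                   atom = rep(seq_len(na), times = nf),
                   x = comp(1L), y = comp(2L), z = comp(3L))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# dt=%.10g", traj$dt), con)
  write.table(format(df, scientific = FALSE, trim = TRUE), con,
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a plain coordinate-table trajectory
#' @param path file written by [write_traj_table()] (or CSV with the same
#'   columns).
#' @param topology optional [structure_model()] to attach.
#' @return a cartesian [trajectory()].
#' @export
read_traj_table <- function(path, topology = NULL) {
  first <- readLines(path, n = 1L)
  dt <- 1
  if (grepl("^#\\s*dt=", first)) dt <- as.numeric(sub("^#\\s*dt=", "", first))
  sep <- if (grepl(",", readLines(path, n = 2L)[2L])) "," else ""
  df <- read.table(path, header = TRUE, comment.char = "#", sep = sep)
  nf <- max(df$frame); na <- max(df$atom)
  ord <- order(df$frame, df$atom)
  df <- df[ord, ]
  arr <- array(0, dim = c(nf, na, 3L))
  arr[cbind(df$frame, df$atom, 1L)] <- df$x
  arr[cbind(df$frame, df$atom, 2L)] <- df$y
  arr[cbind(df$frame, df$atom, 3L)] <- df$z
  trajectory(arr, dt = dt, kind = "cartesian", topology = topology)
}

# ---- distance restraints --------------------------------------------------

#' Construct a distance restraint
#'
#' Groups with more than one atom selector represent pseudoatoms (degenerate
#' proton groups); their distances are combined by r^-6 averaging downstream.
#'
#' @param group_a,group_b data.frames with columns `residue_index`,
#'   `residue_name`, `atom_name` (>= 1 row each, disjoint).
#' @param upper_limit upper bound, Angstrom (> 0).
#' @param kind `"noe"` or `"hbond"`.
#' @return object of class `distance_restraint`.
#' @export
distance_restraint <- function(group_a, group_b, upper_limit,
                               kind = c("noe", "hbond")) {
  kind <- match.arg(kind)
  if (!is.finite(upper_limit) || upper_limit <= 0) {
    stop("upper_limit must be a positive number")
  }
  ga <- as.data.frame(group_a, stringsAsFactors = FALSE)
  gb <- as.data.frame(group_b, stringsAsFactors = FALSE)
  if (nrow(ga) < 1L || nrow(gb) < 1L) stop("restraint groups must be non-empty")
  ka <- paste(ga$residue_index, ga$atom_name)
  kb <- paste(gb$residue_index, gb$atom_name)
  if (length(intersect(ka, kb)) > 0L) stop("restraint groups must be disjoint")
  structure(list(group_a = ga, group_b = gb, upper_limit = upper_limit,
                 kind = kind),
            class = "distance_restraint")
}

# CYANA-style pseudoatom expansion. Keyed "RES:CODE" with a code-only
# fallback; unknown codes are hard errors (silent skipping would corrupt
# violation counts).
.pseudoatom_table <- local({
  tab <- list(
    "GLY:QA" = c("HA2", "HA3"),
    "ALA:QB" = c("HB1", "HB2", "HB3"),
    "ILE:QG1" = c("HG12", "HG13"),
    "VAL:QG1" = c("HG11", "HG12", "HG13"),
    "ASN:QD2" = c("HD21", "HD22"),
    "GLN:QE2" = c("HE21", "HE22"),
    "PHE:QD" = c("HD1", "HD2"), "PHE:QE" = c("HE1", "HE2"),
    "TYR:QD" = c("HD1", "HD2"), "TYR:QE" = c("HE1", "HE2"),
    "MET:QE" = c("HE1", "HE2", "HE3"),
    "LYS:QZ" = c("HZ1", "HZ2", "HZ3"),
    "ARG:QH1" = c("HH11", "HH12"), "ARG:QH2" = c("HH21", "HH22"),
    "QA" = c("HA2", "HA3"),
    "QB" = c("HB2", "HB3"),
    "QG" = c("HG2", "HG3"),
    "QD" = c("HD2", "HD3"),
    "QE" = c("HE2", "HE3"),
    "QD1" = c("HD11", "HD12", "HD13"),
    "QD2" = c("HD21", "HD22", "HD23"),
    "QG2" = c("HG21", "HG22", "HG23"),
    "QQD" = c("HD11", "HD12", "HD13", "HD21", "HD22", "HD23"),
    "QQG" = c("HG11", "HG12", "HG13", "HG21", "HG22", "HG23"))
  tab
})

expand_pseudoatom <- function(residue_name, atom_name) {
  if (!startsWith(atom_name, "Q")) return(atom_name)
  hit <- .pseudoatom_table[[paste0(residue_name, ":", atom_name)]]
  if (is.null(hit)) hit <- .pseudoatom_table[[atom_name]]
  if (is.null(hit)) {
    stop(sprintf("unknown pseudoatom code '%s' (residue %s)", atom_name,
                 residue_name))
  }
  hit
}

upl_group <- function(resi, resn, atom) {
  protons <- expand_pseudoatom(resn, atom)
  data.frame(residue_index = resi, residue_name = resn, atom_name = protons,
             stringsAsFactors = FALSE)
}

#' Parse a CYANA-style .upl upper-limit restraint file
#'
#' Whitespace-separated columns: residue_index residue_name atom_name
#' residue_index residue_name atom_name upper_limit(Angstrom). Pseudoatom
#' names beginning with 'Q' are expanded to their proton group via a built-in
#' table; unknown codes raise an error. Restraints whose atoms are not all
#' protons (e.g. an amide H to a carbonyl O) are classified `kind = "hbond"`.
#'
#' @param path file path; lines starting with `#` and blank lines ignored.
#' @return list of [distance_restraint()] objects.
#' @export
parse_upl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\\s+")[[1L]]
    if (length(f) < 7L) {
      stop(sprintf("upl line %d: expected 7 columns, got %d", i, length(f)))
    }
    lim <- suppressWarnings(as.numeric(f[7L]))
    if (is.na(lim) || lim <= 0) {
      stop(sprintf("upl line %d: non-positive or non-numeric limit '%s'",
                   i, f[7L]))
    }
    ga <- upl_group(as.integer(f[1L]), f[2L], f[3L])
    gb <- upl_group(as.integer(f[4L]), f[5L], f[6L])
    kind <- if (all(startsWith(c(ga$atom_name, gb$atom_name), "H"))) "noe" else "hbond"
    out[[i]] <- distance_restraint(ga, gb, lim, kind)
  }
  out
}

#' Write distance restraints in CYANA .upl format
#'
#' Pseudoatom groups that match a built-in expansion are written back with
#' their pseudoatom code so `parse_upl(write_upl(R))` round-trips.
#'
#' @param restraints list of [distance_restraint()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_upl <- function(restraints, path) {
  collapse_group <- function(g) {
    if (nrow(g) == 1L) return(c(g$residue_index[1L], g$residue_name[1L],
                                g$atom_name[1L]))
    resn <- g$residue_name[1L]
    keys <- c(paste0(resn, ":"), "")
    for (pre in keys) {
      cand <- names(.pseudoatom_table)[startsWith(names(.pseudoatom_table), pre)]
      for (k in cand) {
        code <- sub("^.*:", "", k)
        if (setequal(.pseudoatom_table[[k]], g$atom_name) &&
            identical(expand_pseudoatom(resn, code), .pseudoatom_table[[k]])) {
          return(c(g$residue_index[1L], resn, code))
        }
      }
    }
    stop("cannot collapse proton group to a pseudoatom code: ",
         paste(g$atom_name, collapse = ","))
  }
  lines <- vapply(restraints, function(r) {
    a <- collapse_group(r$group_a); b <- collapse_group(r$group_b)
    sprintf("%4s %-4s %-5s %4s %-4s %-5s %6.2f", a[1L], a[2L], a[3L],
            b[1L], b[2L], b[3L], r$upper_limit)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- geometry primitives --------------------------------------------------

#' Select atom indices in a structure model
#' @param model a [structure_model()].
#' @param atom_names character vector of atom names (NULL = all).
#' @param residues integer vector of residue indices (NULL = all).
#' @return integer vector of atom row indices.
#' @export
atom_select <- function(model, atom_names = NULL, residues = NULL) {
  keep <- rep(TRUE, nrow(model$atoms))
  if (!is.null(atom_names)) keep <- keep & model$atoms$name %in% atom_names
  if (!is.null(residues)) keep <- keep & model$atoms$residue_index %in% residues
  which(keep)
}

# Kabsch: optimal rotation R and translation mapping P onto Q (n x 3 each).
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp); Q0 <- sweep(Q, 2L, cq)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  Pr <- P0 %*% R
  rmsd <- sqrt(mean(rowSums((Pr - Q0)^2)))
  list(rotation = R, center_mobile = cp, center_ref = cq, rmsd = rmsd)
}

#' Best-fit RMSD between two coordinate sets
#' @param P,Q n x 3 matrices (same n, corresponding rows).
#' @return least-squares minimum RMSD over rotations and translations (A).
#' @export
rmsd_fit <- function(P, Q) kabsch(P, Q)$rmsd

#' Superpose one structure model onto another (Kabsch least squares)
#'
#' @param mobile,reference [structure_model()] objects.
#' @param selection integer atom indices (into both models' shared ordering)
#'   or a character vector of atom names, used for the fit; the whole mobile
#'   model is transformed. Default `"CA"`.
#' @return list with `model` (transformed mobile) and `rmsd` (A, over the
#'   selection).
#' @export
superpose <- function(mobile, reference, selection = "CA") {
  if (is.character(selection)) {
    sel_m <- atom_select(mobile, atom_names = selection)
    sel_r <- atom_select(reference, atom_names = selection)
    keym <- paste(mobile$atoms$residue_index[sel_m],
                  mobile$atoms$name[sel_m])
    keyr <- paste(reference$atoms$residue_index[sel_r],
                  reference$atoms$name[sel_r])
    common <- intersect(keym, keyr)
    sel_m <- sel_m[match(common, keym)]
    sel_r <- sel_r[match(common, keyr)]
  } else {
    sel_m <- sel_r <- as.integer(selection)
  }
  if (length(sel_m) < 3L) stop("selection must resolve to >= 3 atom pairs")
  P <- mobile$coords[sel_m, , drop = FALSE]
  Q <- reference$coords[sel_r, , drop = FALSE]
  P0 <- sweep(P, 2L, colMeans(P))
  if (qr(P0)$rank < 2L) stop("selection atoms are collinear")
  k <- kabsch(P, Q)
  newc <- sweep(mobile$coords, 2L, k$center_mobile) %*% k$rotation
  newc <- sweep(newc, 2L, k$center_ref, `+`)
  out <- mobile
  out$coords <- newc
  list(model = out, rmsd = k$rmsd)
}

# IUPAC-sign dihedral from four points, degrees in (-180, 180].
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  cr <- c(n1[2] * n2[3] - n1[3] * n2[2],
          n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  ang <- atan2(sum(cr * b2) / sqrt(sum(b2^2)), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

#' Wrap angles (degrees) into (-180, 180]
#' @param a numeric vector of angles in degrees.
#' @return wrapped angles.
#' @export
wrap_angle <- function(a) {
  w <- ((a + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Backbone phi/psi torsions of a structure model
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1), IUPAC
#' sign convention, degrees in (-180, 180]. Torsions whose defining atoms are
#' missing (chain termini, gaps) are returned as `NA` with a warning — never
#' a silent 0. Downstream featurization must exclude `NA` torsions.
#'
#' @param model a [structure_model()].
#' @param residues residue indices to evaluate (default: all in the model).
#' @return data.frame with columns `residue_index`, `phi`, `psi` (degrees or
#'   `NA`).
#' @export
backbone_torsions <- function(model, residues = NULL) {
  resis <- sort(unique(model$atoms$residue_index))
  if (is.null(residues)) residues <- resis
  get_atom <- function(resi, name) {
    i <- which(model$atoms$residue_index == resi & model$atoms$name == name)
    if (length(i) != 1L) return(NULL)
    model$coords[i, ]
  }
  phi <- psi <- rep(NA_real_, length(residues))
  missing_any <- FALSE
  for (j in seq_along(residues)) {
    r <- residues[j]
    n <- get_atom(r, "N"); ca <- get_atom(r, "CA"); c <- get_atom(r, "C")
    cprev <- get_atom(r - 1L, "C"); nnext <- get_atom(r + 1L, "N")
    if (!is.null(cprev) && !is.null(n) && !is.null(ca) && !is.null(c)) {
      phi[j] <- dihedral4(cprev, n, ca, c)
    } else missing_any <- TRUE
    if (!is.null(n) && !is.null(ca) && !is.null(c) && !is.null(nnext)) {
      psi[j] <- dihedral4(n, ca, c, nnext)
    } else missing_any <- TRUE
  }
  if (missing_any) {
    warning("some torsions are undefined (missing neighbor/backbone atoms); returned as NA")
  }
  data.frame(residue_index = residues, phi = phi, psi = psi)
}
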