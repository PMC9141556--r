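# Fixture builders shared across test files. All fixtures are constructed in
# code; nothing binary is stored.

# Place a fourth atom from three reference atoms by internal coordinates
# (NeRF): bond length to c, bond angle b-c-new, dihedral a-b-c-new (deg).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
         bond * sin(ang) * sin(dih))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Ideal-geometry polypeptide backbone (N, CA, C, O and amide H) with the
# given phi/psi vectors (degrees); omega fixed at 180. Returns a
# structure_model. Torsions measured on the result equal the inputs, which
# makes this an independent oracle for backbone_torsions.
build_peptide <- function(phi, psi, resnames = NULL) {
  n_res <- length(psi)
  stopifnot(length(phi) == n_res)
  if (is.null(resnames)) resnames <- rep("ALA", n_res)
  b_NCa <- 1.458; b_CaC <- 1.525; b_CN <- 1.329; b_CO <- 1.231; b_NH <- 1.01
  a_NCaC <- 111.2; a_CaCN <- 116.2; a_CNCa <- 121.7
  coords <- list(); atoms <- list()
  add <- function(name, el, resi, xyz) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      name = name, element = el, residue_index = resi,
      residue_name = resnames[resi], stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- xyz
    xyz
  }
  N <- add("N", "N", 1L, c(0, 0, 0))
  CA <- add("CA", "C", 1L, c(b_NCa, 0, 0))
  C <- add("C", "C", 1L, place_atom(c(0, -1, 0), N, CA, b_CaC, a_NCaC, 120))
  for (i in seq_len(n_res)) {
    if (i < n_res) {
      Nn <- place_atom(N, CA, C, b_CN, a_CaCN, psi[i])
      add("O", "O", i, place_atom(N, CA, C, b_CO, 121, psi[i] + 180))
      add("N", "N", i + 1L, Nn)
      CAn <- place_atom(CA, C, Nn, b_NCa, a_CNCa, 180)  # omega
      add("H", "H", i + 1L, place_atom(CA, C, Nn, b_NH, 119, 0))
      add("CA", "C", i + 1L, CAn)
      Cn <- place_atom(C, Nn, CAn, b_CaC, a_NCaC, phi[i + 1L])
      add("C", "C", i + 1L, Cn)
      N <- Nn; CA <- CAn; C <- Cn
    } else {
      add("O", "O", i, place_atom(N, CA, C, b_CO, 121, psi[i] + 180))
    }
  }
  structure_model(do.call(rbind, atoms), do.call(rbind, coords))
}

# Random rigid motion applied to an n x 3 coordinate matrix
random_rigid <- function(X, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3)
  R <- qr.Q(qr(A))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(X %*% R, 2, rnorm(3, sd = 5), `+`)
}

# Independent dihedral oracle: direct evaluation of the two-plane atan2
# formula written without reference to the package implementation.
dihedral_oracle <- function(p1, p2, p3, p4) {
  u1 <- p2 - p1; u2 <- p3 - p2; u3 <- p4 - p3
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(u1, u2); n2 <- cross(u2, u3)
  y <- sum(cross(n1, n2) * u2) / sqrt(sum(u2^2))
  x <- sum(n1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# A tiny two-conformer cartesian trajectory: frames drawn from two rigid
# 4-atom templates far apart in RMSD, each with an arbitrary rigid motion.
two_conformer_traj <- function(n_frames, labels, seed = 1) {
  set.seed(seed)
  A <- rbind(c(0, 0, 0), c(3, 0, 0), c(3, 3, 0), c(0, 3, 1))
  B <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(6, 5, 4))
  arr <- array(0, dim = c(n_frames, 4, 3))
  for (f in seq_len(n_frames)) {
    X <- if (labels[f] == 0) A else B
    arr[f, , ] <- random_rigid(X, seed = seed + f)
  }
  topo <- structure_model(
    data.frame(name = c("C1", "C2", "C3", "C4"), element = "C",
               residue_index = 1:4, residue_name = "BEA"),
    A)
  trajectory(arr, dt = 1, kind = "cartesian", topology = topo)
}
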