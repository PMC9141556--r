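# Ensemble quality statistics: precision RMSD, accuracy versus a reference
# structure, Ramachandran classification, van der Waals close contacts, and
# a refinement-statistics report.

#' Ensemble precision: mean RMSD to the iteratively superposed mean
#'
#' All models are superposed onto their running mean structure until the
#' mean converges (< 1e-4 A shift), then the average over models of each
#' model's RMSD to the mean is returned — the convention most NMR
#' refinement tables report. `method = "pairwise"` instead returns the mean
#' over all model pairs of the best-fit RMSD.
#'
#' @param ens an [ensemble()] (>= 2 models).
#' @param residue_range integer residue indices included (default all).
#' @param atoms backbone atom set used (default N, CA, C, O).
#' @param method `"mean"` (default) or `"pairwise"`.
#' @return precision RMSD, Angstrom.
#' @export
ensemble_precision <- function(ens, residue_range = NULL,
                               atoms = c("N", "CA", "C", "O"),
                               method = c("mean", "pairwise")) {
  method <- match.arg(method)
  if (length(ens$models) < 2L) stop("need >= 2 models")
  sel <- atom_select(ens$models[[1L]], atom_names = atoms,
                     residues = residue_range)
  if (length(sel) < 3L) stop("residue range resolves to < 3 atoms")
  X <- lapply(ens$models, function(m) m$coords[sel, , drop = FALSE])
  if (method == "pairwise") {
    nm <- length(X); tot <- 0; np <- 0L
    for (i in seq_len(nm - 1L)) {
      for (j in (i + 1L):nm) {
        tot <- tot + kabsch(X[[i]], X[[j]])$rmsd; np <- np + 1L
      }
    }
    return(tot / np)
  }
  mu <- X[[1L]]
  repeat {
    X <- lapply(X, function(P) {
      k <- kabsch(P, mu)
      sweep(sweep(P, 2L, k$center_mobile) %*% k$rotation, 2L,
            k$center_ref, `+`)
    })
    mu_new <- Reduce(`+`, X) / length(X)
    shift <- sqrt(mean((mu_new - mu)^2))
    mu <- mu_new
    if (shift < 1e-4) break
  }
  mean(vapply(X, function(P) sqrt(mean(rowSums((P - mu)^2))), numeric(1)))
}

# superposed mean coordinates of an ensemble over a selection
superposed_mean <- function(ens, sel) {
  X <- lapply(ens$models, function(m) m$coords[sel, , drop = FALSE])
  mu <- X[[1L]]
  repeat {
    X <- lapply(X, function(P) {
      k <- kabsch(P, mu)
      sweep(sweep(P, 2L, k$center_mobile) %*% k$rotation, 2L,
            k$center_ref, `+`)
    })
    mu_new <- Reduce(`+`, X) / length(X)
    if (sqrt(mean((mu_new - mu)^2)) < 1e-4) { mu <- mu_new; break }
    mu <- mu_new
  }
  mu
}

#' Ensemble accuracy: Calpha RMSD of the mean structure to a reference
#'
#' The ensemble mean coordinates (after iterative precision superposition)
#' are compared with the reference over the common Calpha set, resolved by
#' residue-index intersection minus an explicit exclusion list (flexible
#' termini), after Kabsch superposition.
#'
#' @param ens an [ensemble()].
#' @param reference a [structure_model()].
#' @param exclude_residues residue indices left out of the common set.
#' @return list with `rmsd` (A) and `n_atoms` (size of the common set).
#' @export
accuracy_to_reference <- function(ens, reference, exclude_residues = NULL) {
  res_e <- unique(ens$models[[1L]]$atoms$residue_index[
    ens$models[[1L]]$atoms$name == "CA"])
  res_r <- unique(reference$atoms$residue_index[reference$atoms$name == "CA"])
  common <- setdiff(intersect(res_e, res_r), exclude_residues)
  if (length(common) < 3L) stop("fewer than 3 common Calpha atoms")
  sel_e <- atom_select(ens$models[[1L]], "CA", common)
  sel_r <- atom_select(reference, "CA", common)
  ord_e <- order(ens$models[[1L]]$atoms$residue_index[sel_e])
  ord_r <- order(reference$atoms$residue_index[sel_r])
  mu <- superposed_mean(ens, sel_e[ord_e])
  list(rmsd = kabsch(mu, reference$coords[sel_r[ord_r], , drop = FALSE])$rmsd,
       n_atoms = length(common))
}

# ---- Ramachandran classification ------------------------------------------

# Region labels on a 10 x 10 degree grid. The four-class map (core /
# allowed / generous / disallowed) is built from rectangular core regions
# for the beta, right-handed alpha and left-handed alpha basins, dilated on
# the torus for the allowed and generous classes. This is a synthetic
# approximation of the classic PROCHECK-style map, shipped as inspectable
# text data (inst/extdata/rama_map_*.tsv); it is not the original
# empirical grid.
.rama_levels <- c("core", "allowed", "generous", "disallowed")

rama_cell <- function(angle) pmin(pmax(floor((angle + 180) / 10) + 1, 1L), 36L)

dilate_torus <- function(mask, times = 1L) {
  n <- nrow(mask)
  for (t in seq_len(times)) {
    shifted <- mask
    for (di in -1:1) {
      for (dj in -1:1) {
        idx_i <- ((seq_len(n) - 1 + di) %% n) + 1
        idx_j <- ((seq_len(n) - 1 + dj) %% n) + 1
        shifted <- shifted | mask[idx_i, idx_j]
      }
    }
    mask <- shifted
  }
  mask
}

#' Build a 10x10-degree Ramachandran region map
#'
#' Returns a 36 x 36 integer matrix (phi rows, psi columns, both from -180
#' to 180 in 10-degree cells) with values 1..4 = core, allowed, generous,
#' disallowed. `kind = "gly"` symmetrizes the general map under
#' (phi, psi) -> (-phi, -psi); `kind = "pro"` restricts phi to the
#' pyrrolidine-compatible band around -60 degrees.
#'
#' @param kind `"general"`, `"gly"` or `"pro"`.
#' @return 36 x 36 integer matrix.
#' @export
build_rama_map <- function(kind = c("general", "gly", "pro")) {
  kind <- match.arg(kind)
  core <- matrix(FALSE, 36L, 36L)
  box <- function(phi_lo, phi_hi, psi_lo, psi_hi) {
    i <- rama_cell(phi_lo + 5):rama_cell(phi_hi - 5)
    j <- rama_cell(psi_lo + 5):rama_cell(psi_hi - 5)
    core[i, j] <<- TRUE
  }
  box(-170, -50, 90, 180)    # beta
  box(-170, -50, -180, -170) # beta continuation across the psi boundary
  box(-160, -40, -70, -10)   # right-handed alpha
  box(40, 80, 0, 60)         # left-handed alpha
  if (kind == "gly") core <- core | core[36:1, 36:1]
  allowed <- dilate_torus(core, 1L)
  generous <- dilate_torus(allowed, 2L)
  m <- matrix(4L, 36L, 36L)
  m[generous] <- 3L
  m[allowed] <- 2L
  m[core] <- 1L
  if (kind == "pro") {
    phi_ok <- rama_cell(-115):rama_cell(-35)
    m[setdiff(seq_len(36L), phi_ok), ] <- 4L
  }
  m
}

.rama_cache <- new.env(parent = emptyenv())

load_rama_map <- function(kind) {
  if (!is.null(.rama_cache[[kind]])) return(.rama_cache[[kind]])
  path <- system.file("extdata", paste0("rama_map_", kind, ".tsv"),
                      package = "nbens")
  m <- if (nzchar(path)) {
    as.matrix(read.table(path, header = FALSE))
  } else {
    build_rama_map(kind)  # fallback when running from a source tree
  }
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  .rama_cache[[kind]] <- m
  m
}

#' Classify a (phi, psi) pair into a Ramachandran region
#'
#' @param phi,psi backbone torsions, degrees (vectorized).
#' @param residue_name 3-letter residue code(s); GLY and PRO use their
#'   dedicated maps.
#' @return factor with levels core, allowed, generous, disallowed.
#' @export
ramachandran_classify <- function(phi, psi, residue_name = "ALA") {
  n <- max(length(phi), length(psi))
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  residue_name <- rep_len(residue_name, n)
  kind <- ifelse(residue_name == "GLY", "gly",
                 ifelse(residue_name == "PRO", "pro", "general"))
  out <- integer(n)
  for (k in unique(kind)) {
    m <- load_rama_map(k)
    i <- which(kind == k)
    out[i] <- m[cbind(rama_cell(wrap_angle(phi[i])),
                      rama_cell(wrap_angle(psi[i])))]
  }
  factor(.rama_levels[out], levels = .rama_levels)
}

#' Ramachandran report for an ensemble
#'
#' Classifies every defined (phi, psi) pair of every model. Undefined
#' torsions (termini) are excluded from the aggregation and counted
#' separately.
#'
#' @param ens an [ensemble()] or single [structure_model()].
#' @param residues residue indices to include (default all).
#' @return list with `table` (model, residue_index, phi, psi, region),
#'   `percent` (named percentages over the four regions, summing to 100)
#'   and `n_undefined`.
#' @export
ramachandran_report <- function(ens, residues = NULL) {
  if (inherits(ens, "structure_model")) ens <- ensemble(list(ens))
  rows <- list()
  n_undef <- 0L
  for (m in ens$models) {
    tor <- suppressWarnings(backbone_torsions(m, residues))
    def <- !is.na(tor$phi) & !is.na(tor$psi)
    n_undef <- n_undef + sum(!def)
    if (!any(def)) next
    resn <- m$atoms$residue_name[match(tor$residue_index[def],
                                       m$atoms$residue_index)]
    rows[[length(rows) + 1L]] <- data.frame(
      model = m$model_id, residue_index = tor$residue_index[def],
      phi = tor$phi[def], psi = tor$psi[def],
      region = ramachandran_classify(tor$phi[def], tor$psi[def], resn))
  }
  tab <- do.call(rbind, rows)
  counts <- table(factor(tab$region, levels = .rama_levels))
  list(table = tab, percent = 100 * as.vector(counts) / sum(counts),
       counts = as.vector(counts), n_undefined = n_undef)
}

# ---- van der Waals close contacts -----------------------------------------

.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

#' Count van der Waals close contacts in an ensemble
#'
#' Approximate criterion: two heavy atoms from non-adjacent residues closer
#' than r_i + r_j - `slack` count as one close contact; a pair is reported
#' once if it violates in any model.
#'
#' @param ens an [ensemble()] or [structure_model()].
#' @param slack overlap allowance, Angstrom (default 0.4).
#' @return number of distinct close-contact atom pairs.
#' @export
vdw_close_contacts <- function(ens, slack = 0.4) {
  if (inherits(ens, "structure_model")) ens <- ensemble(list(ens))
  atoms <- ens$models[[1L]]$atoms
  heavy <- which(atoms$element != "H")
  rad <- .vdw_radii[atoms$element[heavy]]
  rad[is.na(rad)] <- 1.7
  resi <- atoms$residue_index[heavy]
  bad_pairs <- character(0)
  for (m in ens$models) {
    xyz <- m$coords[heavy, , drop = FALSE]
    for (a in seq_along(heavy)[-length(heavy)]) {
      b <- (a + 1L):length(heavy)
      sep <- abs(resi[b] - resi[a])
      b <- b[sep >= 2L]
      if (length(b) == 0L) next
      d <- sqrt(rowSums(sweep(xyz[b, , drop = FALSE], 2L, xyz[a, ])^2))
      hit <- b[d < rad[a] + rad[b] - slack]
      if (length(hit)) bad_pairs <- union(bad_pairs, paste(a, hit))
    }
  }
  length(bad_pairs)
}

# ---- refinement-statistics report -----------------------------------------

#' Refinement-statistics report for an NMR-style ensemble
#'
#' Mirrors the rows of a standard structure-refinement statistics table:
#' restraint counts by kind, backbone precision RMSD over a residue range,
#' optional Calpha accuracy to a reference structure, Ramachandran
#' percentages, and NOE violation counts at a threshold. Because the
#' violation-counting convention of refinement tables is ambiguous, both
#' conventions are reported side by side: restraints whose ensemble-averaged
#' effective distance exceeds the limit, and restraints violated in any
#' single model.
#'
#' @param ens an [ensemble()].
#' @param reference optional [structure_model()] for accuracy.
#' @param restraints list of [distance_restraint()] (may be empty).
#' @param threshold violation threshold, Angstrom (default 0.2).
#' @param residue_range residues for the precision RMSD (default all).
#' @param exclude_residues residues excluded from the accuracy common set.
#' @return object of class `ensemble_quality_report` (named list).
#' @export
table1_report <- function(ens, reference = NULL, restraints = list(),
                          threshold = 0.2, residue_range = NULL,
                          exclude_residues = NULL) {
  kinds <- vapply(restraints, function(r) r$kind, character(1))
  rep_ens <- if (length(restraints)) {
    violation_report(ens, restraints, threshold, mode = "ensemble")
  } else NULL
  rep_mod <- if (length(restraints)) {
    violation_report(ens, restraints, threshold, mode = "per_model")
  } else NULL
  rama <- ramachandran_report(ens, residue_range)
  out <- list(
    n_restraints_noe = sum(kinds == "noe"),
    n_restraints_hbond = sum(kinds == "hbond"),
    backbone_rmsd = if (length(ens$models) > 1L) {
      ensemble_precision(ens, residue_range)
    } else NA_real_,
    ca_rmsd_to_reference = if (!is.null(reference)) {
      accuracy_to_reference(ens, reference, exclude_residues)$rmsd
    } else NA_real_,
    rama_percent = setNames(round(rama$percent, 1), .rama_levels),
    noe_violations_ensemble = if (!is.null(rep_ens)) rep_ens$n_violated else 0L,
    noe_violations_any_model = if (!is.null(rep_mod)) rep_mod$n_violated else 0L,
    noe_violations_at_or_below_threshold =
      if (!is.null(rep_ens)) rep_ens$n_at_or_below_threshold else 0L,
    vdw_close_contacts = vdw_close_contacts(ens),
    threshold = threshold)
  class(out) <- "ensemble_quality_report"
  out
}

#' @export
print.ensemble_quality_report <- function(x, ...) {
  cat("Ensemble refinement statistics\n")
  cat(sprintf("  NOE restraints                %d\n", x$n_restraints_noe))
  cat(sprintf("  H-bond restraints             %d\n", x$n_restraints_hbond))
  cat(sprintf("  Backbone RMSD (precision)     %.2f A\n", x$backbone_rmsd))
  if (!is.na(x$ca_rmsd_to_reference)) {
    cat(sprintf("  Calpha RMSD to reference      %.2f A\n",
                x$ca_rmsd_to_reference))
  }
  cat("  Ramachandran space\n")
  for (nm in names(x$rama_percent)) {
    cat(sprintf("    %-12s %5.1f %%\n", nm, x$rama_percent[[nm]]))
  }
  cat(sprintf("  NOE violations (ensemble avg) %d\n",
              x$noe_violations_ensemble))
  cat(sprintf("  NOE violations (any model)    %d\n",
              x$noe_violations_any_model))
  cat(sprintf("  VDW close contacts            %d\n", x$vdw_close_contacts))
  invisible(x)
}

#' Write an ensemble quality report as TSV
#' @param report an `ensemble_quality_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  rows <- c(
    sprintf("NOE restraints\t%d", report$n_restraints_noe),
    sprintf("H-bond restraints\t%d", report$n_restraints_hbond),
    sprintf("Backbone RMSD (A)\t%.3f", report$backbone_rmsd),
    sprintf("Calpha RMSD to reference (A)\t%.3f",
            report$ca_rmsd_to_reference),
    sprintf("Ramachandran core (%%)\t%.1f", report$rama_percent[["core"]]),
    sprintf("Ramachandran allowed (%%)\t%.1f",
            report$rama_percent[["allowed"]]),
    sprintf("Ramachandran generous (%%)\t%.1f",
            report$rama_percent[["generous"]]),
    sprintf("Ramachandran disallowed (%%)\t%.1f",
            report$rama_percent[["disallowed"]]),
    sprintf("NOE violations (ensemble avg)\t%d",
            report$noe_violations_ensemble),
    sprintf("NOE violations (any model)\t%d",
            report$noe_violations_any_model),
    sprintf("VDW close contacts\t%d", report$vdw_close_contacts))
  writeLines(rows, path)
  invisible(path)
}
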