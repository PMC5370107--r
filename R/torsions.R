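#' Read backbone N/CA/C coordinates from a PDB file
#'
#' Extracts per-residue backbone coordinates from the ATOM records of a PDB
#' file. By default the first model is used and chains are kept in file
#' order; residues missing any of the three backbone atoms are excluded with
#' a warning. HETATM records are ignored.
#'
#' @param path Path to a PDB file.
#' @param chains Optional character vector restricting to the given chain
#'   identifiers; default keeps all chains in file order.
#' @return A tibble with one row per complete residue: `chain`, `resno`, and
#'   coordinate columns `n_x, n_y, n_z, ca_x, ca_y, ca_z, c_x, c_y, c_z`
#'   (Angstrom). The number of excluded residues is attached as attribute
#'   `n_incomplete`, the file id (basename without extension) as `id`.
#' @export
read_pdb_backbone <- function(path, chains = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (nrow(at) == 0L) abort(paste0("no ATOM records in ", path))
  at <- at[at$elety %in% c("N", "CA", "C"), , drop = FALSE]
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  keys <- unique(key)  # file order
  rows <- lapply(keys, function(k) {
    sub <- at[key == k, , drop = FALSE]
    coord <- function(e) {
      i <- which(sub$elety == e)[1]  # first altloc wins
      if (is.na(i)) return(NULL)
      as.numeric(sub[i, c("x", "y", "z")])
    }
    n <- coord("N"); ca <- coord("CA"); cc <- coord("C")
    if (is.null(n) || is.null(ca) || is.null(cc)) return(NULL)
    tibble(chain = sub$chain[1], resno = sub$resno[1],
           n_x = n[1], n_y = n[2], n_z = n[3],
           ca_x = ca[1], ca_y = ca[2], ca_z = ca[3],
           c_x = cc[1], c_y = cc[2], c_z = cc[3])
  })
  keep <- !vapply(rows, is.null, logical(1))
  n_incomplete <- sum(!keep)
  if (n_incomplete > 0L) {
    warn(sprintf("excluded %d residue(s) with missing backbone atoms",
                 n_incomplete))
  }
  if (!any(keep)) abort(paste0("no complete backbone residue in ", path))
  out <- dplyr::bind_rows(rows[keep])
  attr(out, "n_incomplete") <- n_incomplete
  attr(out, "id") <- sub("\\.[^.]*$", "", basename(path))
  out
}

#' Dihedral angle of four points
#'
#' Signed dihedral angle (degrees) defined by four 3D points, using the
#' IUPAC sign convention via the atan2 formulation. The value lies in the
#' half-open range \[-180, 180): an exactly planar trans arrangement is
#' reported as -180, a planar cis arrangement as 0.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors.
#' @return Dihedral angle in degrees in \[-180, 180).
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  ang <- atan2(sqrt(sum(b2^2)) * sum(b1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang >= 180) ang <- ang - 360  # half-open range [-180, 180)
  ang
}

#' Backbone phi/psi torsion angles of a structure
#'
#' Computes the Ramachandran torsion angles from backbone coordinates:
#' phi(i) = dihedral(C(i-1), N(i), CA(i), C(i)) for i >= 2 and
#' psi(i) = dihedral(N(i), CA(i), C(i), N(i+1)) for i <= n-1. Undefined
#' terminal angles are omitted, so a single complete chain of n residues
#' yields 2n - 2 angles. Torsions spanning a chain break (different `chain`
#' values on consecutive rows) are excluded.
#'
#' @param backbone Backbone tibble as returned by [read_pdb_backbone()] or
#'   [generate_torsion_structure()].
#' @param layout `"interleaved"` (default) interleaves phi and psi in residue
#'   order (psi_1, phi_2, psi_2, ..., phi_n); `"phi"` or `"psi"` keep one
#'   angle kind only.
#' @return A tibble with columns `resno`, `kind` (`"phi"`/`"psi"`) and
#'   `angle` (degrees in \[-180, 180)), in the requested layout order.
#' @export
compute_torsions <- function(backbone, layout = c("interleaved", "phi", "psi")) {
  layout <- match.arg(layout)
  n <- nrow(backbone)
  if (n < 2L) abort("at least 2 complete residues are required")
  pt <- function(i, a) as.numeric(backbone[i, paste0(a, c("_x", "_y", "_z"))])
  same_chain <- function(i, j) backbone$chain[i] == backbone$chain[j]
  rows <- list()
  for (i in seq_len(n)) {
    if (i >= 2L && same_chain(i - 1L, i)) {
      rows[[length(rows) + 1L]] <- tibble(
        resno = backbone$resno[i], kind = "phi",
        angle = dihedral_angle(pt(i - 1L, "c"), pt(i, "n"),
                               pt(i, "ca"), pt(i, "c")))
    }
    if (i <= n - 1L && same_chain(i, i + 1L)) {
      rows[[length(rows) + 1L]] <- tibble(
        resno = backbone$resno[i], kind = "psi",
        angle = dihedral_angle(pt(i, "n"), pt(i, "ca"),
                               pt(i, "c"), pt(i + 1L, "n")))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (layout != "interleaved") out <- out[out$kind == layout, , drop = FALSE]
  if (nrow(out) == 0L) abort("no defined torsion angles")
  out
}

#' Discretize torsion angles into integer states
#'
#' Uniformly bins \[-180, 180) into `bins` equal half-open intervals
#' (left-closed, right-open); angle a maps to state
#' `floor((a + 180) / (360 / bins)) + 1`.
#'
#' @param angles Numeric vector of angles in degrees in \[-180, 180), or a
#'   torsion tibble from [compute_torsions()] (its `angle` column is used).
#' @param bins Number of bins (>= 2). The default 20 matches the size of the
#'   amino-acid alphabet so sequence and structure branches share one scale.
#' @return Integer vector of states in 1..bins.
#' @export
discretize_torsions <- function(angles, bins = 20L) {
  if (is.data.frame(angles)) angles <- angles$angle
  stopifnot(is.numeric(angles), bins >= 2L)
  if (any(angles < -180 | angles >= 180)) {
    abort("angles must lie in [-180, 180)")
  }
  idx <- floor((angles + 180) / (360 / bins)) + 1L
  as.integer(pmin(idx, bins))  # guard float edge at the top bin
}

#' Write backbone coordinates as a PDB file
#'
#' Writes an N/CA/C backbone tibble as standard fixed-width ATOM records (via
#' bio3d), so synthetic structures flow through the same public PDB entry
#' point as real ones.
#'
#' @param backbone Backbone tibble (see [read_pdb_backbone()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_backbone <- function(backbone, path) {
  n <- nrow(backbone)
  xyz <- as.numeric(t(as.matrix(backbone[, c(
    "n_x", "n_y", "n_z", "ca_x", "ca_y", "ca_z", "c_x", "c_y", "c_z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = rep("ATOM", 3L * n),
    resno = rep(backbone$resno, each = 3L),
    resid = rep("ALA", 3L * n),
    chain = rep(backbone$chain, each = 3L),
    elety = rep(c("N", "CA", "C"), n),
    eleno = seq_len(3L * n))
  invisible(path)
}
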