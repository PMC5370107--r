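#' Generate synthetic protein families with known structure
#'
#' Draws one ancestor sequence per family uniformly over the 20-letter
#' alphabet, then derives each member by i.i.d. point substitutions (uniform
#' over the other 19 residues) and single-site geometric-length indels
#' (insertion or deletion with equal probability, length 1 + Geometric(0.5)).
#' Indels make member lengths unequal, exercising the sliding-window path of
#' the similarity. Fully reproducible from `seed`.
#'
#' @param n_families Number of families.
#' @param members_per_family Members drawn per family.
#' @param ancestor_length Ancestor length in residues (>= 10).
#' @param substitution_rate Per-site substitution probability in \[0, 1).
#' @param indel_rate Per-site indel probability in \[0, 1).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A tibble with columns `id`, `family`, `label` and `residues`;
#'   the seed is attached as attribute `seed`.
#' @examples
#' fam <- generate_families(seed = 7)
#' table(fam$family)
#' @export
generate_families <- function(n_families = 3, members_per_family = 6,
                              ancestor_length = 200,
                              substitution_rate = 0.05, indel_rate = 0.01,
                              seed = NULL) {
  stopifnot(n_families >= 1, members_per_family >= 1, ancestor_length >= 10,
            substitution_rate >= 0, substitution_rate < 1,
            indel_rate >= 0, indel_rate < 1)
  run <- function() {
    out <- purrr::map_dfr(seq_len(n_families), function(f) {
      ancestor <- sample(aa_alphabet(), ancestor_length, replace = TRUE)
      purrr::map_dfr(seq_len(members_per_family), function(m) {
        tibble(id = sprintf("fam%d_m%d", f, m),
               family = sprintf("fam%d", f),
               residues = mutate_sequence(ancestor, substitution_rate,
                                          indel_rate))
      })
    })
    out$label <- out$family
    out[, c("id", "family", "label", "residues")]
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  attr(out, "seed") <- seed
  out
}

mutate_sequence <- function(ancestor, substitution_rate, indel_rate) {
  s <- ancestor
  n <- length(s)
  sub_at <- which(stats::runif(n) < substitution_rate)
  for (i in sub_at) {
    s[i] <- sample(setdiff(aa_alphabet(), s[i]), 1L)
  }
  indel_at <- which(stats::runif(n) < indel_rate)
  for (i in rev(indel_at)) {  # back to front keeps indices valid
    len <- 1L + stats::rgeom(1L, 0.5)
    if (stats::runif(1) < 0.5) {
      ins <- sample(aa_alphabet(), len, replace = TRUE)
      s <- append(s, ins, after = i)
    } else {
      drop <- i:min(i + len - 1L, length(s))
      s <- s[-drop]
    }
  }
  paste(s, collapse = "")
}

#' Write protein records as a FASTA file
#'
#' Writes `id` + `label` headers and residue lines, so synthetic families
#' flow through the same public FASTA entry point as real data.
#'
#' @param proteins Tibble with columns `id`, `residues` and optionally
#'   `label`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  stopifnot(all(c("id", "residues") %in% names(proteins)))
  label <- if ("label" %in% names(proteins)) proteins$label else
    rep(NA_character_, nrow(proteins))
  hdr <- ifelse(is.na(label) | label == "", paste0(">", proteins$id),
                paste0(">", proteins$id, " ", label))
  writeLines(as.vector(rbind(hdr, proteins$residues)), path)
  invisible(path)
}

# canonical backbone geometry (Angstrom / degrees) used by the chain builder
.bond <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329)
.angle <- list(n_ca_c = 111.2, ca_c_n = 116.2, c_n_ca = 121.7)

#' Generate an idealized backbone structure with known torsion angles
#'
#' Builds N/CA/C backbone coordinates from ideal bond lengths and angles
#' (omega fixed at 180 degrees) so that the phi/psi torsion angles sit at
#' canonical helix (-60, -45) or sheet (-120, +120) values, optionally with
#' Gaussian noise. `mixed` uses helix values for the first half of the chain
#' and sheet values for the second. [compute_torsions()] on the output
#' recovers the generating angles, which makes generator and torsion code
#' mutual round-trip checks.
#'
#' @param n_residues Chain length (>= 4).
#' @param motif `"alpha"`, `"beta"` or `"mixed"`.
#' @param noise_deg Standard deviation (degrees) of Gaussian noise added to
#'   every phi/psi target.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A backbone tibble (see [read_pdb_backbone()]) with the generating
#'   angles attached as attribute `target` (tibble `resno`, `phi`, `psi`)
#'   and the motif as attribute `motif`.
#' @export
generate_torsion_structure <- function(n_residues, motif = c("alpha", "beta",
                                                             "mixed"),
                                       noise_deg = 0, seed = NULL) {
  motif <- match.arg(motif)
  stopifnot(n_residues >= 4, noise_deg >= 0)
  canonical <- list(alpha = c(phi = -60, psi = -45),
                    beta = c(phi = -120, psi = 120))
  kind <- switch(motif,
                 alpha = rep("alpha", n_residues),
                 beta = rep("beta", n_residues),
                 mixed = rep(c("alpha", "beta"),
                             c(ceiling(n_residues / 2),
                               floor(n_residues / 2))))
  run <- function() {
    phi <- vapply(kind, function(k) canonical[[k]][["phi"]], numeric(1),
                  USE.NAMES = FALSE)
    psi <- vapply(kind, function(k) canonical[[k]][["psi"]], numeric(1),
                  USE.NAMES = FALSE)
    if (noise_deg > 0) {
      phi <- phi + stats::rnorm(n_residues, 0, noise_deg)
      psi <- psi + stats::rnorm(n_residues, 0, noise_deg)
    }
    wrap <- function(a) ((a + 180) %% 360) - 180
    list(phi = wrap(phi), psi = wrap(psi))
  }
  ang <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  bb <- build_backbone(ang$phi, ang$psi)
  attr(bb, "target") <- tibble(resno = seq_len(n_residues),
                               phi = ang$phi, psi = ang$psi)
  attr(bb, "motif") <- motif
  attr(bb, "id") <- paste0("synthetic_", motif)
  bb
}

# place atom D given A, B, C, the C-D bond length, the B-C-D bond angle and
# the A-B-C-D torsion (standard internal-coordinate chain extension)
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  nrm <- c(ab[2] * bc[3] - ab[3] * bc[2],
           ab[3] * bc[1] - ab[1] * bc[3],
           ab[1] * bc[2] - ab[2] * bc[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  m2 <- c(nrm[2] * bc[3] - nrm[3] * bc[2],
          nrm[3] * bc[1] - nrm[1] * bc[3],
          nrm[1] * bc[2] - nrm[2] * bc[1])
  c + cbind(bc, m2, nrm) %*% d2
}

build_backbone <- function(phi, psi) {
  n <- length(phi)
  N <- CA <- C <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.bond$n_ca, 0, 0)
  a0 <- .angle$n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + .bond$ca_c * c(-cos(a0), sin(a0), 0)
  for (i in seq_len(n - 1L)) {
    # psi_i places the next N, omega = 180 the next CA, phi_{i+1} the next C
    N[i + 1L, ] <- place_atom(N[i, ], CA[i, ], C[i, ], .bond$c_n,
                              .angle$ca_c_n, psi[i])
    CA[i + 1L, ] <- place_atom(CA[i, ], C[i, ], N[i + 1L, ], .bond$n_ca,
                               .angle$c_n_ca, 180)
    C[i + 1L, ] <- place_atom(C[i, ], N[i + 1L, ], CA[i + 1L, ],
                              .bond$ca_c, .angle$n_ca_c, phi[i + 1L])
  }
  tibble(chain = "A", resno = seq_len(n),
         n_x = N[, 1], n_y = N[, 2], n_z = N[, 3],
         ca_x = CA[, 1], ca_y = CA[, 2], ca_z = CA[, 3],
         c_x = C[, 1], c_y = C[, 2], c_z = C[, 3])
}
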