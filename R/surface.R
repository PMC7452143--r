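# Bondi-style van der Waals radii (Angstrom) by element
DEFAULT_VDW_RADII <- c(
  H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
  P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
  FE = 1.40, ZN = 1.39, MG = 1.73, CA = 1.97, "NA" = 2.27, K = 2.75, MN = 1.40
)

# deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

.atom_radii <- function(atoms, radii) {
  r <- radii[atoms$element]
  if (any(is.na(r))) {
    bad <- which(is.na(r))[1]
    stop("no van der Waals radius for element '", atoms$element[bad],
         "' (atom ", atoms$serial[bad], " ", atoms$name[bad], " ",
         atoms$resname[bad], " ", atoms$chain[bad], atoms$resno[bad], ")")
  }
  unname(r)
}

# core Shrake-Rupley on a coordinate matrix with expanded radii R (= r + probe)
.sasa_points <- function(co, R, n_points) {
  n <- nrow(co)
  pts <- .sphere_points(n_points)
  area <- numeric(n)
  maxR <- max(R)
  for (i in seq_len(n)) {
    d2 <- (co[, 1] - co[i, 1])^2 + (co[, 2] - co[i, 2])^2 + (co[, 3] - co[i, 3])^2
    nb <- which(d2 < (R[i] + R)^2 & d2 > 1e-12)
    p <- sweep(pts * R[i], 2, co[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      dd <- (p[, 1] - co[j, 1])^2 + (p[, 2] - co[j, 2])^2 + (p[, 3] - co[j, 3])^2
      free <- free & dd >= R[j]^2
      if (!any(free)) break
    }
    area[i] <- sum(free) / n_points * 4 * pi * R[i]^2
  }
  area
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA by the Shrake-Rupley quadrature: for each heavy atom, the
#' fraction of `n_points` test points on a sphere of radius r_atom + probe
#' not buried inside any neighbouring sphere, scaled by the sphere area.
#' Waters and hydrogens are excluded.
#'
#' @param s A `mol_structure`.
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points Quadrature points per atom (default 960; relative error
#'   on a free sphere is below 1 percent at this density).
#' @param radii Named vector of van der Waals radii by element symbol
#'   (default a Bondi-style table). Atoms whose element has no entry raise
#'   an error.
#' @param annotation Optional `complex_annotation`; when given, per-role
#'   totals are reported.
#' @return A `surface_result` list: `atom_area` (per retained atom, Ų),
#'   `atoms` (the retained atom table), `total`, `by_role` (when annotated),
#'   `probe_radius`, `quadrature_points`.
#' @export
compute_sasa <- function(s, probe = 1.4, n_points = 960,
                         radii = DEFAULT_VDW_RADII, annotation = NULL) {
  at <- .polymer_atoms(s)
  at <- at[!at$water, , drop = FALSE]
  if (nrow(at) == 0) stop("no heavy atoms to compute SASA for")
  R <- .atom_radii(at, radii) + probe
  area <- .sasa_points(.coords(at), R, n_points)
  by_role <- NULL
  if (!is.null(annotation)) {
    role_of <- setNames(names(annotation$roles), unname(unlist(annotation$roles)))
    by_role <- tapply(area, role_of[at$chain], sum)
  }
  structure(list(atom_area = area, atoms = at, total = sum(area),
                 by_role = by_role, probe_radius = probe,
                 quadrature_points = n_points),
            class = "surface_result")
}

#' @export
print.surface_result <- function(x, ...) {
  cat(sprintf("<surface_result> total SASA %.1f A^2 (%d atoms, probe %.2f A, %d points)\n",
              x$total, length(x$atom_area), x$probe_radius, x$quadrature_points))
  if (!is.null(x$by_role)) print(round(x$by_role, 1))
  invisible(x)
}

# subset a mol_structure to a set of chains, without moving atoms
.subset_chains <- function(s, chains) {
  out <- s
  out$atoms <- s$atoms[s$atoms$chain %in% chains, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

#' Buried solvent-accessible surface area of the TCR-pHLA interface
#'
#' BSASA = SASA(TCR alone) + SASA(pHLA alone) - SASA(complex), with the
#' components extracted by chain role and no atom moved. Reported as total
#' burial over both sides; `half = TRUE` divides by two for the per-side
#' convention.
#'
#' @inheritParams compute_sasa
#' @param a A `complex_annotation`.
#' @param half Report per-side burial (default `FALSE`).
#' @return BSASA in Ų.
#' @export
compute_bsasa <- function(s, a, probe = 1.4, n_points = 960,
                          radii = DEFAULT_VDW_RADII, half = FALSE) {
  tcr <- c(.role_chain(a, "TCR_alpha"), .role_chain(a, "TCR_beta"))
  phla <- c(.role_chain(a, "peptide"), .role_chain(a, "HLA_heavy"),
            .role_chain(a, "beta2m"))
  s_all <- .subset_chains(s, c(tcr, phla))
  v <- compute_sasa(.subset_chains(s, tcr), probe, n_points, radii)$total +
    compute_sasa(.subset_chains(s, phla), probe, n_points, radii)$total -
    compute_sasa(s_all, probe, n_points, radii)$total
  if (half) v / 2 else v
}

# dot surface (points + outward normals) of one atom set, excluding points
# buried inside any other atom of the same set
.dot_surface <- function(co, r, n_points) {
  pts <- .sphere_points(n_points)
  keep_p <- list(); keep_n <- list()
  for (i in seq_len(nrow(co))) {
    d2 <- (co[, 1] - co[i, 1])^2 + (co[, 2] - co[i, 2])^2 + (co[, 3] - co[i, 3])^2
    nb <- which(d2 < (r[i] + r)^2 & d2 > 1e-12)
    p <- sweep(pts * r[i], 2, co[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      dd <- (p[, 1] - co[j, 1])^2 + (p[, 2] - co[j, 2])^2 + (p[, 3] - co[j, 3])^2
      free <- free & dd >= r[j]^2
    }
    if (any(free)) {
      keep_p[[length(keep_p) + 1L]] <- p[free, , drop = FALSE]
      keep_n[[length(keep_n) + 1L]] <- pts[free, , drop = FALSE]
    }
  }
  list(points = do.call(rbind, keep_p), normals = do.call(rbind, keep_n))
}

# one direction of the Lawrence-Colman statistic: median over points of A
# within `band` of surface B of (n_A . -n_B) exp(-w d^2)
.sc_one_way <- function(sa, sb, w, band) {
  # prefilter A points by distance to the nearest B point (chunked)
  nb_idx <- integer(nrow(sa$points)); nb_d2 <- numeric(nrow(sa$points))
  chunk <- 1000L
  for (i0 in seq(1L, nrow(sa$points), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, nrow(sa$points))
    d2 <- outer(rowSums(sa$points[ii, , drop = FALSE]^2), rowSums(sb$points^2), "+") -
      2 * (sa$points[ii, , drop = FALSE] %*% t(sb$points))
    nb_idx[ii] <- max.col(-d2, ties.method = "first")
    nb_d2[ii] <- d2[cbind(seq_along(ii), nb_idx[ii])]
  }
  sel <- nb_d2 <= band^2
  if (!any(sel)) return(NA_real_)
  dots <- rowSums(sa$normals[sel, , drop = FALSE] * -sb$normals[nb_idx[sel], , drop = FALSE])
  median(dots * exp(-w * pmax(0, nb_d2[sel])))
}

#' Lawrence-Colman shape complementarity of the TCR-pHLA interface
#'
#' For every surface point of one side lying within `band` of the other
#' side's surface, the statistic S = (n_A . -n_B) exp(-w d^2) is evaluated
#' at the nearest opposing point; the score is the mean of the two median
#' values (A to B and B to A). 1 means perfect complementarity; values for
#' protein-protein interfaces typically fall around 0.6-0.8. Surfaces are
#' dot clouds on the van der Waals spheres of each side's heavy atoms.
#'
#' @param s A `mol_structure`.
#' @param a A `complex_annotation`.
#' @param w Gaussian distance weight in 1/Ų (default 0.5).
#' @param band Interface band width in Angstrom (default 1.5).
#' @param n_points Dot-surface points per atom (default 240).
#' @param radii Van der Waals radius table.
#' @return A `shape_complementarity` list: `sc`, `w_parameter`,
#'   `interface_point_count` (per side), `band`.
#' @export
compute_shape_complementarity <- function(s, a, w = 0.5, band = 1.5,
                                          n_points = 240,
                                          radii = DEFAULT_VDW_RADII) {
  at <- .polymer_atoms(s); at <- at[!at$water, , drop = FALSE]
  tcr_chains <- c(.role_chain(a, "TCR_alpha"), .role_chain(a, "TCR_beta"))
  tgt_chains <- c(.role_chain(a, "peptide"), .role_chain(a, "HLA_heavy"))
  A <- at[at$chain %in% tcr_chains, , drop = FALSE]
  B <- at[at$chain %in% tgt_chains, , drop = FALSE]
  # restrict to atoms near the other side (atom centres within 8 A) to keep
  # the dot clouds small; distant atoms cannot contribute interface points
  coA <- .coords(A); coB <- .coords(B)
  dAB <- outer(rowSums(coA^2), rowSums(coB^2), "+") - 2 * (coA %*% t(coB))
  nearA <- apply(dAB, 1, min) <= 8^2
  nearB <- apply(dAB, 2, min) <= 8^2
  if (!any(nearA) || !any(nearB)) stop("empty interface band: the two sides do not approach each other")
  A <- A[nearA, , drop = FALSE]; B <- B[nearB, , drop = FALSE]
  sa <- .dot_surface(.coords(A), .atom_radii(A, radii), n_points)
  sb <- .dot_surface(.coords(B), .atom_radii(B, radii), n_points)
  s_ab <- .sc_one_way(sa, sb, w, band)
  s_ba <- .sc_one_way(sb, sa, w, band)
  if (is.na(s_ab) || is.na(s_ba)) stop("empty interface band: no surface points within ", band, " A")
  structure(list(sc = mean(c(s_ab, s_ba)), w_parameter = w, band = band,
                 interface_point_count = c(A_to_B = nrow(sa$points), B_to_A = nrow(sb$points))),
            class = "shape_complementarity")
}

#' @export
print.shape_complementarity <- function(x, ...) {
  cat(sprintf("<shape_complementarity> sc = %.3f (w = %.2f /A^2, band = %.1f A)\n",
              x$sc, x$w_parameter, x$band))
  invisible(x)
}
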