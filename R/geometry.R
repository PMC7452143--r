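.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) stop("degenerate zero-length vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Peptide-binding groove reference frame
#'
#' Builds an orthonormal right-handed frame anchored on the pHLA groove:
#' origin at the centroid of the peptide C-alpha atoms; x along the peptide
#' principal axis oriented N to C; y in the groove plane pointing from the
#' alpha-2 helix side toward the alpha-1 helix side (orthogonalised against
#' x); z = x cross y, pointing from the groove toward the bound TCR.
#'
#' @param s A `mol_structure`.
#' @param a A `complex_annotation`.
#' @return A `groove_frame` list: `origin`, `x_axis`, `y_axis`, `z_axis`.
#' @export
compute_groove_frame <- function(s, a) {
  pep <- .calpha(s, .role_chain(a, "peptide"))
  if (nrow(pep) < 8) stop("peptide has ", nrow(pep), " CA atoms; need >= 8")
  co <- .coords(pep)
  origin <- unname(colMeans(co))
  pc <- prcomp(co, center = TRUE)
  x <- unname(pc$rotation[, 1])
  if (sum((co[nrow(co), ] - co[1, ]) * x) < 0) x <- -x

  hla <- .calpha(s, .role_chain(a, "HLA_heavy"))
  h1 <- a$helices$alpha1; h2 <- a$helices$alpha2
  c1 <- unname(colMeans(.coords(hla[hla$resno >= h1[1] & hla$resno <= h1[2], , drop = FALSE])))
  c2 <- unname(colMeans(.coords(hla[hla$resno >= h2[1] & hla$resno <= h2[2], , drop = FALSE])))
  if (any(!is.finite(c1)) || any(!is.finite(c2))) {
    stop("groove helices not found on HLA heavy chain within the annotated ranges")
  }
  y0 <- c1 - c2                       # alpha2 side -> alpha1 side
  y <- y0 - sum(y0 * x) * x
  if (sqrt(sum(y^2)) < 1e-6) {
    stop("degenerate groove geometry: helix-centroid axis is collinear with the peptide axis")
  }
  y <- .unit(y)
  structure(list(origin = origin, x_axis = .unit(x), y_axis = y,
                 z_axis = .cross(.unit(x), y)),
            class = "groove_frame")
}

# Calpha centroid of a variable domain, by rule
.domain_centroid <- function(s, a, role, centroid_rule) {
  ch <- .role_chain(a, role)
  ca <- .calpha(s, ch)
  rng <- a$variable_domains[[role]]
  if (is.null(rng)) stop("annotation lacks a variable-domain range for ", role)
  ca <- ca[ca$resno >= rng[1] & ca$resno <= rng[2], , drop = FALSE]
  if (centroid_rule == "disulfide_ca") {
    cys <- a$cys_positions[[role]]
    if (is.null(cys) || length(cys) != 2) {
      stop("annotation lacks the two conserved cysteine positions for ", role,
           " required by centroid_rule = 'disulfide_ca'; ",
           "use centroid_rule = 'domain_ca' instead")
    }
    ca <- ca[ca$resno %in% cys, , drop = FALSE]
    if (nrow(ca) != 2) {
      stop("conserved cysteine CA atoms not found for ", role,
           "; use centroid_rule = 'domain_ca' instead")
    }
  }
  unname(colMeans(.coords(ca)))
}

#' TCR-pHLA crossing angle
#'
#' The diagonal-docking angle of the TCR over the groove: the angle, in the
#' groove plane, between the Valpha-centroid to Vbeta-centroid vector and
#' the peptide axis, reported unsigned in [0, 180).
#'
#' @param s A `mol_structure`.
#' @param a A `complex_annotation`.
#' @param centroid_rule `"disulfide_ca"` (default; centroid of the two
#'   conserved cysteine C-alpha atoms per variable domain, matching the
#'   common centroid-sphere depiction) or `"domain_ca"` (all variable-domain
#'   C-alpha atoms).
#' @return A `crossing_angle` list: `angle` (degrees), `v_alpha_centroid`,
#'   `v_beta_centroid`, `definition_tag`.
#' @export
compute_crossing_angle <- function(s, a,
                                   centroid_rule = c("disulfide_ca", "domain_ca")) {
  centroid_rule <- match.arg(centroid_rule)
  fr <- compute_groove_frame(s, a)
  ca_a <- .domain_centroid(s, a, "TCR_alpha", centroid_rule)
  ca_b <- .domain_centroid(s, a, "TCR_beta", centroid_rule)
  v <- ca_b - ca_a
  vp <- v - sum(v * fr$z_axis) * fr$z_axis
  if (sqrt(sum(vp^2)) < 1e-9) stop("interdomain vector is normal to the groove plane")
  ang <- acos(max(-1, min(1, sum(.unit(vp) * fr$x_axis)))) * 180 / pi
  if (ang >= 180) ang <- 0
  structure(list(angle = ang, v_alpha_centroid = ca_a, v_beta_centroid = ca_b,
                 definition_tag = paste0("in-plane-unsigned/", centroid_rule)),
            class = "crossing_angle")
}

#' @export
print.crossing_angle <- function(x, ...) {
  cat(sprintf("<crossing_angle> %.1f deg  [%s]\n", x$angle, x$definition_tag))
  invisible(x)
}

#' Docking footprint position over the groove
#'
#' Displacement of the combined Valpha+Vbeta C-alpha centroid from the
#' groove origin, projected onto the groove frame: x along the peptide axis
#' (negative toward the peptide N terminus), y across the helices (positive
#' toward the alpha-1 helix).
#'
#' @inheritParams compute_crossing_angle
#' @return A `footprint_position` list: `x` and `y` displacements (Angstrom).
#' @export
compute_footprint <- function(s, a) {
  fr <- compute_groove_frame(s, a)
  ca <- rbind(
    .coords(.domain_atoms(s, a, "TCR_alpha")),
    .coords(.domain_atoms(s, a, "TCR_beta"))
  )
  d <- unname(colMeans(ca)) - fr$origin
  structure(list(x = sum(d * fr$x_axis), y = sum(d * fr$y_axis)),
            class = "footprint_position")
}

.domain_atoms <- function(s, a, role) {
  ca <- .calpha(s, .role_chain(a, role))
  rng <- a$variable_domains[[role]]
  if (is.null(rng)) stop("annotation lacks a variable-domain range for ", role)
  ca[ca$resno >= rng[1] & ca$resno <= rng[2], , drop = FALSE]
}

#' @export
print.footprint_position <- function(x, ...) {
  cat(sprintf("<footprint_position> x = %+.2f A (peptide axis), y = %+.2f A (across helices)\n",
              x$x, x$y))
  invisible(x)
}

#' Per-loop backbone RMSD between superposed complexes
#'
#' Superposes the variant complex onto the wild type using the HLA heavy
#' chain C-alpha atoms (least squares), then reports, for each annotated
#' CDR/HV4 loop, the backbone (N, CA, C, O) RMSD over positions matched by
#' residue number. Loops whose matched positions differ in count are
#' flagged `comparable = FALSE` rather than raising an error; missing atoms
#' are skipped and counted.
#'
#' @param wt,variant `mol_structure` objects.
#' @param wt_annotation,variant_annotation Matching annotations.
#' @return A data frame: `loop`, `chain_role`, `rmsd` (Angstrom, `NA` when
#'   not comparable), `n_atoms`, `n_skipped`, `comparable`.
#' @export
loop_rmsd <- function(wt, wt_annotation, variant, variant_annotation) {
  if (is.null(wt_annotation$loops)) stop("wild-type annotation carries no loop ranges")
  # superposition on HLA heavy chain CA
  hw <- .calpha(wt, .role_chain(wt_annotation, "HLA_heavy"))
  hv <- .calpha(variant, .role_chain(variant_annotation, "HLA_heavy"))
  common <- intersect(hw$resno, hv$resno)
  if (length(common) < 3) stop("fewer than 3 shared HLA CA positions for superposition")
  A <- .coords(hv[match(common, hv$resno), , drop = FALSE])  # mobile
  B <- .coords(hw[match(common, hw$resno), , drop = FALSE])  # fixed
  tr <- .kabsch(A, B)

  bb <- c("N", "CA", "C", "O")
  out <- list()
  for (lab in names(wt_annotation$loops)) {
    role <- if (endsWith(lab, "a")) "TCR_alpha" else "TCR_beta"
    rw <- wt_annotation$loops[[lab]]
    rv <- if (!is.null(variant_annotation$loops[[lab]])) variant_annotation$loops[[lab]] else rw
    aw <- .polymer_atoms(wt);  aw <- aw[aw$chain == .role_chain(wt_annotation, role) &
                                       aw$resno >= rw[1] & aw$resno <= rw[2] &
                                       aw$name %in% bb, , drop = FALSE]
    av <- .polymer_atoms(variant); av <- av[av$chain == .role_chain(variant_annotation, role) &
                                           av$resno >= rv[1] & av$resno <= rv[2] &
                                           av$name %in% bb, , drop = FALSE]
    kw <- paste(aw$resno, aw$name); kv <- paste(av$resno, av$name)
    shared <- intersect(kw, kv)
    n_skip <- (nrow(aw) - length(shared)) + (nrow(av) - length(shared))
    nres_w <- length(unique(aw$resno)); nres_v <- length(unique(av$resno))
    if (length(shared) == 0 || nres_w != nres_v) {
      out[[lab]] <- data.frame(loop = lab, chain_role = role, rmsd = NA_real_,
                               n_atoms = length(shared), n_skipped = n_skip,
                               comparable = FALSE, stringsAsFactors = FALSE)
      next
    }
    cw <- .coords(aw[match(shared, kw), , drop = FALSE])
    cv <- .coords(av[match(shared, kv), , drop = FALSE])
    cv <- .apply_transform(cv, tr)
    rmsd <- sqrt(mean(rowSums((cw - cv)^2)))
    out[[lab]] <- data.frame(loop = lab, chain_role = role, rmsd = rmsd,
                             n_atoms = length(shared), n_skipped = n_skip,
                             comparable = TRUE, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# least-squares rigid transform mapping A onto B (Kabsch); returns list(R, t)
.kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cb - as.numeric(R %*% ca))
}

.apply_transform <- function(X, tr) {
  sweep(X %*% t(tr$R), 2, tr$t, "+")
}
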