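#' Configuration for the binding-energy estimator
#'
#' Physical constants and model parameters of the simplified MM/GBSA
#' scheme. Defaults: internal dielectric 1, water dielectric 78.5, 150 mM
#' implicit 1:1 salt, nonpolar surface tension 0.0072 kcal/(mol Ų) with
#' zero offset, 298.15 K.
#'
#' @param eps_in,eps_out Internal and solvent dielectric constants.
#' @param coulomb_constant Electrostatic constant in kcal A / (mol e^2).
#' @param salt_molar Implicit monovalent salt concentration (M).
#' @param gamma_np,beta_np Nonpolar term: G_np = gamma * SASA + beta.
#' @param temperature Kelvin, used for K_D conversions.
#' @param gas_constant kcal/(mol K).
#' @param snapshot_count Default number of snapshots an MM/GBSA run draws
#'   from an ensemble (default 300).
#' @param sasa_points Quadrature points for the nonpolar term (default 240;
#'   the SASA difference entering binding energies converges quickly).
#' @return An `energetics_config` list.
#' @export
energetics_config <- function(eps_in = 1.0, eps_out = 78.5,
                              coulomb_constant = 332.0637,
                              salt_molar = 0.150,
                              gamma_np = 0.0072, beta_np = 0.0,
                              temperature = 298.15,
                              gas_constant = 1.9872e-3,
                              snapshot_count = 300,
                              sasa_points = 240) {
  stopifnot(eps_in > 0, eps_out > 0, salt_molar >= 0)
  structure(list(eps_in = eps_in, eps_out = eps_out,
                 coulomb_constant = coulomb_constant, salt_molar = salt_molar,
                 gamma_np = gamma_np, beta_np = beta_np,
                 temperature = temperature, gas_constant = gas_constant,
                 snapshot_count = snapshot_count, sasa_points = sasa_points),
            class = "energetics_config")
}

# Debye screening parameter (1/Angstrom) for monovalent salt in water, 298 K
.debye_kappa <- function(salt_molar) sqrt(salt_molar) / 3.047

#' Read a per-atom force-field parameter table
#'
#' Whitespace-delimited columns: `chain`, `resno`, `atom`, `charge` (e),
#' `rmin_half` (A), `epsilon` (kcal/mol), `born_radius` (A), `screen`
#' (dimensionless descreening scale). Lines starting with `#` are comments.
#'
#' @param path File path.
#' @return A `ff_parameters` data frame.
#' @export
read_parameters <- function(path) {
  df <- read.table(path, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("chain", "resno", "atom", "charge", "rmin_half", "epsilon",
            "born_radius", "screen")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("parameter table lacks column(s): ", paste(miss, collapse = ", "))
  class(df) <- c("ff_parameters", "data.frame")
  df
}

# match parameters to a set of atoms; error on any heavy atom without entries
.match_params <- function(atoms, params) {
  ka <- paste(atoms$chain, atoms$resno, atoms$atom %||% atoms$name, sep = "\r")
  kp <- paste(params$chain, params$resno, params$atom, sep = "\r")
  idx <- match(ka, kp)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("no force-field parameters for atom ",
         atoms$name[bad], " of residue ", atoms$chain[bad], atoms$resno[bad])
  }
  params[idx, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# heavy polymer atoms of the chains playing any role, with matched params
.energy_atoms <- function(s, params, a = NULL, chains = NULL) {
  at <- .polymer_atoms(s)
  at <- at[!at$water, , drop = FALSE]
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  p <- .match_params(at, params)
  list(atoms = at, co = .coords(at),
       q = p$charge, rmin_half = p$rmin_half, eps = p$epsilon,
       born = p$born_radius, screen = p$screen)
}

#' Molecular-mechanics interaction energy between TCR and pHLA
#'
#' Gas-phase pairwise sums over all inter-set heavy-atom pairs, no cutoff:
#' Coulomb k q_i q_j / (eps_in r_ij) and 12-6 Lennard-Jones with
#' Lorentz-Berthelot-style combination (rmin additive, epsilon geometric).
#'
#' @param s A `mol_structure` of the complex.
#' @param params A `ff_parameters` table covering every heavy atom.
#' @param a A `complex_annotation` (defines the TCR and pHLA atom sets).
#' @param config An [energetics_config()].
#' @return A list: `E_vdw`, `E_elec` (kcal/mol).
#' @export
mm_interaction_energy <- function(s, params, a, config = energetics_config()) {
  lig_chains <- c(.role_chain(a, "TCR_alpha"), .role_chain(a, "TCR_beta"))
  rec_chains <- c(.role_chain(a, "peptide"), .role_chain(a, "HLA_heavy"),
                  .role_chain(a, "beta2m"))
  L <- .energy_atoms(s, params, chains = lig_chains)
  R <- .energy_atoms(s, params, chains = rec_chains)
  d2 <- outer(rowSums(L$co^2), rowSums(R$co^2), "+") - 2 * (L$co %*% t(R$co))
  d <- sqrt(pmax(0, d2))
  if (any(d < 0.1)) stop("overlapping atoms across the interface (r < 0.1 A)")
  E_elec <- config$coulomb_constant / config$eps_in *
    sum(outer(L$q, R$q) / d)
  rmin <- outer(L$rmin_half, R$rmin_half, "+")
  epsij <- sqrt(outer(L$eps, R$eps))
  sr6 <- (rmin / d)^6
  E_vdw <- sum(epsij * (sr6^2 - 2 * sr6))
  list(E_vdw = E_vdw, E_elec = E_elec)
}

# ---- generalized Born (OBC-II style rescaled descreening) -----------------

GB_OFFSET <- 0.09            # intrinsic radius offset (Angstrom)
OBC_ALPHA <- 1.0; OBC_BETA <- 0.8; OBC_GAMMA <- 4.85

# effective Born radii by pairwise HCT descreening with OBC tanh rescaling
.effective_radii <- function(co, born, screen) {
  n <- nrow(co)
  rho <- born - GB_OFFSET
  if (any(rho <= 0)) {
    stop("intrinsic Born radius <= offset for atom index ", which(rho <= 0)[1])
  }
  I <- numeric(n)
  if (n > 1) {
    d <- as.matrix(dist(co))
    for (i in seq_len(n)) {
      r <- d[i, -i]
      sr <- screen[-i] * rho[-i]
      act <- rho[i] < r + sr                       # else j is inside i's sphere
      r <- r[act]; sr <- sr[act]
      if (!length(r)) next
      U <- r + sr
      L <- pmax(abs(r - sr), rho[i])
      term <- 0.5 * (1 / L - 1 / U +
                     (r - sr^2 / r) * (1 / U^2 - 1 / L^2) / 4 +
                     log(L / U) / (2 * r))
      term <- term + ifelse(rho[i] < sr - r, 1 / rho[i] - 1 / L, 0)
      I[i] <- sum(term)
    }
  }
  psi <- rho * I
  inv_eff <- 1 / rho - tanh(OBC_ALPHA * psi - OBC_BETA * psi^2 + OBC_GAMMA * psi^3) / born
  if (any(inv_eff <= 0)) {
    stop("nonpositive effective Born radius for atom index ", which(inv_eff <= 0)[1])
  }
  1 / inv_eff
}

# full symmetric GB energy matrix (kcal/mol) in the Still double-sum
# convention: G_pol = sum over all (i, j) including i = j; the diagonal is
# the self term since f_ii reduces to R_i at zero distance
.gb_pair_matrix <- function(co, q, Reff, config) {
  kappa <- .debye_kappa(config$salt_molar)
  d2 <- as.matrix(dist(co))^2
  RR <- outer(Reff, Reff)
  f <- sqrt(d2 + RR * exp(-d2 / (4 * RR)))
  pref <- (1 / config$eps_in - exp(-kappa * f) / config$eps_out)
  -(config$coulomb_constant / 2) * pref * outer(q, q) / f
}

#' Generalized-Born polar solvation energy
#'
#' OBC-style generalized Born: effective radii from pairwise descreening
#' integrals with the OBC tanh rescaling, energy from the Still pairwise
#' form with Debye-Hueckel salt screening:
#' G = -(k/2) sum_ij (1/eps_in - exp(-kappa f_ij)/eps_out) q_i q_j / f_ij,
#' f_ij = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j))).
#'
#' @param s A `mol_structure` (or pass `chains` to restrict the atom set).
#' @param params A `ff_parameters` table.
#' @param config An [energetics_config()].
#' @param chains Optional chain subset.
#' @return A list: `G_pol` (kcal/mol), `per_atom` (self plus half of each
#'   cross term), `effective_radii`.
#' @export
gb_polar_energy <- function(s, params, config = energetics_config(), chains = NULL) {
  E <- .energy_atoms(s, params, chains = chains)
  Reff <- .effective_radii(E$co, E$born, E$screen)
  M <- .gb_pair_matrix(E$co, E$q, Reff, config)
  # each unordered pair {i, j} appears twice in the double sum; assigning the
  # row sums gives every atom its self term plus half of each pair's total
  per_atom <- rowSums(M)
  list(G_pol = sum(M), per_atom = per_atom, effective_radii = Reff)
}

#' Nonpolar solvation term
#'
#' G_np = gamma * SASA + beta over the selected atoms.
#'
#' @inheritParams gb_polar_energy
#' @param probe Probe radius (Angstrom).
#' @return A list: `G_np` (kcal/mol), `sasa`, `per_atom`.
#' @export
nonpolar_energy <- function(s, config = energetics_config(), chains = NULL,
                            probe = 1.4) {
  sub <- if (is.null(chains)) s else .subset_chains(s, chains)
  sr <- compute_sasa(sub, probe = probe, n_points = config$sasa_points)
  list(G_np = config$gamma_np * sr$total + config$beta_np, sasa = sr$total,
       per_atom = config$gamma_np * sr$atom_area)
}

# role -> chain sets for the binding calculation
.binding_sets <- function(a) {
  list(lig = c(.role_chain(a, "TCR_alpha"), .role_chain(a, "TCR_beta")),
       rec = c(.role_chain(a, "peptide"), .role_chain(a, "HLA_heavy"),
               .role_chain(a, "beta2m")))
}

# single-snapshot binding energy components (single-trajectory convention:
# receptor and ligand conformations are taken from the complex frame, so
# internal MM energies cancel and only interaction + desolvation remain)
.snapshot_binding <- function(s, params, a, config) {
  sets <- .binding_sets(a)
  mm <- mm_interaction_energy(s, params, a, config)
  gb_c <- gb_polar_energy(s, params, config, chains = c(sets$lig, sets$rec))
  gb_r <- gb_polar_energy(s, params, config, chains = sets$rec)
  gb_l <- gb_polar_energy(s, params, config, chains = sets$lig)
  np_c <- nonpolar_energy(s, config, chains = c(sets$lig, sets$rec))
  np_r <- nonpolar_energy(s, config, chains = sets$rec)
  np_l <- nonpolar_energy(s, config, chains = sets$lig)
  c(E_vdw = mm$E_vdw, E_elec = mm$E_elec,
    G_pol = gb_c$G_pol - gb_r$G_pol - gb_l$G_pol,
    G_np = np_c$G_np - np_r$G_np - np_l$G_np + config$beta_np)
}

# normalise snapshots input to a list of mol_structure per replica
.snapshot_list <- function(snapshots) {
  if (inherits(snapshots, "trajectory_ensemble")) {
    lapply(seq_along(snapshots$replicas), function(k) {
      ff <- .analysis_frames(snapshots, k)
      lapply(ff, function(f) .frame_structure(snapshots$topology,
                                              snapshots$replicas[[k]][f, ]))
    })
  } else if (inherits(snapshots, "mol_structure")) {
    list(list(snapshots))
  } else if (is.list(snapshots) && all(vapply(snapshots, inherits, logical(1),
                                              "mol_structure"))) {
    list(snapshots)
  } else {
    stop("snapshots must be a trajectory_ensemble, a mol_structure, or a list of them")
  }
}

#' Single-trajectory MM/GBSA binding energy
#'
#' For each snapshot, the binding energy is the inter-set molecular
#' mechanics interaction (vdW + Coulomb) plus the change in generalized-Born
#' polar solvation and in the nonpolar surface term on complex formation,
#' with receptor and ligand conformations extracted from the complex frames
#' (so internal energies cancel). The estimate is the snapshot mean; the
#' spread is the standard deviation of per-replica means.
#'
#' @param snapshots A `trajectory_ensemble`, a single `mol_structure`, or a
#'   list of `mol_structure` snapshots.
#' @param params A `ff_parameters` table.
#' @param a A `complex_annotation`.
#' @param config An [energetics_config()].
#' @param max_snapshots Cap on snapshots per replica, equally spaced
#'   (default `config$snapshot_count`).
#' @return A `binding_energy` list: `dG_bind`, `sd` (between replicas; over
#'   snapshots when only one replica), `components` (means), `n_snapshots`,
#'   `per_replica`.
#' @export
mmgbsa_binding <- function(snapshots, params, a, config = energetics_config(),
                           max_snapshots = config$snapshot_count) {
  reps <- .snapshot_list(snapshots)
  if (!length(reps) || !length(reps[[1]])) stop("empty snapshot list")
  per_rep <- list()
  all_vals <- list()
  for (k in seq_along(reps)) {
    snaps <- reps[[k]]
    if (length(snaps) > max_snapshots) {
      snaps <- snaps[round(seq(1, length(snaps), length.out = max_snapshots))]
    }
    comps <- t(vapply(snaps, .snapshot_binding, numeric(4),
                      params = params, a = a, config = config))
    per_rep[[k]] <- comps
    all_vals[[k]] <- rowSums(comps)
  }
  rep_means <- vapply(all_vals, mean, numeric(1))
  vals <- unlist(all_vals)
  comp_mean <- colMeans(do.call(rbind, per_rep))
  structure(list(
    dG_bind = mean(rep_means),
    sd = if (length(rep_means) > 1) sd(rep_means) else
      (if (length(vals) > 1) sd(vals) else 0),
    components = comp_mean,
    n_snapshots = length(vals),
    per_replica = rep_means
  ), class = "binding_energy")
}

#' @export
print.binding_energy <- function(x, ...) {
  cat(sprintf("<binding_energy> dG_bind = %.3f +/- %.3f kcal/mol (%d snapshots)\n",
              x$dG_bind, x$sd, x$n_snapshots))
  print(round(x$components, 3))
  invisible(x)
}

#' Per-residue decomposition of the MM/GBSA binding energy
#'
#' Attributes the snapshot-averaged binding energy to individual residues:
#' inter-set MM pair terms and GB cross terms are split half-half between
#' the two partner residues; GB self-term changes and nonpolar (SASA)
#' changes go to the owning residue. Residue contributions sum to the total
#' binding energy exactly (to numerical roundoff).
#'
#' @inheritParams mmgbsa_binding
#' @return A `per_residue_energy` data frame: `chain`, `resno`, `resname`,
#'   `vdw`, `elec`, `gb`, `np`, `total`, with attribute `"dG_bind"`.
#' @export
decompose_per_residue <- function(snapshots, params, a,
                                  config = energetics_config(),
                                  max_snapshots = config$snapshot_count) {
  reps <- .snapshot_list(snapshots)
  if (!length(reps) || !length(reps[[1]])) stop("empty snapshot list")
  snaps <- unlist(reps, recursive = FALSE)
  if (length(snaps) > max_snapshots) {
    snaps <- snaps[round(seq(1, length(snaps), length.out = max_snapshots))]
  }
  acc <- NULL
  for (s in snaps) {
    d <- .decompose_snapshot(s, params, a, config)
    if (is.null(acc)) acc <- d else {
      acc[, c("vdw", "elec", "gb", "np")] <-
        acc[, c("vdw", "elec", "gb", "np")] + d[, c("vdw", "elec", "gb", "np")]
    }
  }
  acc[, c("vdw", "elec", "gb", "np")] <- acc[, c("vdw", "elec", "gb", "np")] / length(snaps)
  acc$total <- acc$vdw + acc$elec + acc$gb + acc$np
  attr(acc, "dG_bind") <- sum(acc$total)
  class(acc) <- c("per_residue_energy", "data.frame")
  acc
}

.decompose_snapshot <- function(s, params, a, config) {
  sets <- .binding_sets(a)
  all_chains <- c(sets$lig, sets$rec)
  E <- .energy_atoms(s, params, chains = all_chains)
  at <- E$atoms
  res_key <- paste(at$chain, at$resno, sep = "\r")
  res_ids <- unique(res_key)
  ridx <- match(res_key, res_ids)
  nres <- length(res_ids)
  is_lig <- at$chain %in% sets$lig

  out <- data.frame(
    chain = at$chain[!duplicated(res_key)],
    resno = at$resno[!duplicated(res_key)],
    resname = at$resname[!duplicated(res_key)],
    vdw = 0, elec = 0, gb = 0, np = 0,
    stringsAsFactors = FALSE)

  # MM interaction terms: inter-set pairs only, split half-half
  li <- which(is_lig); rj <- which(!is_lig)
  d <- sqrt(pmax(0, outer(rowSums(E$co[li, , drop = FALSE]^2),
                          rowSums(E$co[rj, , drop = FALSE]^2), "+") -
                   2 * E$co[li, , drop = FALSE] %*% t(E$co[rj, , drop = FALSE])))
  if (any(d < 0.1)) stop("overlapping atoms across the interface (r < 0.1 A)")
  eterm <- config$coulomb_constant / config$eps_in * outer(E$q[li], E$q[rj]) / d
  rmin <- outer(E$rmin_half[li], E$rmin_half[rj], "+")
  sr6 <- (rmin / d)^6
  vterm <- sqrt(outer(E$eps[li], E$eps[rj])) * (sr6^2 - 2 * sr6)
  for (part in list(list(m = eterm, col = "elec"), list(m = vterm, col = "vdw"))) {
    by_li <- rowSums(part$m) / 2
    by_rj <- colSums(part$m) / 2
    out[[part$col]] <- out[[part$col]] +
      as.numeric(tapply(c(by_li, by_rj), c(ridx[li], ridx[rj]), sum)[as.character(seq_len(nres))] |>
                   (\(v) ifelse(is.na(v), 0, v))())
  }

  # GB terms: complex minus separated parts, pairwise matrices
  gb_part <- function(chains) {
    sub <- which(at$chain %in% chains)
    Reff <- .effective_radii(E$co[sub, , drop = FALSE], E$born[sub], E$screen[sub])
    M <- .gb_pair_matrix(E$co[sub, , drop = FALSE], E$q[sub], Reff, config)
    list(idx = sub, M = M)
  }
  gc <- gb_part(all_chains); gr <- gb_part(sets$rec); gl <- gb_part(sets$lig)
  dM <- gc$M
  dM[match(gr$idx, gc$idx), match(gr$idx, gc$idx)] <-
    dM[match(gr$idx, gc$idx), match(gr$idx, gc$idx)] - gr$M
  dM[match(gl$idx, gc$idx), match(gl$idx, gc$idx)] <-
    dM[match(gl$idx, gc$idx), match(gl$idx, gc$idx)] - gl$M
  # row sums give each atom its self-term change plus half of every pair's
  # change (the double-sum counts each unordered pair twice)
  atom_gb <- rowSums(dM)
  out$gb <- out$gb + as.numeric(tapply(atom_gb, ridx[gc$idx], sum)[as.character(seq_len(nres))] |>
                                  (\(v) ifelse(is.na(v), 0, v))())

  # nonpolar: per-atom SASA change times gamma, to the owner residue
  np_atom <- function(chains) {
    sub <- .subset_chains(s, chains)
    sr <- compute_sasa(sub, n_points = config$sasa_points)
    k <- paste(sr$atoms$chain, sr$atoms$resno, sr$atoms$name, sep = "\r")
    setNames(config$gamma_np * sr$atom_area, k)
  }
  nc <- np_atom(all_chains); nr_ <- np_atom(sets$rec); nl <- np_atom(sets$lig)
  parts <- c(nr_, nl)
  dnp <- nc - parts[names(nc)]
  akey <- paste(at$chain, at$resno, at$name, sep = "\r")
  out$np <- out$np + as.numeric(tapply(dnp[akey], ridx, sum)[as.character(seq_len(nres))] |>
                                  (\(v) ifelse(is.na(v), 0, v))())
  out
}

#' @export
print.per_residue_energy <- function(x, ...) {
  cat(sprintf("<per_residue_energy> %d residue(s); dG_bind = %.3f kcal/mol\n",
              nrow(x), attr(x, "dG_bind")))
  top <- x[order(x$total), ][seq_len(min(5, nrow(x))), ]
  print.data.frame(top, digits = 3)
  invisible(x)
}

#' Classify per-residue binding-energy changes
#'
#' ddG = dG(variant) - dG(wild type) per matched residue, labelled
#' `favorable` when ddG <= -threshold, `unfavorable` when ddG >= +threshold,
#' `neutral` in between. Positions whose residue identity differs are
#' flagged as mutation sites.
#'
#' @param wt,variant `per_residue_energy` tables.
#' @param threshold Classification threshold in kcal/mol (default 0.5).
#' @return An `energy_classification` data frame: `chain`, `resno`,
#'   `resname_wt`, `resname_variant`, `ddG`, `label`, `mutation_site`.
#' @export
classify_ddg <- function(wt, variant, threshold = 0.5) {
  kw <- paste(wt$chain, wt$resno); kv <- paste(variant$chain, variant$resno)
  common <- intersect(kw, kv)
  iw <- match(common, kw); iv <- match(common, kv)
  ddg <- variant$total[iv] - wt$total[iw]
  label <- ifelse(ddg <= -threshold, "favorable",
                  ifelse(ddg >= threshold, "unfavorable", "neutral"))
  out <- data.frame(chain = wt$chain[iw], resno = wt$resno[iw],
                    resname_wt = wt$resname[iw],
                    resname_variant = variant$resname[iv],
                    ddG = ddg, label = label,
                    mutation_site = wt$resname[iw] != variant$resname[iv],
                    stringsAsFactors = FALSE)
  class(out) <- c("energy_classification", "data.frame")
  out
}

#' @export
print.energy_classification <- function(x, ...) {
  cat("<energy_classification> ", nrow(x), " residue(s): ",
      sum(x$label == "favorable"), " favorable, ",
      sum(x$label == "neutral"), " neutral, ",
      sum(x$label == "unfavorable"), " unfavorable\n", sep = "")
  invisible(x)
}

#' Experimental binding free energy from a dissociation constant
#'
#' dG = R T ln(K_D) with K_D in molar.
#'
#' @param kd_nM Dissociation constant in nanomolar.
#' @param config An [energetics_config()] (supplies R and T).
#' @return dG in kcal/mol (negative for binding).
#' @export
kd_to_dg <- function(kd_nM, config = energetics_config()) {
  if (any(kd_nM <= 0)) stop("K_D must be positive")
  config$gas_constant * config$temperature * log(kd_nM * 1e-9)
}

#' Affinity fold change between wild type and variant
#'
#' fold = K_D(wild type) / K_D(variant); > 1 means the variant binds more
#' tightly.
#'
#' @param kd_wt_nM,kd_variant_nM Dissociation constants in nanomolar.
#' @return The fold change (dimensionless).
#' @export
fold_change <- function(kd_wt_nM, kd_variant_nM) {
  if (any(c(kd_wt_nM, kd_variant_nM) <= 0)) stop("K_D must be positive")
  kd_wt_nM / kd_variant_nM
}

#' Experimental ddG between wild type and variant
#'
#' ddG = R T ln(K_D,variant / K_D,wt); negative when the variant binds more
#' tightly.
#'
#' @inheritParams fold_change
#' @param config An [energetics_config()].
#' @return ddG in kcal/mol.
#' @export
ddg_exp <- function(kd_wt_nM, kd_variant_nM, config = energetics_config()) {
  if (any(c(kd_wt_nM, kd_variant_nM) <= 0)) stop("K_D must be positive")
  config$gas_constant * config$temperature * log(kd_variant_nM / kd_wt_nM)
}

#' Rank agreement between computed and experimental ddG values
#'
#' Per-pair sign agreement and the Spearman rank correlation across pairs.
#'
#' @param computed,experimental Numeric vectors of ddG values, same order.
#' @return A list: `sign_agreement` (fraction), `n_agree`, `n`,
#'   `spearman_rho`.
#' @export
rank_correlation <- function(computed, experimental) {
  if (length(computed) != length(experimental)) {
    stop("computed and experimental ddG lists differ in length")
  }
  if (length(computed) < 2) stop("need at least 2 pairs")
  agree <- sign(computed) == sign(experimental)
  list(sign_agreement = mean(agree), n_agree = sum(agree), n = length(agree),
       spearman_rho = suppressWarnings(cor(computed, experimental,
                                           method = "spearman")))
}

#' Read an affinity table
#'
#' CSV with columns `label`, `kd_nM` and optional `on_rate` (1/(M s)),
#' `off_rate` (1/s) plus any grouping columns. When both rates are present
#' the kinetic estimate off_rate/on_rate is compared with the reported K_D
#' and the ratio recorded in `kd_kinetic_ratio` (reported, not enforced).
#' A curated table of published TCR-pHLA affinities ships with the package:
#' `system.file("extdata", "tcr_affinities.csv", package = "tcrlens")`.
#'
#' @param path CSV file path.
#' @return An `affinity_table` data frame.
#' @export
read_affinities <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "kd_nM") %in% names(df))) {
    stop("affinity table needs at least columns 'label' and 'kd_nM'")
  }
  if (any(!is.na(df$kd_nM) & df$kd_nM <= 0)) stop("K_D must be positive")
  if (all(c("on_rate", "off_rate") %in% names(df))) {
    kin <- df$off_rate / df$on_rate * 1e9      # nM
    df$kd_kinetic_ratio <- kin / df$kd_nM
  }
  class(df) <- c("affinity_table", "data.frame")
  df
}
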