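# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.atom_row <- function(serial, name, resname, chain, resno, x, y, z, element) {
  data.frame(serial = serial, name = name, altloc = "", resname = resname,
             chain = chain, resno = resno, insert = "", x = x, y = y, z = z,
             occ = 1, b = 0, element = element, het = FALSE, water = FALSE,
             hydrogen = FALSE, stringsAsFactors = FALSE)
}

#' Generate a toy TCR-pHLA complex with known geometry
#'
#' Builds a five-chain C-alpha-level pseudo-complex whose binding geometry
#' is known by construction: the peptide lies along the laboratory x axis,
#' the two groove pseudo-helices flank it along +/- y, and the two
#' pseudo-variable domains sit above the groove so that
#' [compute_crossing_angle()] recovers `crossing_angle` and
#' [compute_footprint()] recovers `footprint_offset`. Each variable domain
#' is a point-symmetric blob (so the domain and disulfide centroid rules
#' coincide exactly); contacts can be planted across the interface at
#' requested distances and types. These are geometric stand-ins, not
#' physically realistic proteins.
#'
#' @param crossing_angle Requested crossing angle in degrees, [0, 180).
#' @param footprint_offset Requested (x, y) displacement of the combined
#'   variable-domain centroid over the groove, Angstrom.
#' @param peptide_length Peptide residues (>= 8, default 9).
#' @param planted_contacts List of contact specs; each a list with fields
#'   `type` (`"vdW"`, `"HB"` or `"SB"`), `target` (`"peptide"` or `"HLA"`),
#'   `tcr_chain` (`"alpha"` or `"beta"`), `distance` (Angstrom, in
#'   (1.5, 6]), and optional `target_resno`.
#' @param chain_lengths Named residue counts `hla`, `b2m`, `tcr_alpha`,
#'   `tcr_beta` (defaults 275, 99, 200, 240, sized like the real chains).
#' @param seed Integer seed for the domain-blob offsets.
#' @return A list: `structure` (`mol_structure`) and `annotation`
#'   (`complex_annotation`).
#' @export
make_toy_complex <- function(crossing_angle = 45, footprint_offset = c(0, 0),
                             peptide_length = 9, planted_contacts = list(),
                             chain_lengths = c(hla = 275, b2m = 99,
                                               tcr_alpha = 200, tcr_beta = 240),
                             seed = 1) {
  if (crossing_angle < 0 || crossing_angle >= 180) {
    stop("crossing_angle must lie in [0, 180)")
  }
  if (peptide_length < 8) stop("peptide_length must be >= 8")
  col <- list(name = character(), resname = character(), chain = character(),
              resno = integer(), x = numeric(), y = numeric(), z = numeric(),
              element = character())
  add <- function(name, resname, chain, resno, x, y, z, element = substr(name, 1, 1)) {
    n <- length(x)
    col$name <<- c(col$name, rep_len(name, n))
    col$resname <<- c(col$resname, rep_len(resname, n))
    col$chain <<- c(col$chain, rep_len(chain, n))
    col$resno <<- c(col$resno, as.integer(resno))
    col$x <<- c(col$x, x); col$y <<- c(col$y, y); col$z <<- c(col$z, z)
    col$element <<- c(col$element, rep_len(element, n))
  }

  # peptide (chain C) along x, centred at the origin
  L <- peptide_length
  pep_x <- ((seq_len(L)) - (L + 1) / 2) * 3.8
  add("CA", "ALA", "C", seq_len(L), pep_x, rep(0, L), rep(0, L), "C")

  # groove pseudo-helices on the HLA heavy chain (chain A)
  hel_x <- seq(-22, by = 4, length.out = 12)
  add("CA", "ALA", "A", 49L + 1:12, hel_x, rep(9, 12), rep(0, 12), "C")
  add("CA", "ALA", "A", 139L + 1:12, hel_x, rep(-9, 12), rep(0, 12), "C")

  grid_fill <- function(chain, resnos, z0, x0) {
    m <- seq_along(resnos)
    add("CA", "GLY", chain, resnos,
        x0 + 5 * ((m - 1) %% 17), -40 + 5 * ((m - 1) %/% 17), rep(z0, length(m)), "C")
  }
  n_hla <- chain_lengths[["hla"]]
  if (n_hla < 152) stop("hla chain length must cover both helix ranges (>= 152)")
  grid_fill("A", c(1:49, 62:139, 152:(n_hla)), -15, -40)
  grid_fill("B", seq_len(chain_lengths[["b2m"]]), -30, -40)

  # variable domains: 110-residue point-symmetric blobs about their centroids
  phi <- crossing_angle * pi / 180
  u <- c(cos(phi), sin(phi), 0)
  mid <- c(footprint_offset[1], footprint_offset[2], 25)
  dsep <- 24
  cen <- list(D = mid - (dsep / 2) * u, E = mid + (dsep / 2) * u)
  offs <- .with_seed(seed, matrix(runif(55 * 3, -6, 6), ncol = 3))
  dom_res <- c(rep("ALA", 110))
  dom_res[c(22, 89)] <- "CYS"
  for (ch in c("D", "E")) {
    pts <- rbind(sweep(offs, 2, cen[[ch]], "+"),
                 sweep(-offs[55:1, , drop = FALSE], 2, cen[[ch]], "+"))
    add("CA", dom_res, ch, 1:110, pts[, 1], pts[, 2], pts[, 3], "C")
  }
  # framework filler beyond the variable domain, well above the groove
  n_a <- chain_lengths[["tcr_alpha"]]; n_b <- chain_lengths[["tcr_beta"]]
  if (n_a > 110) grid_fill("D", 121:(121 + n_a - 111), 50, -60)
  if (n_b > 110) grid_fill("E", 121:(121 + n_b - 111), 50, 30)

  # planted interface contacts
  used_pep <- integer(); used_hla <- integer(); next_loop <- c(D = 111L, E = 111L)
  for (pc in planted_contacts) {
    type <- match.arg(pc$type, c("vdW", "HB", "SB"))
    target <- match.arg(pc$target, c("peptide", "HLA"))
    tchain <- if (match.arg(pc$tcr_chain, c("alpha", "beta")) == "alpha") "D" else "E"
    d <- pc$distance
    if (is.null(d) || d <= 1.5 || d > 6) {
      stop("infeasible planted contact: distance must lie in (1.5, 6] Angstrom")
    }
    if (target == "peptide") {
      rn_t <- pc$target_resno %||% setdiff(2:(L - 1), used_pep)[1]
      if (is.na(rn_t) || rn_t %in% used_pep) stop("infeasible planted contact: no free peptide residue")
      used_pep <- c(used_pep, rn_t)
      base <- c(pep_x[rn_t], 0, 0); t_chain <- "C"
    } else {
      k <- setdiff(1:12, used_hla)[1]
      if (is.na(k)) stop("infeasible planted contact: no free helix residue")
      used_hla <- c(used_hla, k)
      rn_t <- pc$target_resno %||% (49L + k)
      base <- c(hel_x[k], 9, 0); t_chain <- "A"
    }
    spec <- switch(type,
      HB  = list(t_atom = "O",   t_res = NULL,  p_atom = "N",  p_res = "GLY", t_el = "O", p_el = "N"),
      SB  = list(t_atom = "OE1", t_res = "GLU", p_atom = "NZ", p_res = "LYS", t_el = "O", p_el = "N"),
      vdW = list(t_atom = "CB",  t_res = NULL,  p_atom = "CB", p_res = "ALA", t_el = "C", p_el = "C"))
    add(spec$t_atom, spec$t_res %||% "ALA", t_chain, rn_t,
        base[1], base[2], base[3] + 2, spec$t_el)
    if (!is.null(spec$t_res)) {
      # retype the residue the target atom joins (salt-bridge chemistry)
      col$resname[col$chain == t_chain & col$resno == rn_t] <- spec$t_res
    }
    add(spec$p_atom, spec$p_res, tchain, next_loop[[tchain]],
        base[1], base[2], base[3] + 2 + d, spec$p_el)
    next_loop[[tchain]] <- next_loop[[tchain]] + 1L
  }

  atoms_df <- .atom_row(seq_along(col$name), col$name, col$resname, col$chain,
                        col$resno, col$x, col$y, col$z, col$element)
  s <- structure(list(atoms = atoms_df, entry_id = "TOY", resolution = NA_real_,
                      source = "make_toy_complex"),
                 class = "mol_structure")
  ann <- structure(list(
    roles = c(TCR_alpha = "D", TCR_beta = "E", HLA_heavy = "A",
              beta2m = "B", peptide = "C"),
    variable_domains = list(TCR_alpha = c(1L, 110L), TCR_beta = c(1L, 110L)),
    loops = list(CDR1a = c(24L, 31L), CDR2a = c(48L, 55L), HV4a = c(65L, 74L),
                 CDR3a = c(93L, 104L),
                 CDR1b = c(24L, 31L), CDR2b = c(48L, 55L), HV4b = c(65L, 74L),
                 CDR3b = c(93L, 104L)),
    helices = list(alpha1 = c(50L, 61L), alpha2 = c(140L, 151L)),
    cys_positions = list(TCR_alpha = c(22L, 89L), TCR_beta = c(22L, 89L))
  ), class = "complex_annotation")
  list(structure = s, annotation = ann)
}

#' Generate a replica ensemble with planted fluctuation profiles
#'
#' Frames are the base structure plus isotropic Gaussian noise, the
#' per-coordinate standard deviation set residue-wise by `sigma`; the
#' expected C-alpha RMSF of a residue is sigma * sqrt(3). Optional
#' two-state hydrogen-bond switching moves a designated atom between a
#' bound and an unbound distance from its partner with Bernoulli
#' probability per frame.
#'
#' @param base A `mol_structure`.
#' @param replicas,frames Ensemble dimensions (defaults 10 and 100).
#' @param sigma Per-residue, per-coordinate noise in Angstrom; a scalar or a
#'   vector over the residues of `base` in order of appearance.
#' @param hb_pairs Optional data frame: `chain`, `resno`, `atom` (the mobile
#'   atom), `partner_chain`, `partner_resno`, `partner_atom`, `p_bound`,
#'   and optional `d_bound` (default 2.9) and `d_free` (default 4.5).
#' @param seed Integer seed; generation is reproducible given
#'   (arguments, seed).
#' @param burn_in_fraction Passed to [trajectory_ensemble()] (default 0).
#' @param frame_interval Metadata, ns per frame.
#' @return A `trajectory_ensemble`.
#' @export
make_ensemble <- function(base, replicas = 10, frames = 100, sigma = 0.3,
                          hb_pairs = NULL, seed = 1, burn_in_fraction = 0,
                          frame_interval = NA_real_) {
  stopifnot(inherits(base, "mol_structure"), all(sigma >= 0))
  a <- base$atoms
  res_key <- paste(a$chain, a$resno, sep = "\r")
  res_ids <- unique(res_key)
  if (length(sigma) == 1) sigma <- rep(sigma, length(res_ids))
  if (length(sigma) != length(res_ids)) {
    stop("sigma must be scalar or one value per residue (", length(res_ids), ")")
  }
  atom_sigma <- sigma[match(res_key, res_ids)]
  base_xyz <- as.vector(t(.coords(a)))
  col_sigma <- rep(atom_sigma, each = 3)

  mobile <- integer(0); mob_dir <- NULL; mob_anchor <- NULL
  if (!is.null(hb_pairs)) {
    if (is.null(hb_pairs$d_bound)) hb_pairs$d_bound <- 2.9
    if (is.null(hb_pairs$d_free)) hb_pairs$d_free <- 4.5
    find_atom <- function(ch, rn, nm) {
      i <- which(a$chain == ch & a$resno == rn & a$name == nm)
      if (length(i) != 1) stop("hb_pairs atom ", nm, " of ", ch, rn, " not found")
      i
    }
    mobile <- mapply(find_atom, hb_pairs$chain, hb_pairs$resno, hb_pairs$atom)
    anchor <- mapply(find_atom, hb_pairs$partner_chain, hb_pairs$partner_resno,
                     hb_pairs$partner_atom)
    mob_anchor <- .coords(a)[anchor, , drop = FALSE]
    dirs <- .coords(a)[mobile, , drop = FALSE] - mob_anchor
    mob_dir <- dirs / sqrt(rowSums(dirs^2))
  }

  reps <- .with_seed(seed, {
    lapply(seq_len(replicas), function(k) {
      noise <- matrix(rnorm(frames * length(base_xyz), 0,
                            rep(col_sigma, each = frames)),
                      nrow = frames)
      X <- sweep(noise, 2, base_xyz, "+")
      if (length(mobile)) {
        for (p in seq_along(mobile)) {
          bound <- runif(frames) < hb_pairs$p_bound[p]
          dist <- ifelse(bound, hb_pairs$d_bound[p], hb_pairs$d_free[p])
          pos <- mob_anchor[rep(p, frames), , drop = FALSE] +
            outer(dist, mob_dir[p, ])
          X[, .xyz_cols(mobile[p])] <- pos
        }
      }
      X
    })
  })
  trajectory_ensemble(base, reps, frame_interval = frame_interval,
                      burn_in_fraction = burn_in_fraction)
}

#' Generate a toy force-field parameter table
#'
#' Deterministic per-atom parameter assignment sufficient for exercising
#' the energetics module; not a physical force field.
#'
#' @param s A `mol_structure`.
#' @param scheme `"neutral"` (all charges zero), `"single_ion"` (unit charge
#'   on the first atom), `"random"` (seeded small charges and varied radii),
#'   or `"polar"` (alternating +/- 0.4 e charges).
#' @param seed Seed for the `"random"` scheme.
#' @return A `ff_parameters` data frame.
#' @export
make_toy_parameters <- function(s, scheme = c("neutral", "single_ion", "random",
                                              "polar"), seed = 1) {
  scheme <- match.arg(scheme)
  a <- .polymer_atoms(s)
  a <- a[!a$water, , drop = FALSE]
  n <- nrow(a)
  df <- data.frame(chain = a$chain, resno = a$resno, atom = a$name,
                   charge = 0, rmin_half = 1.7, epsilon = 0.1,
                   born_radius = 1.5, screen = 0.8,
                   stringsAsFactors = FALSE)
  if (scheme == "single_ion") {
    df$charge[1] <- 1
  } else if (scheme == "polar") {
    df$charge <- rep_len(c(0.4, -0.4), n)
  } else if (scheme == "random") {
    .with_seed(seed, {
      df$charge <- runif(n, -0.5, 0.5)
      df$born_radius <- runif(n, 1.3, 2.0)
      df$rmin_half <- runif(n, 1.5, 2.0)
      df$epsilon <- runif(n, 0.05, 0.2)
    })
  }
  class(df) <- c("ff_parameters", "data.frame")
  df
}

#' Generate a toy single-chain C-alpha trace
#'
#' An extended C-alpha trace (3.8 A spacing along x), handy as the base
#' structure for replica-ensemble fixtures.
#'
#' @param n_residues Number of residues.
#' @param chain Chain identifier (default `"D"`).
#' @param start_resno First residue number (default 1).
#' @return A `mol_structure`.
#' @export
make_toy_chain <- function(n_residues, chain = "D", start_resno = 1L) {
  stopifnot(n_residues >= 1)
  i <- seq_len(n_residues)
  atoms <- .atom_row(i, "CA", "ALA", chain, start_resno + i - 1L,
                     (i - 1) * 3.8, 0, 0, "C")
  structure(list(atoms = atoms, entry_id = "TOYCHAIN", resolution = NA_real_,
                 source = "make_toy_chain"),
            class = "mol_structure")
}
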