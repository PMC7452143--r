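#' Multi-replica coordinate ensemble
#'
#' Bundles a topology structure with one coordinate-frame matrix per
#' replica. Frames follow the flat xyz layout used by bio3d: one row per
#' frame, columns x1, y1, z1, x2, ...
#'
#' @param topology A `mol_structure` describing the atoms.
#' @param replicas List of numeric matrices, each frames x (3 * n_atoms).
#' @param frame_interval Nanoseconds per frame (metadata, default `NA`).
#' @param burn_in_fraction Fraction of initial frames discarded by the
#'   analysis operations (default 0.10, mirroring the common practice of
#'   dropping the first tenth of each production run).
#' @return A `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(topology, replicas, frame_interval = NA_real_,
                                burn_in_fraction = 0.10) {
  stopifnot(inherits(topology, "mol_structure"), is.list(replicas),
            burn_in_fraction >= 0, burn_in_fraction < 1)
  nxyz <- 3L * nrow(topology$atoms)
  for (k in seq_along(replicas)) {
    if (!is.matrix(replicas[[k]]) || ncol(replicas[[k]]) != nxyz) {
      stop("replica ", k, " is not a frames x ", nxyz,
           " matrix consistent with the topology")
    }
  }
  structure(list(topology = topology, replicas = replicas,
                 frame_interval = frame_interval,
                 burn_in_fraction = burn_in_fraction, aligned = FALSE),
            class = "trajectory_ensemble")
}

#' Read a replica ensemble from multi-model PDB files
#'
#' Each file contributes one replica; its models are the frames. All files
#' must share the topology of the first.
#'
#' @param paths Character vector of multi-model PDB files.
#' @param ... Passed to [trajectory_ensemble()].
#' @return A `trajectory_ensemble`.
#' @export
read_ensemble <- function(paths, ...) {
  stopifnot(length(paths) >= 1)
  topo <- read_structure(paths[1])
  replicas <- lapply(paths, function(p) {
    pdb <- suppressWarnings(bio3d::read.pdb(p, multi = TRUE, rm.alt = FALSE,
                                            verbose = FALSE))
    m <- unclass(pdb$xyz)
    attributes(m) <- list(dim = dim(m))
    m
  })
  trajectory_ensemble(topo, replicas, ...)
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("<trajectory_ensemble> ", length(x$replicas), " replica(s) x ",
      nrow(x$replicas[[1]]), " frame(s), ", nrow(x$topology$atoms), " atoms",
      if (isTRUE(x$aligned)) ", aligned" else "", "\n", sep = "")
  invisible(x)
}

# row index triples for atom indices
.xyz_cols <- function(idx) as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))

# C-alpha atom indices for a residue selection (NULL = all CA)
.ca_indices <- function(topology, resno = NULL, chain = NULL) {
  a <- topology$atoms
  sel <- a$name == "CA" & !a$water & !a$hydrogen
  if (!is.null(resno)) sel <- sel & a$resno %in% resno
  if (!is.null(chain)) sel <- sel & a$chain %in% chain
  which(sel)
}

#' Least-squares align all frames of an ensemble
#'
#' Superposes every frame, on the C-alpha atoms of `selection`, onto an
#' ensemble-average reference computed iteratively (two passes: align to the
#' first frame, rebuild the mean, re-align to the mean).
#'
#' @param e A `trajectory_ensemble`.
#' @param resno,chain Optional residue-number / chain filters defining the
#'   alignment selection (default: every C-alpha).
#' @return The aligned ensemble (`aligned = TRUE`).
#' @export
align_frames <- function(e, resno = NULL, chain = NULL) {
  stopifnot(inherits(e, "trajectory_ensemble"))
  idx <- .ca_indices(e$topology, resno, chain)
  if (length(idx) == 0) stop("empty alignment selection")
  cols <- .xyz_cols(idx)
  align_to <- function(frames, ref_sel) {
    out <- frames
    for (f in seq_len(nrow(frames))) {
      mob <- matrix(frames[f, cols], ncol = 3, byrow = TRUE)
      tr <- .kabsch(mob, ref_sel)
      all_co <- matrix(frames[f, ], ncol = 3, byrow = TRUE)
      out[f, ] <- as.vector(t(.apply_transform(all_co, tr)))
    }
    out
  }
  for (pass in 1:2) {
    ref <- if (pass == 1) {
      matrix(e$replicas[[1]][1, cols], ncol = 3, byrow = TRUE)
    } else {
      mean_xyz <- colMeans(do.call(rbind, e$replicas))
      matrix(mean_xyz[cols], ncol = 3, byrow = TRUE)
    }
    e$replicas <- lapply(e$replicas, align_to, ref_sel = ref)
  }
  e$aligned <- TRUE
  e
}

# frames retained after burn-in
.analysis_frames <- function(e, k) {
  nf <- nrow(e$replicas[[k]])
  drop <- floor(e$burn_in_fraction * nf)
  seq.int(drop + 1L, nf)
}

#' Per-residue, per-replica C-alpha RMSF
#'
#' For each replica, after discarding the burn-in frames, the root mean
#' square fluctuation of each C-alpha about its replica-mean position.
#'
#' @param e A `trajectory_ensemble` (align with [align_frames()] first if
#'   frames contain rigid-body motion).
#' @return An `rmsf_result` list: `rmsf` (residues x replicas matrix, Angstrom),
#'   `resno`, `chain`, `mean` (per-residue mean over replicas).
#' @export
compute_rmsf <- function(e) {
  stopifnot(inherits(e, "trajectory_ensemble"))
  idx <- .ca_indices(e$topology)
  if (length(idx) == 0) stop("topology has no C-alpha atoms")
  cols <- .xyz_cols(idx)
  nr <- length(e$replicas)
  out <- matrix(NA_real_, nrow = length(idx), ncol = nr)
  for (k in seq_len(nr)) {
    ff <- .analysis_frames(e, k)
    if (length(ff) < 2) stop("replica ", k, " has fewer than 2 analysis frames")
    X <- e$replicas[[k]][ff, cols, drop = FALSE]
    mu <- colMeans(X)
    dev2 <- sweep(X, 2, mu)^2
    # sum x,y,z deviations per atom, average over frames
    per_coord <- colMeans(dev2)
    out[, k] <- sqrt(per_coord[c(TRUE, FALSE, FALSE)] +
                     per_coord[c(FALSE, TRUE, FALSE)] +
                     per_coord[c(FALSE, FALSE, TRUE)])
  }
  at <- e$topology$atoms[idx, ]
  structure(list(rmsf = out, resno = at$resno, chain = at$chain,
                 mean = rowMeans(out)),
            class = "rmsf_result")
}

#' @export
print.rmsf_result <- function(x, ...) {
  cat("<rmsf_result> ", nrow(x$rmsf), " residue(s) x ", ncol(x$rmsf),
      " replica(s); mean RMSF ", sprintf("%.2f", mean(x$mean)), " A\n", sep = "")
  invisible(x)
}

#' Compare per-residue flexibility between two ensembles
#'
#' Per matched residue, a two-sample t test on the per-replica RMSF values
#' (the replica, not the frame, is the independent unit). No
#' multiple-testing correction is applied; the per-residue significance
#' flag is at `alpha`.
#'
#' @param wt,variant `trajectory_ensemble`s (>= 2 replicas each).
#' @param alpha Significance level (default 0.05).
#' @param var_equal Use the pooled-variance t test instead of Welch
#'   (default `FALSE`).
#' @return A `flexibility_comparison` data frame: `chain`, `resno`,
#'   `rmsf_wt`, `rmsf_variant`, `delta_rmsf`, `p_value`, `significant`.
#'   Unmatched residues are dropped and listed in attribute `"unmatched"`.
#' @export
compare_rmsf <- function(wt, variant, alpha = 0.05, var_equal = FALSE) {
  if (length(wt$replicas) < 2 || length(variant$replicas) < 2) {
    stop("need >= 2 replicas on each side for significance testing")
  }
  rw <- compute_rmsf(wt); rv <- compute_rmsf(variant)
  kw <- paste(rw$chain, rw$resno); kv <- paste(rv$chain, rv$resno)
  common <- intersect(kw, kv)
  unmatched <- c(setdiff(kw, kv), setdiff(kv, kw))
  iw <- match(common, kw); iv <- match(common, kv)
  n <- length(common)
  p <- numeric(n); dw <- numeric(n); dv <- numeric(n)
  for (i in seq_len(n)) {
    xw <- rw$rmsf[iw[i], ]; xv <- rv$rmsf[iv[i], ]
    dw[i] <- mean(xw); dv[i] <- mean(xv)
    if (sd(xw) < 1e-12 && sd(xv) < 1e-12) {
      p[i] <- if (abs(dw[i] - dv[i]) < 1e-12) 1 else 0
    } else {
      p[i] <- t.test(xv, xw, var.equal = var_equal)$p.value
    }
  }
  out <- data.frame(chain = rw$chain[iw], resno = rw$resno[iw],
                    rmsf_wt = dw, rmsf_variant = dv,
                    delta_rmsf = dv - dw, p_value = p,
                    significant = p < alpha, stringsAsFactors = FALSE)
  attr(out, "unmatched") <- unmatched
  attr(out, "alpha") <- alpha
  class(out) <- c("flexibility_comparison", "data.frame")
  out
}

#' @export
print.flexibility_comparison <- function(x, ...) {
  cat("<flexibility_comparison> ", nrow(x), " residue(s), ",
      sum(x$significant), " significant at alpha = ", attr(x, "alpha"), "\n", sep = "")
  invisible(x)
}

# build a mol_structure whose coordinates come from one xyz frame
.frame_structure <- function(topology, frame) {
  s <- topology
  co <- matrix(frame, ncol = 3, byrow = TRUE)
  s$atoms$x <- co[, 1]; s$atoms$y <- co[, 2]; s$atoms$z <- co[, 3]
  s
}

#' MD-averaged per-residue contact counts
#'
#' Runs [find_contacts()] on every analysis frame and averages the
#' per-pHLA-residue contact map within each replica, then across replicas
#' with equal weight.
#'
#' @param e A `trajectory_ensemble` of the complex.
#' @param a A `complex_annotation`.
#' @param criteria A [contact_criteria()] object.
#' @param stride Analyse every `stride`-th frame (default 1).
#' @return A data frame: `target`, `tgt_chain`, `tgt_resno`, `mean_vdw`,
#'   `mean_hb`.
#' @export
average_contacts <- function(e, a, criteria = contact_criteria(), stride = 1L) {
  acc <- list()
  for (k in seq_along(e$replicas)) {
    ff <- .analysis_frames(e, k)
    ff <- ff[seq(1, length(ff), by = stride)]
    maps <- lapply(ff, function(f) {
      per_residue_contact_map(find_contacts(.frame_structure(e$topology, e$replicas[[k]][f, ]),
                                            a, criteria))
    })
    acc[[k]] <- .average_maps(maps)
  }
  .average_maps(acc)
}

# average a list of per-residue maps (absent residue = 0 contacts)
.average_maps <- function(maps) {
  n <- length(maps)          # empty maps still count toward the denominator
  maps <- Filter(function(m) nrow(m) > 0, maps)
  if (length(maps) == 0) {
    return(data.frame(target = character(), tgt_chain = character(),
                      tgt_resno = integer(), mean_vdw = numeric(),
                      mean_hb = numeric(), stringsAsFactors = FALSE))
  }
  all <- do.call(rbind, lapply(maps, function(m) {
    data.frame(target = m$target, tgt_chain = m$tgt_chain, tgt_resno = m$tgt_resno,
               v = if ("mean_vdw" %in% names(m)) m$mean_vdw else m$n_vdw,
               h = if ("mean_hb" %in% names(m)) m$mean_hb else m$n_hb,
               stringsAsFactors = FALSE)
  }))
  key <- paste(all$target, all$tgt_chain, all$tgt_resno, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(target = all$target[first], tgt_chain = all$tgt_chain[first],
                    tgt_resno = all$tgt_resno[first], stringsAsFactors = FALSE)
  out$mean_vdw <- as.numeric(tapply(all$v, key, sum)[key[first]]) / n
  out$mean_hb  <- as.numeric(tapply(all$h, key, sum)[key[first]]) / n
  out <- out[order(out$target, out$tgt_resno), ]
  rownames(out) <- NULL
  out
}

#' Hydrogen-bond occupancy over an ensemble
#'
#' Fraction of analysis frames in which each candidate donor/acceptor pair
#' satisfies the distance criterion, per replica and pooled.
#'
#' @param e A `trajectory_ensemble`.
#' @param pairs Data frame with columns `donor_chain`, `donor_resno`,
#'   `donor_atom`, `acceptor_chain`, `acceptor_resno`, `acceptor_atom`.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 3.4).
#' @return An `occupancy_series` data frame: one row per pair with
#'   per-replica occupancies (`rep1`, `rep2`, ...) and `pooled`.
#' @export
hb_occupancy <- function(e, pairs, cutoff = 3.4) {
  a <- e$topology$atoms
  find_atom <- function(ch, rn, nm) {
    i <- which(a$chain == ch & a$resno == rn & a$name == nm)
    if (length(i) != 1) {
      stop("atom ", nm, " of residue ", ch, rn,
           if (length(i)) " is ambiguous" else " not found in topology")
    }
    i
  }
  di <- mapply(find_atom, pairs$donor_chain, pairs$donor_resno, pairs$donor_atom)
  ai <- mapply(find_atom, pairs$acceptor_chain, pairs$acceptor_resno, pairs$acceptor_atom)
  nr <- length(e$replicas)
  occ <- matrix(NA_real_, nrow = nrow(pairs), ncol = nr)
  for (k in seq_len(nr)) {
    ff <- .analysis_frames(e, k)
    X <- e$replicas[[k]][ff, , drop = FALSE]
    for (p in seq_len(nrow(pairs))) {
      cd <- .xyz_cols(di[p]); ca <- .xyz_cols(ai[p])
      d <- sqrt(rowSums((X[, cd, drop = FALSE] - X[, ca, drop = FALSE])^2))
      occ[p, k] <- mean(d <= cutoff)
    }
  }
  out <- cbind(pairs, as.data.frame(occ))
  names(out)[(ncol(pairs) + 1):ncol(out)] <- paste0("rep", seq_len(nr))
  out$pooled <- rowMeans(occ)
  class(out) <- c("occupancy_series", "data.frame")
  out
}

#' Frame-averaged interface burial
#'
#' BSASA evaluated on analysis frames: per-replica means, their grand mean
#' and the between-replica standard deviation.
#'
#' @inheritParams average_contacts
#' @param probe,n_points Passed to [compute_bsasa()].
#' @return A list: `mean`, `sd` (between replicas; 0 with one replica and
#'   identical frames), `per_replica`.
#' @export
average_bsasa <- function(e, a, probe = 1.4, n_points = 960, stride = 1L) {
  per_rep <- vapply(seq_along(e$replicas), function(k) {
    ff <- .analysis_frames(e, k)
    ff <- ff[seq(1, length(ff), by = stride)]
    vals <- vapply(ff, function(f) {
      compute_bsasa(.frame_structure(e$topology, e$replicas[[k]][f, ]), a,
                    probe = probe, n_points = n_points)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  list(mean = mean(per_rep),
       sd = if (length(per_rep) > 1) sd(per_rep) else 0,
       per_replica = per_rep)
}
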