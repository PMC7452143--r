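# shared fixture builders: everything is generated in code at test time

# minimal mol_structure from bare columns
mk_structure <- function(name, resname, chain, resno, x, y, z,
                         element = substr(name, 1, 1)) {
  n <- length(x)
  atoms <- data.frame(
    serial = seq_len(n), name = rep_len(name, n), altloc = "",
    resname = rep_len(resname, n), chain = rep_len(chain, n),
    resno = as.integer(rep_len(resno, n)), insert = "",
    x = x, y = y, z = z, occ = 1, b = 0,
    element = rep_len(element, n), het = FALSE, water = FALSE,
    hydrogen = FALSE, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, entry_id = NA_character_,
                 resolution = NA_real_), class = "mol_structure")
}

# stack several mk_structure results into one complex
mk_complex <- function(...) {
  parts <- list(...)
  atoms <- do.call(rbind, lapply(parts, function(p) p$atoms))
  atoms$serial <- seq_len(nrow(atoms))
  structure(list(atoms = atoms, entry_id = NA_character_,
                 resolution = NA_real_), class = "mol_structure")
}

# role-only annotation for hand-built complexes
mk_annotation <- function(tcr_alpha = "D", tcr_beta = "E", hla = "A",
                          b2m = "B", peptide = "C", ...) {
  structure(c(list(roles = c(TCR_alpha = tcr_alpha, TCR_beta = tcr_beta,
                             HLA_heavy = hla, beta2m = b2m, peptide = peptide)),
              list(...)),
            class = "complex_annotation")
}

# formatted PDB ATOM record
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, b = 0, element = substr(name, 1, 1),
                          altloc = " ") {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, altloc, resname, chain, resno, x, y, z, occ, b, element)
}

write_pdb_fixture <- function(lines) {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), tf)
  tf
}

# uniformly random rotation matrix
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# rigid-body move a structure
transform_structure <- function(s, R = diag(3), t = c(0, 0, 0)) {
  co <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s$atoms$x <- co[, 1] + t[1]
  s$atoms$y <- co[, 2] + t[2]
  s$atoms$z <- co[, 3] + t[3]
  s
}

# translate a subset of chains (optionally a residue range)
shift_chains <- function(s, chains, dx = 0, dy = 0, dz = 0, resno = NULL) {
  sel <- s$atoms$chain %in% chains
  if (!is.null(resno)) sel <- sel & s$atoms$resno %in% resno
  s$atoms$x[sel] <- s$atoms$x[sel] + dx
  s$atoms$y[sel] <- s$atoms$y[sel] + dy
  s$atoms$z[sel] <- s$atoms$z[sel] + dz
  s
}

mutate_residue <- function(s, chain, resno, new_resname) {
  sel <- s$atoms$chain == chain & s$atoms$resno == resno
  s$atoms$resname[sel] <- new_resname
  s
}

# a small docked five-chain complex whose TCR-alpha pad touches the peptide:
# used for BSASA / energetics fixtures (tens of atoms, fast)
mk_docked_mini <- function(gap = 1.0) {
  pep <- mk_structure("CA", "ALA", "C", 1:9, ((1:9) - 5) * 3.8, 0, 0)
  hla <- mk_structure("CA", "ALA", "A", 1:10,
                      ((1:10) - 5.5) * 3.8, 8, 0)
  b2m <- mk_structure("CA", "GLY", "B", 1:6, ((1:6) - 3.5) * 3.8, -20, -10)
  g <- expand.grid(x = seq(-6, 6, 3), y = seq(-3, 3, 3))
  tcra <- mk_structure("CB", "ALA", "D", seq_len(nrow(g)),
                       g$x, g$y, 3.4 + gap)
  tcrb <- mk_structure("CB", "ALA", "E", 1:6, ((1:6) - 3.5) * 3.8, 0, 25)
  mk_complex(hla, b2m, pep, tcra, tcrb)
}

# independent all-pairs contact oracle: plain double bookkeeping over a
# precomputed distance matrix with per-pair chemistry re-derived from
# explicit lookup rules (no calls into the package's typing helpers)
oracle_contacts <- function(s, ann, vdw = 4.0, hbc = 3.4, sbc = 3.4) {
  a <- s$atoms[!s$atoms$water & !s$atoms$hydrogen, ]
  tcr <- a[a$chain %in% c(ann$roles[["TCR_alpha"]], ann$roles[["TCR_beta"]]), ]
  tgt <- a[a$chain %in% c(ann$roles[["peptide"]], ann$roles[["HLA_heavy"]]), ]
  don <- function(rn, at) {
    (at == "N" && rn != "PRO") ||
      (rn == "SER" && at == "OG") || (rn == "THR" && at == "OG1") ||
      (rn == "TYR" && at == "OH") || (rn == "CYS" && at == "SG") ||
      (rn == "ASN" && at == "ND2") || (rn == "GLN" && at == "NE2") ||
      (rn == "HIS" && at %in% c("ND1", "NE2")) ||
      (rn == "LYS" && at == "NZ") ||
      (rn == "ARG" && at %in% c("NE", "NH1", "NH2")) ||
      (rn == "TRP" && at == "NE1")
  }
  acc <- function(rn, at) {
    at %in% c("O", "OXT") ||
      (rn == "SER" && at == "OG") || (rn == "THR" && at == "OG1") ||
      (rn == "TYR" && at == "OH") || (rn == "CYS" && at == "SG") ||
      (rn == "ASN" && at == "OD1") || (rn == "GLN" && at == "OE1") ||
      (rn == "HIS" && at %in% c("ND1", "NE2")) || (rn == "MET" && at == "SD") ||
      (rn == "ASP" && at %in% c("OD1", "OD2")) ||
      (rn == "GLU" && at %in% c("OE1", "OE2"))
  }
  pos <- function(rn, at) (rn == "LYS" && at == "NZ") ||
    (rn == "ARG" && at %in% c("NE", "NH1", "NH2"))
  neg <- function(rn, at) (rn == "ASP" && at %in% c("OD1", "OD2")) ||
    (rn == "GLU" && at %in% c("OE1", "OE2"))

  rows <- list()
  for (i in seq_len(nrow(tcr))) {
    for (j in seq_len(nrow(tgt))) {
      d <- sqrt((tcr$x[i] - tgt$x[j])^2 + (tcr$y[i] - tgt$y[j])^2 +
                  (tcr$z[i] - tgt$z[j])^2)
      if (d > vdw) next
      hb <- d <= hbc &&
        ((don(tcr$resname[i], tcr$name[i]) && acc(tgt$resname[j], tgt$name[j])) ||
         (don(tgt$resname[j], tgt$name[j]) && acc(tcr$resname[i], tcr$name[i])))
      sb <- d <= sbc &&
        ((pos(tcr$resname[i], tcr$name[i]) && neg(tgt$resname[j], tgt$name[j])) ||
         (pos(tgt$resname[j], tgt$name[j]) && neg(tcr$resname[i], tcr$name[i])))
      rows[[length(rows) + 1L]] <- data.frame(
        tcr_chain = tcr$chain[i], tcr_resno = tcr$resno[i], tcr_atom = tcr$name[i],
        tgt_chain = tgt$chain[j], tgt_resno = tgt$resno[j], tgt_atom = tgt$name[j],
        distance = d, hb = hb, sb = sb, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$tcr_chain, out$tcr_resno, out$tcr_atom,
            out$tgt_chain, out$tgt_resno, out$tgt_atom), ]
}

# canonical key form of a contact table for set comparison
contact_key <- function(t) {
  if (is.null(t) || nrow(t) == 0) return(character())
  sort(paste(t$tcr_chain, t$tcr_resno, t$tcr_atom,
             t$tgt_chain, t$tgt_resno, t$tgt_atom,
             round(t$distance, 6), t$hb, t$sb))
}

# random two-sided interface for contact stress tests
random_interface <- function(seed, n_per_side = 100) {
  set.seed(seed)
  pick <- function(n) {
    kinds <- list(c("ALA", "CB"), c("GLY", "CA"), c("SER", "OG"),
                  c("LYS", "NZ"), c("ARG", "NH1"), c("ASP", "OD1"),
                  c("GLU", "OE1"), c("ASN", "ND2"), c("HIS", "NE2"),
                  c("THR", "OG1"), c("ALA", "N"), c("ALA", "O"))
    k <- sample(length(kinds), n, replace = TRUE)
    list(resname = vapply(kinds[k], `[`, "", 1),
         name = vapply(kinds[k], `[`, "", 2))
  }
  pa <- pick(n_per_side); pb <- pick(n_per_side)
  side_a <- mk_structure(pa$name, pa$resname, "D", seq_len(n_per_side),
                         runif(n_per_side, 0, 18), runif(n_per_side, 0, 18),
                         runif(n_per_side, 0, 6),
                         element = substr(pa$name, 1, 1))
  side_b <- mk_structure(pb$name, pb$resname, "C", seq_len(n_per_side),
                         runif(n_per_side, 0, 18), runif(n_per_side, 0, 18),
                         runif(n_per_side, 4, 10),
                         element = substr(pb$name, 1, 1))
  mk_complex(side_a, side_b)
}
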