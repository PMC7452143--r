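# Donor / acceptor heavy atoms by residue chemistry. Backbone N (except
# proline) donates; backbone O accepts. Side chains as listed; atoms not
# listed are apolar for hydrogen-bond purposes.
HB_DONORS <- list(
  ALL = "N",
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
  ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"),
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), TRP = "NE1"
)
HB_ACCEPTORS <- list(
  ALL = c("O", "OXT"),
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
  ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), MET = "SD",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")
)
SB_POSITIVE <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
SB_POSITIVE_HIS <- list(HIS = c("ND1", "NE2"))
SB_NEGATIVE <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

STANDARD_AA <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
                 "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

#' Contact classification criteria
#'
#' Distance cutoffs used by [find_contacts()]: all heavy-atom pairs within
#' `vdw_cutoff` are van der Waals contacts; donor/acceptor pairs within
#' `hb_cutoff` are additionally hydrogen bonds; charged-nitrogen /
#' carboxylate-oxygen pairs within `sb_cutoff` are additionally salt
#' bridges. Types are tags on one row, not exclusive bins.
#'
#' @param vdw_cutoff,hb_cutoff,sb_cutoff Distance cutoffs in Angstrom
#'   (defaults 4.0, 3.4, 3.4).
#' @param include_hydrogens Include hydrogen atoms in the search (default
#'   `FALSE`; contacts are heavy-atom only).
#' @param his_protonated Treat histidine as positively charged for salt
#'   bridges (default `FALSE`).
#' @return A `contact_criteria` list.
#' @export
contact_criteria <- function(vdw_cutoff = 4.0, hb_cutoff = 3.4, sb_cutoff = 3.4,
                             include_hydrogens = FALSE, his_protonated = FALSE) {
  stopifnot(vdw_cutoff > 0, hb_cutoff > 0, sb_cutoff > 0)
  if (hb_cutoff > vdw_cutoff) stop("hb_cutoff must be <= vdw_cutoff")
  structure(list(vdw_cutoff = vdw_cutoff, hb_cutoff = hb_cutoff,
                 sb_cutoff = sb_cutoff, include_hydrogens = include_hydrogens,
                 his_protonated = his_protonated),
            class = "contact_criteria")
}

.atom_is <- function(resname, atom, table) {
  hit <- atom %in% table$ALL
  side <- table[names(table) != "ALL"]
  if (length(side)) {
    key <- paste(rep(names(side), lengths(side)), unlist(side))
    hit <- hit | paste(resname, atom) %in% key
  }
  hit
}

#' Enumerate and classify TCR to pHLA interface contacts
#'
#' Finds all heavy-atom pairs with one atom on a TCR chain and the other on
#' the peptide or HLA heavy chain within the van der Waals cutoff, and tags
#' each pair as hydrogen bond and/or salt bridge when the distance and the
#' residue chemistry (donor/acceptor or charged-group typing) allow.
#' Residues without a chemistry entry raise a warning and contribute
#' vdW-only rows.
#'
#' @param s A `mol_structure`.
#' @param a A `complex_annotation`.
#' @param criteria A [contact_criteria()] object.
#' @return A `contact_table` data frame: `tcr_role`, `tcr_chain`,
#'   `tcr_resno`, `tcr_resname`, `tcr_atom`, `target` (`"peptide"` or
#'   `"HLA"`), `tgt_chain`, `tgt_resno`, `tgt_resname`, `tgt_atom`,
#'   `distance`, and logical `vdw`, `hb`, `sb` flags.
#' @export
find_contacts <- function(s, a, criteria = contact_criteria()) {
  at <- .polymer_atoms(s, heavy = !criteria$include_hydrogens)
  at <- at[!at$water, , drop = FALSE]
  tcr_chains <- c(.role_chain(a, "TCR_alpha"), .role_chain(a, "TCR_beta"))
  tgt_chains <- c(.role_chain(a, "peptide"), .role_chain(a, "HLA_heavy"))
  A <- at[at$chain %in% tcr_chains, , drop = FALSE]
  B <- at[at$chain %in% tgt_chains, , drop = FALSE]
  if (nrow(A) == 0 || nrow(B) == 0) return(.empty_contact_table())

  unk <- setdiff(unique(c(A$resname, B$resname)), c(STANDARD_AA, "GLY"))
  if (length(unk)) {
    warning("no chemistry entry for residue(s) ", paste(unk, collapse = ", "),
            "; treated as vdW-only")
  }

  ca <- .coords(A); cb <- .coords(B)
  # cross-distance matrix, chunked over TCR atoms to bound memory
  rows <- list()
  chunk <- 2000L
  for (i0 in seq(1L, nrow(A), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, nrow(A))
    d2 <- outer(rowSums(ca[ii, , drop = FALSE]^2), rowSums(cb^2), "+") -
      2 * (ca[ii, , drop = FALSE] %*% t(cb))
    hit <- which(d2 <= criteria$vdw_cutoff^2, arr.ind = TRUE)
    if (nrow(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        i = ii[hit[, 1]], j = hit[, 2],
        distance = sqrt(pmax(0, d2[hit])), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.empty_contact_table())
  pr <- do.call(rbind, rows)
  Ai <- A[pr$i, ]; Bj <- B[pr$j, ]

  don_a <- .atom_is(Ai$resname, Ai$name, HB_DONORS) & !(Ai$resname == "PRO" & Ai$name == "N")
  acc_a <- .atom_is(Ai$resname, Ai$name, HB_ACCEPTORS)
  don_b <- .atom_is(Bj$resname, Bj$name, HB_DONORS) & !(Bj$resname == "PRO" & Bj$name == "N")
  acc_b <- .atom_is(Bj$resname, Bj$name, HB_ACCEPTORS)
  hb <- pr$distance <= criteria$hb_cutoff & ((don_a & acc_b) | (don_b & acc_a))

  pos_tab <- SB_POSITIVE
  if (criteria$his_protonated) pos_tab <- c(SB_POSITIVE, SB_POSITIVE_HIS)
  pos_a <- .atom_is(Ai$resname, Ai$name, c(list(ALL = character()), pos_tab))
  neg_a <- .atom_is(Ai$resname, Ai$name, c(list(ALL = character()), SB_NEGATIVE))
  pos_b <- .atom_is(Bj$resname, Bj$name, c(list(ALL = character()), pos_tab))
  neg_b <- .atom_is(Bj$resname, Bj$name, c(list(ALL = character()), SB_NEGATIVE))
  sb <- pr$distance <= criteria$sb_cutoff & ((pos_a & neg_b) | (pos_b & neg_a))

  pep_chain <- .role_chain(a, "peptide")
  out <- data.frame(
    tcr_role = ifelse(Ai$chain == .role_chain(a, "TCR_alpha"), "TCR_alpha", "TCR_beta"),
    tcr_chain = Ai$chain, tcr_resno = Ai$resno, tcr_resname = Ai$resname,
    tcr_atom = Ai$name,
    target = ifelse(Bj$chain == pep_chain, "peptide", "HLA"),
    tgt_chain = Bj$chain, tgt_resno = Bj$resno, tgt_resname = Bj$resname,
    tgt_atom = Bj$name,
    distance = pr$distance,
    vdw = TRUE, hb = hb, sb = sb,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$target, out$tgt_resno, out$tcr_chain, out$tcr_resno,
                   out$tcr_atom, out$tgt_atom), ]
  rownames(out) <- NULL
  class(out) <- c("contact_table", "data.frame")
  out
}

.empty_contact_table <- function() {
  out <- data.frame(tcr_role = character(), tcr_chain = character(),
                    tcr_resno = integer(), tcr_resname = character(),
                    tcr_atom = character(), target = character(),
                    tgt_chain = character(), tgt_resno = integer(),
                    tgt_resname = character(), tgt_atom = character(),
                    distance = numeric(), vdw = logical(), hb = logical(),
                    sb = logical(), stringsAsFactors = FALSE)
  class(out) <- c("contact_table", "data.frame")
  out
}

#' @export
print.contact_table <- function(x, ...) {
  cat("<contact_table> ", nrow(x), " contact row(s): ",
      sum(x$vdw), " vdW, ", sum(x$hb), " HB, ", sum(x$sb), " SB\n", sep = "")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}

#' Per-pHLA-residue contact counts
#'
#' Aggregates a contact table over TCR partners, giving the number of van
#' der Waals contacts and hydrogen bonds each peptide/HLA residue receives.
#'
#' @param t A `contact_table`.
#' @return A data frame: `target`, `tgt_chain`, `tgt_resno`, `n_vdw`, `n_hb`.
#' @export
per_residue_contact_map <- function(t) {
  if (nrow(t) == 0) {
    return(data.frame(target = character(), tgt_chain = character(),
                      tgt_resno = integer(), n_vdw = integer(), n_hb = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(t$target, t$tgt_chain, t$tgt_resno, sep = "\r")
  ord <- !duplicated(key)
  out <- data.frame(target = t$target[ord], tgt_chain = t$tgt_chain[ord],
                    tgt_resno = t$tgt_resno[ord], stringsAsFactors = FALSE)
  out$n_vdw <- as.integer(tapply(t$vdw, key, sum)[key[ord]])
  out$n_hb  <- as.integer(tapply(t$hb, key, sum)[key[ord]])
  out <- out[order(out$target, out$tgt_resno), ]
  rownames(out) <- NULL
  out
}

#' Compare wild-type and variant contact tables
#'
#' Differences in contact counts by type (vdW, HB, SB) and by target
#' (peptide, HLA, total), plus how many of the wild type's `k` most
#' contacted pHLA residues still receive at least `min_contacts` contacts
#' in the variant ("preserved top contacts"). Ranking ties are broken by
#' residue order.
#'
#' @param wt,variant `contact_table`s from comparably annotated complexes.
#' @param k Number of top wild-type residues to track (default 10).
#' @param min_contacts Minimum variant contacts for a residue to count as
#'   preserved (default 1).
#' @return A `contact_comparison` list: `delta` (3 x 3 matrix, types by
#'   targets), `preserved_top_contacts`, `k`, `top_wt_residues`.
#' @export
compare_contact_tables <- function(wt, variant, k = 10, min_contacts = 1) {
  counts <- function(t) {
    m <- matrix(0L, nrow = 3, ncol = 3,
                dimnames = list(c("vdw", "hb", "sb"), c("peptide", "HLA", "total")))
    for (ty in rownames(m)) {
      for (tg in c("peptide", "HLA")) {
        m[ty, tg] <- sum(t[[ty]][t$target == tg])
      }
      m[ty, "total"] <- m[ty, "peptide"] + m[ty, "HLA"]
    }
    m
  }
  delta <- counts(variant) - counts(wt)

  mw <- per_residue_contact_map(wt)
  totals <- mw$n_vdw
  ord <- order(-totals, seq_len(nrow(mw)))
  top <- mw[ord, , drop = FALSE][seq_len(min(k, nrow(mw))), , drop = FALSE]
  mv <- per_residue_contact_map(variant)
  keyv <- paste(mv$target, mv$tgt_chain, mv$tgt_resno, sep = "\r")
  keyt <- paste(top$target, top$tgt_chain, top$tgt_resno, sep = "\r")
  nvar <- mv$n_vdw[match(keyt, keyv)]
  preserved <- sum(!is.na(nvar) & nvar >= min_contacts)

  structure(list(delta = delta, preserved_top_contacts = preserved, k = k,
                 top_wt_residues = top),
            class = "contact_comparison")
}

#' @export
print.contact_comparison <- function(x, ...) {
  cat("<contact_comparison>\n")
  print(x$delta)
  cat("preserved top contacts: ", x$preserved_top_contacts, " / ", x$k, "\n", sep = "")
  invisible(x)
}
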