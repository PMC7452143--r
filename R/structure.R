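#' @importFrom stats median prcomp sd t.test cor setNames rnorm runif dist
#' @importFrom utils read.table read.csv write.csv head packageVersion
NULL

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Read a macromolecular structure from a PDB file
#'
#' Parses a standard PDB coordinate file into a `mol_structure` object.
#' Waters and hetero-groups are retained but flagged; hydrogens are retained
#' but excluded from the default heavy-atom selections used throughout the
#' package. The crystallographic resolution is taken from the `REMARK   2`
#' header when present.
#'
#' @param path Path to a PDB file.
#' @param altloc_policy How alternate locations are resolved:
#'   `"highest_occupancy"` (default) keeps, per (chain, residue, insertion
#'   code, atom name), the altloc with the highest occupancy, ties broken by
#'   altloc identifier order; `"first"` keeps the first record encountered;
#'   `"all"` keeps every record.
#' @param model For multi-model files, the 1-based model index to extract
#'   (default 1).
#' @return A `mol_structure`: a list with an `atoms` data frame (columns
#'   `serial`, `name`, `altloc`, `resname`, `chain`, `resno`, `insert`,
#'   `x`, `y`, `z`, `occ`, `b`, `element`, `het`, `water`, `hydrogen`),
#'   plus `entry_id` and `resolution` (Angstrom, `NA` if absent).
#' @export
read_structure <- function(path, altloc_policy = c("highest_occupancy", "first", "all"),
                           model = 1) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !any(grepl("^(ATOM|HETATM)", lines))) {
    stop("no ATOM/HETATM records in '", path, "': empty or not a PDB file")
  }
  .validate_pdb_records(lines)

  multi <- any(grepl("^MODEL", lines))
  pdb <- suppressWarnings(
    bio3d::read.pdb(path, multi = multi, rm.alt = FALSE, verbose = FALSE)
  )
  at <- pdb$atom
  if (multi) {
    nmod <- nrow(pdb$xyz)
    if (model < 1 || model > nmod) {
      stop("model index ", model, " out of range (file has ", nmod, " models)")
    }
    co <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- co[, 1]; at$y <- co[, 2]; at$z <- co[, 3]
  }

  atoms <- data.frame(
    serial  = at$eleno,
    name    = at$elety,
    altloc  = ifelse(is.na(at$alt), "", at$alt),
    resname = at$resid,
    chain   = ifelse(is.na(at$chain), " ", at$chain),
    resno   = at$resno,
    insert  = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b   = ifelse(is.na(at$b), 0, at$b),
    element = .element_of(at$elesy, at$elety),
    het   = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms$water    <- atoms$resname %in% WATER_RESNAMES
  atoms$hydrogen <- atoms$element %in% c("H", "D")

  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in '", path, "'")
  }
  atoms <- .resolve_altlocs(atoms, altloc_policy)

  res <- .parse_resolution(lines)
  entry <- .parse_entry_id(lines)
  structure(list(atoms = atoms, entry_id = entry, resolution = res,
                 source = path),
            class = "mol_structure")
}

.validate_pdb_records <- function(lines) {
  idx <- grep("^(ATOM|HETATM)", lines)
  bad <- idx[nchar(lines[idx]) < 54]
  if (length(bad)) {
    stop("malformed ATOM/HETATM record at line ", bad[1],
         ": record shorter than coordinate fields")
  }
  coords <- substr(lines[idx], 31, 54)
  xs <- suppressWarnings(as.numeric(substr(coords, 1, 8)))
  ys <- suppressWarnings(as.numeric(substr(coords, 9, 16)))
  zs <- suppressWarnings(as.numeric(substr(coords, 17, 24)))
  bad <- idx[is.na(xs) | is.na(ys) | is.na(zs)]
  if (length(bad)) {
    stop("malformed ATOM/HETATM record at line ", bad[1],
         ": non-numeric coordinate field")
  }
  invisible(TRUE)
}

.element_of <- function(elesy, elety) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  # fall back on the first alphabetic character of the atom name
  miss <- el == ""
  if (any(miss)) {
    guess <- toupper(sub("^[0-9]*", "", trimws(elety[miss])))
    guess <- substr(guess, 1, 1)
    # two-letter guesses only for a few common hetero elements
    el[miss] <- guess
  }
  el
}

.resolve_altlocs <- function(atoms, policy) {
  if (policy == "all") return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  keep <- logical(nrow(atoms))
  for (grp in split(seq_len(nrow(atoms)), key)) {
    if (length(grp) == 1L) { keep[grp] <- TRUE; next }
    if (policy == "first") {
      keep[grp[1L]] <- TRUE
    } else {
      o <- order(-atoms$occ[grp], atoms$altloc[grp])
      keep[grp[o[1L]]] <- TRUE
    }
  }
  out <- atoms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.parse_resolution <- function(lines) {
  rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (!length(rl)) return(NA_real_)
  m <- regmatches(rl[1], regexpr("[0-9]+\\.[0-9]+", rl[1]))
  if (!length(m)) return(NA_real_)
  as.numeric(m)
}

.parse_entry_id <- function(lines) {
  hl <- grep("^HEADER", lines, value = TRUE)
  if (!length(hl) || nchar(hl[1]) < 66) return(NA_character_)
  id <- trimws(substr(hl[1], 63, 66))
  if (nzchar(id)) id else NA_character_
}

#' Write a structure back to PDB format
#'
#' @param s A `mol_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "mol_structure"))
  a <- s$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$het, "HETATM", "ATOM"),
    eleno = a$serial, elety = a$name, resid = a$resname,
    chain = a$chain, resno = a$resno, insert = ifelse(a$insert == "", NA, a$insert),
    o = a$occ, b = a$b, elesy = a$element
  )
  invisible(path)
}

#' @export
print.mol_structure <- function(x, ...) {
  a <- x$atoms
  cat("<mol_structure>",
      if (!is.na(x$entry_id)) paste0(" entry ", x$entry_id) else "", "\n", sep = "")
  cat("  ", nrow(a), " atoms, ", length(unique(a$chain[!a$water])), " chains",
      if (!is.na(x$resolution)) paste0(", resolution ", x$resolution, " A") else "",
      "\n", sep = "")
  invisible(x)
}

# default heavy-atom polymer selection used across the analysis modules
.polymer_atoms <- function(s, heavy = TRUE) {
  a <- s$atoms
  sel <- !a$water
  if (heavy) sel <- sel & !a$hydrogen
  a[sel, , drop = FALSE]
}

# coordinates as an n x 3 matrix
.coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

# Calpha atoms of a chain, in file order
.calpha <- function(s, chain = NULL) {
  a <- .polymer_atoms(s)
  a <- a[a$name == "CA" & !a$het, , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  a
}

# one-letter sequence of a chain (from CA records, file order)
.chain_sequence <- function(s, chain) {
  ca <- .calpha(s, chain)
  bio3d::aa321(ca$resname)
}

# number of residues per chain (CA count)
.chain_lengths <- function(s) {
  ca <- .calpha(s)
  tab <- table(ca$chain)
  setNames(as.integer(tab), names(tab))
}
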