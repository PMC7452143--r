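TCR_ROLES <- c("TCR_alpha", "TCR_beta", "HLA_heavy", "beta2m", "peptide")

# built-in loop ranges (author-style numbering commonly used for TCR variable
# domains); real systems should supply curated per-system ranges instead.
DEFAULT_LOOP_RANGES <- list(
  CDR1 = c(24L, 31L),
  CDR2 = c(48L, 55L),
  HV4  = c(65L, 74L),
  CDR3 = c(93L, 104L)
)

#' Annotate chain roles and loop regions of a TCR-pHLA complex
#'
#' Assigns each chain of the complex one of the five roles (TCR alpha and
#' beta chains, HLA heavy chain, beta-2 microglobulin, peptide) and records
#' the residue ranges of the variable domains, the eight antigen-binding
#' loops (CDR1-3 and HV4 on each TCR chain) and the two groove helices of
#' the HLA. Roles come from `config` when given; otherwise a chain-length
#' heuristic is applied: peptide 8-13 residues, beta2m roughly 95-105, HLA
#' heavy roughly 270-285, and the two remaining mid-sized chains assigned
#' TCR alpha / TCR beta in file order (or per `tcr_order`).
#'
#' @param s A `mol_structure`.
#' @param config Optional list overriding the heuristic. Recognised fields:
#'   `roles` (named character, role -> chain id), `variable_domains`
#'   (named list, role -> c(first, last) residue numbers), `loops` (named
#'   list, label such as `"CDR3b"` -> c(first, last)), `helices`
#'   (list with `alpha1`, `alpha2` residue ranges on the HLA heavy chain),
#'   `cys_positions` (named list, role -> the two conserved cysteine residue
#'   numbers of the variable domain).
#' @param tcr_order Order in which unassigned candidate TCR chains appear:
#'   `"alpha_first"` (default) or `"beta_first"`.
#' @param default_loops Use the built-in loop ranges when `config` supplies
#'   none (default `TRUE`). With `FALSE` the annotation carries no loop
#'   ranges and downstream loop-based analyses will refuse to guess.
#' @return A `complex_annotation` list with `roles`, `variable_domains`,
#'   `loops` (each labelled loop carries the owning role), `helices` and
#'   `cys_positions`.
#' @export
annotate_complex <- function(s, config = NULL,
                             tcr_order = c("alpha_first", "beta_first"),
                             default_loops = TRUE) {
  stopifnot(inherits(s, "mol_structure"))
  tcr_order <- match.arg(tcr_order)
  lens <- .chain_lengths(s)

  if (!is.null(config$roles)) {
    roles <- unlist(config$roles)
    missing_roles <- setdiff(TCR_ROLES, names(roles))
    if (length(missing_roles)) {
      stop("config$roles is missing roles: ", paste(missing_roles, collapse = ", "))
    }
    roles <- roles[TCR_ROLES]
  } else {
    if (length(lens) < 4) {
      stop("complex has only ", length(lens),
           " polymer chains; need >= 4 (5 with a separate peptide chain). ",
           "Supply explicit roles via config.")
    }
    roles <- .assign_roles_heuristic(lens, tcr_order)
  }
  plen <- lens[[roles[["peptide"]]]]
  if (plen < 8 || plen > 13) {
    stop("peptide chain '", roles[["peptide"]], "' has ", plen,
         " residues; expected 8-13")
  }

  vd <- config$variable_domains
  if (is.null(vd)) {
    # default: first ~115 residues of each TCR chain form the variable domain
    vd <- lapply(c(TCR_alpha = "TCR_alpha", TCR_beta = "TCR_beta"), function(role) {
      ca <- .calpha(s, roles[[role]])
      c(min(ca$resno), min(max(ca$resno), min(ca$resno) + 114L))
    })
  }

  loops <- config$loops
  if (is.null(loops) && default_loops) {
    loops <- list()
    for (role in c("TCR_alpha", "TCR_beta")) {
      suf <- if (role == "TCR_alpha") "a" else "b"
      for (lab in names(DEFAULT_LOOP_RANGES)) {
        loops[[paste0(lab, suf)]] <- DEFAULT_LOOP_RANGES[[lab]]
      }
    }
  }
  if (!is.null(loops)) .check_loop_overlap(loops)

  helices <- config$helices
  if (is.null(helices)) {
    # canonical HLA class I groove helices in author numbering
    helices <- list(alpha1 = c(50L, 85L), alpha2 = c(138L, 180L))
  }

  structure(list(
    roles = roles,
    variable_domains = vd,
    loops = loops,
    helices = helices,
    cys_positions = config$cys_positions
  ), class = "complex_annotation")
}

.assign_roles_heuristic <- function(lens, tcr_order) {
  chains <- names(lens)
  cand <- list(
    peptide   = chains[lens >= 8 & lens <= 13],
    beta2m    = chains[lens >= 85 & lens <= 115],
    HLA_heavy = chains[lens >= 255 & lens <= 300]
  )
  for (role in names(cand)) {
    if (length(cand[[role]]) != 1L) {
      stop("ambiguous role assignment: role '", role, "' has ",
           length(cand[[role]]), " candidate chains (",
           paste(cand[[role]], collapse = ", "),
           "); supply explicit roles via config")
    }
  }
  rest <- setdiff(chains, unlist(cand))
  rest <- rest[lens[rest] >= 150 & lens[rest] <= 260]
  if (length(rest) != 2L) {
    stop("ambiguous role assignment: expected exactly 2 TCR-sized chains ",
         "(150-260 residues), found ", length(rest),
         "; supply explicit roles via config")
  }
  if (tcr_order == "beta_first") rest <- rev(rest)
  c(TCR_alpha = rest[1], TCR_beta = rest[2],
    HLA_heavy = cand$HLA_heavy, beta2m = cand$beta2m, peptide = cand$peptide)
}

.check_loop_overlap <- function(loops) {
  by_chain <- split(names(loops), sub("^.*(a|b)$", "\\1", names(loops)))
  for (labs in by_chain) {
    if (length(labs) < 2) next
    rng <- lapply(loops[labs], function(r) seq(r[1], r[2]))
    all_pos <- unlist(rng)
    if (anyDuplicated(all_pos)) {
      stop("loop ranges overlap within a chain: ", paste(labs, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' @export
print.complex_annotation <- function(x, ...) {
  cat("<complex_annotation>\n")
  for (role in names(x$roles)) cat("  ", role, ": chain ", x$roles[[role]], "\n", sep = "")
  if (!is.null(x$loops)) cat("  loops: ", paste(names(x$loops), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# chain id for a role
.role_chain <- function(a, role) unname(a$roles[[role]])

# which loop (if any) contains author-numbered position `pos` on `role`
.loop_of <- function(a, role, pos) {
  if (is.null(a$loops)) return("framework")
  suf <- if (role == "TCR_alpha") "a" else "b"
  for (lab in names(a$loops)) {
    if (!endsWith(lab, suf)) next
    r <- a$loops[[lab]]
    if (pos >= r[1] && pos <= r[2]) return(lab)
  }
  "framework"
}

#' Sequence differences between wild-type and variant TCR chains
#'
#' Globally aligns the TCR alpha and beta chain sequences of two annotated
#' complexes and lists substitutions, each labelled with the loop (CDR/HV4)
#' it falls in or `"framework"`. Insertions and deletions are reported
#' separately (attribute `"indels"`) and excluded from the substitution
#' count.
#'
#' @param wt,variant `mol_structure` objects.
#' @param wt_annotation,variant_annotation Matching `complex_annotation`s.
#' @param min_identity Alignment identity floor (fraction, default 0.7);
#'   lower identity raises an error since it usually indicates mispaired
#'   chains.
#' @return A `sequence_difference` data frame with columns `chain_role`,
#'   `position` (wild-type author numbering), `wt`, `variant`, `region`.
#' @export
diff_sequences <- function(wt, wt_annotation, variant, variant_annotation,
                           min_identity = 0.7) {
  rows <- list(); indels <- list()
  for (role in c("TCR_alpha", "TCR_beta")) {
    cw <- .role_chain(wt_annotation, role)
    cv <- .role_chain(variant_annotation, role)
    ca_w <- .calpha(wt, cw); ca_v <- .calpha(variant, cv)
    sw <- paste(bio3d::aa321(ca_w$resname), collapse = "")
    sv <- paste(bio3d::aa321(ca_v$resname), collapse = "")
    al <- Biostrings::pairwiseAlignment(sw, sv, type = "global",
                                        substitutionMatrix = "BLOSUM62",
                                        gapOpening = 10, gapExtension = 0.5)
    pw <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
    pv <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
    both <- pw != "-" & pv != "-"
    ident <- sum(pw[both] == pv[both]) / max(1, sum(both))
    if (ident < min_identity) {
      stop(role, " alignment identity ", round(100 * ident, 1),
           "% is below the ", round(100 * min_identity),
           "% floor; chains are likely mispaired")
    }
    iw <- cumsum(pw != "-"); iv <- cumsum(pv != "-")
    for (k in seq_along(pw)) {
      if (pw[k] == "-" || pv[k] == "-") {
        indels[[length(indels) + 1L]] <- data.frame(
          chain_role = role,
          kind = if (pw[k] == "-") "insertion" else "deletion",
          position = if (pw[k] == "-") ca_v$resno[iv[k]] else ca_w$resno[iw[k]],
          residue = if (pw[k] == "-") pv[k] else pw[k],
          stringsAsFactors = FALSE)
      } else if (pw[k] != pv[k]) {
        pos <- ca_w$resno[iw[k]]
        rows[[length(rows) + 1L]] <- data.frame(
          chain_role = role, position = pos,
          wt = pw[k], variant = pv[k],
          region = .loop_of(wt_annotation, role, pos),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain_role = character(), position = integer(),
               wt = character(), variant = character(), region = character(),
               stringsAsFactors = FALSE)
  attr(out, "indels") <- if (length(indels)) do.call(rbind, indels) else NULL
  class(out) <- c("sequence_difference", "data.frame")
  out
}

#' @export
print.sequence_difference <- function(x, ...) {
  cat("<sequence_difference> ", nrow(x), " substitution(s)\n", sep = "")
  if (nrow(x)) {
    lab <- paste0(x$wt, x$position, x$variant, " (", x$chain_role, ", ", x$region, ")")
    cat(paste0("  ", lab, collapse = "\n"), "\n")
  }
  ind <- attr(x, "indels")
  if (!is.null(ind)) cat("  plus ", nrow(ind), " indel position(s)\n", sep = "")
  invisible(x)
}
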