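#' Run the full wild-type versus variant comparison pipeline
#'
#' Executes the geometry, contact, surface and (optionally) ensemble and
#' energetics stages for each wild-type/variant pair of a manifest and
#' collects one summary row per complex plus one comparison row per pair.
#' A stage failure is recorded for its pair and the run continues; the call
#' errors only if every pair fails.
#'
#' @param manifest A list of pairs. Each pair is a list with elements `wt`
#'   and `variant` (each itself a list with `structure` and `annotation`,
#'   or a `path` to a PDB file plus `config` for [annotate_complex()]),
#'   plus optional `label`, `kd_wt_nM`, `kd_variant_nM`, `wt_ensemble`,
#'   `variant_ensemble` (`trajectory_ensemble`s of the apo TCRs or
#'   complexes for the flexibility comparison), `wt_params`,
#'   `variant_params` (force-field tables enabling the MM/GBSA stage).
#' @param criteria A [contact_criteria()] object.
#' @param config An [energetics_config()].
#' @param k Top-contact preservation depth (default 10).
#' @param sasa_points Quadrature density for the surface stage.
#' @return A `comparison_report` list: `summary` (data frame, one row per
#'   complex), `pairs` (data frame, one row per pair), `errors` (named list
#'   of failed stages), `parameters`.
#' @export
run_compare <- function(manifest, criteria = contact_criteria(),
                        config = energetics_config(), k = 10,
                        sasa_points = 240) {
  summaries <- list(); pair_rows <- list(); errors <- list()
  for (p in seq_along(manifest)) {
    pair <- manifest[[p]]
    label <- pair$label %||% paste0("pair", p)
    res <- tryCatch({
      wt <- .load_entry(pair$wt); va <- .load_entry(pair$variant)
      sw <- .complex_summary(wt, paste0(label, "_wt"), criteria, sasa_points)
      sv <- .complex_summary(va, paste0(label, "_variant"), criteria, sasa_points)
      cw <- find_contacts(wt$structure, wt$annotation, criteria)
      cv <- find_contacts(va$structure, va$annotation, criteria)
      cc <- compare_contact_tables(cw, cv, k = k)
      row <- data.frame(
        label = label,
        d_vdw = cc$delta["vdw", "total"], d_hb = cc$delta["hb", "total"],
        d_sb = cc$delta["sb", "total"],
        d_peptide = sum(cc$delta[, "peptide"]), d_hla = sum(cc$delta[, "HLA"]),
        preserved_top = cc$preserved_top_contacts, k = cc$k,
        d_angle = sv$crossing_angle - sw$crossing_angle,
        d_bsasa = sv$bsasa - sw$bsasa,
        stringsAsFactors = FALSE)
      row$fold_change <- if (!is.null(pair$kd_wt_nM) && !is.null(pair$kd_variant_nM)) {
        fold_change(pair$kd_wt_nM, pair$kd_variant_nM)
      } else NA_real_
      row$ddg_exp <- if (!is.na(row$fold_change)) {
        ddg_exp(pair$kd_wt_nM, pair$kd_variant_nM, config)
      } else NA_real_
      if (!is.null(pair$wt_ensemble) && !is.null(pair$variant_ensemble)) {
        fc <- compare_rmsf(pair$wt_ensemble, pair$variant_ensemble)
        row$n_sig_drmsf <- sum(fc$significant)
        row$mean_drmsf <- mean(fc$delta_rmsf)
      } else {
        row$n_sig_drmsf <- NA_integer_; row$mean_drmsf <- NA_real_
      }
      if (!is.null(pair$wt_params) && !is.null(pair$variant_params)) {
        dw <- decompose_per_residue(wt$structure, pair$wt_params, wt$annotation, config)
        dv <- decompose_per_residue(va$structure, pair$variant_params, va$annotation, config)
        cls <- classify_ddg(dw, dv)
        row$ddg_comp <- attr(dv, "dG_bind") - attr(dw, "dG_bind")
        row$n_favorable <- sum(cls$label == "favorable")
        row$n_unfavorable <- sum(cls$label == "unfavorable")
      } else {
        row$ddg_comp <- NA_real_; row$n_favorable <- NA_integer_
        row$n_unfavorable <- NA_integer_
      }
      list(summaries = list(sw, sv), row = row)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[label]] <- conditionMessage(res)
    } else {
      summaries <- c(summaries, res$summaries)
      pair_rows[[label]] <- res$row
    }
  }
  if (length(manifest) && length(errors) == length(manifest)) {
    stop("all pairs failed: ", paste(unlist(errors), collapse = "; "))
  }
  structure(list(
    summary = if (length(summaries)) do.call(rbind, summaries) else NULL,
    pairs = if (length(pair_rows)) do.call(rbind, c(pair_rows, make.row.names = FALSE)) else NULL,
    errors = errors,
    parameters = list(criteria = unclass(criteria), config = unclass(config),
                      k = k, sasa_points = sasa_points,
                      package_version = as.character(utils::packageVersion("tcrlens")))
  ), class = "comparison_report")
}

.load_entry <- function(entry) {
  if (!is.null(entry$structure)) {
    stopifnot(inherits(entry$structure, "mol_structure"))
    ann <- entry$annotation %||% annotate_complex(entry$structure, entry$config)
    return(list(structure = entry$structure, annotation = ann))
  }
  if (is.null(entry$path)) stop("manifest entry needs either a structure or a path")
  s <- read_structure(entry$path)
  list(structure = s, annotation = annotate_complex(s, entry$config))
}

.complex_summary <- function(x, entry_label, criteria, sasa_points) {
  ca <- compute_crossing_angle(x$structure, x$annotation,
                               centroid_rule = if (is.null(x$annotation$cys_positions))
                                 "domain_ca" else "disulfide_ca")
  fp <- compute_footprint(x$structure, x$annotation)
  ct <- find_contacts(x$structure, x$annotation, criteria)
  bs <- compute_bsasa(x$structure, x$annotation, n_points = sasa_points)
  sc <- tryCatch(compute_shape_complementarity(x$structure, x$annotation)$sc,
                 error = function(e) NA_real_)
  data.frame(entry = entry_label,
             entry_id = x$structure$entry_id %||% NA_character_,
             crossing_angle = ca$angle, footprint_x = fp$x, footprint_y = fp$y,
             bsasa = bs, sc = sc,
             n_vdw = sum(ct$vdw), n_hb = sum(ct$hb), n_sb = sum(ct$sb),
             stringsAsFactors = FALSE)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", if (is.null(x$pairs)) 0 else nrow(x$pairs),
      " pair(s), ", length(x$errors), " failure(s)\n", sep = "")
  if (!is.null(x$pairs)) print.data.frame(x$pairs, digits = 3)
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Emits `summary.csv` (one row per complex), `pairs.csv` (one row per
#' pair) and `run_log.json` (parameters, package version, errors) into
#' `dir`.
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$summary)) {
    write.csv(report$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  }
  if (!is.null(report$pairs)) {
    write.csv(report$pairs, file.path(dir, "pairs.csv"), row.names = FALSE)
  }
  jsonlite::write_json(
    list(schema_version = "1.0", parameters = report$parameters,
         errors = report$errors),
    file.path(dir, "run_log.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
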