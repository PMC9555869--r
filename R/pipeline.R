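#' Default analysis parameters
#'
#' The pipeline defaults: 2.4 Angstrom clustering radius, 5% mixing
#' threshold, CA selection, 4.5 Angstrom van der Waals cutoff, 25,000-frame
#' even subsampling, 100 representatives per cluster.
#'
#' @return named list of defaults
#' @export
shift_defaults <- function() {
  list(radius = 2.4, mixing_threshold = 0.05, selection = "CA",
       vdw_cutoff = 4.5, n_frames = 25000L, n_representatives = 100L)
}

#' Enumerate receptor-ligand complexes from a manifest
#'
#' Expands a manifest (variants x states) into the deterministic complex
#' list: for each variant in listed order, the apo state first (when
#' included), then the ligands in listed order, minus exclusions.
#'
#' @param variants character vector of receptor variant ids
#' @param ligands character vector of ligand ids
#' @param include_apo include an unliganded state per variant
#'   (default `TRUE`)
#' @param exclusions list of `list(variant =, ligands =)` entries; `ligands`
#'   may be a vector of ligand ids or `"all"` for every liganded state of
#'   that variant
#' @return data.frame with columns `variant`, `state` (`"APO"` or a ligand
#'   id)
#' @export
enumerate_complexes <- function(variants, ligands, include_apo = TRUE,
                                exclusions = list()) {
  stopifnot(length(variants) >= 1)
  if (anyDuplicated(variants) || anyDuplicated(ligands)) {
    stop("duplicate variant or ligand ids")
  }
  for (ex in exclusions) {
    if (!ex$variant %in% variants) {
      stop("exclusion references unknown variant: ", ex$variant)
    }
  }
  states <- c(if (include_apo) "APO", ligands)
  out <- expand.grid(state = states, variant = variants,
                     stringsAsFactors = FALSE)[, c("variant", "state")]
  for (ex in exclusions) {
    drop_lig <- if (identical(ex$ligands, "all")) ligands else ex$ligands
    out <- out[!(out$variant == ex$variant & out$state %in% drop_lig), ]
  }
  rownames(out) <- NULL
  out
}

#' Run the ensemble-shift analysis over a set of complexes
#'
#' For each variant, clusters the apo ensemble together with each liganded
#' ensemble ([combined_cluster()]), applies the mixing rule, and computes
#' the overlap fraction ([overlap_fraction()]). Optionally correlates the
#' overlap fractions with an activity table and writes a JSON + CSV report.
#'
#' @param ensembles named list: `ensembles[[variant]]` is a named list with
#'   an `APO` ensemble and one ensemble per ligand id
#' @param radius clustering radius, Angstrom (default from
#'   [shift_defaults()])
#' @param threshold mixing threshold (default 0.05)
#' @param selection atom selection for RMSD (default `"CA"`)
#' @param activities optional activity data.frame
#'   (see [read_activity_csv()])
#' @param metric activity metric for the correlation (default
#'   `"log10_ec50"`)
#' @param out_dir optional directory for `report.json`, `phi.csv` and
#'   per-complex cluster tables
#' @return list of class `shift_report`: `phi` (data.frame `variant`,
#'   `ligand`, `phi`, `n_clusters`, `n_mixed`), `tables` (named list of
#'   cluster tables), `correlation` (or `NULL`), `params`
#' @export
run_shift_analysis <- function(ensembles,
                               radius = shift_defaults()$radius,
                               threshold = shift_defaults()$mixing_threshold,
                               selection = shift_defaults()$selection,
                               activities = NULL, metric = "log10_ec50",
                               out_dir = NULL) {
  stopifnot(is.list(ensembles), length(ensembles) >= 1)
  rows <- list()
  tables <- list()
  for (variant in names(ensembles)) {
    states <- ensembles[[variant]]
    if (is.null(states$APO)) {
      stop("variant ", variant, " has no APO ensemble")
    }
    ligs <- setdiff(names(states), "APO")
    for (lig in ligs) {
      cc <- combined_cluster(states$APO, states[[lig]], radius = radius,
                             selection = selection,
                             group_names = c("apo", "liganded"))
      ov <- overlap_fraction(cc$table, threshold = threshold)
      key <- paste(variant, lig, sep = "|")
      tables[[key]] <- cc$table
      rows[[key]] <- data.frame(variant = variant, ligand = lig,
                                phi = ov$phi,
                                n_clusters = nrow(cc$table),
                                n_mixed = sum(ov$mixed),
                                stringsAsFactors = FALSE)
    }
    if (length(ligs) == 0L) {
      # apo-only entry: still record its own clustering
      assignment <- cluster_fixed_radius(states$APO, radius = radius,
                                         selection = selection)
      tables[[paste(variant, "APO", sep = "|")]] <-
        cluster_table(assignment$cluster_id,
                      rep(TRUE, length(assignment$cluster_id)),
                      c("apo", "apo"))
    }
  }
  phi <- if (length(rows) > 0L) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(variant = character(), ligand = character(), phi = numeric(),
               n_clusters = integer(), n_mixed = integer())
  }
  correlation <- NULL
  if (!is.null(activities) && nrow(phi) >= 3L) {
    correlation <- tryCatch(
      correlate_activity(phi, activities, metric = metric),
      error = function(e) {
        warning("activity correlation skipped: ", conditionMessage(e))
        NULL
      })
  }
  report <- structure(
    list(phi = phi, tables = tables, correlation = correlation,
         params = list(radius = radius, threshold = threshold,
                       selection = selection)),
    class = "shift_report")
  if (!is.null(out_dir)) write_shift_report(report, out_dir)
  report
}

#' @export
print.shift_report <- function(x, ...) {
  cat(sprintf("<shift_report> %d complex(es), radius %.2f A, threshold %.2f\n",
              nrow(x$phi), x$params$radius, x$params$threshold))
  if (nrow(x$phi) > 0L) print(x$phi)
  if (!is.null(x$correlation)) {
    cat(sprintf("  phi vs %s: r = %.3f (n = %d)\n", x$correlation$metric,
                x$correlation$r, x$correlation$n))
  }
  invisible(x)
}

#' Write a shift report to disk
#'
#' Writes `report.json` (overlap fractions, parameters, correlation),
#' `phi.csv`, and one cluster-table CSV per complex under
#' `cluster_tables/`.
#'
#' @param report a `shift_report` from [run_shift_analysis()]
#' @param out_dir output directory (created if missing)
#' @return `out_dir`, invisibly
#' @export
write_shift_report <- function(report, out_dir) {
  dir.create(file.path(out_dir, "cluster_tables"), recursive = TRUE,
             showWarnings = FALSE)
  utils::write.csv(report$phi, file.path(out_dir, "phi.csv"),
                   row.names = FALSE)
  for (key in names(report$tables)) {
    fn <- paste0(gsub("[^A-Za-z0-9_.-]", "_", key), ".csv")
    utils::write.csv(report$tables[[key]],
                     file.path(out_dir, "cluster_tables", fn),
                     row.names = FALSE)
  }
  payload <- list(params = report$params, phi = report$phi)
  if (!is.null(report$correlation)) {
    payload$correlation <- report$correlation[c("r", "p", "n", "metric",
                                                "method")]
  }
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}
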