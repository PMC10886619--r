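# End-to-end glue: spot table -> titrations -> phagogram -> JSON report.

#' Run the full titration and potency pipeline
#'
#' Titrates every phage-strain series of a spot table, optionally builds
#' the phagogram against a reference-host map, and assembles a summary
#' report (counts per titration status, anomaly-flag tallies, virulence
#' class tallies).  Deterministic given its inputs.
#'
#' @param spots Spot-observation data frame (schema of
#'   [read_spot_table()]).
#' @param rules A [quantification_rules()] object.
#' @param reference_hosts Optional named phage -> strain map; when given, a
#'   phagogram is built.
#' @param out_dir Optional directory: writes `titrations.csv`,
#'   `titrations.json`, `report.json` and, with `reference_hosts`,
#'   `phagogram.tsv` and `phagogram_records.csv`.
#'
#' @return An object of class `pipeline_result`: list with `titrations`,
#'   `phagogram` (or `NULL`) and `report`.
#' @export
run_pipeline <- function(spots, rules = quantification_rules(),
                         reference_hosts = NULL, out_dir = NULL) {
  titr <- titrate_panel(spots, rules)
  pg <- if (!is.null(reference_hosts))
    build_phagogram(titr, reference_hosts)

  flags <- unlist(strsplit(titr$anomaly_flags[titr$anomaly_flags != ""], ","))
  report <- list(
    schema_version = SCHEMA_VERSION,
    n_spots = nrow(spots),
    n_series = nrow(titr),
    status_tally = as.list(table(titr$status)),
    anomaly_flag_tally = as.list(table(flags)),
    precision_acceptable = sum(titr$precision_acceptable, na.rm = TRUE),
    class_tally = if (!is.null(pg)) summary(pg)$class_tally)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_titration_results(titr, file.path(out_dir, "titrations.csv"))
    write_titration_json(titr, file.path(out_dir, "titrations.json"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(pg))
      write_phagogram(pg,
                      matrix_path = file.path(out_dir, "phagogram.tsv"),
                      records_path = file.path(out_dir, "phagogram_records.csv"))
  }
  structure(list(titrations = titr, phagogram = pg, report = report),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d series from %d spots\n",
              x$report$n_series, x$report$n_spots))
  for (s in names(x$report$status_tally))
    cat(sprintf("  %-26s %d\n", s, x$report$status_tally[[s]]))
  if (!is.null(x$phagogram)) print(x$phagogram)
  invisible(x)
}
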