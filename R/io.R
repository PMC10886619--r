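# Readers and writers for the package's tabular interfaces, and the
# packaged method-comparison fixture (paired manual/automated titers of one
# phage on its host strain, four dilution tubes x four replicates).

SCHEMA_VERSION <- "1.0"

.fail_row <- function(row, msg)
  stop(sprintf("row %d: %s", row, msg), call. = FALSE)

#' Read and validate a spot-observation table
#'
#' Reads the CSV spot schema: columns `phage_id, strain_id,
#' dilution_exponent, replicate, drop_volume_ul, status, plaque_count,
#' merge_partner`, one row per drop.  Status vocabulary is exactly
#' `counted`, `confluent`, `no_lysis`, `no_drop`, `merged`.  Counted spots
#' must carry a non-negative plaque count; `no_drop`, `no_lysis` and
#' `confluent` spots must not; merged spots must reference a symmetric
#' merge partner, both partners carrying the blob's combined count (empty
#' when the blob is unreadable).  Validation errors name the offending row.
#'
#' @param path Path to the CSV file.
#' @return Validated spot-observation data frame.
#' @export
read_spot_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(phage_id = "character",
                                       strain_id = "character"))
  if (!identical(sort(names(df)), sort(SPOT_COLUMNS)))
    stop("spot table header must be exactly: ",
         paste(SPOT_COLUMNS, collapse = ","), call. = FALSE)
  df <- df[SPOT_COLUMNS]
  validate_spot_table(df)
}

#' Validate a spot-observation data frame
#'
#' @param df Data frame in the spot schema (see [read_spot_table()]).
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_spot_table <- function(df) {
  stopifnot(is.data.frame(df))
  for (i in seq_len(nrow(df))) {
    st <- df$status[i]
    if (!st %in% SPOT_STATUSES)
      .fail_row(i, sprintf("unknown status token '%s'", st))
    if (!is.finite(df$dilution_exponent[i]) || df$dilution_exponent[i] < 0)
      .fail_row(i, "dilution_exponent must be a non-negative integer")
    cnt <- df$plaque_count[i]
    if (st == "counted" && (is.na(cnt)))
      .fail_row(i, "counted spot without a plaque count")
    if (st %in% c("no_drop", "no_lysis", "confluent") && !is.na(cnt))
      .fail_row(i, sprintf("status '%s' must not carry a plaque count", st))
    if (!is.na(cnt) && cnt < 0)
      .fail_row(i, "negative plaque count")
    if (st != "no_drop" &&
        (!is.finite(df$drop_volume_ul[i]) || df$drop_volume_ul[i] <= 0))
      .fail_row(i, "drop_volume_ul must be positive")
    if (st == "merged") {
      j <- which(df$phage_id == df$phage_id[i] &
                   df$strain_id == df$strain_id[i] &
                   df$dilution_exponent == df$dilution_exponent[i] &
                   df$replicate == df$merge_partner[i])
      if (length(j) != 1 || df$status[j] != "merged" ||
          is.na(df$merge_partner[j]) ||
          df$merge_partner[j] != df$replicate[i])
        .fail_row(i, "merged spot without a symmetric merge partner")
    }
  }
  df
}

#' Write a spot-observation table to CSV
#'
#' @param spots Spot-observation data frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_spot_table <- function(spots, path) {
  out <- spots[SPOT_COLUMNS]
  out$drop_volume_ul <- ifelse(is.na(out$drop_volume_ul), "",
                               sprintf("%.6e", out$drop_volume_ul))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a paired-titer table
#'
#' CSV with columns `group, label, reference_titer, evaluated_titer`: one
#' row per paired measurement of the same sample by two methods, grouped
#' into replicate sets (e.g. dilution tubes).
#'
#' @param path Path to the CSV file.
#' @return Validated data frame for [method_comparison_report()].
#' @export
read_paired_titers <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "label", "reference_titer", "evaluated_titer")
  if (!all(need %in% names(df)))
    stop("paired-titer table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  bad <- which(df$reference_titer <= 0 | df$evaluated_titer <= 0 |
                 !is.finite(df$reference_titer) | !is.finite(df$evaluated_titer))
  if (length(bad)) .fail_row(bad[1], "titers must be positive")
  df[need]
}

#' Paired manual/automated titers of the validation experiment
#'
#' The packaged method-comparison fixture: one virulent coliphage titrated
#' on its host strain from four dilution tubes (A: undiluted to D: 10^-3),
#' four independent replicates per tube, by a manual (reference) and an
#' automated (evaluated) drop-off method — 16 paired titers.
#'
#' @return Data frame with columns `group` (tube), `label` (replicate),
#'   `reference_titer` and `evaluated_titer`, in PFU/mL.
#' @examples
#' head(table1_titers())
#' @export
table1_titers <- function() {
  path <- system.file("extdata", "validation_paired_titers.csv",
                      package = "phagodrop", mustWork = TRUE)
  read_paired_titers(path)
}

#' Published summary statistics of the validation experiment
#'
#' The per-tube mean, SD and CV of [table1_titers()] as printed in the
#' validation report (titers at 3 significant digits, CVs at 2 decimals),
#' for regression tests of the replicate statistics.
#'
#' @return Data frame with columns `group`, `method` (`reference` /
#'   `evaluated`), `mean_titer`, `sd_titer`, `cv_percent`.
#' @export
table1_summary <- function() {
  data.frame(
    group = rep(c("A", "B", "C", "D"), 2),
    method = rep(c("reference", "evaluated"), each = 4),
    mean_titer = c(1.03e9, 1.18e8, 1.05e7, 1.65e6,
                   1.08e9, 1.30e8, 1.25e7, 1.03e6),
    sd_titer = c(3.51e8, 2.06e7, 2.74e6, 3.37e5,
                 2.27e8, 1.28e7, 1.26e6, 1.28e5),
    cv_percent = c(33.93, 17.44, 26.11, 20.44,
                   20.94, 9.82, 10.10, 12.35),
    stringsAsFactors = FALSE)
}

#' Write titration results as CSV
#'
#' One row per phage-strain pair; replicate titers are semicolon-joined;
#' titers use stable `%.6e` scientific notation.
#'
#' @param titrations Data frame from [titrate_panel()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_titration_results <- function(titrations, path) {
  out <- titrations
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.6e", v))
  out$mean_titer <- fmt(out$mean_titer)
  out$sd_titer <- fmt(out$sd_titer)
  out$cv_percent <- ifelse(is.na(titrations$cv_percent), "",
                           sprintf("%.4f", titrations$cv_percent))
  out$replicate_titers <- vapply(titrations$replicate_titers, function(v)
    paste(sprintf("%.6e", v), collapse = ";"), "")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write titration results as JSON
#'
#' @param titrations Data frame from [titrate_panel()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_titration_json <- function(titrations, path) {
  recs <- lapply(seq_len(nrow(titrations)), function(i) {
    r <- as.list(titrations[i, setdiff(names(titrations), "replicate_titers")])
    r$replicate_titers <- titrations$replicate_titers[[i]]
    r
  })
  jsonlite::write_json(list(schema_version = SCHEMA_VERSION,
                            titrations = recs),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write a phagogram
#'
#' Writes the EOP matrix as TSV (strains as rows, phages as columns; cells
#' hold the EOP, `not_active`, or `NA` for non-evaluable pairs), the long
#' per-pair record table as CSV, and a JSON report with classification
#' tallies.
#'
#' @param phagogram A [build_phagogram()] result.
#' @param matrix_path,records_path,report_path Output paths; any may be
#'   `NULL` to skip that artifact.
#' @return Invisibly, the phagogram.
#' @export
write_phagogram <- function(phagogram, matrix_path = NULL,
                            records_path = NULL, report_path = NULL) {
  stopifnot(inherits(phagogram, "phagogram"))
  if (!is.null(matrix_path)) {
    cells <- ifelse(!is.na(phagogram$eop_matrix),
                    sprintf("%.6e", phagogram$eop_matrix),
                    ifelse(phagogram$class_matrix == "not_active",
                           "not_active", "NA"))
    m <- cbind(strain_id = rownames(phagogram$eop_matrix), cells)
    colnames(m) <- c("strain_id", colnames(phagogram$eop_matrix))
    utils::write.table(m, matrix_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(records_path))
    utils::write.csv(phagogram$records, records_path, row.names = FALSE,
                     quote = FALSE, na = "NA")
  if (!is.null(report_path))
    jsonlite::write_json(
      c(list(schema_version = SCHEMA_VERSION), summary(phagogram)),
      report_path, auto_unbox = TRUE, digits = NA)
  invisible(phagogram)
}

#' Serialize an agreement report to JSON
#'
#' @param report A [method_comparison_report()] result.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_agreement_json <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  out <- list(
    schema_version = SCHEMA_VERSION,
    n_pairs = report$n_pairs,
    per_group = report$per_group,
    mean_abs_log10_diff = report$mean_abs_log10_diff,
    bias_ratio = report$bland_altman$bias_ratio,
    bias_ci = report$bland_altman$bias_ci,
    limits_of_agreement = report$bland_altman$limits_of_agreement,
    ccc = report$ccc$ccc, ccc_ci = report$ccc$ci,
    ccc_scale = report$ccc_scale,
    variability_test = report$variability_test[
      c("test_name", "statistic", "p_value")],
    cv_reference = unname(report$variability_test$group_summary$a),
    cv_evaluated = unname(report$variability_test$group_summary$b))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
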