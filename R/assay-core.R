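# Core titration arithmetic for drop-off plaque assays: spot counts ->
# titers, anomaly resolution within triplicates, dilution selection and
# replicate aggregation.

SPOT_STATUSES <- c("counted", "confluent", "no_lysis", "no_drop", "merged")

SPOT_COLUMNS <- c("phage_id", "strain_id", "dilution_exponent", "replicate",
                  "drop_volume_ul", "status", "plaque_count", "merge_partner")

#' Quantification rules for titer determination
#'
#' Bundles the thresholds that govern which dilution of a serial spot assay
#' is quantifiable and when a replicate set is flagged as imprecise.
#'
#' @param min_countable Smallest plaque count per spot accepted for
#'   quantification (counts of zero carry no titer information).
#' @param max_countable Largest plaque count per spot that can still be
#'   read reliably before plaques merge into confluent lysis; spots beyond
#'   this ceiling are treated as too numerous to count.
#' @param cv_acceptable_percent Coefficient-of-variation threshold (percent)
#'   below which a triplicate is flagged as acceptably precise.
#' @param min_reliable_pfu Plaque count per spot above which the assay's
#'   precision is expected to reach `cv_acceptable_percent`; used for
#'   flagging, never for exclusion.
#'
#' @return An object of class `quantification_rules`.
#' @examples
#' quantification_rules()
#' quantification_rules(max_countable = 100)
#' @export
quantification_rules <- function(min_countable = 1L,
                                 max_countable = 50L,
                                 cv_acceptable_percent = 15,
                                 min_reliable_pfu = 15L) {
  if (!is.numeric(min_countable) || min_countable <= 0)
    stop("min_countable must be a positive integer", call. = FALSE)
  if (!is.numeric(max_countable) || max_countable < min_countable)
    stop("max_countable must be >= min_countable", call. = FALSE)
  if (!is.numeric(cv_acceptable_percent) || cv_acceptable_percent <= 0)
    stop("cv_acceptable_percent must be positive", call. = FALSE)
  if (!is.numeric(min_reliable_pfu) || min_reliable_pfu <= 0)
    stop("min_reliable_pfu must be positive", call. = FALSE)
  structure(list(min_countable = as.integer(min_countable),
                 max_countable = as.integer(max_countable),
                 cv_acceptable_percent = as.numeric(cv_acceptable_percent),
                 min_reliable_pfu = as.integer(min_reliable_pfu)),
            class = "quantification_rules")
}

#' @export
print.quantification_rules <- function(x, ...) {
  cat("Quantification rules:\n")
  cat(sprintf("  countable range per spot : [%d, %d] plaques\n",
              x$min_countable, x$max_countable))
  cat(sprintf("  acceptable CV            : < %g%%\n", x$cv_acceptable_percent))
  cat(sprintf("  reliable-count guideline : >= %d PFU/spot\n", x$min_reliable_pfu))
  invisible(x)
}

#' Titer of the undiluted suspension from one spot count
#'
#' Converts a plaque count observed in a single drop of a ten-fold serial
#' dilution into the titer of the undiluted stock, in PFU/mL:
#' `count / volume_mL * 10^dilution_exponent`.  Vectorised over all three
#' arguments.
#'
#' @param plaque_count Non-negative plaque count(s) per spot.
#' @param drop_volume_ul Drop volume(s) in microlitres; must be positive.
#' @param dilution_exponent Ten-fold serial dilution step(s); 0 means the
#'   undiluted stock, k means a 10^-k dilution.
#'
#' @return Titer(s) in PFU/mL.
#' @examples
#' titer_from_count(5, 5, 6)    # 1e9 PFU/mL
#' titer_from_count(11, 5, 2)   # 2.2e5 PFU/mL
#' @export
titer_from_count <- function(plaque_count, drop_volume_ul, dilution_exponent) {
  if (any(!is.finite(drop_volume_ul)) || any(drop_volume_ul <= 0))
    stop("drop_volume_ul must be positive", call. = FALSE)
  if (any(plaque_count < 0, na.rm = TRUE))
    stop("plaque_count must be non-negative", call. = FALSE)
  if (any(dilution_exponent < 0))
    stop("dilution_exponent must be non-negative", call. = FALSE)
  plaque_count / (drop_volume_ul * 1e-3) * 10^dilution_exponent
}

#' Resolve plate anomalies within one replicate set
#'
#' Turns the spots of one phage/strain/dilution replicate set into effective
#' per-replicate plaque counts.  Merged (coalesced) adjacent drops each
#' contribute half of the blob's combined count; missed drops (`no_drop`)
#' contribute nothing and reduce the number of usable replicates; clear
#' spots (`no_lysis`) contribute a count of zero; confluent spots carry no
#' usable count and are tallied separately.
#'
#' @param triplicate A data frame of spot observations (see
#'   [read_spot_table()] for the schema) sharing one phage, strain and
#'   dilution, with distinct replicate indices.
#'
#' @return A list with elements `counts` (effective counts named by
#'   replicate index; merged blobs with unreadable counts are dropped),
#'   `n_confluent` (number of replicates whose plaques were too numerous to
#'   count), and `flags` (subset of `"merged_resolved"`,
#'   `"missing_replicate"`).
#' @examples
#' tri <- data.frame(phage_id = "p", strain_id = "s", dilution_exponent = 3,
#'                   replicate = 1:3, drop_volume_ul = 5,
#'                   status = c("merged", "merged", "counted"),
#'                   plaque_count = c(24, 24, 13), merge_partner = c(2, 1, NA))
#' resolve_anomalies(tri)$counts  # 12 12 13
#' @export
resolve_anomalies <- function(triplicate) {
  stopifnot(is.data.frame(triplicate), nrow(triplicate) >= 1)
  if (length(unique(triplicate$phage_id)) != 1 ||
      length(unique(triplicate$strain_id)) != 1 ||
      length(unique(triplicate$dilution_exponent)) != 1)
    stop("replicate set must share one phage, strain and dilution", call. = FALSE)
  if (anyDuplicated(triplicate$replicate))
    stop("replicate indices must be distinct", call. = FALSE)

  status <- as.character(triplicate$status)
  rep_ix <- triplicate$replicate
  counts <- numeric(0)
  flags <- character(0)
  n_confluent <- 0L

  merged <- which(status == "merged")
  if (length(merged)) {
    for (i in merged) {
      p <- triplicate$merge_partner[i]
      j <- match(p, rep_ix)
      if (is.na(p) || is.na(j) || status[j] != "merged" ||
          !identical(as.numeric(triplicate$merge_partner[j]),
                     as.numeric(rep_ix[i])))
        stop(sprintf(
          "merged spot (replicate %s) lacks a symmetric merge partner",
          rep_ix[i]), call. = FALSE)
    }
    flags <- c(flags, "merged_resolved")
  }

  for (i in seq_len(nrow(triplicate))) {
    s <- status[i]
    if (s == "counted") {
      counts[as.character(rep_ix[i])] <- triplicate$plaque_count[i]
    } else if (s == "no_lysis") {
      counts[as.character(rep_ix[i])] <- 0
    } else if (s == "no_drop") {
      flags <- c(flags, "missing_replicate")
    } else if (s == "confluent") {
      n_confluent <- n_confluent + 1L
    } else if (s == "merged") {
      # both partners carry the blob's combined count; each gets half
      cc <- triplicate$plaque_count[i]
      if (is.na(cc)) n_confluent <- n_confluent + 1L
      else counts[as.character(rep_ix[i])] <- cc / 2
    } else {
      stop(sprintf("unknown spot status '%s'", s), call. = FALSE)
    }
  }
  list(counts = counts, n_confluent = n_confluent, flags = unique(flags))
}

# TRUE where a spot shows any lytic activity (plaques or clearance)
.has_lysis <- function(status, plaque_count) {
  status == "confluent" |
    (status %in% c("counted", "merged") &
       (is.na(plaque_count) | plaque_count > 0))
}

#' Select the quantifiable dilution of a serial spot series
#'
#' Scans all dilutions of one phage-strain series and picks the one usable
#' for titration.  A dilution is quantifiable when it retains at least two
#' effective replicate counts, every effective count lies within the
#' countable range, and no replicate at that dilution is confluent; among
#' quantifiable dilutions the one with the largest mean count wins (it
#' carries the most counting information).  Series without any such
#' dilution are classified: `no_activity` when no spot shows lysis;
#' `excluded_unreliable_count` when even the highest tested dilution is
#' still beyond the countable ceiling; `excluded_no_pfu` when lawn
#' clearance occurs without individual plaques at higher dilutions (e.g.
#' lysis from without), so no titer can be computed.
#'
#' @param series Data frame of spot observations for one phage-strain pair
#'   across dilutions.
#' @param rules A [quantification_rules()] object.
#'
#' @return A list with `status` (one of `"quantified"`, `"no_activity"`,
#'   `"excluded_no_pfu"`, `"excluded_unreliable_count"`) and, when
#'   quantified, `dilution_exponent`.
#' @export
select_quantifiable_dilution <- function(series, rules = quantification_rules()) {
  if (!is.data.frame(series) || nrow(series) == 0)
    stop("series must be a non-empty data frame of spot observations",
         call. = FALSE)
  stopifnot(inherits(rules, "quantification_rules"))

  exps <- sort(unique(series$dilution_exponent))
  best_exp <- NA_integer_
  best_mean <- -Inf
  for (k in exps) {
    res <- resolve_anomalies(series[series$dilution_exponent == k, , drop = FALSE])
    ok <- res$n_confluent == 0L &&
      length(res$counts) >= 2L &&
      all(res$counts >= rules$min_countable & res$counts <= rules$max_countable)
    if (ok && mean(res$counts) > best_mean) {
      best_mean <- mean(res$counts)
      best_exp <- as.integer(k)
    }
  }
  if (!is.na(best_exp))
    return(list(status = "quantified", dilution_exponent = best_exp))

  if (!any(.has_lysis(as.character(series$status), series$plaque_count)))
    return(list(status = "no_activity"))

  # highest tested dilution with at least one landed drop
  landed <- series[series$status != "no_drop", , drop = FALSE]
  top <- max(landed$dilution_exponent)
  res <- resolve_anomalies(series[series$dilution_exponent == top, , drop = FALSE])
  too_many <- res$n_confluent > 0L ||
    (length(res$counts) > 0 && mean(res$counts) > rules$max_countable)
  if (too_many) list(status = "excluded_unreliable_count")
  else list(status = "excluded_no_pfu")
}

#' Replicate statistics for a set of titers
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator) and
#' coefficient of variation of replicate titers.
#'
#' @param titers Numeric vector of positive replicate titers (PFU/mL), at
#'   least two values.
#'
#' @return A list with `mean`, `sd`, `cv_percent` and `n`.
#' @examples
#' aggregate_replicates(c(7.33e6, 1.40e7, 1.07e7, 1.00e7))
#' @export
aggregate_replicates <- function(titers) {
  if (length(titers) < 2)
    stop("at least two replicate titers are required", call. = FALSE)
  if (any(!is.finite(titers)) || any(titers <= 0))
    stop("replicate titers must be positive and finite", call. = FALSE)
  m <- mean(titers)
  s <- stats::sd(titers)
  list(mean = m, sd = s, cv_percent = 100 * s / m, n = length(titers))
}

#' Titrate one phage-strain serial spot series
#'
#' Full titration pipeline for a single phage-strain pair: select the
#' quantifiable dilution, resolve anomalies into effective counts, convert
#' counts to titers of the undiluted stock, and aggregate replicates into
#' mean, SD and CV.  Exclusion statuses from dilution selection are carried
#' through with all numeric fields absent.
#'
#' @param series Data frame of spot observations for one phage-strain pair.
#' @param rules A [quantification_rules()] object.
#'
#' @return An object of class `titration`: a list with `phage_id`,
#'   `strain_id`, `status`, `selected_dilution_exponent`,
#'   `replicate_titers`, `mean_titer`, `sd_titer`, `cv_percent`,
#'   `n_replicates_used`, `precision_acceptable` and `anomaly_flags`.
#' @examples
#' s <- data.frame(phage_id = "p", strain_id = "s", dilution_exponent = 3,
#'                 replicate = 1:3, drop_volume_ul = 5, status = "counted",
#'                 plaque_count = c(10, 12, 11), merge_partner = NA)
#' titrate(s)
#' @export
titrate <- function(series, rules = quantification_rules()) {
  sel <- select_quantifiable_dilution(series, rules)
  phage <- as.character(series$phage_id[1])
  strain <- as.character(series$strain_id[1])

  if (sel$status != "quantified") {
    out <- list(phage_id = phage, strain_id = strain, status = sel$status,
                selected_dilution_exponent = NA_integer_,
                replicate_titers = numeric(0),
                mean_titer = NA_real_, sd_titer = NA_real_,
                cv_percent = NA_real_, n_replicates_used = 0L,
                precision_acceptable = NA,
                anomaly_flags = character(0))
    class(out) <- "titration"
    return(out)
  }

  k <- sel$dilution_exponent
  sub <- series[series$dilution_exponent == k, , drop = FALSE]
  res <- resolve_anomalies(sub)
  vols <- sub$drop_volume_ul[match(as.integer(names(res$counts)), sub$replicate)]
  titers <- titer_from_count(unname(res$counts), vols, k)
  agg <- aggregate_replicates(titers)

  out <- list(phage_id = phage, strain_id = strain, status = "quantified",
              selected_dilution_exponent = k,
              replicate_titers = titers,
              mean_titer = agg$mean, sd_titer = agg$sd,
              cv_percent = agg$cv_percent,
              n_replicates_used = agg$n,
              precision_acceptable = agg$cv_percent < rules$cv_acceptable_percent,
              anomaly_flags = res$flags)
  class(out) <- "titration"
  out
}

#' @export
print.titration <- function(x, ...) {
  cat(sprintf("Titration of phage %s on strain %s: %s\n",
              x$phage_id, x$strain_id, x$status))
  if (x$status == "quantified") {
    cat(sprintf("  dilution 10^-%d, %d replicates%s\n",
                x$selected_dilution_exponent, x$n_replicates_used,
                if (length(x$anomaly_flags))
                  paste0(" [", paste(x$anomaly_flags, collapse = ", "), "]")
                else ""))
    cat(sprintf("  titer %.3g PFU/mL (SD %.3g, CV %.2f%%, precision %s)\n",
                x$mean_titer, x$sd_titer, x$cv_percent,
                if (isTRUE(x$precision_acceptable)) "acceptable" else "poor"))
  }
  invisible(x)
}

#' Titrate every phage-strain pair of a spot table
#'
#' Applies [titrate()] to each phage-strain series of a full spot table.
#'
#' @param spots Spot-observation data frame covering one or more
#'   phage-strain pairs (schema of [read_spot_table()]).
#' @param rules A [quantification_rules()] object.
#'
#' @return A data frame with one row per phage-strain pair and columns
#'   `phage_id`, `strain_id`, `status`, `selected_dilution_exponent`,
#'   `mean_titer`, `sd_titer`, `cv_percent`, `n_replicates_used`,
#'   `precision_acceptable`, `anomaly_flags` (comma-joined) and the
#'   list-column `replicate_titers`.
#' @export
titrate_panel <- function(spots, rules = quantification_rules()) {
  stopifnot(is.data.frame(spots), nrow(spots) > 0)
  key <- interaction(spots$phage_id, spots$strain_id, drop = TRUE, sep = "\r")
  pieces <- split(seq_len(nrow(spots)), key)
  res <- lapply(pieces, function(ix) titrate(spots[ix, , drop = FALSE], rules))
  out <- data.frame(
    phage_id = vapply(res, `[[`, "", "phage_id"),
    strain_id = vapply(res, `[[`, "", "strain_id"),
    status = vapply(res, `[[`, "", "status"),
    selected_dilution_exponent = vapply(res, `[[`, 1L, "selected_dilution_exponent"),
    mean_titer = vapply(res, `[[`, 1, "mean_titer"),
    sd_titer = vapply(res, `[[`, 1, "sd_titer"),
    cv_percent = vapply(res, `[[`, 1, "cv_percent"),
    n_replicates_used = vapply(res, `[[`, 1L, "n_replicates_used"),
    precision_acceptable = vapply(res, `[[`, NA, "precision_acceptable"),
    anomaly_flags = vapply(res, function(r)
      paste(r$anomaly_flags, collapse = ","), ""),
    stringsAsFactors = FALSE, row.names = NULL)
  out$replicate_titers <- I(unname(lapply(res, `[[`, "replicate_titers")))
  out[order(out$phage_id, out$strain_id), , drop = FALSE]
}
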