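# Efficiency of plaquing (EOP), virulence classification and phagogram
# assembly across a phage x strain panel.

VIRULENCE_CLASSES <- c("highly_virulent", "moderately_virulent",
                       "weakly_or_avirulent", "not_active", "not_evaluable")

#' Efficiency of plaquing
#'
#' Ratio of a phage's titer on a test strain to its titer on its reference
#' host strain, titrated in parallel.  Dimensionless; 1 means the phage
#' plaques as efficiently on the test strain as on its host.
#'
#' @param titer_test Titer on the tested strain (PFU/mL), positive.
#' @param titer_reference Titer on the phage's reference host (PFU/mL),
#'   positive.
#'
#' @return The EOP ratio (vectorised).
#' @examples
#' efficiency_of_plaquing(1e7, 1e9)  # 0.01
#' @export
efficiency_of_plaquing <- function(titer_test, titer_reference) {
  if (any(!is.finite(titer_reference)) || any(titer_reference <= 0))
    stop("reference titer must be positive", call. = FALSE)
  if (any(!is.finite(titer_test)) || any(titer_test <= 0))
    stop("test titer must be positive", call. = FALSE)
  titer_test / titer_reference
}

#' Virulence class from an EOP value
#'
#' Classifies efficiency-of-plaquing ratios with the commonly used
#' thresholds: highly virulent for EOP >= 0.1 (including EOP > 1, where the
#' test strain supports plaquing better than the reference host),
#' moderately virulent for 0.001 <= EOP < 0.1, weakly or avirulent for
#' EOP < 0.001.  The intervals are half-open so every positive EOP is
#' classified.
#'
#' @param eop Positive EOP ratio(s).
#'
#' @return Character vector of classes among `"highly_virulent"`,
#'   `"moderately_virulent"`, `"weakly_or_avirulent"`.
#' @examples
#' classify_eop(c(0.5, 0.01, 5e-4))
#' @export
classify_eop <- function(eop) {
  if (any(!is.finite(eop)) || any(eop <= 0))
    stop("eop must be positive", call. = FALSE)
  ifelse(eop >= 0.1, "highly_virulent",
         ifelse(eop >= 0.001, "moderately_virulent", "weakly_or_avirulent"))
}

#' Assemble a phagogram from panel titrations
#'
#' Builds the phage x strain potency matrix: quantified pairs get an EOP
#' (against the phage's reference host, titrated within the same panel) and
#' a virulence class; series without lysis are `not_active`; excluded
#' series are `not_evaluable`.  A phage whose reference-host titration is
#' missing or not quantified yields a `not_evaluable` column with a
#' warning.  The reference host's own cell has EOP exactly 1.
#'
#' @param titrations Data frame from [titrate_panel()].
#' @param reference_hosts Named character vector mapping each phage id to
#'   its reference host strain id.
#'
#' @return An object of class `phagogram`: a list with `phage_ids`,
#'   `strain_ids`, `records` (long data frame, one row per pair),
#'   `eop_matrix` (strains x phages) and `class_matrix`.
#' @export
build_phagogram <- function(titrations, reference_hosts) {
  stopifnot(is.data.frame(titrations))
  if (is.null(names(reference_hosts)) || any(names(reference_hosts) == ""))
    stop("reference_hosts must be a named phage -> strain map", call. = FALSE)

  phages <- sort(unique(titrations$phage_id))
  strains <- sort(unique(titrations$strain_id))
  if (anyDuplicated(titrations[c("phage_id", "strain_id")]))
    stop("titrations must contain one row per phage-strain pair", call. = FALSE)

  recs <- expand.grid(strain_id = strains, phage_id = phages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  recs <- recs[c("phage_id", "strain_id")]
  ix <- match(paste(recs$phage_id, recs$strain_id, sep = "\r"),
              paste(titrations$phage_id, titrations$strain_id, sep = "\r"))
  recs$status <- titrations$status[ix]
  recs$mean_titer <- titrations$mean_titer[ix]
  recs$reference_strain_id <- unname(reference_hosts[recs$phage_id])
  recs$eop <- NA_real_
  recs$virulence_class <- NA_character_

  for (ph in phages) {
    host <- reference_hosts[[ph]]
    col <- recs$phage_id == ph
    ref_row <- which(titrations$phage_id == ph & titrations$strain_id == host)
    ref_ok <- length(ref_row) == 1 &&
      titrations$status[ref_row] == "quantified"
    if (is.null(host) || !ref_ok) {
      warning(sprintf(
        "phage %s: reference host titration missing or not quantified; column set to not_evaluable",
        ph), call. = FALSE)
      recs$virulence_class[col] <- "not_evaluable"
      next
    }
    ref_titer <- titrations$mean_titer[ref_row]
    for (i in which(col)) {
      st <- recs$status[i]
      if (is.na(st)) {
        recs$virulence_class[i] <- "not_evaluable"
      } else if (st == "quantified") {
        recs$eop[i] <- if (recs$strain_id[i] == host) 1
                       else efficiency_of_plaquing(recs$mean_titer[i], ref_titer)
        recs$virulence_class[i] <- classify_eop(recs$eop[i])
      } else if (st == "no_activity") {
        recs$virulence_class[i] <- "not_active"
      } else {
        recs$virulence_class[i] <- "not_evaluable"
      }
    }
  }

  eop_m <- matrix(NA_real_, nrow = length(strains), ncol = length(phages),
                  dimnames = list(strains, phages))
  cls_m <- matrix(NA_character_, nrow = length(strains), ncol = length(phages),
                  dimnames = list(strains, phages))
  eop_m[cbind(match(recs$strain_id, strains), match(recs$phage_id, phages))] <- recs$eop
  cls_m[cbind(match(recs$strain_id, strains), match(recs$phage_id, phages))] <- recs$virulence_class

  structure(list(phage_ids = phages, strain_ids = strains,
                 records = recs, eop_matrix = eop_m, class_matrix = cls_m),
            class = "phagogram")
}

#' @export
print.phagogram <- function(x, ...) {
  cat(sprintf("Phagogram: %d phages x %d strains\n",
              length(x$phage_ids), length(x$strain_ids)))
  tab <- table(factor(x$records$virulence_class, levels = VIRULENCE_CLASSES))
  for (cl in names(tab))
    cat(sprintf("  %-20s %d\n", cl, tab[[cl]]))
  invisible(x)
}

#' @export
summary.phagogram <- function(object, ...) {
  tab <- table(factor(object$records$virulence_class, levels = VIRULENCE_CLASSES))
  list(n_phages = length(object$phage_ids),
       n_strains = length(object$strain_ids),
       class_tally = as.list(tab))
}
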