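# Stochastic simulator of the automated drop-off assay: serial-dilution
# pipetting error, Poisson plaque counting per drop, drop failures
# (no_drop), coalescence of adjacent replicate drops, and a countability
# ceiling.  Provides ground truth for closed-loop testing of the titration
# pipeline, plus run-plan/throughput arithmetic for the liquid handler.

# lognormal sdlog giving a multiplicative error with median 1 and the
# requested coefficient of variation
.sdlog_from_cv <- function(cv) sqrt(log(1 + cv^2))

#' Simulation configuration for the drop-off assay
#'
#' Generative parameters of the robotic spot assay.  Defaults reproduce the
#' validated instrument's operating conditions: 5 uL drops, triplicates,
#' eight ten-fold dilutions (undiluted to 10^-7), a countable ceiling of 50
#' plaques per spot, missed drops at 0.93% of spots and coalescence of
#' adjacent replicate drops at 1.97% per adjacent pair.
#'
#' @param susceptibility Data frame with columns `phage_id`, `strain_id`,
#'   `stock_titer` giving the true titer (PFU/mL) of each susceptible
#'   phage-strain interaction; pairs absent from the table are not
#'   susceptible.  May have zero rows.
#' @param strain_ids,phage_ids Full panel of strains/phages to spot
#'   (defaults: those appearing in `susceptibility`).
#' @param n_dilutions Number of ten-fold serial dilutions including the
#'   undiluted stock (default 8, exponents 0-7).
#' @param n_replicates Spots per phage-dilution (default 3).
#' @param drop_volume_ul Nominal drop volume in microlitres (default 5).
#' @param pipetting_cv Multiplicative lognormal error (median 1) per
#'   ten-fold transfer, as a fractional CV (default 0.05).
#' @param drop_volume_cv Fractional jitter of the dispensed drop volume
#'   (default 0.02).
#' @param p_no_drop Probability that a spot is missed because the drop
#'   stays attached to the tip (default 0.0093).
#' @param p_coalescence Probability that a given pair of adjacent replicate
#'   drops merges on the agar surface (default 0.0197); a drop merges with
#'   at most one partner, and merges never cross phages or dilutions.
#' @param max_countable Plaque count above which a spot reads as confluent
#'   lysis (default 50).
#' @param seed Integer seed making [simulate_assay()] reproducible.
#'
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(susceptibility = data.frame(
                                phage_id = character(), strain_id = character(),
                                stock_titer = numeric()),
                              strain_ids = NULL, phage_ids = NULL,
                              n_dilutions = 8L, n_replicates = 3L,
                              drop_volume_ul = 5, pipetting_cv = 0.05,
                              drop_volume_cv = 0.02, p_no_drop = 0.0093,
                              p_coalescence = 0.0197, max_countable = 50L,
                              seed = NULL) {
  stopifnot(is.data.frame(susceptibility),
            all(c("phage_id", "strain_id", "stock_titer") %in%
                  names(susceptibility)))
  if (any(susceptibility$stock_titer <= 0))
    stop("stock titers must be positive", call. = FALSE)
  if (anyDuplicated(susceptibility[c("phage_id", "strain_id")]))
    stop("susceptibility must list each phage-strain pair once", call. = FALSE)
  if (is.null(strain_ids)) strain_ids <- sort(unique(susceptibility$strain_id))
  if (is.null(phage_ids)) phage_ids <- sort(unique(susceptibility$phage_id))
  if (length(strain_ids) == 0 || length(phage_ids) == 0)
    stop("panel must contain at least one strain and one phage", call. = FALSE)
  for (p in c(p_no_drop, p_coalescence))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (drop_volume_ul <= 0) stop("drop volume must be positive", call. = FALSE)
  if (n_dilutions < 1 || n_replicates < 1)
    stop("n_dilutions and n_replicates must be positive", call. = FALSE)
  if (pipetting_cv < 0 || drop_volume_cv < 0)
    stop("error CVs must be non-negative", call. = FALSE)
  structure(list(susceptibility = susceptibility,
                 strain_ids = as.character(strain_ids),
                 phage_ids = as.character(phage_ids),
                 n_dilutions = as.integer(n_dilutions),
                 n_replicates = as.integer(n_replicates),
                 drop_volume_ul = drop_volume_ul,
                 pipetting_cv = pipetting_cv,
                 drop_volume_cv = drop_volume_cv,
                 p_no_drop = p_no_drop,
                 p_coalescence = p_coalescence,
                 max_countable = as.integer(max_countable),
                 seed = seed), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Drop-off assay simulation: %d strains x %d phages x %d dilutions x %d replicates\n",
    length(x$strain_ids), length(x$phage_ids), x$n_dilutions, x$n_replicates))
  cat(sprintf("  %d susceptible interactions; drop %g uL; pipetting CV %g; p(no drop) %g; p(coalescence) %g\n",
              nrow(x$susceptibility), x$drop_volume_ul, x$pipetting_cv,
              x$p_no_drop, x$p_coalescence))
  invisible(x)
}

#' Example susceptibility panel for a large screening experiment
#'
#' Builds a sparse phage x strain susceptibility map shaped like a typical
#' screening campaign: each phage gets one reference host strain with a
#' high-titer stock (log-uniform between 1e8 and 1e10 PFU/mL, phage stocks
#' being > 1e8 PFU/mL), plus additional random positive interactions with
#' titers log-uniform between 1e4 and 7e10 PFU/mL.  Draws from the current
#' RNG stream (call `set.seed()` first for reproducibility).
#'
#' @param n_strains,n_phages Panel dimensions (defaults 126 and 11).
#' @param n_positive Total number of susceptible interactions including the
#'   reference hosts (default 151).
#'
#' @return List with `susceptibility` (data frame for
#'   [simulation_config()]), `reference_hosts` (named phage -> strain map),
#'   `strain_ids` and `phage_ids`.
#' @export
example_susceptibility <- function(n_strains = 126L, n_phages = 11L,
                                   n_positive = 151L) {
  stopifnot(n_strains >= 1, n_phages >= 1, n_positive >= n_phages,
            n_positive <= n_strains * n_phages)
  strains <- sprintf("strain_%03d", seq_len(n_strains))
  phages <- sprintf("phage_%02d", seq_len(n_phages))
  hosts <- strains[((seq_len(n_phages) - 1L) %% n_strains) + 1L]
  names(hosts) <- phages

  sus <- data.frame(phage_id = phages, strain_id = hosts,
                    stock_titer = 10^stats::runif(n_phages, 8, 10),
                    stringsAsFactors = FALSE)
  n_extra <- n_positive - n_phages
  if (n_extra > 0) {
    all_pairs <- expand.grid(phage_id = phages, strain_id = strains,
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    key <- paste(all_pairs$phage_id, all_pairs$strain_id)
    free <- which(!key %in% paste(sus$phage_id, sus$strain_id))
    pick <- sample(free, n_extra)
    sus <- rbind(sus, data.frame(
      phage_id = all_pairs$phage_id[pick],
      strain_id = all_pairs$strain_id[pick],
      stock_titer = 10^stats::runif(n_extra, 4, log10(7e10)),
      stringsAsFactors = FALSE))
  }
  list(susceptibility = sus, reference_hosts = hosts,
       strain_ids = strains, phage_ids = phages)
}

#' Simulate realized concentrations of a ten-fold dilution series
#'
#' Each transfer divides the concentration by ten and multiplies by a
#' lognormal pipetting error with median 1 and coefficient of variation
#' `pipetting_cv`; errors compound along the series.  The undiluted well
#' (exponent 0) is the stock itself.  Draws from the current RNG stream.
#'
#' @param stock Stock titer, PFU/mL (> 0).
#' @param pipetting_cv Fractional CV of the per-transfer error.
#' @param n_dilutions Series length including the undiluted well.
#'
#' @return Named numeric vector of concentrations for exponents
#'   `0:(n_dilutions - 1)`.
#' @examples
#' simulate_dilution_series(1e9, 0, 8)  # exact powers of ten
#' @export
simulate_dilution_series <- function(stock, pipetting_cv = 0.05,
                                     n_dilutions = 8L) {
  if (!is.finite(stock) || stock <= 0)
    stop("stock must be positive", call. = FALSE)
  if (n_dilutions < 1) stop("n_dilutions must be >= 1", call. = FALSE)
  eps <- if (n_dilutions > 1 && pipetting_cv > 0)
    stats::rlnorm(n_dilutions - 1L, 0, .sdlog_from_cv(pipetting_cv))
  else rep(1, max(0L, n_dilutions - 1L))
  conc <- stock * c(1, cumprod(eps / 10))
  names(conc) <- 0:(n_dilutions - 1L)
  conc
}

#' Simulate a single spot observation
#'
#' With probability `p_no_drop` the drop never lands; otherwise the
#' dispensed volume is jittered (lognormal, median `drop_volume_ul`, CV
#' `drop_volume_cv`) and the plaque count is Poisson with mean
#' concentration x volume.  A count of zero reads as `no_lysis`, counts up
#' to `max_countable` as `counted`, larger counts as confluent lysis.
#' Draws from the current RNG stream.
#'
#' @param concentration Phage concentration in the spotted dilution,
#'   PFU/mL (>= 0).
#' @param drop_volume_ul Nominal drop volume (uL).
#' @param drop_volume_cv Fractional volume jitter.
#' @param p_no_drop Probability of a missed drop.
#' @param max_countable Countability ceiling (plaques/spot).
#'
#' @return List with `status`, `plaque_count` (NA unless counted) and
#'   `drop_volume_ul` (realized volume, NA for missed drops).
#' @export
simulate_spot <- function(concentration, drop_volume_ul = 5,
                          drop_volume_cv = 0.02, p_no_drop = 0.0093,
                          max_countable = 50L) {
  if (!is.finite(concentration) || concentration < 0)
    stop("concentration must be non-negative", call. = FALSE)
  if (stats::runif(1) < p_no_drop)
    return(list(status = "no_drop", plaque_count = NA_integer_,
                drop_volume_ul = NA_real_))
  vol <- if (drop_volume_cv > 0)
    drop_volume_ul * stats::rlnorm(1, 0, .sdlog_from_cv(drop_volume_cv))
  else drop_volume_ul
  count <- stats::rpois(1, concentration * vol * 1e-3)
  status <- if (count == 0) "no_lysis"
            else if (count <= max_countable) "counted"
            else "confluent"
  list(status = status,
       plaque_count = if (status == "counted") count else NA_integer_,
       drop_volume_ul = vol)
}

#' Apply coalescence events to one replicate set
#'
#' Adjacent replicate drops of the same phage and dilution may merge on the
#' agar surface.  Pairs are considered in replicate order; each still-free
#' adjacent pair of landed drops merges independently with probability
#' `p_coalescence`, so a drop merges with at most one partner.  Merged
#' partners both take status `merged` and carry the blob's combined plaque
#' count (NA when either partner was confluent, since the blob cannot be
#' read).  Draws from the current RNG stream.
#'
#' @param triplicate Data frame of spot observations for one
#'   phage-strain-dilution replicate set, ordered by replicate.
#' @param p_coalescence Per-adjacent-pair merge probability.
#'
#' @return The replicate set with merged pairs resolved into `merged`
#'   statuses and symmetric `merge_partner` indices.
#' @export
apply_coalescence <- function(triplicate, p_coalescence) {
  stopifnot(is.data.frame(triplicate))
  n <- nrow(triplicate)
  out <- triplicate[order(triplicate$replicate), , drop = FALSE]
  if (n < 2 || p_coalescence <= 0) return(out)
  status <- as.character(out$status)
  eff_count <- ifelse(status == "no_lysis", 0L, out$plaque_count)
  for (i in seq_len(n - 1)) {
    if (status[i] == "merged") next  # already taken by the previous pair
    landed <- !status[i] %in% "no_drop" && !status[i + 1] %in% "no_drop"
    if (landed && stats::runif(1) < p_coalescence) {
      combined <- eff_count[i] + eff_count[i + 1]  # NA if either confluent
      status[c(i, i + 1)] <- "merged"
      out$plaque_count[c(i, i + 1)] <- combined
      out$merge_partner[i] <- out$replicate[i + 1]
      out$merge_partner[i + 1] <- out$replicate[i]
    }
  }
  out$status <- status
  out
}

#' Simulate a full drop-off assay
#'
#' Generates the complete factorial spot table (strain x phage x dilution x
#' replicate) of a robotic drop-off run under a [simulation_config()]:
#' realized serial dilutions with compounding pipetting error, jittered
#' drop volumes, Poisson plaque counts, missed drops and coalescence of
#' adjacent replicate drops.  Reproducible: the same `seed` yields a
#' byte-identical table.
#'
#' @param config A [simulation_config()].
#' @param seed Optional integer seed overriding `config$seed`.
#'
#' @return List with `spots` (spot-observation data frame in the schema of
#'   [read_spot_table()]) and `truth`, a list holding the realized
#'   concentration of every (phage, strain, dilution), the anomaly event
#'   log, and the configuration.
#' @export
simulate_assay <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)

  strains <- config$strain_ids; phages <- config$phage_ids
  nd <- config$n_dilutions; nr <- config$n_replicates
  pairs <- expand.grid(phage_id = phages, strain_id = strains,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$strain_id, pairs$phage_id), , drop = FALSE]
  np <- nrow(pairs)
  stock <- config$susceptibility$stock_titer[
    match(paste(pairs$phage_id, pairs$strain_id),
          paste(config$susceptibility$phage_id,
                config$susceptibility$strain_id))]
  stock[is.na(stock)] <- 0

  # realized concentrations: compounding lognormal error per transfer
  conc <- matrix(0, nrow = np, ncol = nd)
  sus <- which(stock > 0)
  if (length(sus)) {
    conc[sus, 1] <- stock[sus]
    if (nd > 1) {
      eps <- matrix(
        if (config$pipetting_cv > 0)
          stats::rlnorm(length(sus) * (nd - 1L), 0,
                        .sdlog_from_cv(config$pipetting_cv))
        else 1,
        nrow = length(sus), ncol = nd - 1L)
      steps <- apply(log(eps / 10), 1, cumsum)
      steps <- if (is.matrix(steps)) t(steps) else matrix(steps, ncol = 1L)
      conc[sus, -1] <- exp(log(stock[sus]) + steps)
    }
  }

  n_spots <- np * nd * nr
  spot <- data.frame(
    phage_id = rep(pairs$phage_id, each = nd * nr),
    strain_id = rep(pairs$strain_id, each = nd * nr),
    dilution_exponent = rep(rep(0:(nd - 1L), each = nr), times = np),
    replicate = rep(seq_len(nr), times = np * nd),
    stringsAsFactors = FALSE)
  lambda_conc <- conc[cbind(rep(seq_len(np), each = nd * nr),
                            spot$dilution_exponent + 1L)]

  no_drop <- stats::runif(n_spots) < config$p_no_drop
  vol <- if (config$drop_volume_cv > 0)
    config$drop_volume_ul *
      stats::rlnorm(n_spots, 0, .sdlog_from_cv(config$drop_volume_cv))
  else rep(config$drop_volume_ul, n_spots)
  count <- stats::rpois(n_spots, lambda_conc * vol * 1e-3)

  # coalescence: sequential adjacent pairs within each replicate set
  merged <- rep(FALSE, n_spots)
  partner <- rep(NA_integer_, n_spots)
  combined <- rep(NA_real_, n_spots)
  if (nr >= 2 && config$p_coalescence > 0) {
    ntrip <- np * nd
    first <- (seq_len(ntrip) - 1L) * nr  # offset of replicate 1 per set
    u <- matrix(stats::runif(ntrip * (nr - 1L)), nrow = ntrip)
    for (j in seq_len(nr - 1L)) {
      i1 <- first + j; i2 <- first + j + 1L
      free <- !merged[i1]
      hit <- free & !no_drop[i1] & !no_drop[i2] & u[, j] < config$p_coalescence
      if (any(hit)) {
        a <- i1[hit]; b <- i2[hit]
        merged[a] <- TRUE; merged[b] <- TRUE
        partner[a] <- j + 1L; partner[b] <- j
        combined[a] <- combined[b] <- count[a] + count[b]
      }
    }
  }

  status <- ifelse(no_drop, "no_drop",
            ifelse(merged, "merged",
            ifelse(count == 0, "no_lysis",
            ifelse(count <= config$max_countable, "counted", "confluent"))))
  pc <- rep(NA_real_, n_spots)
  pc[status == "counted"] <- count[status == "counted"]
  pc[status == "merged"] <- combined[status == "merged"]
  spot$drop_volume_ul <- ifelse(no_drop, NA_real_, vol)
  spot$status <- status
  spot$plaque_count <- pc
  spot$merge_partner <- partner

  truth_conc <- data.frame(
    phage_id = rep(pairs$phage_id, each = nd),
    strain_id = rep(pairs$strain_id, each = nd),
    dilution_exponent = rep(0:(nd - 1L), times = np),
    concentration = as.vector(t(conc)),
    stringsAsFactors = FALSE)
  ev_nd <- spot[no_drop, c("phage_id", "strain_id", "dilution_exponent",
                           "replicate")]
  ev_co <- spot[merged & !is.na(partner) & partner > spot$replicate,
                c("phage_id", "strain_id", "dilution_exponent", "replicate")]
  events <- rbind(
    if (nrow(ev_nd)) cbind(type = "no_drop", ev_nd),
    if (nrow(ev_co)) cbind(type = "coalescence", ev_co))

  list(spots = spot,
       truth = list(concentrations = truth_conc, events = events,
                    stocks = data.frame(phage_id = pairs$phage_id,
                                        strain_id = pairs$strain_id,
                                        stock_titer = stock,
                                        stringsAsFactors = FALSE),
                    config = config, seed = seed))
}

#' Run plan and throughput arithmetic for the liquid handler
#'
#' Computes plate, spot and run counts for a screening campaign, and the
#' volume each tip must aspirate per distribution cycle, `3 v n + 10` uL
#' for `n` plates per run and drop volume `v` (three replicate drops per
#' plate plus a 10 uL dead volume).
#'
#' @param n_strains Number of bacterial strains (one lawn plate set each).
#' @param n_phage_wells Number of phage suspensions to spot (single phages
#'   plus any cocktails).
#' @param n_dilutions,n_replicates Serial dilutions and replicate spots.
#' @param drop_volume_ul Drop volume v in uL.
#' @param phages_per_run Phage wells processed per run (one per pipetting
#'   channel; default 4).
#' @param plates_per_run_max Plate capacity of the work table (default 10).
#'
#' @return An object of class `run_plan` with `spots_per_plate`,
#'   `spots_per_run`, `plates_per_strain`, `total_plates`, `total_runs`,
#'   `total_spots` and `aspiration_volume_per_tip_ul`.
#' @examples
#' plan_run(10, 4)    # 96 spots/plate, 960 per run
#' plan_run(126, 11)  # 378 plates, 38 runs, 33264 spots
#' @export
plan_run <- function(n_strains, n_phage_wells, n_dilutions = 8L,
                     n_replicates = 3L, drop_volume_ul = 5,
                     phages_per_run = 4L, plates_per_run_max = 10L) {
  if (n_strains < 1 || n_phage_wells < 1)
    stop("n_strains and n_phage_wells must be positive", call. = FALSE)
  spots_per_plate <- phages_per_run * n_dilutions * n_replicates
  plates_per_strain <- ceiling(n_phage_wells / phages_per_run)
  total_plates <- n_strains * plates_per_strain
  total_runs <- ceiling(total_plates / plates_per_run_max)
  plates_per_run <- min(total_plates, plates_per_run_max)
  structure(list(
    n_strains = n_strains, n_phage_wells = n_phage_wells,
    n_dilutions = n_dilutions, n_replicates = n_replicates,
    phages_per_run = phages_per_run,
    plates_per_run_max = plates_per_run_max,
    spots_per_plate = spots_per_plate,
    spots_per_run = spots_per_plate * plates_per_run,
    plates_per_strain = plates_per_strain,
    total_plates = total_plates,
    total_runs = total_runs,
    total_spots = n_strains * n_phage_wells * n_dilutions * n_replicates,
    aspiration_volume_per_tip_ul = 3 * drop_volume_ul * plates_per_run + 10),
    class = "run_plan")
}

#' @export
print.run_plan <- function(x, ...) {
  cat(sprintf("Run plan: %d strains x %d phage wells x %d dilutions x %d replicates\n",
              x$n_strains, x$n_phage_wells, x$n_dilutions, x$n_replicates))
  cat(sprintf("  %d spots/plate, %d spots/run, %d total spots\n",
              x$spots_per_plate, x$spots_per_run, x$total_spots))
  cat(sprintf("  %d plates per strain, %d plates, %d runs\n",
              x$plates_per_strain, x$total_plates, x$total_runs))
  cat(sprintf("  aspiration per tip: %g uL\n", x$aspiration_volume_per_tip_ul))
  invisible(x)
}

#' Empirical anomaly rates of a spot table
#'
#' Estimates the missed-drop rate (missed spots over all spots) and the
#' coalescence rate per adjacent-pair opportunity: within each replicate
#' set, adjacent pairs are examined in order; a pair counts as an
#' opportunity when both drops landed and the left drop was not already
#' merged with its predecessor, which makes the estimator the exact
#' binomial counterpart of the generative per-pair merge probability.
#' Exact (Clopper-Pearson) binomial confidence intervals accompany both
#' rates; the fraction of spots in merged state is reported alongside.
#'
#' @param spots Spot-observation data frame.
#' @param conf_level Confidence level for the intervals (default 0.95).
#'
#' @return List with `no_drop` (`count`, `n`, `rate`, `ci`), `coalescence`
#'   (`events`, `opportunities`, `rate`, `ci`) and `merged_spot_fraction`.
#' @export
estimate_anomaly_rates <- function(spots, conf_level = 0.95) {
  stopifnot(is.data.frame(spots), nrow(spots) > 0)
  ord <- order(spots$strain_id, spots$phage_id, spots$dilution_exponent,
               spots$replicate)
  s <- spots[ord, , drop = FALSE]
  st <- as.character(s$status)
  pt <- s$merge_partner
  n <- nrow(s)

  n_no_drop <- sum(st == "no_drop")
  nd_ci <- stats::binom.test(n_no_drop, n, conf.level = conf_level)$conf.int

  events <- 0L; opps <- 0L
  if (n >= 2) {
    i <- seq_len(n - 1L)  # row pairs (i, i + 1) after ordering
    adjacent <- s$strain_id[i] == s$strain_id[i + 1L] &
      s$phage_id[i] == s$phage_id[i + 1L] &
      s$dilution_exponent[i] == s$dilution_exponent[i + 1L] &
      s$replicate[i + 1L] - s$replicate[i] == 1L
    landed <- st[i] != "no_drop" & st[i + 1L] != "no_drop"
    taken <- st[i] == "merged" & !is.na(pt[i]) &
      pt[i] == s$replicate[i] - 1L
    hit <- st[i] == "merged" & !is.na(pt[i]) &
      pt[i] == s$replicate[i] + 1L
    opps <- sum(adjacent & landed & !taken)
    events <- sum(adjacent & hit)
  }
  co_rate <- if (opps > 0) events / opps else NA_real_
  co_ci <- if (opps > 0)
    stats::binom.test(events, opps, conf.level = conf_level)$conf.int
  else c(NA_real_, NA_real_)

  list(no_drop = list(count = n_no_drop, n = nrow(spots),
                      rate = n_no_drop / nrow(spots),
                      ci = as.numeric(nd_ci)),
       coalescence = list(events = events, opportunities = opps,
                          rate = co_rate, ci = as.numeric(co_ci)),
       merged_spot_fraction = mean(st == "merged"))
}
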