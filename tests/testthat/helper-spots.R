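# Builders for in-code spot-table fixtures.

spot_rows <- function(exponent, statuses, counts = NA, partners = NA,
                      phage = "p1", strain = "s1", vol = 5) {
  n <- length(statuses)
  data.frame(phage_id = phage, strain_id = strain,
             dilution_exponent = exponent, replicate = seq_len(n),
             drop_volume_ul = vol, status = statuses,
             plaque_count = rep_len(as.numeric(counts), n),
             merge_partner = rep_len(as.numeric(partners), n),
             stringsAsFactors = FALSE)
}

# series: named list mapping exponent -> replicate layout; each entry is a
# numeric vector of counts (status counted; 0 -> no_lysis) or a character
# vector of statuses
series_spots <- function(layout, phage = "p1", strain = "s1", vol = 5,
                         n_rep = 3) {
  do.call(rbind, lapply(names(layout), function(k) {
    v <- layout[[k]]
    if (is.character(v)) {
      spot_rows(as.integer(k), rep_len(v, n_rep), phage = phage,
                strain = strain, vol = vol)
    } else {
      v <- rep_len(v, n_rep)
      spot_rows(as.integer(k),
                ifelse(v == 0, "no_lysis", "counted"),
                counts = ifelse(v == 0, NA, v),
                phage = phage, strain = strain, vol = vol)
    }
  }))
}

# triplicate with a symmetric merged pair (replicates 1 and 2) carrying the
# blob's combined count, plus a counted third replicate
merged_triplicate <- function(combined, third, exponent = 3, ...) {
  spot_rows(exponent, c("merged", "merged", "counted"),
            counts = c(combined, combined, third),
            partners = c(2, 1, NA), ...)
}
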