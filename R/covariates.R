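# Per-patch covariates: arthropod biomass density, insect Shannon
# diversity, fractional vegetation cover; assembly into the per-home-range
# covariate table with same-type gap filling.

#' Arthropod orders treated as non-insect
#'
#' These contribute to biomass but are excluded from the insect Shannon
#' index (specimens were identified to order level for insects only).
#' @export
NON_INSECT_ORDERS <- c("Araneae", "Opiliones", "Acari", "Isopoda",
                       "Gastropoda", "Myriapoda", "Chilopoda", "Diplopoda")

#' Shannon diversity of a count vector
#'
#' \eqn{H = -\sum p_i \ln p_i} over entries with count > 0 (natural log).
#'
#' @param counts Named nonnegative counts (one entry per taxon).
#' @return H >= 0.
#' @export
shannon_index <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) stop("Shannon index undefined for all-zero counts")
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Dry-mass density of a vacuum sample
#'
#' Sampled area is n_touchdowns x pi x (diameter/2)^2.
#'
#' @param dry_mass_g Dry mass of the sample (g).
#' @param device_diameter_m Suction-tube diameter (m).
#' @param n_touchdowns Number of touchdowns along the transect.
#' @return Biomass density in g/m^2.
#' @export
biomass_density <- function(dry_mass_g, device_diameter_m, n_touchdowns = 20L) {
  if (device_diameter_m <= 0) stop("device diameter must be > 0")
  stopifnot(dry_mass_g >= 0, n_touchdowns >= 1)
  dry_mass_g / (n_touchdowns * pi * (device_diameter_m / 2)^2)
}

#' Fractional vegetation cover of a record
#'
#' Zero for field paths (birds land on the bare track) and for vegetation
#' up to 5 cm (no hampering effect near the ground); otherwise the mean of
#' the observer estimates.
#'
#' @param record One-row vegetation table (est1..est3, low_vegetation,
#'   is_field_path).
#' @return FVC percent.
#' @export
fvc <- function(record) {
  if (isTRUE(record$is_field_path) || isTRUE(record$low_vegetation)) return(0)
  est <- c(record$est1, record$est2, record$est3)
  est <- est[!is.na(est)]
  if (!length(est)) stop("vegetation record ", record$record_id,
                         " has no observer estimate")
  mean(est)
}

# Shannon H of one arthropod-sample row over its count_* columns,
# excluding non-insect orders.  NA when no insect was caught.
sample_shannon <- function(sample_row) {
  cc <- grep("^count_", names(sample_row), value = TRUE)
  orders <- sub("^count_", "", cc)
  keep <- !(orders %in% NON_INSECT_ORDERS)
  counts <- as.numeric(sample_row[1, cc[keep]])
  if (sum(counts, na.rm = TRUE) == 0) return(NA_real_)
  shannon_index(counts[!is.na(counts)])
}

#' Assemble the covariate table of a home range
#'
#' One row per clipped patch with FVC, biomass density and insect Shannon
#' H.  A patch without its own measurement inherits the mean over sampled
#' patches of the same habitat type inside the same home range
#' (\code{imputed_same_type}); if none exists the gap is kept
#' (\code{missing}).  Imputation never crosses home ranges or habitat
#' types.
#'
#' @param home_range A \code{home_range}.
#' @param samples Arthropod-sample table.
#' @param vegetation Vegetation-record table.
#' @return data.frame with values and a provenance column per covariate.
#' @export
assemble_covariates <- function(home_range, samples, vegetation) {
  ids <- vapply(home_range$patches, function(p) p$patch_id, "")
  hab <- vapply(home_range$patches, function(p) p$habitat_type, "")
  n <- length(ids)
  val <- data.frame(patch_id = ids, habitat_type = hab,
                    fvc_pct = NA_real_, biomass_gm2 = NA_real_,
                    shannon_H = NA_real_,
                    fvc_prov = "missing", biomass_prov = "missing",
                    shannon_prov = "missing", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    s <- samples[samples$patch_id == ids[i], , drop = FALSE]
    if (nrow(s)) {
      s <- s[1, , drop = FALSE]
      val$biomass_gm2[i] <- biomass_density(s$dry_mass_g, s$device_diameter_m,
                                            s$n_touchdowns)
      val$biomass_prov[i] <- "measured"
      h <- sample_shannon(s)
      if (!is.na(h)) {
        val$shannon_H[i] <- h
        val$shannon_prov[i] <- "measured"
      }
    }
    v <- vegetation[vegetation$patch_id == ids[i], , drop = FALSE]
    if (nrow(v)) {
      val$fvc_pct[i] <- fvc(v[1, , drop = FALSE])
      val$fvc_prov[i] <- "measured"
    } else if (hab[i] == "field_path") {
      # field paths are zero by convention even without a record
      val$fvc_pct[i] <- 0
      val$fvc_prov[i] <- "measured"
    }
  }
  prov_map <- c(fvc_pct = "fvc_prov", biomass_gm2 = "biomass_prov",
                shannon_H = "shannon_prov")
  for (cov in names(prov_map)) {
    prov <- prov_map[[cov]]
    miss <- is.na(val[[cov]])
    for (i in which(miss)) {
      same <- which(hab == hab[i] & !is.na(val[[cov]]) &
                      val[[prov]] == "measured")
      if (length(same)) {
        val[[cov]][i] <- mean(val[[cov]][same])
        val[[prov]][i] <- "imputed_same_type"
      }
    }
  }
  val
}
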