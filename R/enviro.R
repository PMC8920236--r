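# PSS-78 coefficients (practical salinity from conductivity ratio and
# temperature at atmospheric pressure). The a-coefficients sum to 35 and the
# b-coefficients to 0, pinning S(R=1, 15 C) = 35.
pss_a <- c(0.0080, -0.1692, 25.3851, 14.0941, -7.0261, 2.7081)
pss_b <- c(0.0005, -0.0056, -0.0066, -0.0375, 0.0636, -0.0144)
pss_c <- c(0.6766097, 2.00564e-2, 1.104259e-4, -6.9698e-7, 1.0031e-9)
pss_k <- 0.0162
cond_35_15 <- 42.914  # mS/cm, conductivity of standard seawater at 15 C

#' Convert electrical conductivity to practical salinity
#'
#' Implements the Practical Salinity Scale 1978 (valid for salinities 2-42)
#' with the Hill et al. extension below salinity 2, at atmospheric pressure.
#' Salinity is dimensionless (practical scale). The extension makes the
#' scale continuous down to S = 0 (zero conductivity maps to zero salinity);
#' the two branches agree to ~2e-5 at the S = 2 boundary.
#'
#' Field probes usually report *specific conductance* — conductivity
#' temperature-compensated to 25 C. With `specific_conductance = TRUE`
#' (the default, matching that instrument convention) the input is first
#' converted back to in-situ conductivity with the standard 1.91 %/C linear
#' compensation before PSS-78 is applied at the measured temperature. Pass
#' `FALSE` when the input is raw in-situ conductivity.
#'
#' @param conductivity Conductivity in mS/cm (vector).
#' @param temperature Water temperature in degrees C (vector, recycled).
#' @param specific_conductance Logical; see Details.
#' @return Practical salinity (same length as `conductivity`). Values above
#'   42 are outside the scale's validity and trigger a warning but are still
#'   returned.
#' @examples
#' ec_to_salinity(42.914, 15, specific_conductance = FALSE)  # 35 by definition
#' @export
ec_to_salinity <- function(conductivity, temperature = 25,
                           specific_conductance = TRUE) {
  if (any(conductivity < 0, na.rm = TRUE)) {
    stop("conductivity must be non-negative", call. = FALSE)
  }
  n <- max(length(conductivity), length(temperature))
  conductivity <- rep_len(as.numeric(conductivity), n)
  temperature <- rep_len(as.numeric(temperature), n)
  if (specific_conductance) {
    conductivity <- conductivity * (1 + 0.0191 * (temperature - 25))
  }
  t <- temperature
  R <- conductivity / cond_35_15
  rt <- pss_c[1] + pss_c[2] * t + pss_c[3] * t^2 + pss_c[4] * t^3 + pss_c[5] * t^4
  Rt <- R / rt
  ft <- (t - 15) / (1 + pss_k * (t - 15))
  Rtp <- outer(Rt, (0:5) / 2, `^`)
  S <- drop(Rtp %*% pss_a) + ft * drop(Rtp %*% pss_b)
  x <- 400 * Rt
  y <- 100 * Rt
  S_low <- S - pss_a[1] / (1 + 1.5 * x + x^2) -
    pss_b[1] * ft / (1 + sqrt(y) + y + y^1.5)
  out <- ifelse(!is.na(S) & S < 2, S_low, S)
  if (any(out > 42, na.rm = TRUE)) {
    warning("salinity above 42 is outside the PSS-78 validity range",
            call. = FALSE)
  }
  out
}

#' Volume of water filtered, from a net flowmeter
#'
#' The product of the flowmeter rotation count, the flowmeter constant
#' (distance of water column per count) and the net mouth area.
#'
#' @param rotation_count Flowmeter counts (vector).
#' @param flowmeter_constant Metres of water column per count.
#' @param mouth_area Net mouth area in m^2.
#' @return Volume in m^3.
#' @export
flowmeter_volume <- function(rotation_count, flowmeter_constant, mouth_area) {
  if (any(mouth_area <= 0, na.rm = TRUE)) {
    stop("mouth_area must be positive", call. = FALSE)
  }
  if (any(rotation_count < 0, na.rm = TRUE) ||
      any(flowmeter_constant < 0, na.rm = TRUE)) {
    stop("rotation_count and flowmeter_constant must be non-negative",
         call. = FALSE)
  }
  rotation_count * flowmeter_constant * mouth_area
}

#' Catch per unit effort from a subsample count
#'
#' CPUE = organisms counted / fraction of the sample enumerated / volume of
#' water sampled, in individuals per m^3.
#'
#' @param organisms_counted Number of organisms counted (vector).
#' @param subsample_fraction Fraction of the sample enumerated, in (0, 1].
#' @param volume Volume of water sampled in m^3 (> 0).
#' @return CPUE in individuals per m^3.
#' @export
compute_cpue <- function(organisms_counted, subsample_fraction, volume) {
  if (any(subsample_fraction <= 0 | subsample_fraction > 1, na.rm = TRUE)) {
    stop("subsample_fraction must be in (0, 1]", call. = FALSE)
  }
  if (any(volume <= 0, na.rm = TRUE)) {
    stop("volume must be positive", call. = FALSE)
  }
  organisms_counted / subsample_fraction / volume
}

#' Attach carbon biomass concentrations to catch records
#'
#' Multiplies each record's CPUE by the literature carbon mass per individual
#' for its taxon/lifestage. Taxa without a literature value get missing
#' biomass (not zero), reflecting gaps in the literature.
#'
#' @param catch Catch records with `Taxlifestage` and `CPUE`.
#' @param biomass_table Tibble with `Taxlifestage`,
#'   `Carbon_mass_micrograms` (> 0) and optionally `Reference`.
#' @return `catch` with a `BPUE_ugC` column (micrograms of carbon per m^3).
#' @export
add_biomass <- function(catch, biomass_table) {
  biomass_table <- tibble::as_tibble(biomass_table)
  if (any(biomass_table$Carbon_mass_micrograms <= 0, na.rm = TRUE)) {
    stop("carbon masses must be positive", call. = FALSE)
  }
  i <- match(catch$Taxlifestage, biomass_table$Taxlifestage)
  catch$BPUE_ugC <- catch$CPUE * biomass_table$Carbon_mass_micrograms[i]
  catch
}

#' Flag taxa undersampled by a gear via matched-sample comparison
#'
#' Restricts both gears' catch to station/dates where both collected a
#' sample, sums CPUE per taxon/lifestage over those matched samples in each
#' gear, and compares the totals. When the meso/micro ratio falls below
#' `retain_ratio_threshold` the meso gear is flagged undersampled for that
#' taxon; above `1/retain_ratio_threshold`, the micro gear is. Only taxa
#' counted by both gears are compared. Flags mark records for cautious
#' analysis; nothing is deleted.
#'
#' @param meso,micro Catch tables carrying `Station`, `Date`, `Taxlifestage`,
#'   `CPUE` for the two gears.
#' @param matching Optional tibble of `Station`, `Date` pairs to use; by
#'   default the intersection of the two tables' pairs.
#' @param retain_ratio_threshold Ratio inside
#'   `[threshold, 1/threshold]` is considered comparable (default 0.75, which
#'   retains a taxon whose net catch is 80% of its pump catch).
#' @return Tibble: `Taxlifestage`, `CPUE_meso`, `CPUE_micro`, `Ratio`,
#'   `FlaggedGear` (`"Meso"`, `"Micro"` or `"none"`).
#' @export
flag_undersampled <- function(meso, micro, matching = NULL,
                              retain_ratio_threshold = 0.75) {
  meso <- tibble::as_tibble(meso)
  micro <- tibble::as_tibble(micro)
  pairs_of <- function(x) dplyr::distinct(x[, c("Station", "Date")])
  if (is.null(matching)) {
    matching <- dplyr::inner_join(pairs_of(meso), pairs_of(micro),
                                  by = c("Station", "Date"))
  }
  if (nrow(matching) == 0) {
    stop("no matched station/date pairs between the two gears", call. = FALSE)
  }
  key <- function(x) paste(x$Station, x$Date)
  mkey <- key(matching)
  meso_m <- meso[key(meso) %in% mkey, ]
  micro_m <- micro[key(micro) %in% mkey, ]
  shared <- intersect(unique(meso$Taxlifestage), unique(micro$Taxlifestage))
  tot <- function(x) {
    x <- x[x$Taxlifestage %in% shared, ]
    dplyr::summarise(dplyr::group_by(x, .data$Taxlifestage),
                     Total = sum(.data$CPUE, na.rm = TRUE), .groups = "drop")
  }
  cmp <- dplyr::full_join(dplyr::rename(tot(meso_m), CPUE_meso = "Total"),
                          dplyr::rename(tot(micro_m), CPUE_micro = "Total"),
                          by = "Taxlifestage")
  cmp$CPUE_meso[is.na(cmp$CPUE_meso)] <- 0
  cmp$CPUE_micro[is.na(cmp$CPUE_micro)] <- 0
  cmp$Ratio <- ifelse(cmp$CPUE_micro > 0, cmp$CPUE_meso / cmp$CPUE_micro,
                      ifelse(cmp$CPUE_meso > 0, Inf, NA_real_))
  thr <- retain_ratio_threshold
  cmp$FlaggedGear <- dplyr::case_when(
    is.na(cmp$Ratio) ~ "none",
    cmp$Ratio < thr ~ "Meso",
    cmp$Ratio > 1 / thr ~ "Micro",
    TRUE ~ "none")
  cmp
}

#' Undersampled list from a gear comparison
#'
#' @param comparison Output of [flag_undersampled()].
#' @return Tibble `Taxlifestage`, `Gear` of flagged combinations (the
#'   undersampled.csv shape).
#' @export
undersampled_list <- function(comparison) {
  flagged <- comparison[comparison$FlaggedGear != "none", ]
  tibble::tibble(Taxlifestage = flagged$Taxlifestage,
                 Gear = flagged$FlaggedGear)
}
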