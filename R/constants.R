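#' Emission sector codes
#'
#' The five anthropogenic emission sectors whose scaling factors form the
#' emulator input space: residential (RES), industry (IND), land transport
#' (TRA), agriculture (AGR), and power generation (ENE). A scaling factor of
#' 1.0 corresponds to the 2015 baseline emissions of that sector; the design
#' space is \[0, 1.5\] (0\%--150\%).
#'
#' @return Character vector of the five sector codes, in canonical order.
#' @export
#' @examples
#' sectors()
sectors <- function() c("RES", "IND", "TRA", "AGR", "ENE")

#' Bounds of the emission-scaling design space
#' @return Numeric vector `c(lower, upper)` = `c(0, 1.5)`.
#' @export
scaling_bounds <- function() c(0, 1.5)

#' Annual air-quality thresholds for PM2.5
#'
#' WHO annual Air Quality Guideline (AQG, 10), WHO Interim Targets 3/2/1
#' (15/25/35), and China's National Air Quality Target (NAQT, 35), all in
#' micrograms per cubic metre. IT-2 and IT-3 are the WHO 2005 annual interim
#' targets; they are external constants, not fitted quantities.
#'
#' @return Named numeric vector of thresholds (ug/m3).
#' @export
#' @examples
#' aq_thresholds()
aq_thresholds <- function() {
  c(AQG = 10, "IT-3" = 15, "IT-2" = 25, "IT-1" = 35, NAQT = 35)
}

#' Region names used for regional aggregation
#'
#' Seven regional groupings of mainland China commonly used for air-quality
#' reporting: North China, North East China, East China, South Central China,
#' South West China, North West China, and the Guangdong-Hong Kong-Macau
#' Greater Bay Area (GBA).
#'
#' @return Character vector of region names.
#' @export
regions <- function() {
  c("North China", "North East China", "East China", "South Central China",
    "South West China", "North West China", "GBA")
}

#' Default per-region first-order variance-share profiles
#'
#' Target first-order Sobol shares of PM2.5 variance per emission sector for
#' each region, expressed as fractions summing to 1. These encode the typical
#' regional pattern of wintertime sectoral dominance over China: residential
#' emissions dominate everywhere (roughly 50--95\%), industry is the usual
#' second contributor, agriculture matters most in the South West and North
#' West, and land transport and power generation are small except for land
#' transport in the South West. Integer-percent patterns are normalized so
#' each profile sums exactly to 1.
#'
#' @param china_only If `TRUE`, return a single country-wide profile
#'   (RES 64, IND 16, TRA 4, AGR 14, ENE 1 \%) applied to every region.
#' @return Data frame with columns `region`, `RES`, `IND`, `TRA`, `AGR`,
#'   `ENE`; rows sum to 1.
#' @export
#' @examples
#' region_profiles()
region_profiles <- function(china_only = FALSE) {
  raw <- rbind(
    "North China"         = c(73, 20, 1, 4, 3),
    "North East China"    = c(94, 5, 1, 0, 1),
    "East China"          = c(77, 18, 1, 3, 0),
    "South Central China" = c(81, 13, 1, 4, 0),
    "South West China"    = c(52, 7, 13, 24, 1),
    "North West China"    = c(51, 23, 3, 22, 1),
    "GBA"                 = c(56, 31, 2, 11, 0)
  )
  if (china_only) {
    raw <- matrix(c(64, 16, 4, 14, 1), nrow = nrow(raw), ncol = 5,
                  byrow = TRUE, dimnames = dimnames(raw))
  }
  shares <- sweep(raw, 1, rowSums(raw), "/")
  colnames(shares) <- sectors()
  data.frame(region = rownames(raw), shares, row.names = NULL,
             check.names = FALSE)
}

#' Default per-region baseline exposure magnitudes
#'
#' Illustrative monthly-mean (January) baseline PM2.5 exposures (ug/m3) used
#' to scale the synthetic simulator so exposure numbers are plausible for
#' wintertime China (roughly 50--120 ug/m3 by region). Illustrative only;
#' nothing downstream asserts these values.
#'
#' @return Named numeric vector, one value per region (ug/m3).
#' @export
region_baselines <- function() {
  c("North China" = 122.2, "North East China" = 80.8, "East China" = 104.1,
    "South Central China" = 111.5, "South West China" = 116.6,
    "North West China" = 50.2, "GBA" = 54.8)
}

# internal: validate a 5-vector of scaling factors
check_scaling <- function(x, allow_outside = FALSE) {
  if (length(x) != 5L || anyNA(x) || !is.numeric(x))
    stop("emission-scaling vector must be 5 finite numbers (RES, IND, TRA, AGR, ENE)")
  b <- scaling_bounds()
  if (!allow_outside && (any(x < b[1]) || any(x > b[2])))
    stop("emission-scaling factors must lie in [", b[1], ", ", b[2], "]")
  invisible(x)
}
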