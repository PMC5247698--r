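#' Hepatocyte cross-sectional area from perpendicular diameters
#'
#' Hepatocyte profiles are modelled as ovals: two perpendicular diameters
#' `d1` and `d2` (microns) give area `pi * (d1/2) * (d2/2)`. Vectorised and
#' symmetric in its arguments.
#'
#' @param d1_um,d2_um Perpendicular diameters in microns (>= 0).
#' @return Area in square microns.
#' @examples
#' ellipse_area(20, 20)  # circle of diameter 20: 100*pi
#' @export
ellipse_area <- function(d1_um, d2_um) {
  if (any(d1_um < 0) || any(d2_um < 0))
    stop_input("diameters must be non-negative")
  pi * (d1_um / 2) * (d2_um / 2)
}

#' Per-biopsy hepatocyte area
#'
#' The biopsy's hepatocyte area (HA) is the median of the individual cell
#' areas; with an even count, the mean of the two central values. A typical
#' protocol measures 50 cells per biopsy (5 cells on each of 10 random
#' fields); fewer trigger a warning, not an error.
#'
#' @param areas_um2 Vector of hepatocyte areas (um^2), or a data.frame with
#'   columns `d1_um` and `d2_um` from which areas are computed.
#' @param expected_n Sample size below which to warn (default 50).
#' @return Median area in um^2.
#' @export
biopsy_hepatocyte_area <- function(areas_um2, expected_n = 50L) {
  if (is.data.frame(areas_um2)) {
    if (!all(c("d1_um", "d2_um") %in% names(areas_um2)))
      stop_input("data.frame input needs columns d1_um and d2_um")
    areas_um2 <- ellipse_area(areas_um2$d1_um, areas_um2$d2_um)
  }
  if (!length(areas_um2)) stop_input("no hepatocyte measurements supplied")
  if (length(areas_um2) < expected_n)
    warning(sprintf("only %d hepatocytes measured (protocol samples %d)",
                    length(areas_um2), expected_n), call. = FALSE)
  stats::median(areas_um2)
}

#' Per-biopsy lobule radius
#'
#' Median of the portal-tract-to-central-vein distances measured around the
#' biopsy's identifiable lobules.
#'
#' @param distances_um Positive distances in microns.
#' @return Median distance in um.
#' @export
biopsy_lobule_radius <- function(distances_um) {
  if (!length(distances_um)) stop_input("no lobule distances supplied")
  if (any(distances_um <= 0)) stop_input("lobule distances must be positive")
  stats::median(distances_um)
}

#' Hepatocytes per lobule under the hexagonal lobule model
#'
#' The liver lobule is idealised as a regular hexagon whose radius is the
#' portal-tract-to-central-vein distance. Dividing the hexagon's
#' cross-sectional area by the hepatocyte cross-sectional area gives an
#' approximate (2-dimensional) hepatocyte count per lobule - an index, not
#' an actual cell count.
#'
#' Two conventions are offered for what the measured distance means:
#' \describe{
#'   \item{`"circumradius"` (default)}{distance to a hexagon corner; the
#'     portal tracts sit at lobule corners, so the portal-tract-to-central-
#'     vein distance is the circumradius `R` and the area is
#'     `(3*sqrt(3)/2) * R^2`.}
#'   \item{`"apothem"`}{distance to an edge midpoint `a`; area
#'     `2*sqrt(3) * a^2`. For the same measured distance this yields exactly
#'     4/3 of the circumradius value.}
#' }
#'
#' @param lr_um Lobule radius in microns (> 0).
#' @param ha_um2 Hepatocyte area in square microns (> 0).
#' @param convention `"circumradius"` or `"apothem"`.
#' @return Approximate hepatocytes per lobule (dimensionless).
#' @examples
#' hepatocytes_per_lobule(466, 273)  # about 2066.5
#' @export
hepatocytes_per_lobule <- function(lr_um, ha_um2,
                                   convention = c("circumradius", "apothem")) {
  convention <- match.arg(convention)
  if (any(lr_um <= 0)) stop_input("lr_um must be positive")
  if (any(ha_um2 <= 0)) stop_input("ha_um2 must be positive")
  hex_area <- switch(convention,
    circumradius = (3 * sqrt(3) / 2) * lr_um^2,
    apothem = 2 * sqrt(3) * lr_um^2
  )
  hex_area / ha_um2
}

#' Summarise morphometry measurements per biopsy
#'
#' Consumes long tables of raw measurements - hepatocyte diameter pairs and
#' lobule radii - and returns one row per biopsy with HA (median hepatocyte
#' area), LR (median lobule radius) and the derived HpL.
#'
#' @param hepatocytes data.frame with columns `biopsy_id`, `d1_um`, `d2_um`.
#' @param lobules data.frame with columns `biopsy_id`, `distance_um`.
#' @param convention Hexagon convention, see [hepatocytes_per_lobule()].
#' @return data.frame with columns `biopsy_id`, `ha_um2`, `lr_um`, `hpl`,
#'   `n_hepatocytes`, `n_lobule_measurements`.
#' @export
biopsy_morphometry <- function(hepatocytes, lobules,
                               convention = c("circumradius", "apothem")) {
  convention <- match.arg(convention)
  for (nm in c("biopsy_id", "d1_um", "d2_um"))
    if (!nm %in% names(hepatocytes)) stop_input("hepatocytes table lacks column ", nm)
  for (nm in c("biopsy_id", "distance_um"))
    if (!nm %in% names(lobules)) stop_input("lobules table lacks column ", nm)
  ids <- sort(unique(c(hepatocytes$biopsy_id, lobules$biopsy_id)))
  rows <- lapply(ids, function(id) {
    h <- hepatocytes[hepatocytes$biopsy_id == id, , drop = FALSE]
    l <- lobules[lobules$biopsy_id == id, , drop = FALSE]
    if (!nrow(h) || !nrow(l))
      stop_input("biopsy ", id, " lacks hepatocyte or lobule measurements")
    ha <- suppressWarnings(biopsy_hepatocyte_area(h))
    lr <- biopsy_lobule_radius(l$distance_um)
    data.frame(biopsy_id = id, ha_um2 = ha, lr_um = lr,
               hpl = hepatocytes_per_lobule(lr, ha, convention),
               n_hepatocytes = nrow(h), n_lobule_measurements = nrow(l),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
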