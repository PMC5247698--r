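#' Fat segmentation parameters
#'
#' Controls [segment_fat()]. Candidate fat pixels are those whose red, green
#' and blue values all reach their channel thresholds ("white" against
#' eosin-pink cytoplasm). Candidate connected components are then kept as
#' fat only if they fall inside an area window and are round enough;
#' everything else (dilated sinusoids, vessel lumens, other near-white
#' confounders) is moved to the exclusion mask - an automated stand-in for
#' manual editing of artifacts.
#'
#' @param channel_thresholds Lower bounds (R, G, B) in `[0, 255]`; default
#'   `c(200, 200, 200)` sits between typical eosin staining and unstained
#'   fat.
#' @param min_object_area_um2,max_object_area_um2 Retained-object area
#'   window in square microns (defaults 20 and 8000; a 8000 um^2 circle has
#'   diameter ~101 um, just above the largest macrovesicular vacuoles).
#' @param min_circularity Shape cut in `[0, 1]`; circularity is
#'   `4*pi*area / perimeter^2` with perimeter measured along the
#'   8-connected boundary contour. Discs score near 1, ribbons near 0.
#' @param fill_holes Fill enclosed holes in candidate components before
#'   measuring them.
#' @return An object of class `"segmentation_params"`.
#' @export
segmentation_params <- function(channel_thresholds = c(200, 200, 200),
                                min_object_area_um2 = 20,
                                max_object_area_um2 = 8000,
                                min_circularity = 0.5,
                                fill_holes = TRUE) {
  if (length(channel_thresholds) != 3L || any(channel_thresholds < 0) ||
      any(channel_thresholds > 255))
    stop_input("channel_thresholds must be three values in [0, 255]")
  assert_scalar_num(min_object_area_um2, "min_object_area_um2", lo = 0)
  assert_scalar_num(max_object_area_um2, "max_object_area_um2", lo = 0)
  if (min_object_area_um2 >= max_object_area_um2)
    stop_input("min_object_area_um2 must be below max_object_area_um2")
  assert_scalar_num(min_circularity, "min_circularity", lo = 0, hi = 1)
  structure(list(channel_thresholds = as.numeric(channel_thresholds),
                 min_object_area_um2 = as.numeric(min_object_area_um2),
                 max_object_area_um2 = as.numeric(max_object_area_um2),
                 min_circularity = as.numeric(min_circularity),
                 fill_holes = isTRUE(fill_holes)),
            class = "segmentation_params")
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a union-find pass over the label adjacencies.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  n <- max(lab)
  if (n < 2) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  a1 <- lab[-H, -W]; b1 <- lab[-1, -1]    # \ diagonal
  a2 <- lab[-H, -1]; b2 <- lab[-1, -W]    # / diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (!nrow(pairs)) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[out > 0] <- remap[out[out > 0]]
  out
}

# Perimeter of each labeled object as the length of its 8-connected boundary
# contour (unit steps count 1, diagonal steps sqrt(2)).
contour_perimeters <- function(lab) {
  ct <- EBImage::ocontour(lab)
  vapply(ct, function(p) {
    if (nrow(p) < 2) return(0)
    d <- sqrt(rowSums((p - p[c(2:nrow(p), 1), , drop = FALSE])^2))
    sum(d)
  }, numeric(1))
}

#' Segment fat vacuoles in a calibrated RGB field
#'
#' Implements the mFPA segmentation for one field:
#' \enumerate{
#'   \item candidate fat = pixels with all three channels at or above the
#'     channel thresholds;
#'   \item off-section background = candidate components touching the field
#'     border with area above 10% of the field (section edges, not fat);
#'   \item remaining candidate components are filtered by the area window
#'     and circularity; components that fail are excluded (the automated
#'     proxy for manual editing of sinusoids, vessels and other artifacts);
#'   \item any user-supplied `manual_exclusion` pixels are always excluded;
#'   \item parenchyma = all non-background pixels minus exclusions (fat
#'     pixels remain part of the parenchyma, whose area is the mFPA
#'     denominator).
#' }
#'
#' @param field An [rgb_field()] (or the `$field` element returned by
#'   [generate_field()]).
#' @param params A [segmentation_params()].
#' @param manual_exclusion Optional logical matrix of the field's size;
#'   `TRUE` pixels are removed from both fat and parenchyma.
#' @return An object of class `"segmentation_result"`: logical masks
#'   `fat_mask`, `parenchyma_mask`, `exclusion_mask`, `background_mask`,
#'   areas `fat_area_um2` and `parenchyma_area_um2`, the per-field fat
#'   `fraction`, and `field_id`.
#' @export
segment_fat <- function(field, params = segmentation_params(),
                        manual_exclusion = NULL) {
  if (is.list(field) && !inherits(field, "rgb_field") && inherits(field$field, "rgb_field"))
    field <- field$field
  if (!inherits(field, "rgb_field")) stop_input("`field` must be an rgb_field")
  if (!inherits(params, "segmentation_params")) stop_input("`params` must be segmentation_params")
  if (is.null(field$um_per_px) || field$um_per_px <= 0)
    stop_input("field is not calibrated (um_per_px missing or <= 0)")
  px <- field$pixels
  H <- dim(px)[1]; W <- dim(px)[2]
  if (!is.null(manual_exclusion)) {
    if (!identical(dim(manual_exclusion), c(H, W)))
      stop_input("manual_exclusion must match the field's pixel dimensions")
    manual_exclusion <- manual_exclusion > 0
  } else manual_exclusion <- matrix(FALSE, H, W)

  th <- params$channel_thresholds
  cand <- px[, , 1] >= th[1] & px[, , 2] >= th[2] & px[, , 3] >= th[3]
  if (all(cand)) stop_input("no tissue detected: every pixel passes the whiteness rule")

  um2 <- field$um_per_px^2

  # off-section background: big white components touching the border
  background <- matrix(FALSE, H, W)
  if (any(cand)) {
    lab <- label8(cand)
    n <- max(lab)
    if (n > 0) {
      areas <- tabulate(lab[lab > 0], nbins = n)
      border_labs <- unique(c(lab[1, ], lab[H, ], lab[, 1], lab[, W]))
      border_labs <- border_labs[border_labs > 0]
      bg_labs <- border_labs[areas[border_labs] > 0.10 * H * W]
      if (length(bg_labs)) background <- matrix(lab %in% bg_labs, H, W)
    }
  }

  work <- cand & !background
  if (params$fill_holes && any(work)) work <- EBImage::fillHull(work * 1) > 0

  fat <- matrix(FALSE, H, W)
  exclusion <- matrix(FALSE, H, W)
  if (any(work)) {
    lab <- label8(work)
    n <- max(lab)
    areas_px <- tabulate(lab[lab > 0], nbins = n)
    perim <- contour_perimeters(lab)
    areas_um2 <- areas_px * um2
    circ <- ifelse(perim < 1, 1, pmin(1, 4 * pi * areas_px / perim^2))
    keep <- areas_um2 >= params$min_object_area_um2 &
            areas_um2 <= params$max_object_area_um2 &
            circ >= params$min_circularity
    keep_labs <- which(keep)
    fat <- matrix(lab %in% keep_labs, H, W)
    exclusion <- work & !fat
  }
  fat <- fat & !manual_exclusion
  exclusion <- (exclusion | manual_exclusion) & !background
  parenchyma <- !background & !exclusion

  structure(list(fat_mask = fat, parenchyma_mask = parenchyma,
                 exclusion_mask = exclusion, background_mask = background,
                 fat_area_um2 = sum(fat) * um2,
                 parenchyma_area_um2 = sum(parenchyma) * um2,
                 fraction = if (sum(parenchyma) > 0) sum(fat) / sum(parenchyma) else NA_real_,
                 field_id = field$field_id),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result '%s'> fat %.0f um^2 / parenchyma %.0f um^2 = %.2f%%\n",
              x$field_id, x$fat_area_um2, x$parenchyma_area_um2, 100 * x$fraction))
  invisible(x)
}

#' Pool field segmentations into a biopsy mFPA
#'
#' The biopsy's measured fat proportionate area is a single pooled ratio:
#' total fat area over total parenchyma area across all fields, times 100.
#' It is not the mean of per-field percentages (the two agree only when all
#' fields have equal parenchyma area).
#'
#' @param results List of [segment_fat()] results (>= 1).
#' @param biopsy_id Identifier.
#' @param tolerance,window Passed to [adequacy_check()] on the per-field
#'   fraction sequence; adequacy is reported, not enforced.
#' @return An object of class `"biopsy_mfpa"`: `biopsy_id`, `mfpa_pct`,
#'   `n_fields`, `fat_area_um2`, `parenchyma_area_um2`,
#'   `adequacy_converged`, and the `field_results`.
#' @export
aggregate_mfpa <- function(results, biopsy_id = "biopsy",
                           tolerance = 0.5, window = 5L) {
  if (inherits(results, "segmentation_result")) results <- list(results)
  if (!length(results)) stop_input("no field results to aggregate")
  for (r in results)
    if (!inherits(r, "segmentation_result"))
      stop_input("all elements must be segmentation_result objects")
  par_areas <- vapply(results, `[[`, numeric(1), "parenchyma_area_um2")
  zero <- which(par_areas == 0)
  if (length(zero))
    stop_input("field(s) with zero parenchyma area: ",
               paste(vapply(results[zero], `[[`, character(1), "field_id"), collapse = ", "))
  fat_areas <- vapply(results, `[[`, numeric(1), "fat_area_um2")
  fractions <- fat_areas / par_areas
  converged <- if (length(results) >= window)
    adequacy_check(fractions, tolerance = tolerance, window = window) else NA
  structure(list(biopsy_id = biopsy_id,
                 mfpa_pct = 100 * sum(fat_areas) / sum(par_areas),
                 n_fields = length(results),
                 fat_area_um2 = sum(fat_areas),
                 parenchyma_area_um2 = sum(par_areas),
                 adequacy_converged = converged,
                 field_results = results),
            class = "biopsy_mfpa")
}

#' @export
print.biopsy_mfpa <- function(x, ...) {
  cat(sprintf("<biopsy_mfpa '%s'> mFPA %.2f%% over %d fields (adequacy: %s)\n",
              x$biopsy_id, x$mfpa_pct, x$n_fields,
              if (is.na(x$adequacy_converged)) "n/a" else x$adequacy_converged))
  invisible(x)
}

#' Randomly sample fields for a biopsy
#'
#' Uniform sample without replacement, deterministic under `seed`; the
#' default of 21 fields reflects the standard protocol of imaging 21
#' randomly selected non-overlapping areas per biopsy.
#'
#' @param candidate_fields List (or vector) of candidates.
#' @param n Number to select (default 21).
#' @param seed Integer seed.
#' @return The selected subset, in sampled order.
#' @export
sample_fields <- function(candidate_fields, n = 21L, seed = 1L) {
  if (length(candidate_fields) < n)
    stop_input(sprintf("only %d candidate fields for a sample of %d",
                       length(candidate_fields), n))
  set.seed(seed)
  idx <- sample.int(length(candidate_fields), n)
  if (is.list(candidate_fields)) candidate_fields[idx] else candidate_fields[idx]
}

#' Sampling-adequacy check on the running mFPA estimate
#'
#' After each field, the running mFPA estimate is the cumulative mean of the
#' per-field fat fractions (x100). Sampling is judged adequate when the
#' running estimate has stabilised: over the last `window` added fields its
#' spread (max minus min) is at most `tolerance` percentage points. This is
#' a reconstruction of a stopping rule for choosing the number of fields;
#' the convention here is a running-estimate convergence criterion.
#'
#' @param per_field_fractions Per-field fat fractions (proportions in
#'   `[0, 1]`), in acquisition order; at least `window` values.
#' @param tolerance Maximum allowed drift, percentage points (default 0.5).
#' @param window Number of most recent fields over which drift is measured
#'   (default 5, minimum 2).
#' @return `TRUE` if converged, else `FALSE`.
#' @export
adequacy_check <- function(per_field_fractions, tolerance = 0.5, window = 5L) {
  if (window < 2) stop_input("window must be at least 2")
  n <- length(per_field_fractions)
  if (n < window)
    stop_input(sprintf("need at least %d per-field fractions, got %d", window, n))
  if (any(per_field_fractions < 0 | per_field_fractions > 1))
    stop_input("per-field fractions must be proportions in [0, 1]")
  running <- 100 * cumsum(per_field_fractions) / seq_len(n)
  recent <- running[(n - window + 1):n]
  (max(recent) - min(recent)) <= tolerance
}
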