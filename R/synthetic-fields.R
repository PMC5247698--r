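#' Specification of a synthetic H&E field image
#'
#' Describes one microscope field to be rendered by [generate_field()]:
#' geometry and calibration, the target fat fraction, the vacuole size range
#' and the density of near-white confounding artifacts (dilated sinusoids and
#' vessel lumens) that a segmentation step must learn to exclude.
#'
#' @param width_px,height_px Field size in pixels (each at least 64).
#' @param um_per_px Calibration, microns per pixel (> 0). The default 0.5
#'   corresponds to a typical x20 objective acquisition.
#' @param target_fat_fraction Desired fat area as a proportion of the field,
#'   in `[0, 0.6]`; vacuoles are packed without overlap, which becomes
#'   infeasible beyond roughly 60%.
#' @param vacuole_diameter_um Length-2 range (min, max) of vacuole diameters
#'   in microns. The default 10-80 um spans micro- to macrovesicular fat.
#' @param artifact_density Expected number of artifacts per field (Poisson
#'   rate, >= 0). Artifacts are near-white like fat but either elongated
#'   (sinusoid ribbons) or much larger than any vacuole (vessel lumens).
#' @param artifact_kinds Character subset of `c("sinusoid", "vessel")`.
#' @param seed Integer seed; identical specs give bit-identical fields.
#' @param colours Optional list overriding the rendered colour model; see
#'   Details.
#'
#' @details The colour model (8-bit RGB means and spreads) defaults to
#' `parenchyma_mean = c(200, 120, 150)`, `parenchyma_sd = c(15, 20, 20)`,
#' `nucleus_mean = c(80, 60, 140)`, `vacuole_mean = c(245, 245, 245)` with
#' `vacuole_sd = 5`, and near-white artifacts at `c(248, 248, 248)`. These
#' emulate eosin-pink cytoplasm with haematoxylin nuclear speckle and
#' unstained fat, and make the default segmentation thresholds meaningful.
#'
#' @return An object of class `"field_spec"`.
#' @seealso [generate_field()]
#' @export
field_spec <- function(width_px = 512L, height_px = 512L, um_per_px = 0.5,
                       target_fat_fraction = 0.1,
                       vacuole_diameter_um = c(10, 80),
                       artifact_density = 0,
                       artifact_kinds = c("sinusoid", "vessel"),
                       seed = 1L, colours = list()) {
  assert_scalar_num(width_px, "width_px", lo = 64)
  assert_scalar_num(height_px, "height_px", lo = 64)
  assert_scalar_num(um_per_px, "um_per_px", lo = 0, strict_lo = TRUE)
  assert_scalar_num(target_fat_fraction, "target_fat_fraction", lo = 0, hi = 1)
  if (target_fat_fraction > 0.6)
    stop_input("target_fat_fraction > 0.6: non-overlapping vacuole packing is not feasible")
  if (length(vacuole_diameter_um) != 2L || any(vacuole_diameter_um <= 0) ||
      vacuole_diameter_um[1] > vacuole_diameter_um[2])
    stop_input("vacuole_diameter_um must be an increasing positive (min, max) pair")
  assert_scalar_num(artifact_density, "artifact_density", lo = 0)
  artifact_kinds <- match.arg(artifact_kinds, several.ok = TRUE)
  assert_scalar_num(seed, "seed")
  col <- list(parenchyma_mean = c(200, 120, 150), parenchyma_sd = c(15, 20, 20),
              nucleus_mean = c(80, 60, 140), nucleus_sd = 8,
              vacuole_mean = c(245, 245, 245), vacuole_sd = 5,
              artifact_mean = c(248, 248, 248), artifact_sd = 4)
  col[names(colours)] <- colours
  structure(list(width_px = as.integer(width_px), height_px = as.integer(height_px),
                 um_per_px = um_per_px, target_fat_fraction = target_fat_fraction,
                 vacuole_diameter_um = vacuole_diameter_um,
                 artifact_density = artifact_density, artifact_kinds = artifact_kinds,
                 seed = as.integer(seed), colours = col),
            class = "field_spec")
}

#' Render a synthetic H&E-like field with ground truth
#'
#' Renders pink/eosin parenchyma with blue nuclear speckle, places fat
#' vacuoles as non-overlapping near-white discs until the target fat fraction
#' is reached (rejection sampling with bounded retries), and optionally adds
#' near-white artifacts: elongated sinusoid ribbons and large vessel lumens.
#' Artifacts never overlap vacuoles, so the fat and artifact ground-truth
#' masks are disjoint.
#'
#' The true fat fraction is the rasterised vacuole pixel count divided by the
#' parenchyma pixel count (all pixels not covered by artifacts), and is
#' recorded exactly in the returned ground truth.
#'
#' @param spec A [field_spec()].
#' @param field_id Identifier stored on the returned field.
#' @param max_retries Total placement attempts before the generator gives up
#'   and errors, naming the fat fraction it achieved.
#'
#' @return A list with components
#' \describe{
#'   \item{field}{`rgb_field`: `pixels` (height x width x 3 array of 0-255
#'     integers), `um_per_px`, `field_id`.}
#'   \item{truth}{`ground_truth`: logical `fat_mask` and `artifact_mask`
#'     (disjoint), `true_fat_fraction`, and `vacuoles` (x, y, r in pixels).}
#' }
#' @export
generate_field <- function(spec, field_id = "field", max_retries = 10000L) {
  if (!inherits(spec, "field_spec")) stop_input("`spec` must be a field_spec")
  set.seed(spec$seed)
  W <- spec$width_px; H <- spec$height_px
  npx <- W * H
  fat <- matrix(FALSE, H, W)
  art <- matrix(FALSE, H, W)

  rmin <- max(2, spec$vacuole_diameter_um[1] / 2 / spec$um_per_px)
  rmax <- spec$vacuole_diameter_um[2] / 2 / spec$um_per_px
  rmax <- min(rmax, (min(W, H) - 4) / 2)  # vacuoles must fit inside the field
  if (rmax < rmin) rmin <- rmax

  target_px <- round(spec$target_fat_fraction * npx)
  min_disc_px <- pi * rmin^2
  vac <- list(x = numeric(0), y = numeric(0), r = numeric(0))
  placed_px <- 0
  tries <- 0L
  while (placed_px < target_px - min_disc_px / 2) {
    remaining <- target_px - placed_px
    r <- if (remaining >= pi * rmax^2) runif(1, rmin, rmax) else
      clamp(sqrt(remaining / pi), rmin, rmax)
    placed <- FALSE
    # rejection sampling; when a radius cannot be placed in a congested
    # field it is shrunk, so dense targets fill in with smaller vacuoles
    while (!placed) {
      for (attempt in 1:60) {
        cx <- runif(1, r + 2, W - r - 1)
        cy <- runif(1, r + 2, H - r - 1)
        # 2 px gap so neighbouring vacuoles never touch, keeping
        # ground-truth components separable under 8-connectivity
        ok <- !length(vac$r) || all((vac$x - cx)^2 + (vac$y - cy)^2 > (vac$r + r + 2)^2)
        tries <- tries + 1L
        if (ok) { placed <- TRUE; break }
        if (tries > max_retries)
          stop_input(sprintf(
            "vacuole packing failed after %d attempts: achieved fat fraction %.4f of target %.4f",
            max_retries, placed_px / npx, spec$target_fat_fraction))
      }
      if (!placed) {
        r <- r * 0.7
        if (r < rmin)
          stop_input(sprintf(
            "vacuole packing failed (field too congested): achieved fat fraction %.4f of target %.4f",
            placed_px / npx, spec$target_fat_fraction))
      }
    }
    idx <- disc_pixels(cx, cy, r, H, W)
    fat[idx] <- TRUE
    placed_px <- placed_px + length(idx)
    vac$x <- c(vac$x, cx); vac$y <- c(vac$y, cy); vac$r <- c(vac$r, r)
  }

  if (spec$artifact_density > 0) {
    n_art <- stats::rpois(1, spec$artifact_density)
    for (k in seq_len(n_art)) {
      for (attempt in 1:50) {
        kind <- sample(spec$artifact_kinds, 1)
        if (kind == "sinusoid") {
          # whole ribbon kept inside the field so it stays elongated
          # (a border-clipped stub could look as round as a vacuole)
          len <- runif(1, 0.15, 0.5) * min(W, H)
          ang <- runif(1, 0, pi)
          hw <- runif(1, 1.5, 4)
          m <- hw + 2
          dx <- len * cos(ang); dy <- len * sin(ang)
          x1 <- if (dx >= 0) runif(1, m, W - m - dx) else runif(1, m - dx, W - m)
          y1 <- runif(1, m, H - m - dy)
          idx <- segment_pixels(x1, y1, x1 + dx, y1 + dy, halfwidth = hw, H, W)
        } else {
          # vessel lumen: round but far larger than the vacuole size window
          r <- runif(1, 55, 90) / spec$um_per_px
          idx <- disc_pixels(runif(1, 1, W), runif(1, 1, H), r, H, W)
        }
        if (length(idx) && !any(fat[idx])) { art[idx] <- TRUE; break }
      }
    }
  }

  px <- render_field_pixels(spec, fat, art)
  parenchyma_px <- npx - sum(art)
  truth <- structure(list(fat_mask = fat, artifact_mask = art,
                          true_fat_fraction = sum(fat) / parenchyma_px,
                          vacuoles = data.frame(x = vac$x, y = vac$y, r = vac$r)),
                     class = "ground_truth")
  list(field = rgb_field(px, spec$um_per_px, field_id), truth = truth)
}

# Colour rendering: base parenchyma noise, nuclear speckle, then vacuole and
# artifact pixels painted over (masks stay authoritative).
render_field_pixels <- function(spec, fat, art) {
  W <- spec$width_px; H <- spec$height_px; cl <- spec$colours
  px <- array(0, dim = c(H, W, 3))
  for (ch in 1:3)
    px[, , ch] <- stats::rnorm(H * W, cl$parenchyma_mean[ch], cl$parenchyma_sd[ch])

  # one nucleus per ~300 um^2 of tissue, radius ~2.5-4 um
  area_um2 <- W * H * spec$um_per_px^2
  n_nuc <- round(area_um2 / 300)
  if (n_nuc > 0) {
    nx <- runif(n_nuc, 1, W); ny <- runif(n_nuc, 1, H)
    nr <- runif(n_nuc, 2.5, 4) / spec$um_per_px
    for (i in seq_len(n_nuc)) {
      idx <- disc_pixels(nx[i], ny[i], nr[i], H, W)
      idx <- idx[!fat[idx] & !art[idx]]
      if (!length(idx)) next
      for (ch in 1:3)
        px[idx + (ch - 1L) * H * W] <- stats::rnorm(length(idx), cl$nucleus_mean[ch], cl$nucleus_sd)
    }
  }
  fidx <- which(fat); aidx <- which(art)
  for (ch in 1:3) {
    off <- (ch - 1L) * H * W
    if (length(fidx))
      px[fidx + off] <- stats::rnorm(length(fidx), cl$vacuole_mean[ch], cl$vacuole_sd)
    if (length(aidx))
      px[aidx + off] <- stats::rnorm(length(aidx), cl$artifact_mean[ch], cl$artifact_sd)
  }
  array(as.integer(round(clamp(px, 0, 255))), dim = dim(px))
}

#' Construct a calibrated RGB field
#'
#' @param pixels Height x width x 3 array of 8-bit values (0-255).
#' @param um_per_px Microns per pixel (> 0).
#' @param field_id Identifier.
#' @return An object of class `"rgb_field"`.
#' @export
rgb_field <- function(pixels, um_per_px, field_id = "field") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_input("`pixels` must be a height x width x 3 array")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop_input("`pixels` must be 8-bit (0-255)")
  assert_scalar_num(um_per_px, "um_per_px", lo = 0, strict_lo = TRUE)
  structure(list(pixels = pixels, um_per_px = um_per_px,
                 field_id = as.character(field_id)),
            class = "rgb_field")
}

#' @export
print.rgb_field <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_field '%s'> %d x %d px @ %.3g um/px (%.0f x %.0f um)\n",
              x$field_id, d[2], d[1], x$um_per_px,
              d[2] * x$um_per_px, d[1] * x$um_per_px))
  invisible(x)
}
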