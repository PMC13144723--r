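# Synthetic egocentric head-ROI frames: two dark elliptical eyes at
# commanded orientations on a noisy light background, with a JSON sidecar
# carrying the ground-truth geometry. The fixture for the eye-tracking
# stage.

#' Render synthetic head-ROI frames
#'
#' The head region is `roi_mm` x `roi_mm`, the body axis runs along the
#' image rows (anterior at row 1), and the two eyes sit left/right of the
#' midline. A positive eye angle rotates the eye counter-clockwise in the
#' egocentric view (anterior up), for both eyes.
#'
#' @param left_angle_rad,right_angle_rad commanded eye angles per frame
#' @param px_per_mm pixels per millimeter (20 or 50, i.e. 50 or 20 um/px)
#' @param seed integer seed for the background noise
#' @param roi_mm region size (default 0.9 mm)
#' @param eye_sep_mm midline-to-eye-center distance (default 0.24)
#' @param eye_axes_mm ellipse semi-axes (default 0.18 x 0.11 mm)
#' @param noise_sd background noise SD in intensity units (default 0.015)
#' @return list of class `head_frames`: `frames` (list of matrices in
#'   `[0,1]`, dark eyes on light background), `px_per_mm`, `sidecar`
#'   (data.frame of commanded angles and true eye centers in px)
#' @export
render_head_frames <- function(left_angle_rad, right_angle_rad, px_per_mm,
                               seed = 1L, roi_mm = 0.9, eye_sep_mm = 0.24,
                               eye_axes_mm = c(0.16, 0.09),
                               noise_sd = 0.015) {
  stopifnot(length(left_angle_rad) == length(right_angle_rad))
  if (!length(left_angle_rad)) stop("empty angle series")
  set.seed(seed)
  npx <- round(roi_mm * px_per_mm)
  ctr <- (npx + 1) / 2
  # pixel centers in mm relative to the head center; x right, y anterior
  xs <- ((seq_len(npx)) - ctr) / px_per_mm
  ys <- -((seq_len(npx)) - ctr) / px_per_mm   # row 1 = anterior (y > 0)
  ss <- 4L  # supersampling factor per axis
  off <- (seq_len(ss) - (ss + 1) / 2) / (ss * px_per_mm)
  frames <- vector("list", length(left_angle_rad))
  sidecar <- data.frame(frame = seq_along(left_angle_rad),
                        left_angle_rad = left_angle_rad,
                        right_angle_rad = right_angle_rad,
                        left_cx_px = ctr - eye_sep_mm * px_per_mm,
                        right_cx_px = ctr + eye_sep_mm * px_per_mm,
                        cy_px = ctr)
  a2 <- eye_axes_mm[1]^2; b2 <- eye_axes_mm[2]^2
  for (f in seq_along(frames)) {
    img <- matrix(0.85, npx, npx)
    for (eye in c(-1, 1)) {
      ang <- if (eye < 0) left_angle_rad[f] else right_angle_rad[f]
      ex <- eye * eye_sep_mm; ey <- 0
      # coverage of the rotated ellipse, supersampled
      cov <- matrix(0, npx, npx)
      for (ox in off) for (oy in off) {
        X <- outer(rep(1, npx), xs + ox) - ex       # rows = y, cols = x
        Y <- outer(ys + oy, rep(1, npx)) - ey
        # major axis along the body axis (y) rotated by ang (CCW)
        u <- X * cos(ang) + Y * sin(ang)            # minor direction
        v <- -X * sin(ang) + Y * cos(ang)           # major direction
        cov <- cov + (v^2 / a2 + u^2 / b2 <= 1)
      }
      img <- img - 0.7 * cov / (ss * ss)
    }
    img <- img + rnorm(npx * npx, 0, noise_sd)
    frames[[f]] <- pmin(pmax(img, 0), 1)
  }
  structure(list(frames = frames, px_per_mm = px_per_mm, sidecar = sidecar),
            class = "head_frames")
}

#' Write frames as multi-page TIFF with a JSON sidecar
#' @param hf a `head_frames`
#' @param tiff_path output TIFF path (sidecar written next to it as .json)
#' @return invisible paths
#' @export
write_head_frames <- function(hf, tiff_path) {
  tiff::writeTIFF(hf$frames, tiff_path, bits.per.sample = 16)
  side <- sub("\\.tiff?$", ".json", tiff_path)
  jsonlite::write_json(list(px_per_mm = hf$px_per_mm, sidecar = hf$sidecar),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(tiff_path, side))
}

#' Read frames written by [write_head_frames()]
#' @param tiff_path TIFF path
#' @return a `head_frames`
#' @export
read_head_frames <- function(tiff_path) {
  fr <- tiff::readTIFF(tiff_path, all = TRUE)
  side <- sub("\\.tiff?$", ".json", tiff_path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  structure(list(frames = fr, px_per_mm = meta$px_per_mm,
                 sidecar = meta$sidecar),
            class = "head_frames")
}
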