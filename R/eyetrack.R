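# Eye tracking on egocentric head-ROI frames: difference-of-Gaussians
# filtering isolates the dark eyes, axis projections and a bimodal
# mixture locate the two eye centers, and second central moments within a
# rectangular mask give each eye's orientation.

#' Difference-of-Gaussians filter
#'
#' Band-passes the intensity-inverted frame between the two Gaussian
#' scales (fine minus coarse), so dark eyes on a light background become
#' positive blobs (near-infrared fish eyes are dark; the inversion and
#' the subtraction order fix the polarity).
#' Default scales: 0.10/0.06 mm for the single-animal rig, 0.15/0.07 mm
#' for the multi-animal rig.
#'
#' @param frame 2-D numeric matrix in `[0, 1]`
#' @param px_per_mm pixels per millimeter
#' @param sigma1_mm,sigma2_mm Gaussian scales (sigma1 > sigma2)
#' @param invert invert intensities first (default TRUE)
#' @return filtered matrix, same size
#' @export
dog_filter <- function(frame, px_per_mm, sigma1_mm = 0.10,
                       sigma2_mm = 0.06, invert = TRUE) {
  if (length(dim(frame)) != 2L) stop("frame must be a 2-D matrix")
  stopifnot(sigma1_mm > sigma2_mm, sigma2_mm > 0)
  x <- if (invert) max(frame) - frame else frame
  g1 <- EBImage::gblur(x, sigma = sigma1_mm * px_per_mm)
  g2 <- EBImage::gblur(x, sigma = sigma2_mm * px_per_mm)
  g2 - g1
}

#' Locate the two eye centers
#'
#' The eye row (body-axis position) is the peak of the maximum projection
#' of the filtered intensities onto the body axis; the two eye columns are
#' the means of a two-component, equal-variance 1-D Gaussian mixture
#' fitted to the projection onto the orthogonal axis, initialized at its
#' two largest local maxima.
#'
#' @param filtered DoG-filtered frame (body axis along rows)
#' @param px_per_mm pixels per millimeter (sets the projection band width)
#' @param band_mm half-width of the row band used for the x projection
#'   (default 0.1 mm)
#' @return list: `left` and `right` centers `c(x_px, y_px)` with
#'   left x < right x, `quality` in `[0, 1]` (0 when the mixture
#'   collapses: means closer than 2 px)
#' @export
locate_eyes <- function(filtered, px_per_mm = 50, band_mm = 0.1) {
  pos <- pmax(filtered, 0)
  # blank-frame guard: no coherent band-pass response
  if (max(pos) < 6 * mad(filtered)) {
    mid <- round(nrow(filtered) / 2)
    return(list(left = c(NA_real_, mid), right = c(NA_real_, mid),
                quality = 0))
  }
  y_proj <- apply(pos, 1, max)
  y_pk <- which.max(y_proj)
  # refine: intensity centroid of the rows near the peak (robust when the
  # band-pass response is ring-like rather than a filled blob)
  rs <- rowSums(pos)
  near <- max(1, y_pk - round(0.2 * px_per_mm)):
    min(nrow(pos), y_pk + round(0.2 * px_per_mm))
  y_ctr <- round(sum(near * rs[near]) / max(sum(rs[near]), 1e-12))
  half_band <- max(2L, round(band_mm * px_per_mm))
  band <- pos[max(1, y_ctr - half_band):min(nrow(pos), y_ctr + half_band),
              , drop = FALSE]
  x_proj <- colSums(band)
  fit <- bimodal_1d(x_proj, init_smooth = 0.06 * px_per_mm)
  if (is.null(fit) || abs(diff(fit$means)) < 2)
    return(list(left = c(NA_real_, y_ctr), right = c(NA_real_, y_ctr),
                quality = 0))
  mx <- sort(fit$means)
  # refine each center as the local projection centroid (robust when the
  # band-pass response is double-humped across an eye)
  refine <- function(cx) {
    w <- max(2L, round(0.1 * px_per_mm))
    cols <- max(1, round(cx) - w):min(length(x_proj), round(cx) + w)
    if (sum(x_proj[cols]) <= 0) return(cx)
    sum(cols * x_proj[cols]) / sum(x_proj[cols])
  }
  list(left = c(refine(mx[1]), y_ctr), right = c(refine(mx[2]), y_ctr),
       quality = 1)
}

# weighted equal-variance two-component mixture on a 1-D profile
bimodal_1d <- function(w, max_iter = 200L, init_smooth = 0) {
  w <- pmax(w, 0)
  if (sum(w) <= 0) return(NULL)
  x <- seq_along(w)
  # init at the two largest local maxima of the (lightly smoothed) profile
  ws <- if (init_smooth > 0) gaussian_smooth(w, init_smooth) else w
  is_pk <- c(FALSE, ws[2:(length(ws) - 1)] > ws[1:(length(ws) - 2)] &
               ws[2:(length(ws) - 1)] >= ws[3:length(ws)], FALSE)
  pks <- which(is_pk)
  if (length(pks) < 2L) {
    q <- cumsum(w) / sum(w)
    mu <- c(x[which.min(abs(q - 0.25))], x[which.min(abs(q - 0.75))])
  } else mu <- sort(pks[order(-ws[pks])][1:2])
  pi1 <- 0.5
  s2 <- max(var(rep(x, times = pmax(round(w * 100), 0))), 1)
  for (it in seq_len(max_iter)) {
    d1 <- pi1 * dnorm(x, mu[1], sqrt(s2))
    d2 <- (1 - pi1) * dnorm(x, mu[2], sqrt(s2))
    g <- d1 / pmax(d1 + d2, 1e-300)
    w1 <- sum(w * g); w2 <- sum(w * (1 - g))
    if (w1 <= 0 || w2 <= 0) return(NULL)
    mu_new <- c(sum(w * g * x) / w1, sum(w * (1 - g) * x) / w2)
    s2 <- (sum(w * g * (x - mu_new[1])^2) +
             sum(w * (1 - g) * (x - mu_new[2])^2)) / (w1 + w2)
    s2 <- max(s2, 0.25)
    pi1 <- w1 / (w1 + w2)
    if (max(abs(mu_new - mu)) < 1e-6) { mu <- mu_new; break }
    mu <- mu_new
  }
  list(means = mu, sd = sqrt(s2), pi = c(pi1, 1 - pi1))
}

#' Eye angles from central moments
#'
#' Within a rectangular mask around each center, the orientation of the
#' intensity blob is `0.5 atan2(2 mu11, mu20 - mu02)` of its second
#' central moments, reported relative to the body axis; positive angles
#' are counter-clockwise in the egocentric (anterior-up) view for both
#' eyes, so conjugate saccades deflect both angles the same way. Moments
#' are taken on the inverted raw frame with its background pedestal
#' (median of the mask) removed; the band-passed DoG image is used only
#' for localization, since it distorts blob anisotropy.
#'
#' @param frame raw frame (dark eyes on light background)
#' @param centers output of [locate_eyes()]
#' @param px_per_mm pixels per millimeter
#' @param mask_mm mask half-width (default 0.18 mm, a 0.36 mm box that
#'   contains a rotated eye at any angle)
#' @param smooth_mm SD of the isotropic pre-smoothing in mm (default 0.02;
#'   0 disables)
#' @return list of class `eye_fit`: per eye `center`, `moments`
#'   (mu20, mu02, mu11), `angle_rad` in `(-pi/2, pi/2]`; plus `quality`
#' @export
eye_angles <- function(frame, centers, px_per_mm, mask_mm = 0.18,
                       smooth_mm = 0.02) {
  half <- max(3L, round(mask_mm * px_per_mm))
  inv <- max(frame) - frame
  # light isotropic smoothing against pixel quantization; it inflates both
  # principal variances equally and leaves the orientation unchanged
  if (smooth_mm > 0) inv <- EBImage::gblur(inv, sigma = smooth_mm * px_per_mm)
  one <- function(ctr) {
    if (anyNA(ctr)) return(list(center = ctr, moments = rep(NA_real_, 3),
                                angle_rad = NA_real_))
    cx <- round(ctr[1]); cy <- round(ctr[2])
    take <- function(cx, cy) {
      rows <- max(1L, cy - half):min(nrow(inv), cy + half)
      cols <- max(1L, cx - half):min(ncol(inv), cx + half)
      # peak-fraction floor: level sets of the blurred eye share its
      # orientation, while background noise pixels drop out; squaring
      # further downweights residual background
      m <- pmax(inv[rows, cols, drop = FALSE] -
                  0.2 * max(inv[rows, cols]), 0)^2
      list(m = m, rows = rows, cols = cols)
    }
    w <- take(cx, cy)
    if (sum(w$m) > 0) {  # recenter the mask on the blob centroid once
      cx2 <- round(sum(w$m * outer(rep(1, length(w$rows)), w$cols)) / sum(w$m))
      cy2 <- round(sum(w$m * outer(w$rows, rep(1, length(w$cols)))) / sum(w$m))
      if (cx2 != cx || cy2 != cy) w <- take(cx2, cy2)
    }
    m <- w$m; rows <- w$rows; cols <- w$cols
    tot <- sum(m)
    if (tot <= 0) stop("zero-mass mask around eye center")
    # x = column (rightward), y = anterior = -row
    xg <- outer(rep(1, length(rows)), cols)
    yg <- outer(-rows, rep(1, length(cols)))
    mx <- sum(m * xg) / tot; my <- sum(m * yg) / tot
    mu20 <- sum(m * (xg - mx)^2) / tot
    mu02 <- sum(m * (yg - my)^2) / tot
    mu11 <- sum(m * (xg - mx) * (yg - my)) / tot
    # orientation of the major axis from the x axis, then measured from
    # the body axis (y): angle = atan2 form rotated by pi/2
    if ((mu20 - mu02)^2 + 4 * mu11^2 < (0.05 * (mu20 + mu02))^2) {
      # circularly symmetric blob: orientation undefined, reported as 0
      return(list(center = ctr,
                  moments = c(mu20 = mu20, mu02 = mu02, mu11 = mu11),
                  angle_rad = 0))
    }
    th <- 0.5 * atan2(2 * mu11, mu20 - mu02)
    ang <- -(pi / 2 - th)        # 0 when the major axis lies on the body axis
    if (ang <= -pi / 2) ang <- ang + pi
    if (ang > pi / 2) ang <- ang - pi
    list(center = ctr, moments = c(mu20 = mu20, mu02 = mu02, mu11 = mu11),
         angle_rad = ang)
  }
  structure(list(left = one(centers$left), right = one(centers$right),
                 quality = centers$quality),
            class = "eye_fit")
}

#' Track eye angles across a frame stack
#'
#' Runs [dog_filter()], [locate_eyes()] and [eye_angles()] per frame.
#'
#' @param hf a `head_frames` (or list of matrices plus `px_per_mm`)
#' @param sigma1_mm,sigma2_mm DoG scales
#' @return data.frame per frame: `left_rad`, `right_rad`, `quality`
#' @export
track_eyes <- function(hf, sigma1_mm = 0.10, sigma2_mm = 0.06) {
  frames <- hf$frames; ppm <- hf$px_per_mm
  out <- data.frame(frame = seq_along(frames), left_rad = NA_real_,
                    right_rad = NA_real_, quality = 0)
  for (f in seq_along(frames)) {
    filt <- dog_filter(frames[[f]], ppm, sigma1_mm, sigma2_mm)
    ctr <- locate_eyes(filt, ppm)
    out$quality[f] <- ctr$quality
    if (ctr$quality <= 0) next
    fit <- eye_angles(hf$frames[[f]], ctr, ppm)
    out$left_rad[f] <- fit$left$angle_rad
    out$right_rad[f] <- fit$right$angle_rad
  }
  out
}
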