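#' Integrated fluorescence intensity image
#'
#' Sums all temporal frames of the stack (prebleach and FLIM alike) and
#' subtracts the fixed background originating from the camera offset and
#' ambient light (`frame_count * fixed_background_dn` per pixel). Negative
#' results are clamped to zero; the clamped map is used only for
#' segmentation, the raw frames are never modified.
#'
#' @param stack A [gated_stack()].
#' @return Numeric matrix of integrated intensities (DN).
#' @export
build_intensity_image <- function(stack) {
  stopifnot(is_gated_stack(stack))
  img <- Reduce(`+`, stack$frames)
  img <- img - length(stack$frames) * stack$fixed_background_dn
  img[img < 0] <- 0
  img
}

#' Dead-cell exclusion mask
#'
#' Dead cells appear as regions both larger and brighter than kinetochore
#' foci. Pixels above `median + k_mad * MAD` of the intensity image are
#' grouped into connected components; components with at least `min_area_px`
#' pixels are kept (foci, though bright, are far smaller) and dilated by
#' `dilate_px` to give the exclusion mask.
#'
#' @param intensity Intensity image from [build_intensity_image()].
#' @param min_area_px Minimum component area (px) to count as a dead cell;
#'   must exceed a focus footprint (default 40).
#' @param k_mad Robust intensity threshold factor (default 8).
#' @param dilate_px Mask dilation radius in px (default 2).
#' @return Logical matrix, `TRUE` where excluded. May be all-`FALSE`.
#' @export
mask_dead_cells <- function(intensity, min_area_px = 40, k_mad = 8,
                            dilate_px = 2) {
  # robust scale; the intensity map is zero-clamped, which can put half the
  # background mass at exactly 0 and collapse the MAD, so fall back on the
  # upper-quartile spread (unaffected by the clamp)
  med <- stats::median(intensity)
  s <- max(stats::mad(intensity),
           (stats::quantile(intensity, 0.75, names = FALSE) - med) * 1.4826)
  if (s == 0) {
    # degenerate (noiseless / empty) image: no robust brightness scale, and
    # "typically brighter" is undefined — exclude nothing
    return(matrix(FALSE, nrow(intensity), ncol(intensity)))
  }
  thr <- med + k_mad * s
  bw <- intensity > thr
  if (!any(bw)) return(matrix(FALSE, nrow(intensity), ncol(intensity)))
  lab <- EBImage::bwlabel(matrix(as.numeric(bw), nrow(intensity)))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_px)
  mask <- matrix(lab %in% keep, nrow(intensity))
  if (!any(mask)) return(mask)
  if (dilate_px > 0) {
    brush <- EBImage::makeBrush(2 * dilate_px + 1, shape = "disc")
    mask <- EBImage::dilate(matrix(as.numeric(mask), nrow(intensity)),
                            brush) > 0
  }
  matrix(mask, nrow(intensity))
}

# Chebyshev ring offsets at radius `h` (the 1-px-thick boundary of a
# (2h+1) x (2h+1) square); 24 offsets for h = 3.
ring_offsets <- function(h) {
  g <- expand.grid(dr = -h:h, dc = -h:h)
  g[pmax(abs(g$dr), abs(g$dc)) == h, ]
}

# Maximum over shifted copies of `img` at the given offsets; out-of-frame
# neighbors are -Inf.
shift_max <- function(img, offsets) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(-Inf, nr, nc)
  for (i in seq_len(nrow(offsets))) {
    dr <- offsets$dr[i]; dc <- offsets$dc[i]
    sh <- matrix(-Inf, nr, nc)
    rsrc <- max(1, 1 + dr):min(nr, nr + dr)
    csrc <- max(1, 1 + dc):min(nc, nc + dc)
    sh[rsrc - dr, csrc - dc] <- img[rsrc, csrc]
    out <- pmax(out, sh)
  }
  out
}

#' Detect kinetochore foci with a modified nonlinear top-hat
#'
#' A nonlinear top-hat (NTH) spot detector: the score of a pixel is its
#' intensity minus the maximum over the surrounding ring (the boundary of a
#' `(2*ring_half+1)`-square window), so only pixels brighter than everything
#' in their local background ring score positively. Pixels scoring above
#' `k_sigma` times a robust (MAD-based) noise scale, computed outside the
#' exclusion mask, are grouped into connected components and the brightest
#' pixel of each component is the focus center (ties broken toward the
#' smallest row-major index). Centers inside the exclusion mask or closer
#' than `ring_half` px to the frame edge (so the background ring of the
#' downstream 7x7 hollow square fits) are discarded. The threshold is
#' relative to the image's own robust scale, so detection is invariant to
#' multiplying the image by a positive constant.
#'
#' @param intensity Intensity image from [build_intensity_image()].
#' @param exclusion Optional logical exclusion mask from
#'   [mask_dead_cells()].
#' @param inner_half Half-width of the focus core window (default 1, a 3x3
#'   core); must be smaller than `ring_half`.
#' @param ring_half Chebyshev radius of the background ring (default 3, the
#'   boundary of a 7x7 window).
#' @param k_sigma Detection threshold in robust-noise units (default 4).
#' @return Data frame of focus centers: `row`, `col` (0-based), `score`.
#' @export
detect_foci_nth <- function(intensity, exclusion = NULL, inner_half = 1,
                            ring_half = 3, k_sigma = 4) {
  stopifnot(ring_half > inner_half, inner_half >= 1)
  nr <- nrow(intensity); nc <- ncol(intensity)
  if (is.null(exclusion)) exclusion <- matrix(FALSE, nr, nc)
  stopifnot(all(dim(exclusion) == c(nr, nc)))

  score <- intensity - shift_max(intensity, ring_offsets(ring_half))
  ok <- is.finite(score) & !exclusion
  sigma <- stats::mad(score[ok])
  if (!is.finite(sigma) || sigma <= 0) {
    # degenerate (noiseless) images: any strictly positive score is a peak
    sigma <- 0
  }
  cand <- ok & score > k_sigma * sigma
  if (!any(cand)) {
    return(data.frame(row = integer(), col = integer(), score = numeric()))
  }
  lab <- EBImage::bwlabel(matrix(as.numeric(cand), nr))
  centers <- lapply(seq_len(max(lab)), function(l) {
    idx <- which(lab == l)            # column-major linear indices
    r <- (idx - 1) %% nr              # 0-based row
    c <- (idx - 1) %/% nr             # 0-based col
    vals <- intensity[idx]
    best <- vals == max(vals)
    # tie-break: smallest row-major index r * nc + c
    rank <- r * nc + c
    j <- which(best)[which.min(rank[best])]
    data.frame(row = r[j], col = c[j], score = score[idx[j]])
  })
  out <- do.call(rbind, centers)
  edge_ok <- out$row >= ring_half & out$row <= nr - 1 - ring_half &
    out$col >= ring_half & out$col <= nc - 1 - ring_half
  excl_ok <- !exclusion[cbind(out$row + 1, out$col + 1)]
  out <- out[edge_ok & excl_ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subtract the local time-varying background around each focus
#'
#' For each detected center, the focus region is the 3x3 pixel square around
#' it and the local background is the 24-pixel 1-px-thick boundary of the
#' 7x7 square ("hollow square"). In every temporal frame, the time-varying
#' background (TVB) is the median over the surviving ring pixels and is
#' subtracted from each member pixel; the focus's frame signal is the sum of
#' the nine background-subtracted member values. Ring pixels falling in the
#' exclusion mask or inside any focus's member square are removed from the
#' ring (overlapping kinetochore pairs would otherwise contaminate each
#' other's background); foci left with fewer than 8 ring pixels are dropped
#' with a warning. Negative subtracted values are retained — clamping would
#' bias low-signal decays upward.
#'
#' Because the TVB is a per-frame median of pixels sharing the focus's local
#' neighborhood, any spatially uniform per-frame offset added to the whole
#' stack cancels exactly in `decay_dn`.
#'
#' @param stack A [gated_stack()].
#' @param centers Data frame of focus centers (`row`, `col`, 0-based), e.g.
#'   from [detect_foci_nth()]; centers must be at least 3 px from the edge.
#' @param exclusion Optional logical exclusion mask.
#' @return List of `focus_region` objects with fields `center_px`,
#'   `member_px`, `ring_px` (all 0-based), `decay_dn` (per-FLIM-frame
#'   TVB-subtracted signal), `all_frames_dn`, `per_frame_tvb_dn`, and
#'   `total_signal_dn` (summed TVB-subtracted FLIM signal, the QC
#'   statistic).
#' @export
subtract_tvb <- function(stack, centers, exclusion = NULL) {
  stopifnot(is_gated_stack(stack), is.data.frame(centers))
  tpl <- stack$template
  nr <- tpl$frame_shape[1]; nc <- tpl$frame_shape[2]
  if (is.null(exclusion)) exclusion <- matrix(FALSE, nr, nc)
  n_foci <- nrow(centers)
  if (!n_foci) return(list())
  if (any(centers$row < 3 | centers$row > nr - 4 |
            centers$col < 3 | centers$col > nc - 4)) {
    stop("all centers must be at least 3 px from the frame edge")
  }

  member_of <- matrix(FALSE, nr, nc)
  members <- vector("list", n_foci)
  for (i in seq_len(n_foci)) {
    r <- centers$row[i]; c <- centers$col[i]
    g <- expand.grid(row = (r - 1):(r + 1), col = (c - 1):(c + 1))
    members[[i]] <- as.matrix(g)
    member_of[cbind(g$row + 1, g$col + 1)] <- TRUE
  }

  roff <- ring_offsets(3)
  flim_idx <- flim_frames(tpl)
  regions <- vector("list", n_foci)
  for (i in seq_len(n_foci)) {
    r <- centers$row[i]; c <- centers$col[i]
    ring <- cbind(row = r + roff$dr, col = c + roff$dc)
    keep <- !exclusion[cbind(ring[, 1] + 1, ring[, 2] + 1)] &
      !member_of[cbind(ring[, 1] + 1, ring[, 2] + 1)]
    ring <- ring[keep, , drop = FALSE]
    if (nrow(ring) < 8) {
      warning("focus at (", r, ",", c, ") dropped: only ", nrow(ring),
              " usable background-ring pixels")
      next
    }
    mem_idx <- cbind(members[[i]][, 1] + 1, members[[i]][, 2] + 1)
    ring_idx <- cbind(ring[, 1] + 1, ring[, 2] + 1)
    nf <- tpl$n_frames
    tvb <- numeric(nf)
    sig <- numeric(nf)
    for (f in seq_len(nf)) {
      fr <- stack$frames[[f]]
      tvb[f] <- stats::median(fr[ring_idx])
      sig[f] <- sum(fr[mem_idx]) - nrow(mem_idx) * tvb[f]
    }
    regions[[i]] <- structure(
      list(center_px = c(row = r, col = c),
           member_px = members[[i]],
           ring_px = ring,
           decay_dn = sig[flim_idx],
           all_frames_dn = sig,
           per_frame_tvb_dn = tvb,
           total_signal_dn = sum(sig[flim_idx])),
      class = "focus_region"
    )
  }
  regions[!vapply(regions, is.null, logical(1))]
}

#' @export
print.focus_region <- function(x, ...) {
  cat("<focus_region> center (", x$center_px["row"], ",",
      x$center_px["col"], "), total flim signal",
      round(x$total_signal_dn), "DN,", nrow(x$ring_px), "ring px\n")
  invisible(x)
}
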