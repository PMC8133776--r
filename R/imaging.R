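#' Synthesize a ground-truth cell image
#'
#' Renders a multi-channel 2-D grayscale image emulating a confocal plane of
#' cultured cells: a `lamin` channel with nuclear rims (annuli), a `fish`
#' channel with Gaussian RNA-FISH spots placed inside or outside nuclei, a
#' `body` channel with filled perinuclear discs, and a `dapi` channel with
#' filled nuclei. Gaussian background noise is added to every channel. The
#' truth ledger records every nucleus, spot (with inside/outside label) and
#' body.
#'
#' @param n_nuclei Number of nuclei; placed without overlap by rejection
#'   sampling (sizing error after bounded attempts).
#' @param radius_range Nucleus radius range in px.
#' @param n_spots_in,n_spots_out FISH spots inside / outside nuclei.
#' @param n_bodies Perinuclear discs in the `body` channel.
#' @param body_radius Disc radius in px.
#' @param noise_sd Gaussian noise SD (intensity units; rim amplitude 100).
#' @param dim Image size in px (rows, cols).
#' @param pixel_size Pixel size in micrometres.
#' @param spot_sigma FISH spot Gaussian sigma in px.
#' @param seed Integer seed; identical seeds give identical arrays.
#' @return A `CellImage`: list with `channels` (named list of matrices),
#'   `pixel_size`, and `truth` (lists `nuclei`, `spots`, `bodies`).
#' @export
synthesize_cell_image <- function(n_nuclei = 4L, radius_range = c(16, 24),
                                  n_spots_in = 4L, n_spots_out = 6L,
                                  n_bodies = 3L, body_radius = 5,
                                  noise_sd = 2, dim = c(256L, 256L),
                                  pixel_size = 0.1, spot_sigma = 1.5,
                                  seed = 1L) {
  with_substream(seed, "synthesize_cell_image", {
    nr <- dim[1]; nc <- dim[2]
    xg <- matrix(seq_len(nr), nr, nc)
    yg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

    ## place nuclei without overlap
    nuclei <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0))
    tries <- 0L
    while (nrow(nuclei) < n_nuclei) {
      tries <- tries + 1L
      if (tries > 5000L)
        stop("sizing error: cannot place ", n_nuclei,
             " non-overlapping nuclei in a ", nr, "x", nc, " image")
      r <- stats::runif(1, radius_range[1], radius_range[2])
      x <- stats::runif(1, r + 4, nr - r - 4)
      y <- stats::runif(1, r + 4, nc - r - 4)
      if (nrow(nuclei) == 0L ||
          all(sqrt((nuclei$x - x)^2 + (nuclei$y - y)^2) >
              nuclei$r + r + 16))
        nuclei <- rbind(nuclei, data.frame(x = x, y = y, r = r))
    }

    dist_to <- function(x, y) sqrt((xg - x)^2 + (yg - y)^2)

    lamin <- matrix(0, nr, nc)
    dapi <- matrix(0, nr, nc)
    for (i in seq_len(nrow(nuclei))) {
      d <- dist_to(nuclei$x[i], nuclei$y[i])
      lamin <- lamin + 100 * exp(-((d - nuclei$r[i])^2) / (2 * 1.5^2))
      dapi[d <= nuclei$r[i]] <- 80
    }

    ## spots: inside = within some nucleus (2 px margin), outside = clear of
    ## every nucleus by 4 px
    inside_of <- function(x, y)
      which(sqrt((nuclei$x - x)^2 + (nuclei$y - y)^2) <= nuclei$r - 2)
    place_spot <- function(want_inside) {
      for (k in seq_len(5000L)) {
        if (want_inside && nrow(nuclei) > 0L) {
          i <- sample.int(nrow(nuclei), 1L)
          a <- stats::runif(1, 0, 2 * pi)
          rad <- sqrt(stats::runif(1)) * (nuclei$r[i] - 3)
          x <- nuclei$x[i] + rad * cos(a); y <- nuclei$y[i] + rad * sin(a)
          if (x > 3 && x < nr - 3 && y > 3 && y < nc - 3) return(c(x, y))
        } else {
          x <- stats::runif(1, 4, nr - 4); y <- stats::runif(1, 4, nc - 4)
          dmin <- if (nrow(nuclei)) min(sqrt((nuclei$x - x)^2 +
                                             (nuclei$y - y)^2) - nuclei$r)
                  else Inf
          if (dmin > 4) return(c(x, y))
        }
      }
      stop("sizing error: cannot place spot")
    }
    spots <- data.frame(x = numeric(0), y = numeric(0), inside = logical(0))
    for (i in seq_len(n_spots_in)) {
      p <- place_spot(TRUE)
      spots <- rbind(spots, data.frame(x = p[1], y = p[2], inside = TRUE))
    }
    for (i in seq_len(n_spots_out)) {
      p <- place_spot(FALSE)
      spots <- rbind(spots, data.frame(x = p[1], y = p[2], inside = FALSE))
    }
    # enforce spot separation so detection truth is unambiguous
    if (nrow(spots) > 1L) {
      dd <- as.matrix(stats::dist(spots[, c("x", "y")]))
      diag(dd) <- Inf
      while (any(dd < 6)) {
        i <- which(dd < 6, arr.ind = TRUE)[1, 1]
        p <- place_spot(spots$inside[i])
        spots$x[i] <- p[1]; spots$y[i] <- p[2]
        dd <- as.matrix(stats::dist(spots[, c("x", "y")]))
        diag(dd) <- Inf
      }
    }
    fish <- matrix(0, nr, nc)
    for (i in seq_len(nrow(spots))) {
      d2 <- (xg - spots$x[i])^2 + (yg - spots$y[i])^2
      fish <- fish + 100 * exp(-d2 / (2 * spot_sigma^2))
    }

    bodies <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0))
    body <- matrix(0, nr, nc)
    for (i in seq_len(n_bodies)) {
      x <- stats::runif(1, body_radius + 2, nr - body_radius - 2)
      y <- stats::runif(1, body_radius + 2, nc - body_radius - 2)
      if (nrow(bodies) && any(sqrt((bodies$x - x)^2 + (bodies$y - y)^2) <
                              2 * body_radius + 4)) next
      bodies <- rbind(bodies, data.frame(x = x, y = y, r = body_radius))
      body[dist_to(x, y) <= body_radius] <- 100
    }

    noisy <- function(m) if (noise_sd > 0)
      pmax(m + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc), 0) else m
    structure(list(channels = list(lamin = noisy(lamin),
                                   fish = noisy(fish),
                                   body = noisy(body), dapi = noisy(dapi)),
                   pixel_size = pixel_size,
                   truth = list(nuclei = nuclei, spots = spots,
                                bodies = bodies)),
              class = "CellImage")
  })
}

dog_filter <- function(img, sigma_small, sigma_large) {
  stopifnot(sigma_small < sigma_large)
  EBImage::gblur(img, sigma = sigma_small) -
    EBImage::gblur(img, sigma = sigma_large)
}

#' Segment nuclei from a lamin-rim channel
#'
#' Applies a difference-of-Gaussians band-pass to the lamin staining,
#' binarises at a fraction of the response maximum, morphologically closes
#' the rim, fills its interior, removes components below a minimum area and
#' labels the rest.
#'
#' @param lamin 2-D numeric matrix.
#' @param sigma_small,sigma_large DoG sigmas in px.
#' @param threshold Fraction of the maximum DoG response.
#' @param min_area Minimum nucleus area in px^2.
#' @return A `NucleusMask`: integer label matrix (0 = background) with the
#'   per-label areas in `attr(, "areas")`.
#' @export
segment_nuclei <- function(lamin, sigma_small = 2, sigma_large = 8,
                           threshold = 0.3, min_area = 60) {
  dog <- dog_filter(lamin, sigma_small, sigma_large)
  mx <- max(dog)
  if (mx <= 0) {
    out <- matrix(0L, nrow(lamin), ncol(lamin))
    attr(out, "areas") <- numeric(0)
    return(out)
  }
  bin <- dog > threshold * mx
  closed <- EBImage::closing(EBImage::Image(bin * 1),
                             EBImage::makeBrush(5, shape = "disc"))
  filled <- EBImage::fillHull(closed)
  # the thresholded rim extends beyond the envelope midline; erode back to
  # approximately the mid-rim contour
  filled <- EBImage::erode(filled, EBImage::makeBrush(7, shape = "disc"))
  lab <- EBImage::bwlabel(filled)
  m <- EBImage::imageData(lab)
  areas <- table(m[m > 0])
  small <- as.integer(names(areas)[areas < min_area])
  if (length(small)) m[m %in% small] <- 0
  # relabel contiguously
  old <- sort(unique(as.vector(m[m > 0])))
  if (length(old)) m[] <- match(m, c(0, old)) - 1L
  out <- matrix(as.integer(m), nrow(lamin), ncol(lamin))
  attr(out, "areas") <- as.numeric(table(out[out > 0]))
  out
}

#' Detect diffraction-limited spots
#'
#' Local maxima of a difference-of-Gaussians response above a fraction of
#' its maximum, with greedy non-maximum suppression at a minimum separation
#' and sub-pixel localisation by intensity-weighted centroid in a small
#' window. Two true spots closer than `min_separation` merge into one
#' detection by design.
#'
#' @param fish 2-D numeric matrix.
#' @param sigma_small,sigma_large DoG sigmas in px (matched to the spot
#'   size; defaults suit sigma ~1.5 px spots).
#' @param threshold Fraction of the maximum DoG response.
#' @param min_separation Minimum distance between detections in px.
#' @return data.frame with sub-pixel `x`, `y` (row, col) and `response`.
#' @export
detect_foci <- function(fish, sigma_small = 1.5, sigma_large = 3,
                        threshold = 0.3, min_separation = 5) {
  stopifnot(sigma_small > 0, sigma_large > sigma_small,
            min_separation > 0)
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      response = numeric(0))
  dog <- dog_filter(fish, sigma_small, sigma_large)
  mx <- max(dog)
  if (mx <= 0) return(empty)
  thr <- threshold * mx
  nr <- nrow(dog); nc <- ncol(dog)
  cand <- which(dog > thr)
  if (!length(cand)) return(empty)
  ij <- arrayInd(cand, dim(dog))
  inner <- ij[, 1] > 1 & ij[, 1] < nr & ij[, 2] > 1 & ij[, 2] < nc
  ij <- ij[inner, , drop = FALSE]
  if (!nrow(ij)) return(empty)
  v <- dog[ij]
  is_max <- vapply(seq_len(nrow(ij)), function(k) {
    i <- ij[k, 1]; j <- ij[k, 2]
    v[k] >= max(dog[(i - 1):(i + 1), (j - 1):(j + 1)])
  }, logical(1))
  ij <- ij[is_max, , drop = FALSE]; v <- v[is_max]
  o <- order(-v)
  ij <- ij[o, , drop = FALSE]; v <- v[o]
  keep <- logical(nrow(ij))
  for (k in seq_len(nrow(ij))) {
    if (!any(keep)) { keep[k] <- TRUE; next }
    sel <- which(keep)
    if (all((ij[sel, 1] - ij[k, 1])^2 + (ij[sel, 2] - ij[k, 2])^2 >=
            min_separation^2)) keep[k] <- TRUE
  }
  ij <- ij[keep, , drop = FALSE]; v <- v[keep]
  ## sub-pixel centroid in a 5x5 window of the DoG response
  half <- 2L
  cx <- numeric(nrow(ij)); cy <- numeric(nrow(ij))
  for (k in seq_len(nrow(ij))) {
    i0 <- max(1L, ij[k, 1] - half); i1 <- min(nr, ij[k, 1] + half)
    j0 <- max(1L, ij[k, 2] - half); j1 <- min(nc, ij[k, 2] + half)
    w <- pmax(dog[i0:i1, j0:j1, drop = FALSE], 0)
    tot <- sum(w)
    cx[k] <- sum(w * matrix(i0:i1, nrow(w), ncol(w))) / tot
    cy[k] <- sum(w * matrix(j0:j1, nrow(w), ncol(w), byrow = TRUE)) / tot
  }
  out <- data.frame(x = cx, y = cy, response = v)
  out[order(out$x, out$y), , drop = FALSE]
}

#' Count nuclear versus cytoplasmic foci
#'
#' A spot is nuclear when its rounded coordinate lies on a nonzero label of
#' the nucleus mask (the filled lamin rim, so rim pixels count as inside
#' the nuclear envelope).
#'
#' @param spots data.frame with `x`, `y` (from [detect_foci()]).
#' @param mask Label matrix from [segment_nuclei()].
#' @return A `FociResult`: list with `n_nuclei`, `n_dots_total`,
#'   `n_dots_nuclear`, and `per_nucleus` (named integer vector).
#' @export
count_nuclear_cytoplasmic <- function(spots, mask) {
  n_nuclei <- length(setdiff(unique(as.vector(mask)), 0L))
  per <- stats::setNames(integer(n_nuclei), as.character(seq_len(n_nuclei)))
  if (nrow(spots) == 0L)
    return(structure(list(n_nuclei = n_nuclei, n_dots_total = 0L,
                          n_dots_nuclear = 0L, per_nucleus = per),
                     class = "FociResult"))
  xi <- pmin(pmax(round(spots$x), 1L), nrow(mask))
  yi <- pmin(pmax(round(spots$y), 1L), ncol(mask))
  lab <- mask[cbind(xi, yi)]
  tab <- table(lab[lab > 0])
  per[names(tab)] <- as.integer(tab)
  structure(list(n_nuclei = n_nuclei, n_dots_total = nrow(spots),
                 n_dots_nuclear = sum(lab > 0),
                 per_nucleus = per), class = "FociResult")
}

#' @export
print.FociResult <- function(x, ...) {
  cat("FociResult: N_nuc =", x$n_nuclei, "| n_dots =", x$n_dots_total,
      "(", x$n_dots_nuclear, "nuclear )\n")
  invisible(x)
}

#' Particle number and size in a body channel
#'
#' Binarises at a fraction of the channel maximum, labels connected
#' components and reports those at or above a minimum area, in px^2 and
#' (via the pixel size) in square micrometres.
#'
#' @param body 2-D numeric matrix.
#' @param threshold Fraction of the channel maximum, in (0, 1).
#' @param min_area Minimum particle area in px^2.
#' @param pixel_size Pixel size in micrometres (for `area_um2`).
#' @return A `ParticleReport`: list with `n_particles`, `areas_px2`,
#'   `areas_um2`, `threshold_used`.
#' @export
particle_stats <- function(body, threshold = 0.3, min_area = 4,
                           pixel_size = 0.1) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold fraction must be in (0, 1)")
  mx <- max(body)
  if (mx <= 0)
    return(structure(list(n_particles = 0L, areas_px2 = numeric(0),
                          areas_um2 = numeric(0),
                          threshold_used = threshold * mx),
                     class = "ParticleReport"))
  bin <- body > threshold * mx
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  m <- EBImage::imageData(lab)
  areas <- as.numeric(table(m[m > 0]))
  areas <- areas[areas >= min_area]
  structure(list(n_particles = length(areas), areas_px2 = areas,
                 areas_um2 = areas * pixel_size^2,
                 threshold_used = threshold * mx),
            class = "ParticleReport")
}

#' @export
print.ParticleReport <- function(x, ...) {
  cat("ParticleReport:", x$n_particles, "particle(s); total area",
      sum(x$areas_px2), "px^2\n")
  invisible(x)
}

#' Quantify nuclear/cytoplasmic foci in one image
#'
#' Convenience wrapper: segment nuclei from the lamin channel, detect FISH
#' spots, and count nuclear versus total foci.
#'
#' @param image A `CellImage` (or list with `channels$lamin` and
#'   `channels$fish`).
#' @param ... Passed to [segment_nuclei()] and [detect_foci()] where names
#'   match.
#' @return A `FociResult` with the detected `spots` attached as an
#'   attribute.
#' @export
quantify_foci <- function(image, ...) {
  dots <- list(...)
  seg_args <- dots[names(dots) %in% names(formals(segment_nuclei))]
  det_args <- dots[names(dots) %in% names(formals(detect_foci))]
  mask <- do.call(segment_nuclei, c(list(image$channels$lamin), seg_args))
  spots <- do.call(detect_foci, c(list(image$channels$fish), det_args))
  res <- count_nuclear_cytoplasmic(spots, mask)
  attr(res, "spots") <- spots
  attr(res, "mask") <- mask
  res
}
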