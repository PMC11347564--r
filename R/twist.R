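#' Otsu luminance threshold
#'
#' Exhaustive maximization of the between-class variance over all candidate
#' grey levels of the histogram. Binarization convention: a pixel is
#' foreground when `value >= threshold`. A manual override is honoured when
#' supplied.
#'
#' @param image numeric or integer matrix (nonconstant)
#' @param manual optional manual threshold override
#' @return the selected threshold (same units as the image)
#' @export
otsu_threshold <- function(image, manual = NULL) {
  if (!is.null(manual)) return(manual)
  v <- as.vector(image)
  if (max(v) == min(v)) stop("constant image: Otsu threshold undefined")
  lev <- sort(unique(v))
  cnt <- tabulate(match(v, lev), nbins = length(lev))
  n <- length(v)
  # class 0 = {x < t}, class 1 = {x >= t}; candidate t = each level
  w0 <- cumsum(cnt)[-length(lev)] / n                 # P(x < lev[k+1])
  mu <- cumsum(cnt * lev)
  mu0 <- mu[-length(lev)] / (w0 * n)
  mu1 <- (mu[length(lev)] - mu[-length(lev)]) / ((1 - w0) * n)
  sb <- w0 * (1 - w0) * (mu0 - mu1)^2
  lev[which.max(sb) + 1L]
}

#' Binarize an image with the Otsu (or a manual) threshold
#'
#' @inheritParams otsu_threshold
#' @param threshold optional explicit threshold (default: Otsu)
#' @return logical matrix (TRUE = foreground)
#' @export
binarize <- function(image, threshold = NULL) {
  if (is.null(threshold)) threshold <- otsu_threshold(image)
  image >= threshold
}

#' Label 8-connected foreground components
#'
#' @param binary logical matrix
#' @return integer matrix of component labels (0 = background)
#' @export
label_components <- function(binary) {
  stopifnot(is.matrix(binary))
  label_components_cpp(matrix(as.integer(binary), nrow(binary), ncol(binary)))
}

# Moore neighborhood, clockwise starting West, in (row, col) offsets
.MOORE <- matrix(c(0L, -1L,  -1L, -1L,  -1L, 0L,  -1L, 1L,
                   0L, 1L,   1L, 1L,   1L, 0L,   1L, -1L),
                 ncol = 2, byrow = TRUE)

#' Trace outer boundaries with Moore-Neighbor tracing
#'
#' One closed boundary-pixel chain per 8-connected foreground component,
#' traced clockwise with the Moore-Neighbor algorithm. Termination follows
#' Jacob's stopping criterion: tracing stops when the start pixel is
#' re-entered from the same direction it was first entered (i.e. when the
#' (pixel, backtrack) state repeats), which is robust on one-pixel-wide
#' appendages where the naive "stop at start" rule exits early.
#'
#' @param binary logical matrix
#' @return list of integer matrices, each n x 2 (row, col) boundary chains in
#'   tracing order; an isolated pixel yields a chain of length 1
#' @export
trace_boundaries <- function(binary) {
  stopifnot(is.matrix(binary))
  lab <- label_components(binary)
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  nr <- nrow(binary); nc <- ncol(binary)
  fg <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && binary[r, c]
  chains <- vector("list", nlab)
  for (l in seq_len(nlab)) {
    idx <- which(lab == l)
    # start pixel: first in column-major scan = leftmost column, topmost row
    s <- idx[1]
    sr <- ((s - 1L) %% nr) + 1L
    sc <- ((s - 1L) %/% nr) + 1L
    b <- c(sr, sc - 1L)            # backtrack: start entered from the west
    p <- c(sr, sc)
    chain <- matrix(0L, 256L, 2L)
    chain[1L, ] <- p
    clen <- 1L
    # Jacob's criterion: stop when the start pixel is about to be left in a
    # previously seen (start, backtrack) state, i.e. the entry direction of a
    # revisit repeats; the initial west-entry state seeds the record
    seen_at_start <- list(b)
    repeat {
      if (p[1] == sr && p[2] == sc && clen > 1L) {
        rep_state <- any(vapply(seen_at_start, function(v)
          v[1] == b[1] && v[2] == b[2], logical(1)))
        if (rep_state) { clen <- clen - 1L; break }
        seen_at_start[[length(seen_at_start) + 1L]] <- b
      }
      # position of the backtrack within p's Moore neighborhood
      off <- b - p
      i <- which(.MOORE[, 1] == off[1] & .MOORE[, 2] == off[2])
      found <- FALSE
      for (step in 1:8) {
        j <- ((i - 1L + step) %% 8L) + 1L
        n <- p + .MOORE[j, ]
        if (fg(n[1], n[2])) {
          b_new <- p + .MOORE[((j - 2L) %% 8L) + 1L, ]
          found <- TRUE
          break
        }
      }
      if (!found) break            # isolated pixel: chain of length 1
      # primary stop: at the start pixel and about to repeat the first move
      if (p[1] == sr && p[2] == sc && clen > 1L &&
          n[1] == chain[2L, 1L] && n[2] == chain[2L, 2L]) {
        clen <- clen - 1L          # the re-appended start closes the loop
        break
      }
      p <- n; b <- b_new
      if (clen == nrow(chain))
        chain <- rbind(chain, matrix(0L, nrow(chain), 2L))
      clen <- clen + 1L
      chain[clen, ] <- p
      if (clen > 4L * (nr * nc)) stop("boundary tracing failed to terminate")
    }
    chains[[l]] <- chain[seq_len(clen), , drop = FALSE]
  }
  chains
}

#' Select petals and compute centroid polar coordinates
#'
#' Keeps the `|ell|` largest-area components when `ell` is supplied (all
#' components above `min_area` otherwise); everything else is deemed an
#' artifact and excluded. Areas and centroids are computed from the filled
#' components (all member pixels), not just boundary pixels, to reduce
#' pixelation bias; centroids are converted to polar coordinates about the
#' beam center.
#'
#' @param binary logical matrix (foreground = petal candidate)
#' @param ell topological charge (petal count |ell|), or NULL to keep all
#'   above `min_area`
#' @param center beam-axis pixel coordinates c(x = col, y = row); default the
#'   image centre
#' @param min_area minimum component area in pixels
#' @param chains optional precomputed boundary chains (from
#'   [trace_boundaries()]); traced on demand otherwise
#' @param frame_id identifier stored on the result
#' @return object of class `petal_set`: list(polygons, centroids
#'   (data.frame radius_px, angle; angle in \[0, 2*pi)), areas, flagged,
#'   center, frame_id)
#' @export
petal_filter <- function(binary, ell = NULL, center = NULL, min_area = 9,
                         chains = NULL, frame_id = NA) {
  lab <- label_components(binary)
  nlab <- max(lab)
  if (is.null(center)) center <- c((ncol(binary) + 1) / 2, (nrow(binary) + 1) / 2)
  if (nlab == 0L) {
    return(structure(list(polygons = list(),
                          centroids = data.frame(radius_px = numeric(0),
                                                 angle = numeric(0)),
                          areas = numeric(0), flagged = TRUE,
                          center = center, frame_id = frame_id),
                     class = "petal_set"))
  }
  areas <- tabulate(lab[lab > 0L], nbins = nlab)
  keep <- if (!is.null(ell)) {
    order(areas, decreasing = TRUE)[seq_len(min(abs(ell), nlab))]
  } else which(areas >= min_area)
  keep <- keep[areas[keep] >= min_area]
  if (is.null(chains)) chains <- trace_boundaries(binary)
  nr <- nrow(binary)
  cent <- t(vapply(keep, function(l) {
    idx <- which(lab == l)
    r <- ((idx - 1L) %% nr) + 1L
    c2 <- ((idx - 1L) %/% nr) + 1L
    cx <- mean(c2) - center[1]
    cy <- mean(r) - center[2]
    c(sqrt(cx^2 + cy^2), atan2(cy, cx) %% (2 * pi))
  }, numeric(2)))
  flagged <- if (!is.null(ell)) length(keep) < abs(ell) else length(keep) == 0L
  structure(list(polygons = chains[keep],
                 centroids = data.frame(radius_px = cent[, 1], angle = cent[, 2]),
                 areas = areas[keep], flagged = flagged,
                 center = center, frame_id = frame_id),
            class = "petal_set")
}

#' Petal set directly from an interferogram
#'
#' Convenience wrapper: Otsu threshold, binarize, trace, filter.
#'
#' @param image count matrix (an interferogram)
#' @param ell topological charge
#' @param center beam-axis pixel coordinates; default the image centre
#' @param threshold manual threshold override (default: Otsu)
#' @param min_area minimum petal area in pixels
#' @param frame_id identifier stored on the result
#' @return a `petal_set`
#' @export
petal_set <- function(image, ell, center = NULL, threshold = NULL,
                      min_area = 9, frame_id = NA) {
  bin <- binarize(image, threshold)
  petal_filter(bin, ell = ell, center = center, min_area = min_area,
               frame_id = frame_id)
}

#' @export
print.petal_set <- function(x, ...) {
  cat(sprintf("petal set: %d petal(s)%s, centroid angles (deg): %s\n",
              nrow(x$centroids), if (x$flagged) " [flagged]" else "",
              paste(sprintf("%.1f", sort(x$centroids$angle) * 180 / pi),
                    collapse = ", ")))
  invisible(x)
}

# wrap an angle difference into (-pi, pi]
.wrap_pi <- function(d) {
  w <- (d + pi) %% (2 * pi) - pi
  ifelse(w == -pi, pi, w)
}

# rotation from petal set a to petal set b: minimal circular-distance cyclic
# assignment of sorted centroid angles, then circular mean of per-petal
# differences; returns the rotation with attribute per_petal
.petal_rotation <- function(a, b, ell) {
  aa <- sort(a$centroids$angle)
  bb <- sort(b$centroids$angle)
  m <- min(length(aa), length(bb))
  if (m == 0L) return(NA_real_)
  aa <- aa[seq_len(m)]; bb <- bb[seq_len(m)]
  best <- NULL; best_cost <- Inf
  for (s in 0:(m - 1)) {
    d <- .wrap_pi(bb[((seq_len(m) - 1 + s) %% m) + 1] - aa)
    cost <- sum(abs(d))
    if (cost < best_cost) { best_cost <- cost; best <- d }
  }
  rot <- atan2(mean(sin(best)), mean(cos(best)))
  attr(rot, "per_petal") <- best
  rot
}

#' Relative twist series from petal sets
#'
#' Matches petals between consecutive frames by minimal circular-distance
#' assignment, wraps each per-petal angle difference across the 0/2*pi seam,
#' averages them circularly into a frame rotation, and accumulates the
#' rotations into the relative twist Theta versus frame 0. Frames that are
#' flagged or whose petal count changes are marked and their twist is
#' linearly interpolated with a gap marker.
#'
#' @param petal_sets list of `petal_set` objects (>= 2 unflagged)
#' @param times frame times in seconds (default 0.1 s spacing)
#' @param ell topological charge (used for the aliasing guard |step| <
#'   pi/|ell|)
#' @return object of class `twist_series`: data.frame(frame, t_s, theta_rad,
#'   theta_deg, petals_found, flagged) with attribute `per_petal` (list of
#'   per-step per-petal differences)
#' @export
relative_twist <- function(petal_sets, times = NULL, ell = NULL) {
  nf <- length(petal_sets)
  ok <- !vapply(petal_sets, function(p) isTRUE(p$flagged), logical(1))
  if (sum(ok) < 2L) stop("need at least 2 unflagged frames")
  if (is.null(times)) times <- (seq_len(nf) - 1) * 0.1
  counts <- vapply(petal_sets, function(p) nrow(p$centroids), integer(1))
  theta <- rep(NA_real_, nf)
  theta[1] <- 0
  flag <- !ok
  per_petal <- vector("list", nf)
  last_good <- 1L
  if (!ok[1]) {
    last_good <- which(ok)[1]
    theta[last_good] <- 0
  }
  for (i in seq_len(nf)[-1]) {
    if (!ok[i]) { flag[i] <- TRUE; next }
    j <- last_good
    if (counts[i] != counts[j]) flag[i] <- TRUE
    rot <- .petal_rotation(petal_sets[[j]], petal_sets[[i]],
                           ell %||% counts[i])
    if (is.na(rot)) { flag[i] <- TRUE; next }
    if (!is.null(ell) && abs(rot) >= pi / abs(ell))
      warning(sprintf("frame %d: twist step %.2f deg reaches the pi/|ell| aliasing bound",
                      i, rot * 180 / pi))
    theta[i] <- theta[j] + as.numeric(rot)
    per_petal[[i]] <- attr(rot, "per_petal")
    last_good <- i
  }
  # interpolate gaps (flagged frames keep flag = TRUE as the gap marker)
  if (anyNA(theta)) {
    known <- which(!is.na(theta))
    theta <- approx(known, theta[known], xout = seq_len(nf), rule = 2)$y
  }
  out <- data.frame(frame = seq_len(nf), t_s = times,
                    theta_rad = theta, theta_deg = theta * 180 / pi,
                    petals_found = counts, flagged = flag)
  attr(out, "per_petal") <- per_petal
  class(out) <- c("twist_series", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Beam center from an image or frame stack
#'
#' Intensity centroid of the (time-averaged) image, the default definition of
#' the polar-coordinate origin for petal analysis.
#'
#' @param x a count matrix or a `frame_stack`
#' @return numeric c(x = col, y = row) in fractional pixel coordinates
#' @export
find_beam_center <- function(x) {
  img <- if (inherits(x, "frame_stack")) Reduce(`+`, x$frames) / length(x$frames) else x
  img <- img - min(img)
  tot <- sum(img)
  if (tot == 0) return(c(x = (ncol(img) + 1) / 2, y = (nrow(img) + 1) / 2))
  cols <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  rows <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  c(x = sum(cols * img) / tot, y = sum(rows * img) / tot)
}

#' Measure the relative twist of an on-axis interferogram stack
#'
#' Full measurement chain: beam center (intensity centroid of the averaged
#' stack unless overridden), per-frame Otsu binarization, boundary tracing,
#' petal filtering, and frame-to-frame unwrapped rotation.
#'
#' @param stack a `frame_stack` (or list of count matrices)
#' @param ell topological charge
#' @param center "auto" or numeric c(x, y) pixel coordinates
#' @param threshold manual threshold override (default per-frame Otsu)
#' @param min_area minimum petal area, pixels
#' @return a `twist_series`
#' @export
measure_twist <- function(stack, ell, center = "auto", threshold = NULL,
                          min_area = 9) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  times <- if (inherits(stack, "frame_stack")) stack$times else NULL
  if (identical(center, "auto")) center <- find_beam_center(
    if (inherits(stack, "frame_stack")) stack else Reduce(`+`, frames) / length(frames))
  sets <- lapply(seq_along(frames), function(i)
    petal_set(frames[[i]], ell = ell, center = center, threshold = threshold,
              min_area = min_area, frame_id = i))
  relative_twist(sets, times = times, ell = ell)
}
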