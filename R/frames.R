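# Per-element material coordinate frames.
#
# Each bone element receives a right-handed orthonormal triad: e1 radial,
# e2 tangential (circumferential), e3 axial (longitudinal).  e3 follows
# the longitudinal harmonic gradient; e1 is the radial gradient made
# orthogonal to e3 by Gram-Schmidt; e2 closes the triad.  Virtual fill
# elements carry no frame - they exist only so the longitudinal field can
# flow through the ridge.

#' Build per-element material frames from the two gradient fields
#'
#' @param mesh a [tet_mesh()].
#' @param grad_long,grad_rad n_elems x 3 gradient matrices (from
#'   [element_gradients()]); rows may be `NA` outside the bone regions.
#' @param bone_regions region tags that receive frames.
#' @param reference optional n_elems x 3 matrix of reference axial
#'   directions (e.g. the proxy centerline tangent at element centroids)
#'   used only to orient the sign of e3; columns of the elastic tensor are
#'   insensitive to axis sign, but stable signs make runs comparable.
#' @param min_angle_deg gradients closer than this angle (or a vanishing
#'   longitudinal gradient) mark the element degenerate. Default 1 degree.
#' @param fallback repair degenerate elements from the nearest (centroid
#'   distance) non-degenerate bone element (default `TRUE`); if `FALSE`,
#'   degenerate elements raise an error.  When only the radial gradient is
#'   unusable (the common case: the radial field is constant deep in the
#'   cancellous core, where it is bounded entirely by its zero-valued
#'   seed surface) the element keeps its own longitudinal axis and borrows
#'   the neighbour's radial direction, re-orthogonalised; only elements
#'   whose longitudinal gradient also vanishes copy the whole frame.
#' @return List of class `frame_field`: `e1`, `e2`, `e3` (n_elems x 3,
#'   `NA` rows off-bone), logical `fallback` flag per element, and
#'   `elem_ids` of the framed elements.
#' @export
build_frames <- function(mesh, grad_long, grad_rad,
                         bone_regions = c(1L, 2L), reference = NULL,
                         min_angle_deg = 1, fallback = TRUE) {
  el <- which(mesh$region %in% bone_regions)
  gl <- grad_long[el, , drop = FALSE]
  gr <- grad_rad[el, , drop = FALSE]
  if (anyNA(gl) || anyNA(gr))
    stop("gradients undefined on some bone elements")

  nl <- sqrt(rowSums(gl^2))
  degen <- nl < 1e-12
  e3 <- gl / pmax(nl, 1e-300)
  # flip e3 toward the reference direction where provided
  if (!is.null(reference)) {
    rf <- reference[el, , drop = FALSE]
    flip <- rowSums(e3 * rf) < 0
    e3[flip, ] <- -e3[flip, ]
  }
  # Gram-Schmidt: e1 = normalize(gr - (gr.e3) e3)
  proj <- rowSums(gr * e3)
  r1 <- gr - proj * e3
  n1 <- sqrt(rowSums(r1^2))
  ngr <- sqrt(rowSums(gr^2))
  # angle between gradients below threshold -> degenerate
  sin_ang <- n1 / pmax(ngr, 1e-300)
  degen <- degen | ngr < 1e-12 | sin_ang < sin(min_angle_deg * pi / 180)
  e1 <- r1 / pmax(n1, 1e-300)
  e2 <- cbind(e3[, 2] * e1[, 3] - e3[, 3] * e1[, 2],
              e3[, 3] * e1[, 1] - e3[, 1] * e1[, 3],
              e3[, 1] * e1[, 2] - e3[, 2] * e1[, 1])

  if (any(degen)) {
    if (!fallback)
      stop("degenerate frame gradients on element(s): ",
           paste(utils::head(el[degen], 10L), collapse = ", "))
    cen <- element_centroids(mesh)[el, , drop = FALSE]
    good <- which(!degen)
    if (!length(good)) stop("all bone elements are frame-degenerate")
    long_ok <- nl >= 1e-12
    for (i in which(degen)) {
      d2 <- (cen[good, 1] - cen[i, 1])^2 + (cen[good, 2] - cen[i, 2])^2 +
            (cen[good, 3] - cen[i, 3])^2
      j <- good[which.min(d2)]
      if (long_ok[i]) {
        # keep own e3; re-orthogonalise the neighbour's radial direction
        r1i <- e1[j, ] - sum(e1[j, ] * e3[i, ]) * e3[i, ]
        n1i <- sqrt(sum(r1i^2))
        if (n1i > 1e-8) {
          e1[i, ] <- r1i / n1i
          e2[i, ] <- c(e3[i, 2] * e1[i, 3] - e3[i, 3] * e1[i, 2],
                       e3[i, 3] * e1[i, 1] - e3[i, 1] * e1[i, 3],
                       e3[i, 1] * e1[i, 2] - e3[i, 2] * e1[i, 1])
          next
        }
      }
      e1[i, ] <- e1[j, ]; e2[i, ] <- e2[j, ]; e3[i, ] <- e3[j, ]
    }
  }

  expand <- function(x) {
    out <- matrix(NA_real_, n_elems(mesh), 3L)
    out[el, ] <- x
    out
  }
  fb <- rep(NA, n_elems(mesh)); fb[el] <- degen
  structure(list(e1 = expand(e1), e2 = expand(e2), e3 = expand(e3),
                 fallback = fb, elem_ids = el),
            class = "frame_field")
}

#' @export
print.frame_field <- function(x, ...) {
  cat(sprintf("frame_field: %d framed elements (%d by fallback)\n",
              length(x$elem_ids), sum(x$fallback, na.rm = TRUE)))
  invisible(x)
}

# 3x3 frame matrix (columns e1,e2,e3) of one element.
frame_matrix <- function(frames, e) {
  cbind(frames$e1[e, ], frames$e2[e, ], frames$e3[e, ])
}

#' Zoned (simplified) comparator frames
#'
#' Emulates the simplified orthotropic scheme that splits the mandible
#' into a few zones with one fixed local coordinate system each: bone
#' elements are binned into `n_zones` equal-width intervals of their mean
#' longitudinal field value, and every element of a zone inherits the
#' per-element frame of the element nearest the zone centroid (or an
#' explicitly supplied triad).
#'
#' @param mesh a [tet_mesh()].
#' @param phi_long longitudinal harmonic node field.
#' @param frames a `frame_field` from [build_frames()] supplying the
#'   representative frames.
#' @param n_zones number of zones (default 4).
#' @param zone_axes optional list of `n_zones` 3x3 triads overriding the
#'   representative frames.
#' @return A `frame_field` with an extra `zone` integer per element.
#' @export
zoned_frames <- function(mesh, phi_long, frames, n_zones = 4L,
                         zone_axes = NULL) {
  stopifnot(inherits(frames, "frame_field"), n_zones >= 1L)
  el <- frames$elem_ids
  vals <- matrix(phi_long[mesh$tets[el, , drop = FALSE]], ncol = 4L)
  if (anyNA(vals)) stop("phi_long undefined on some framed elements")
  mphi <- rowMeans(vals)
  br <- seq(min(mphi), max(mphi), length.out = n_zones + 1L)
  zone <- pmin(pmax(findInterval(mphi, br, rightmost.closed = TRUE), 1L),
               n_zones)
  if (length(unique(zone)) < n_zones)
    stop("empty zone in the phi_long partition; use fewer zones")

  cen <- element_centroids(mesh)[el, , drop = FALSE]
  e1 <- e2 <- e3 <- matrix(NA_real_, n_elems(mesh), 3L)
  for (z in seq_len(n_zones)) {
    members <- which(zone == z)
    if (is.null(zone_axes)) {
      zc <- colMeans(cen[members, , drop = FALSE])
      d2 <- (cen[members, 1] - zc[1])^2 + (cen[members, 2] - zc[2])^2 +
            (cen[members, 3] - zc[3])^2
      rep_el <- el[members[which.min(d2)]]
      R <- frame_matrix(frames, rep_el)
    } else R <- zone_axes[[z]]
    gel <- el[members]
    e1[gel, ] <- matrix(R[, 1], length(gel), 3L, byrow = TRUE)
    e2[gel, ] <- matrix(R[, 2], length(gel), 3L, byrow = TRUE)
    e3[gel, ] <- matrix(R[, 3], length(gel), 3L, byrow = TRUE)
  }
  fb <- rep(NA, n_elems(mesh)); fb[el] <- FALSE
  zz <- rep(NA_integer_, n_elems(mesh)); zz[el] <- zone
  structure(list(e1 = e1, e2 = e2, e3 = e3, fallback = fb,
                 elem_ids = el, zone = zz),
            class = "frame_field")
}

#' Angular deviation of the axial frame direction from a reference
#'
#' Scores frame quality as `acos(|e3 . t_ref|)` in degrees (0 = aligned,
#' 90 = orthogonal; axis sign is immaterial), with summaries over the
#' requested region tags.
#'
#' @param frames a `frame_field`.
#' @param mesh a [tet_mesh()].
#' @param reference function mapping an n x 3 matrix of centroids to an
#'   n x 3 matrix of unit reference directions, or an n_elems x 3 matrix.
#' @param regions region tags to summarise over (default: all framed).
#' @return List with `deviation_deg` (per element, `NA` off-domain),
#'   `mean`, `max`, and `n`.
#' @export
frame_quality <- function(frames, mesh, reference, regions = NULL) {
  el <- frames$elem_ids
  if (!is.null(regions)) el <- el[mesh$region[el] %in% regions]
  cen <- element_centroids(mesh)[el, , drop = FALSE]
  ref <- if (is.function(reference)) reference(cen)
         else reference[el, , drop = FALSE]
  ref <- ref / sqrt(rowSums(ref^2))
  d <- abs(rowSums(frames$e3[el, , drop = FALSE] * ref))
  dev <- acos(pmin(pmax(d, 0), 1)) * 180 / pi
  out <- rep(NA_real_, n_elems(mesh))
  out[el] <- dev
  list(deviation_deg = out, mean = mean(dev), max = max(dev),
       n = length(el))
}
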