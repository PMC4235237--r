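# Peri-implant region-of-interest selection and the comparison tables:
# max / volume-weighted average of the six scalar measures (equivalent,
# tensile, compressive x stress, strain) over cortical and cancellous
# ROIs, per material model, with percent change against the isotropic
# baseline.

#' Select a region of interest as a distance band
#'
#' Elements of the restricted region whose centroid lies within `distance`
#' of the anchor: a named node set, a named face set (its nodes), or a
#' region tag (its elements' nodes).  This operationalises "bone
#' surrounding the implant" as a band of stated width.
#'
#' @param mesh a [tet_mesh()].
#' @param around anchor: node-set name, face-set name, region name (see
#'   [region_tags()]) or region tag integer.
#' @param distance band width (mm); `Inf` selects the whole restricted
#'   region.
#' @param restrict_to region name or tag the ROI is limited to.
#' @return Integer vector of element ids.
#' @export
select_roi <- function(mesh, around, distance, restrict_to) {
  if (distance <= 0) stop("distance must be positive")
  tags <- region_tags()
  as_tag <- function(x) if (is.character(x) && x %in% names(tags))
    tags[[x]] else x
  anchor_nodes <-
    if (is.character(around) && !is.null(mesh$node_sets[[around]]))
      mesh$node_sets[[around]]
    else if (is.character(around) && !is.null(mesh$face_sets[[around]]))
      unique(as.vector(mesh$face_sets[[around]]))
    else {
      tag <- as_tag(around)
      el <- which(mesh$region == tag)
      if (!length(el)) stop("unknown ROI anchor: ", around)
      unique(as.vector(mesh$tets[el, , drop = FALSE]))
    }
  rtag <- as_tag(restrict_to)
  cand <- which(mesh$region == rtag)
  if (!length(cand)) stop("no elements in region ", restrict_to)
  if (is.infinite(distance)) return(cand)
  cen <- element_centroids(mesh)[cand, , drop = FALSE]
  P <- mesh$nodes[anchor_nodes, , drop = FALSE]
  # min distance centroid -> anchor node, chunked to bound memory
  d2min <- rep(Inf, nrow(cen))
  step <- 512L
  for (s in seq(1L, nrow(P), by = step)) {
    blk <- P[s:min(s + step - 1L, nrow(P)), , drop = FALSE]
    D2 <- outer(cen[, 1], blk[, 1], "-")^2 +
          outer(cen[, 2], blk[, 2], "-")^2 +
          outer(cen[, 3], blk[, 3], "-")^2
    d2min <- pmin(d2min, apply(D2, 1L, min))
  }
  roi <- cand[d2min <= distance^2]
  if (!length(roi))
    stop("empty ROI; increase the band distance")
  roi
}

#' Summarise scalar measures over an ROI
#'
#' One row per (measure type, quantity): max and volume-weighted average.
#' The compressive "max" is the most negative third-principal value
#' (signed); its magnitude is also reported.
#'
#' @param stress,strain data frames from [scalar_measures()] (MPa /
#'   dimensionless).
#' @param mesh a [tet_mesh()].
#' @param roi element ids from [select_roi()].
#' @param model,region labels for the output rows.
#' @return Data frame with columns `model, region, type, quantity, max,
#'   avg, max_magnitude, n_elems, volume`.
#' @export
summarize_region <- function(stress, strain, mesh, roi, model, region) {
  if (!length(roi)) stop("empty ROI")
  geo <- element_geometry(mesh)
  V <- geo$volume[roi]
  wavg <- function(x) sum(x * V) / sum(V)
  one <- function(df, type) {
    q <- list(equivalent = df$equivalent[roi],
              tensile = df$first_principal[roi],
              compressive = df$third_principal[roi])
    if (anyNA(q$equivalent)) stop("measures undefined on ROI elements")
    do.call(rbind, lapply(names(q), function(nm) {
      x <- q[[nm]]
      mx <- if (nm == "compressive") min(x) else max(x)
      data.frame(model = model, region = region, type = type,
                 quantity = nm, max = mx, avg = wavg(x),
                 max_magnitude = abs(mx), n_elems = length(roi),
                 volume = sum(V), stringsAsFactors = FALSE)
    }))
  }
  rbind(one(stress, "stress"), one(strain, "strain"))
}

#' Percent-change comparison against the isotropic baseline
#'
#' @param summaries data frame of stacked [summarize_region()] outputs
#'   covering all models.
#' @param baseline model label of the isotropic reference (default
#'   `"isotropic"`).
#' @return The input with a `pct_change` column: `100 (x - x_iso) /
#'   x_iso` per (region, type, quantity) row, computed on max and avg as
#'   `pct_change_max` / `pct_change_avg`; baseline rows carry 0.
#' @export
compare_models <- function(summaries, baseline = "isotropic") {
  if (!baseline %in% summaries$model)
    stop("baseline model '", baseline, "' not found in summaries")
  key <- function(df) paste(df$region, df$type, df$quantity, sep = "|")
  base <- summaries[summaries$model == baseline, ]
  i <- match(key(summaries), key(base))
  if (anyNA(i)) stop("summaries do not share region definitions")
  summaries$pct_change_max <-
    100 * (summaries$max - base$max[i]) / base$max[i]
  summaries$pct_change_avg <-
    100 * (summaries$avg - base$avg[i]) / base$avg[i]
  summaries
}

#' Write a comparison table as CSV
#'
#' Deterministic output; run metadata is embedded as `#`-prefixed header
#' comments.
#'
#' @param comparison data frame from [compare_models()].
#' @param path output file.
#' @param metadata named character vector written as header comments.
#' @return Invisibly, `path`.
#' @export
write_comparison_csv <- function(comparison, path, metadata = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(metadata))
    writeLines(sprintf("# %s: %s", nm, metadata[[nm]]), con)
  num <- vapply(comparison, is.numeric, logical(1))
  out <- comparison
  out[num] <- lapply(out[num], function(x)
    trimws(formatC(x, format = "g", digits = 10)))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
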