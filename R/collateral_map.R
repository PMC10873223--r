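#' Build the per-phase collateral map images
#'
#' Each phase image is the voxelwise temporal maximum-intensity
#' projection over the frames whose midpoint falls inside the phase
#' window (half-open `[start, end)`: a frame exactly on a boundary joins
#' the later window), after subtraction of the per-voxel mean of the
#' pre-arrival baseline frames.  Negative post-subtraction values are
#' clipped to zero.
#'
#' @param series a [series4d()].
#' @param windows a [phase_windows()].
#' @return object of class `phase_map`: list of five 3D images plus the
#'   voxel size.
#' @export
build_phase_maps <- function(series, windows) {
  stopifnot(inherits(series, "series4d"), inherits(windows, "phase_windows"))
  t <- series$times
  nf <- length(t)
  M <- matrix(series$data, ncol = nf)
  arr_start <- windows$windows$arterial["start"]
  pre <- which(t < arr_start)
  base <- if (length(pre)) rowMeans(M[, pre, drop = FALSE]) else 0
  imgs <- lapply(windows$windows, function(w) {
    sel <- which(t >= w["start"] & t < w["end"])
    if (!length(sel))
      stop("internal error: phase window contains no frame")
    v <- M[, sel[1]]
    for (j in sel[-1]) v <- pmax(v, M[, j])
    array(pmax(v - base, 0), dim = dim(series$data)[1:3])
  })
  structure(list(images = imgs, voxel_size_mm = series$voxel_size_mm),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat("<phase_map>", paste(names(x$images), collapse = ", "), "\n")
  invisible(x)
}

# 6-connectivity connected components of a 3D logical mask, via igraph.
label_components <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(list(labels = array(0L, d), sizes = integer(0)))
  pos <- arrayInd(idx, d)
  key <- array(0L, d)
  key[idx] <- seq_along(idx)
  edges <- integer(0)
  for (ax in 1:3) {
    ok <- pos[, ax] < d[ax]
    nb <- pos[ok, , drop = FALSE]
    nb[, ax] <- nb[, ax] + 1L
    j <- key[nb]
    keep <- j > 0L
    edges <- c(edges, rbind(key[idx[ok]][keep], j[keep]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  labels <- array(0L, d)
  labels[idx] <- comp$membership
  list(labels = labels, sizes = as.integer(comp$csize))
}

# drop connected components smaller than min_voxels
filter_small_components <- function(mask, min_voxels) {
  if (min_voxels <= 1L || !any(mask)) return(mask)
  cc <- label_components(mask)
  keep <- which(cc$sizes >= min_voxels)
  array(cc$labels %in% keep, dim = dim(mask))
}

#' Delineate nested hypoperfusion masks by mirrored-hemisphere comparison
#'
#' A voxel of the ipsilateral MCA territory is hypoperfused in a phase
#' when its phase-image intensity is below `threshold_fraction` times the
#' intensity of its mirror voxel in the contralateral hemisphere.  The
#' capillary-phase mask is cleaned of connected components smaller than
#' `min_cluster_voxels`; each later phase keeps only the voxels of the
#' capillary mask that still satisfy the criterion in every intervening
#' phase (the persisting-region rule), so the masks are nested:
#' delay \eqn{\subseteq} late venous \eqn{\subseteq} early venous
#' \eqn{\subseteq} capillary.  An arterial-phase mask is computed for
#' completeness but never used in grading.
#'
#' @param maps a [build_phase_maps()] result.
#' @param atlas a `region_atlas` aligned to the maps.
#' @param threshold_fraction relative perfusion threshold (default 0.5).
#' @param min_cluster_voxels minimum connected-component size kept in
#'   the capillary mask (default 27, a 3x3x3 neighbourhood).
#' @return object of class `hypoperfusion_set`: nested logical masks,
#'   per-phase volumes in mL, and the parameters used.
#' @export
detect_hypoperfusion <- function(maps, atlas, threshold_fraction = 0.5,
                                 min_cluster_voxels = 27L) {
  stopifnot(inherits(maps, "phase_map"), inherits(atlas, "region_atlas"),
            all(dim(maps$images[[1]]) == dim(atlas$labels)),
            threshold_fraction > 0)
  territory <- atlas_mask(atlas, ipsi_region_labels())
  raw <- lapply(maps$images, function(img)
    territory & (img < threshold_fraction * mirror_volume(img, atlas)))
  arterial <- filter_small_components(raw$arterial, min_cluster_voxels)
  cap <- filter_small_components(raw$capillary, min_cluster_voxels)
  ev <- cap & raw$early_venous
  lv <- ev & raw$late_venous
  dl <- lv & raw$delay
  masks <- list(capillary = cap, early_venous = ev, late_venous = lv,
                delay = dl)
  vols <- vapply(masks, mask_volume, numeric(1),
                 voxel_size_mm = maps$voxel_size_mm)
  structure(list(masks = masks, arterial_mask = arterial,
                 volumes_ml = vols,
                 params = list(threshold_fraction = threshold_fraction,
                               min_cluster_voxels = min_cluster_voxels)),
            class = "hypoperfusion_set")
}

#' @export
print.hypoperfusion_set <- function(x, ...) {
  cat("<hypoperfusion_set> volumes (mL):\n")
  print(round(x$volumes_ml, 2))
  invisible(x)
}

#' Volume of a binary mask in millilitres
#'
#' @param mask logical (or 0/1) 3D array.
#' @param voxel_size_mm voxel edge lengths in mm.
#' @return volume in mL (`count * voxel volume / 1000`).
#' @export
mask_volume <- function(mask, voxel_size_mm) {
  v <- as.vector(mask)
  if (!is.logical(v) && !all(v %in% c(0, 1)))
    stop("mask_volume: mask must be binary")
  sum(as.logical(v)) * prod(voxel_size_mm) / 1000
}

#' Dice overlap coefficient of two binary masks
#' @param a,b logical arrays of identical dimension.
#' @return `2|A∩B| / (|A| + |B|)`; 0 when both masks are empty.
#' @export
dice <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(0)
  2 * sum(a & b) / (sa + sb)
}
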