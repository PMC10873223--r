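#' Build a symmetric MCA-territory region atlas
#'
#' Constructs a label volume dividing each hemisphere's middle cerebral
#' artery (MCA) territory into the 8 ASPECTS regions used for collateral
#' grading (insula, basal ganglia/internal capsule, M1--M6), plus an
#' arterial reference ROI in the contralateral MCA and a venous ROI at the
#' superior sagittal sinus.  The atlas is mirror-symmetric about the
#' mid-sagittal plane (the first array axis), so flipping that axis maps
#' each ipsilateral region onto its contralateral counterpart.
#'
#' Label conventions: ipsilateral regions 1--8, contralateral regions
#' 11--18, arterial ROI 21, venous ROI 22, background 0.
#'
#' @param grid_shape integer vector of 3 voxel counts (x = left-right).
#' @param voxel_size_mm numeric vector of 3 voxel edge lengths in mm.
#' @return An object of class `region_atlas`: a list with `labels`
#'   (integer 3D array), `table` (data frame of label, hemisphere, region
#'   id and name), `voxel_size_mm` and the mirror mapping.
#' @export
build_region_atlas <- function(grid_shape = c(64L, 64L, 32L),
                               voxel_size_mm = c(1.8, 1.8, 4)) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 12L),
            length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  nx <- as.integer(grid_shape[1]); ny <- as.integer(grid_shape[2])
  nz <- as.integer(grid_shape[3])
  if (nx %% 2L != 0L)
    stop("grid_shape[1] must be even so the midline falls between voxels")
  mx <- nx %/% 2L
  lab <- array(0L, dim = c(nx, ny, nz))

  frac <- function(n, a, b) {
    i0 <- max(1L, as.integer(ceiling(n * a)))
    i1 <- min(n, as.integer(floor(n * b)))
    if (i1 < i0) stop("grid too small for atlas layout")
    i0:i1
  }
  # ipsilateral (left) MCA block, split 2 x 2 x 2 into the 8 regions
  bx <- frac(mx, 0.10, 0.90); by <- frac(ny, 0.14, 0.88)
  bz <- frac(nz, 0.15, 0.85)
  xs <- split(bx, rep(1:2, c(ceiling(length(bx) / 2), floor(length(bx) / 2))))
  ys <- split(by, rep(1:2, c(ceiling(length(by) / 2), floor(length(by) / 2))))
  zs <- split(bz, rep(1:2, c(ceiling(length(bz) / 2), floor(length(bz) / 2))))
  region_names <- c("insula", "basal_ganglia_ic", "M1", "M2", "M3", "M4",
                    "M5", "M6")
  r <- 0L
  for (iz in 1:2) for (iy in 1:2) for (ix in 1:2) {
    r <- r + 1L
    lab[xs[[ix]], ys[[iy]], zs[[iz]]] <- r
  }
  # contralateral regions by mirroring (labels + 10)
  flip <- nx:1
  mirrored <- lab[flip, , ]
  lab[mirrored > 0L] <- mirrored[mirrored > 0L] + 10L

  # arterial ROI: contralateral MCA, anterior to the region block
  ax <- mx + frac(mx, 0.25, 0.55)
  ay <- frac(ny, 0.02, 0.10); az <- frac(nz, 0.40, 0.62)
  lab[ax, ay, az] <- 21L
  # venous ROI: superior sagittal sinus, posterior midline, symmetric in x
  vx_half <- frac(mx, 0.88, 1.00)
  vx <- c(vx_half, nx + 1L - rev(vx_half))
  vy <- frac(ny, 0.90, 0.98); vz <- az
  lab[vx, vy, vz] <- 22L

  tab <- data.frame(
    label = c(1:8, 11:18, 21L, 22L),
    hemisphere = c(rep("ipsi", 8), rep("contra", 8), "contra", "midline"),
    region = c(1:8, 1:8, NA, NA),
    name = c(region_names, region_names, "arterial_roi", "venous_roi"),
    stringsAsFactors = FALSE
  )
  structure(list(labels = lab, table = tab, voxel_size_mm = voxel_size_mm,
                 midline_axis = 1L),
            class = "region_atlas")
}

#' Mirror a volume across the atlas midline
#'
#' @param vol 3D array on the atlas grid.
#' @param atlas a `region_atlas`.
#' @return The volume flipped across the mid-sagittal plane.
#' @export
mirror_volume <- function(vol, atlas) {
  stopifnot(inherits(atlas, "region_atlas"),
            all(dim(vol) == dim(atlas$labels)))
  vol[dim(vol)[1]:1, , , drop = FALSE]
}

#' Logical mask of one or more atlas labels
#' @param atlas a `region_atlas`.
#' @param labels integer labels to select.
#' @return logical 3D array.
#' @export
atlas_mask <- function(atlas, labels) {
  array(atlas$labels %in% labels, dim = dim(atlas$labels))
}

ipsi_region_labels <- function() 1:8
contra_region_labels <- function() 11:18

#' @export
print.region_atlas <- function(x, ...) {
  cat("<region_atlas> ", paste(dim(x$labels), collapse = " x "),
      " voxels, voxel size ", paste(x$voxel_size_mm, collapse = " x "),
      " mm\n", sep = "")
  cat("  8 MCA regions per hemisphere + arterial/venous ROIs\n")
  invisible(x)
}
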