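## Label codes used on the voxel grid. HOTSPOT voxels are thyroid tissue
## carrying a raised activity concentration; TRACHEA is air-equivalent.
LABELS <- c(AIR = 0L, WATER = 1L, THYROID = 2L, TRACHEA = 3L, HOTSPOT = 4L)

#' Case specification for the benchmark grid
#'
#' One cell of the experimental grid: gland volume, relative background
#' activity concentration, relative hotspot activity concentration, and the
#' RNG seed driving the noise realisation. The default grid crosses
#' volumes {20, 35, 50} ml, backgrounds {5, 10, 15, 20} % and hotspot
#' contrasts {100, 150, 200, 250} %, i.e. 48 cases; `hotspot_rel = 1`
#' is the homogeneous gland.
#'
#' @param volume_ml target active thyroid volume in ml
#' @param background_rel background activity as a fraction of the thyroid
#'   baseline (e.g. 0.20)
#' @param hotspot_rel hotspot activity as a multiple of the thyroid
#'   baseline (1 = homogeneous)
#' @param seed integer seed for the case's noise realisation
#' @return object of class `case_spec`
#' @export
case_spec <- function(volume_ml, background_rel, hotspot_rel = 1, seed = 1L) {
  stopifnot(volume_ml > 0, background_rel >= 0, hotspot_rel >= 1)
  structure(list(volume_ml = volume_ml, background_rel = background_rel,
                 hotspot_rel = hotspot_rel, seed = as.integer(seed)),
            class = "case_spec")
}

#' @exportS3Method base::print
print.case_spec <- function(x, ...) {
  cat(sprintf("case: %g ml gland, %g%% background, %g%% hotspot, seed %d\n",
              x$volume_ml, 100 * x$background_rel, 100 * x$hotspot_rel, x$seed))
  invisible(x)
}

## Ellipsoid "insideness": q <= 1 inside; larger values further outside.
ellipsoid_q <- function(z, y, x, centre, semi) {
  ((z - centre[1]) / semi[1])^2 + ((y - centre[2]) / semi[2])^2 +
    ((x - centre[3]) / semi[3])^2
}

## Geometry of the digital neck: sizes in mm, coordinates relative to the
## grid centre. The gland is a butterfly of two ellipsoidal lobes joined by
## a thin isthmus, wrapped anteriorly around an air-filled tracheal tube.
phantom_geometry <- function(scale = 1) {
  list(
    trachea_radius = 8,                      # 16 mm adult trachea
    # compact water tank, water level just above the mounted phantom
    bath_radius    = 55,
    bath_halfh     = 55,
    # lobe semi-axes (z, y, x) at scale 1; right lobe marginally larger,
    # as is typical anatomically, which also breaks grid symmetry
    lobe_semi_R  = scale * c(22, 11, 10) * 1.03,
    lobe_semi_L  = scale * c(22, 11, 10) * 0.97,
    # lobe centres: lateral offset hugs the trachea, slightly anterior
    lobe_centre_R = c( 1.3, -11.7, scale * 10 + 9.3),
    lobe_centre_L = c(-0.7, -11.3, -(scale * 10 + 9.1)),
    isthmus_semi  = scale * c(9, 4.5, 14),
    isthmus_centre = c(0.9, -13.9, 0.1)
  )
}

## Continuous insideness field of the gland at a given lobe scale:
## max over the three solids of (1 - q); >= 0 inside the analytic gland.
gland_field <- function(z, y, x, scale) {
  g <- phantom_geometry(scale)
  f <- 1 - ellipsoid_q(z, y, x, g$lobe_centre_R, g$lobe_semi_R)
  f <- pmax(f, 1 - ellipsoid_q(z, y, x, g$lobe_centre_L, g$lobe_semi_L))
  pmax(f, 1 - ellipsoid_q(z, y, x, g$isthmus_centre, g$isthmus_semi))
}

#' Build a digital thyroid phantom
#'
#' Voxelizes a butterfly-shaped thyroid (two ellipsoidal lobes joined by an
#' isthmus) wrapped around a cylindrical air-filled trachea, immersed in a
#' cylindrical water bath, with air outside. The lobe scale is solved by
#' bisection so the voxelized gland volume matches `volume_ml`; residual
#' voxelization jumps are resolved by rank on the continuous insideness
#' field, so the achieved volume is exact to the nearest voxel.
#'
#' @param volume_ml target active gland volume in ml (20, 35 and 50 are the
#'   benchmark values)
#' @param voxel_mm isotropic voxel size in mm (default 4.42)
#' @param grid grid shape, length-3 integer (z, y, x), default 128^3
#' @return object of class `label_phantom` with fields `labels` (3-D
#'   integer array of codes in [LABELS]), `voxel_mm`, `true_volume_ml`
#' @export
build_phantom <- function(volume_ml, voxel_mm = 4.42, grid = c(128L, 128L, 128L)) {
  if (!is.numeric(voxel_mm) || voxel_mm <= 0) stop("voxel_mm must be positive")
  if (!is.numeric(volume_ml) || volume_ml <= 0) stop("volume_ml must be positive")
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3L, all(grid > 0))
  vox_ml <- voxel_mm^3 / 1000
  n_target <- round(volume_ml / vox_ml)
  if (n_target < 1) stop("requested volume is below one voxel")

  # voxel-centre coordinates in mm, origin at the grid centre
  cz <- (seq_len(grid[1]) - 0.5 - grid[1] / 2) * voxel_mm
  cy <- (seq_len(grid[2]) - 0.5 - grid[2] / 2) * voxel_mm
  cx <- (seq_len(grid[3]) - 0.5 - grid[3] / 2) * voxel_mm

  g0 <- phantom_geometry(1)
  # restrict gland voxelization to a generous bounding box
  max_ext <- 80
  iz <- which(abs(cz) < max_ext); iy <- which(cy > -max_ext & cy < max_ext)
  ix <- which(abs(cx) < max_ext)
  if (length(iz) < 3 || length(iy) < 3 || length(ix) < 3)
    stop("grid too small to contain the phantom")
  bb <- expand.grid(z = cz[iz], y = cy[iy], x = cx[ix])

  trachea_bb <- bb$x^2 + bb$y^2 < g0$trachea_radius^2
  count_at <- function(s) {
    sum(gland_field(bb$z, bb$y, bb$x, s) >= 0 & !trachea_bb)
  }

  lo <- 0.05; hi <- 4
  if (count_at(hi) < n_target)
    stop("requested volume unachievable on this grid")
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (count_at(mid) < n_target) lo <- mid else hi <- mid
  }
  s <- hi
  f <- gland_field(bb$z, bb$y, bb$x, s)
  f[trachea_bb] <- -Inf
  # exact-count trim: keep the n_target innermost voxels
  ord <- order(f, decreasing = TRUE)
  sel <- ord[seq_len(n_target)]
  if (f[sel[n_target]] < 0)
    stop("requested volume unachievable on this grid")

  labels <- array(LABELS[["AIR"]], grid)
  bath <- outer(cy^2, cx^2, `+`) < g0$bath_radius^2     # ny x nx
  inz <- abs(cz) < g0$bath_halfh
  water_slice <- array(rep(bath, each = grid[1]), grid)
  water_slice[!inz, , ] <- FALSE
  labels[water_slice] <- LABELS[["WATER"]]

  trach <- outer(cy^2, cx^2, `+`) < g0$trachea_radius^2
  trach_vol <- array(rep(trach, each = grid[1]), grid)
  trach_vol[!inz, , ] <- FALSE
  labels[trach_vol] <- LABELS[["TRACHEA"]]

  # map bounding-box selection back to full-grid linear indices
  bb_idx <- as.matrix(expand.grid(z = iz, y = iy, x = ix))
  lin <- bb_idx[sel, 1] + (bb_idx[sel, 2] - 1L) * grid[1] +
    (bb_idx[sel, 3] - 1L) * grid[1] * grid[2]
  labels[lin] <- LABELS[["THYROID"]]

  structure(list(labels = labels, voxel_mm = voxel_mm,
                 grid = grid, lobe_scale = s,
                 true_volume_ml = n_target * vox_ml),
            class = "label_phantom")
}

#' @exportS3Method base::print
print.label_phantom <- function(x, ...) {
  n <- table(factor(x$labels, levels = LABELS, labels = names(LABELS)))
  cat(sprintf("thyroid phantom: %.2f ml gland on a %s grid, %.2f mm voxels\n",
              x$true_volume_ml, paste(x$grid, collapse = "x"), x$voxel_mm))
  print(n)
  invisible(x)
}

## voxel counts per label
label_count <- function(phantom, label) sum(phantom$labels == LABELS[[label]])

#' Gland mask (thyroid plus hotspot voxels)
#' @param phantom a `label_phantom`
#' @return 3-D logical array
#' @export
gland_mask <- function(phantom) {
  phantom$labels == LABELS[["THYROID"]] | phantom$labels == LABELS[["HOTSPOT"]]
}

#' Place a spherical hotspot inside the right lobe
#'
#' Relabels a quasi-spherical sub-region of the gland from `THYROID` to
#' `HOTSPOT`. The region is the set of `round(fraction * n_gland)` gland
#' voxels nearest to the hotspot centre (default: the right lobe centre),
#' so the gland's total voxel count -- and hence `true_volume_ml` -- is
#' unchanged.
#'
#' @param phantom a `label_phantom` without an existing hotspot
#' @param fraction fraction of the gland volume to relabel, in (0, 1);
#'   default 0.10
#' @param centre_mm optional length-3 centre (z, y, x) in mm relative to
#'   the grid centre; defaults to the right lobe centre
#' @return the modified `label_phantom`
#' @export
place_hotspot <- function(phantom, fraction = 0.10, centre_mm = NULL) {
  stopifnot(inherits(phantom, "label_phantom"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie in (0, 1)")
  if (label_count(phantom, "HOTSPOT") > 0)
    stop("phantom already has a hotspot")
  thy <- which(phantom$labels == LABELS[["THYROID"]])
  n_hot <- max(1L, round(fraction * length(thy)))
  if (n_hot >= length(thy)) stop("hotspot cannot fit inside the gland")
  if (is.null(centre_mm)) {
    g <- phantom_geometry(phantom$lobe_scale)
    centre_mm <- g$lobe_centre_R
  }
  d <- phantom$grid
  idx0 <- thy - 1L
  z <- idx0 %% d[1]; rest <- idx0 %/% d[1]
  y <- rest %% d[2]; x <- rest %/% d[2]
  vz <- (z + 0.5 - d[1] / 2) * phantom$voxel_mm
  vy <- (y + 0.5 - d[2] / 2) * phantom$voxel_mm
  vx <- (x + 0.5 - d[3] / 2) * phantom$voxel_mm
  dist2 <- (vz - centre_mm[1])^2 + (vy - centre_mm[2])^2 + (vx - centre_mm[3])^2
  sel <- thy[order(dist2)[seq_len(n_hot)]]
  # a hotspot centred outside the gland would not be a lobe lesion
  if (min(dist2) > (3 * phantom$voxel_mm)^2)
    stop("hotspot centre falls outside the gland; cannot place")
  phantom$labels[sel] <- LABELS[["HOTSPOT"]]
  phantom
}

#' Compose the per-voxel relative activity map for a case
#'
#' Thyroid tissue gets the baseline activity concentration 1, hotspot
#' voxels `hotspot_rel`, water `background_rel`, air and trachea 0.
#'
#' @param phantom a `label_phantom`; must carry a hotspot region when
#'   `case$hotspot_rel > 1`
#' @param case a [case_spec()]
#' @return object of class `activity_map` with fields `values`, `voxel_mm`,
#'   `case`, `phantom`
#' @export
compose_activity <- function(phantom, case) {
  stopifnot(inherits(phantom, "label_phantom"), inherits(case, "case_spec"))
  if (case$hotspot_rel > 1 && label_count(phantom, "HOTSPOT") == 0)
    stop("case requests a hotspot but the phantom has none")
  v <- array(0, phantom$grid)
  v[phantom$labels == LABELS[["WATER"]]] <- case$background_rel
  v[phantom$labels == LABELS[["THYROID"]]] <- 1
  v[phantom$labels == LABELS[["HOTSPOT"]]] <- case$hotspot_rel
  structure(list(values = v, voxel_mm = phantom$voxel_mm,
                 case = case, phantom = phantom),
            class = "activity_map")
}

#' Attenuation map (1/mm) implied by the phantom labels
#'
#' Water, thyroid and hotspot voxels receive the narrow-beam attenuation
#' coefficient of water at 140 keV; air and trachea are non-attenuating.
#'
#' @param phantom a `label_phantom`
#' @param mu_water attenuation coefficient in 1/mm (default 0.0155)
#' @return 3-D numeric array
#' @export
attenuation_map <- function(phantom, mu_water = 0.0155) {
  mu <- array(0, phantom$grid)
  mu[phantom$labels %in% LABELS[c("WATER", "THYROID", "HOTSPOT")]] <- mu_water
  mu
}

#' Write a label phantom to NIfTI
#' @param phantom a `label_phantom`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_phantom_nifti <- function(phantom, path) {
  write_volume_nifti(phantom$labels, phantom$voxel_mm, path, datatype = "uint8")
}
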