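#' Distance field from a vessel surface (exterior only)
#'
#' Every voxel outside the vessel mask carries the Euclidean distance (um) to
#' the nearest vessel voxel; voxels inside the mask carry `NA` and are
#' excluded from all band accounting.  Distances are measured to the nearest
#' foreground voxel *centre*, a documented bias of at most half a voxel
#' versus the true surface.
#'
#' @param vessel_mask a nonempty `voxel_grid` mask on an isotropic grid.
#' @return a `voxel_grid` of distances with `NA` inside the vessels.
#' @export
surface_distance_field <- function(vessel_mask) {
  stopifnot_voxel_grid(vessel_mask, "vessel_mask")
  check_isotropic(vessel_mask, "surface_distance_field")
  m <- as_logical_mask(vessel_mask)
  if (!any(m)) stop("vessel_mask is empty: no surface to measure from")
  d <- array(cpp_edt(as.vector(m), dim(m), vessel_mask$spacing), dim(m))
  d[m] <- NA_real_
  voxel_grid(d, vessel_mask$spacing, vessel_mask$origin, "grayscale")
}

#' Assemble a distance-band report from volumes
#'
#' The band-table arithmetic: per half-open band `[lo, hi)` the region
#' volume, the steatotic volume inside it, and
#' `percent = 100 * steatotic / region`.  Exposed separately so printed
#' band volumes can be turned into percentages without voxel data.
#'
#' @param edges_um band edges, strictly increasing from 0.
#' @param region_volume_um3,steatotic_volume_um3 one value per band.
#' @return a data.frame of class `band_report`.
#' @export
band_report <- function(edges_um, region_volume_um3, steatotic_volume_um3) {
  nb <- length(edges_um) - 1
  if (nb < 1 || any(diff(edges_um) <= 0) || edges_um[1] != 0)
    stop("edges_um must be strictly increasing and start at 0")
  if (length(region_volume_um3) != nb || length(steatotic_volume_um3) != nb)
    stop("need one volume per band")
  if (any(steatotic_volume_um3 > region_volume_um3 + 1e-9))
    stop("steatotic volume exceeds region volume in some band")
  out <- data.frame(
    band_lo_um = edges_um[-length(edges_um)],
    band_hi_um = edges_um[-1],
    region_volume_um3 = region_volume_um3,
    steatotic_volume_um3 = steatotic_volume_um3,
    percent = ifelse(region_volume_um3 > 0,
                     100 * steatotic_volume_um3 / region_volume_um3, NA_real_))
  class(out) <- c("band_report", "data.frame")
  out
}

#' Quantify steatosis by perivascular distance band
#'
#' Partitions the exterior shell `[0, max(edges))` around the vessel surface
#' into half-open bands and reports, per band, the region volume, the
#' steatotic volume and the percent steatotic — the structure of the
#' distance-stratified steatosis table.
#'
#' @param dist a distance `voxel_grid` from [surface_distance_field()].
#' @param steatosis_mask `voxel_grid` mask on the same grid.
#' @param edges_um band edges (um), strictly increasing from 0.
#' @param exclude_mask optional `voxel_grid`: voxels (e.g. the lumens of
#'   vessels other than the reference tree, which can hold no steatosis)
#'   removed from the band region before accounting.
#' @return a `band_report` data.frame.
#' @export
band_quantify <- function(dist, steatosis_mask,
                          edges_um = c(0, 30, 60, 90, 120),
                          exclude_mask = NULL) {
  stopifnot_voxel_grid(dist, "dist")
  stopifnot_voxel_grid(steatosis_mask, "steatosis_mask")
  check_same_grid(dist, steatosis_mask, "dist and steatosis_mask")
  if (edges_um[1] != 0 || any(diff(edges_um) <= 0))
    stop("edges_um must be strictly increasing from 0")
  d <- as.vector(dist$data)
  s <- as.vector(as_logical_mask(steatosis_mask))
  vox <- voxel_volume(dist)
  sel <- !is.na(d) & d < max(edges_um)
  if (!is.null(exclude_mask)) {
    check_same_grid(dist, exclude_mask, "dist and exclude_mask")
    sel <- sel & !as.vector(as_logical_mask(exclude_mask))
  }
  band <- findInterval(d[sel], edges_um, left.open = FALSE)
  nb <- length(edges_um) - 1
  region <- tabulate(band, nb) * vox
  steat <- tabulate(band[s[sel]], nb) * vox
  band_report(edges_um, region, steat)
}

#' Dilate a shell around a vessel branch
#'
#' The set of exterior voxels within `radius_um` of the branch surface —
#' the "dilate 150 um from the surface" construction.  The branch interior
#' is excluded, so the shell is disjoint from the branch by construction.
#' A radius below one voxel spacing still yields the one-voxel-thick rind of
#' face-adjacent exterior voxels.
#'
#' @param branch_mask `voxel_grid` mask on an isotropic grid.
#' @param radius_um shell radius (> 0), default 150.
#' @return a logical `voxel_grid`.
#' @export
dilate_shell <- function(branch_mask, radius_um = 150) {
  stopifnot_voxel_grid(branch_mask, "branch_mask")
  check_isotropic(branch_mask, "dilate_shell")
  if (radius_um <= 0) stop("radius_um must be positive")
  m <- as_logical_mask(branch_mask)
  d <- array(cpp_edt(as.vector(m), dim(m), branch_mask$spacing), dim(m))
  r_eff <- max(radius_um, branch_mask$spacing[1])
  voxel_grid(d > 0 & d <= r_eff, branch_mask$spacing,
             branch_mask$origin, "labels")
}

#' Steatosis around central-vein branches, stratified by branch diameter
#'
#' Branches are binned by their arc-length-weighted mean diameter into
#' classes defined by `class_edges_um` (default <100, 100-150, >150 um);
#' per class, the shells (`dilate_shell`, default 150 um) of its branches
#' are unioned (overlaps within a class counted once), vessel interiors are
#' excluded, and voxels claimed by a larger-diameter class are not counted
#' again (inter-class overlap goes to the larger class).  Classes with no
#' branches are absent from the report.
#'
#' @param branch_masks list of `voxel_grid` masks, one per branch.
#' @param branch_diameters_um mean diameter per branch (um); `NA` raises an
#'   error.
#' @param steatosis_mask `voxel_grid` mask.
#' @param class_edges_um internal diameter class edges (um).
#' @param shell_radius_um shell radius around each branch.
#' @param exclude_mask optional additional mask (e.g. all vessel lumens)
#'   excluded from every shell.
#' @return a data.frame of class `diameter_class_report` with one row per
#'   populated class: class label, shell volume, steatotic volume, percent.
#' @export
diameter_class_report <- function(branch_masks, branch_diameters_um,
                                  steatosis_mask,
                                  class_edges_um = c(100, 150),
                                  shell_radius_um = 150,
                                  exclude_mask = NULL) {
  if (length(branch_masks) != length(branch_diameters_um))
    stop("one diameter per branch mask required")
  if (any(is.na(branch_diameters_um)))
    stop("branch without diameter data")
  stopifnot_voxel_grid(steatosis_mask, "steatosis_mask")
  edges <- c(0, class_edges_um, Inf)
  cls <- findInterval(branch_diameters_um, edges)
  labels <- c(sprintf("<%g", class_edges_um[1]),
              sprintf("%g-%g", class_edges_um[-length(class_edges_um)],
                      class_edges_um[-1]),
              sprintf(">%g", class_edges_um[length(class_edges_um)]))
  d <- dim(steatosis_mask$data)
  vox <- voxel_volume(steatosis_mask)
  all_vessel <- array(FALSE, d)
  for (bm in branch_masks) all_vessel <- all_vessel | as_logical_mask(bm)
  if (!is.null(exclude_mask)) all_vessel <- all_vessel | as_logical_mask(exclude_mask)
  s <- as_logical_mask(steatosis_mask)

  claimed <- array(FALSE, d)
  rows <- list()
  for (ci in rev(seq_along(labels))) { # larger-diameter classes claim first
    members <- which(cls == ci)
    if (length(members) == 0) next
    shell <- array(FALSE, d)
    for (b in members)
      shell <- shell | dilate_shell(branch_masks[[b]], shell_radius_um)$data
    shell <- shell & !all_vessel & !claimed
    claimed <- claimed | shell
    rows[[length(rows) + 1]] <- data.frame(
      class = labels[ci],
      n_branches = length(members),
      shell_volume_um3 = sum(shell) * vox,
      steatotic_volume_um3 = sum(shell & s) * vox)
  }
  out <- do.call(rbind, rev(rows))
  out$percent <- ifelse(out$shell_volume_um3 > 0,
                        100 * out$steatotic_volume_um3 / out$shell_volume_um3,
                        NA_real_)
  class(out) <- c("diameter_class_report", "data.frame")
  out
}
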