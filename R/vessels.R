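#' Seed points for region growing
#'
#' Seeds are physical coordinates (um), not voxel indices, so seed lists stay
#' valid across resampling.
#'
#' @param x,y,z numeric um coordinates.
#' @param type claimed vein type per seed: `"central"`, `"portal"` or
#'   `"unknown"`.
#' @return a data.frame of class `seed_points`.
#' @export
seed_points <- function(x, y, z, type = "unknown") {
  type <- match.arg(type, c("central", "portal", "unknown"), several.ok = TRUE)
  df <- data.frame(x = x, y = y, z = z,
                   type = rep_len(type, length(x)),
                   stringsAsFactors = FALSE)
  class(df) <- c("seed_points", "data.frame")
  df
}

#' Seeded region growing
#'
#' Classic flood fill: starting from each seed, grows the maximal connected
#' set of voxels whose intensity lies in `[low, high]`.  Seeds are processed
#' in list order; a voxel reachable from several seeds keeps the label of the
#' first seed that reaches it (documented tie-break), so if two seeds share a
#' component the whole component carries the first seed's label.
#'
#' @param gray a grayscale `voxel_grid`.
#' @param seeds a [seed_points()] data.frame.
#' @param low,high inclusive intensity window; every seed voxel must fall
#'   inside it (a seed outside raises an error naming the seed).
#' @param connectivity 6, 18 or 26 (default 26, the usual choice for bright
#'   tubular structures).
#' @return a label `voxel_grid`: voxel value `s` means "reached first from
#'   seed `s`"; attribute `seed_types` maps labels to claimed vein types.
#' @export
region_grow <- function(gray, seeds, low, high, connectivity = 26) {
  stopifnot_voxel_grid(gray, "gray")
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  if (nrow(seeds) == 0) stop("no seeds given")
  idx <- phys_to_index(gray, as.matrix(seeds[, c("x", "y", "z")]))
  lab <- cpp_region_grow(as.numeric(gray$data), dim(gray$data),
                         idx - 1L, low, high, as.integer(connectivity))
  out <- voxel_grid(array(lab, dim(gray$data)), gray$spacing, gray$origin,
                    "labels")
  attr(out, "seed_types") <- as.character(seeds$type)
  out
}

#' Segment hepatic sinusoids by thresholding with vessel subtraction
#'
#' Thresholds the grayscale volume to `[low, high]`, removes everything
#' claimed by the vessel mask, and drops connected components smaller than
#' `min_volume_um3` (the size filter that discards speckle and non-sinusoid
#' debris).  The result is disjoint from `vessel_mask` by construction.
#'
#' @param gray a grayscale `voxel_grid`.
#' @param low,high inclusive intensity window for lumen voxels.
#' @param vessel_mask `voxel_grid` on the same grid.
#' @param min_volume_um3 minimum component volume retained.
#' @param connectivity connectivity for the component filter.
#' @return a logical `voxel_grid`.
#' @export
segment_sinusoids <- function(gray, low, high, vessel_mask,
                              min_volume_um3 = 0, connectivity = 26) {
  stopifnot_voxel_grid(gray, "gray")
  stopifnot_voxel_grid(vessel_mask, "vessel_mask")
  check_same_grid(gray, vessel_mask, "gray and vessel_mask")
  m <- gray$data >= low & gray$data <= high
  m <- m & !as_logical_mask(vessel_mask)
  if (min_volume_um3 > 0 && any(m)) {
    lab <- cpp_label_components(as.vector(m), dim(m),
                                as.integer(connectivity))
    sizes <- tabulate(lab)
    keep <- sizes * voxel_volume(gray) >= min_volume_um3
    m <- array(lab > 0 & keep[pmax(lab, 1L)], dim(m))
  }
  voxel_grid(m, gray$spacing, gray$origin, "labels")
}

#' Classify vein branches as central or portal by companion proximity
#'
#' In Nissl volumes the portal vein is accompanied by the hepatic artery and
#' bile duct while nothing runs alongside the central vein.  A branch is
#' called *portal* iff the fraction of its skeleton points that have a
#' companion-mask voxel within `search_radius_um` exceeds
#' `companion_fraction_threshold`; otherwise *central*.  An empty companion
#' mask is valid and classifies every branch as central.
#'
#' @param vein_graph a `skeleton_graph` (see [build_graph()]); must be
#'   nonempty.
#' @param companion_mask `voxel_grid` of artery/bile-duct (and similar)
#'   structures.
#' @param search_radius_um search radius around each skeleton point.
#' @param companion_fraction_threshold fraction in \[0, 1\]; `0` means any
#'   single nearby companion voxel makes the branch portal.
#' @return a character vector (`"central"`/`"portal"`), one entry per edge of
#'   the graph; attribute `companion_fraction` carries the per-branch
#'   fractions.
#' @export
classify_vein_branches <- function(vein_graph, companion_mask,
                                   search_radius_um,
                                   companion_fraction_threshold = 0.5) {
  if (length(vein_graph$edges) == 0) stop("vein_graph has no branches")
  if (search_radius_um <= 0) stop("search_radius_um must be positive")
  stopifnot_voxel_grid(companion_mask, "companion_mask")
  cm <- as_logical_mask(companion_mask)
  if (!any(cm)) {
    out <- rep("central", length(vein_graph$edges))
    attr(out, "companion_fraction") <- rep(0, length(out))
    return(out)
  }
  dfield <- array(cpp_edt(as.vector(cm), dim(cm), companion_mask$spacing),
                  dim(cm))
  frac <- vapply(vein_graph$edges, function(e) {
    idx <- phys_to_index(companion_mask, e$points)
    mean(dfield[cbind(idx[, 1], idx[, 2], idx[, 3])] <= search_radius_um)
  }, numeric(1))
  out <- ifelse(frac > companion_fraction_threshold, "portal", "central")
  attr(out, "companion_fraction") <- frac
  out
}

#' Split a vessel mask into central and portal parts by seed membership
#'
#' Each connected component of the mask is assigned wholly to the claimed
#' type of the seed(s) it contains.  Components containing seeds of both
#' types raise a conflict error; components containing no seed raise an error
#' listing the orphans.
#'
#' @param label_grid a `voxel_grid` mask or label volume (nonzero =
#'   foreground).
#' @param seeds a [seed_points()] data.frame with types `central`/`portal`.
#' @param connectivity component connectivity.
#' @return list with logical `voxel_grid`s `central` and `portal`.
#' @export
split_by_seed <- function(label_grid, seeds, connectivity = 26) {
  stopifnot_voxel_grid(label_grid, "label_grid")
  m <- as_logical_mask(label_grid)
  lab <- array(cpp_label_components(as.vector(m), dim(m),
                                    as.integer(connectivity)), dim(m))
  idx <- phys_to_index(label_grid, as.matrix(seeds[, c("x", "y", "z")]))
  comp <- lab[cbind(idx[, 1], idx[, 2], idx[, 3])]
  if (any(comp == 0))
    stop("seed(s) ", paste(which(comp == 0), collapse = ", "),
         " fall outside the mask")
  ncomp <- max(lab)
  type_of <- rep(NA_character_, ncomp)
  for (s in seq_along(comp)) {
    ty <- as.character(seeds$type[s])
    if (!ty %in% c("central", "portal"))
      stop("seed ", s, " has no claimed vein type")
    if (!is.na(type_of[comp[s]]) && type_of[comp[s]] != ty)
      stop("component ", comp[s], " contains both central and portal seeds")
    type_of[comp[s]] <- ty
  }
  orphans <- which(is.na(type_of) & tabulate(lab, ncomp) > 0)
  if (length(orphans) > 0)
    stop("component(s) without a seed: ", paste(orphans, collapse = ", "))
  mk <- function(ty) {
    sel <- which(type_of == ty)
    voxel_grid(array(lab %in% sel, dim(lab)), label_grid$spacing,
               label_grid$origin, "labels")
  }
  list(central = mk("central"), portal = mk("portal"))
}
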