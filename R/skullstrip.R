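# CT skull stripping by thresholding + morphology: soft-tissue HU band
# selection, skull exclusion, morphological closing, largest connected
# component, and a final erosion scaled by the fractional parameter (the
# analogue of a BET-style fractional intensity threshold: larger values give
# tighter brain masks).

#' Segmentation configuration
#'
#' Houses every tunable of the hemispheric-asymmetry workflow.
#'
#' @param frac_threshold fractional tightness of the skull strip in (0, 1);
#'   the final erosion radius is `5 * frac_threshold` mm. Default 0.35.
#' @param iso_spacing working isotropic resolution, mm. Default 1.0.
#' @param hu_window intensity-normalization window, HU. Default `c(-20, 80)`.
#' @param percentile asymmetry-map threshold percentile. Default 98.
#' @param min_cluster_mm3 minimum lesion cluster size, mm^3. Default 500.
#' @param connectivity voxel connectivity for clustering: 6, 18 or 26.
#' @param side_rule keep only voxels hypodense relative to their mirror
#'   (disambiguates the lesion from its contralateral mirror site).
#' @param soft_tissue_hu HU band treated as brain soft tissue.
#' @param skull_hu_min HU above which voxels are treated as bone.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(frac_threshold = 0.35, iso_spacing = 1.0,
                                hu_window = c(-20, 80), percentile = 98,
                                min_cluster_mm3 = 500, connectivity = 26,
                                side_rule = TRUE,
                                soft_tissue_hu = c(0, 100),
                                skull_hu_min = 300) {
  if (!(frac_threshold > 0 && frac_threshold < 1))
    stop_asym("config", "frac_threshold must be in (0, 1)")
  if (!(percentile > 0 && percentile < 100))
    stop_asym("config", "percentile must be in (0, 100)")
  if (min_cluster_mm3 < 0) stop_asym("config", "min_cluster_mm3 must be >= 0")
  if (!connectivity %in% c(6, 18, 26))
    stop_asym("config", "connectivity must be 6, 18 or 26")
  if (!(hu_window[1] < hu_window[2]))
    stop_asym("config", "hu_window must satisfy lo < hi")
  structure(list(frac_threshold = frac_threshold, iso_spacing = iso_spacing,
                 hu_window = hu_window, percentile = percentile,
                 min_cluster_mm3 = min_cluster_mm3,
                 connectivity = as.integer(connectivity),
                 side_rule = isTRUE(side_rule),
                 soft_tissue_hu = soft_tissue_hu,
                 skull_hu_min = skull_hu_min),
            class = "segmentation_config")
}

morph_ball <- function(mask, r_vox, erode) {
  if (r_vox < 1) return(mask)
  array(.cpp_morph_ball(mask, dim(mask), r_vox, erode), dim(mask))
}

largest_component <- function(mask, connectivity = 26L) {
  lab <- .cpp_label_components(mask, dim(mask), as.integer(connectivity))
  if (max(lab) == 0L) return(mask & FALSE)
  counts <- tabulate(lab)
  array(lab == which.max(counts), dim(mask))
}

# Fill interior cavities: complement components that do not touch the volume
# border become part of the mask (ventricles and strongly hypodense infarcts
# fall outside the soft-tissue band but belong to the brain mask).
fill_holes <- function(mask) {
  dm <- dim(mask)
  lab <- array(.cpp_label_components(!mask, dm, 6L), dm)
  border <- unique(c(lab[c(1, dm[1]), , ], lab[, c(1, dm[2]), ],
                     lab[, , c(1, dm[3])]))
  border <- border[border > 0]
  mask | array(!(lab %in% c(0L, border)), dm)
}

#' Skull-strip a head CT
#'
#' Selects the soft-tissue HU band, excludes bone and background,
#' morphologically closes the result, keeps the largest connected component
#' and erodes it by `5 * frac_threshold` mm. Raising `frac_threshold` never
#' enlarges the mask.
#'
#' @param volume a [ct_volume()] in Hounsfield units.
#' @param config a [segmentation_config()].
#' @return Logical array (brain mask) on the volume's grid.
#' @export
skull_strip_ct <- function(volume, config = segmentation_config()) {
  stopifnot(inherits(volume, "ct_volume"))
  v <- volume$voxels
  soft <- v >= config$soft_tissue_hu[1] & v <= config$soft_tissue_hu[2]
  if (!any(soft)) stop_asym("skull_strip", "no brain tissue found")
  soft <- soft & !(v > config$skull_hu_min)
  r_close <- 3 / min(volume$spacing)          # ~3 mm closing
  m <- morph_ball(soft, r_close, erode = FALSE)
  m <- morph_ball(m, r_close, erode = TRUE)
  m <- largest_component(m, 26L)
  m <- fill_holes(m)
  r_erode <- (5 * config$frac_threshold) / min(volume$spacing)
  m <- morph_ball(m, r_erode, erode = TRUE)
  if (!any(m)) stop_asym("skull_strip", "no brain tissue found")
  m
}
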