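#' Voxel label volumes
#'
#' A `label_volume` is the container used for all voxelized phantoms: a dense
#' 3-D integer array of tissue ids on a uniform rectilinear grid, together
#' with the voxel spacing (mm), the world coordinate of the centre of voxel
#' index (0,0,0), and a name-to-id map. World coordinates are right-handed
#' with +z up and +x toward the nose (so +y points to the subject's left);
#' all voxel values are cell-centred.
#'
#' @param labels integer 3-D array of tissue ids (0 = air).
#' @param spacing isotropic voxel edge length in mm.
#' @param origin numeric(3), world coordinate (mm) of the centre of the
#'   voxel with 0-based index (0,0,0).
#' @param label_map named integer vector mapping tissue names to ids; must
#'   contain `air = 0`.
#' @param geometry optional list describing the analytic construction
#'   (sphere centre and radii, limb axes, ...), used by electrode placement.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing, origin = c(0, 0, 0),
                         label_map = default_label_map(), geometry = NULL) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L,
            is.numeric(spacing), length(spacing) == 1L, spacing > 0,
            length(origin) == 3L)
  if (!("air" %in% names(label_map)) || label_map[["air"]] != 0L)
    stop("label_map must contain 'air' with id 0")
  if (anyDuplicated(label_map))
    stop("label ids must be unique within a label_map")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 label_map = label_map, geometry = geometry),
            class = "label_volume")
}

#' Default tissue-name to id map
#'
#' Ids shared by all phantoms in a family so masks are comparable across
#' members. Air is always 0.
#' @return Named integer vector.
#' @export
default_label_map <- function() {
  c(air = 0L, skin = 1L, skull = 2L, cerebrospinal_fluid = 3L,
    brain_grey_matter = 4L, brain_white_matter = 5L, cerebellum = 6L,
    thalamus = 7L, midbrain = 8L, pons = 9L, medulla_oblongata = 10L,
    fat = 11L, muscle = 12L, bone = 13L,
    sponge = 20L, electrode_pad = 21L)
}

#' @method print label_volume
#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("label_volume: %d x %d x %d voxels @ %g mm\n", d[1], d[2], d[3],
              x$spacing))
  present <- sort(unique(as.integer(x$labels)))
  nm <- names(x$label_map)[match(present, x$label_map)]
  cat("  tissues:", paste(nm, collapse = ", "), "\n")
  invisible(x)
}

#' @method dim label_volume
#' @export
dim.label_volume <- function(x) dim(x$labels)

# cell-centre world coordinates along one axis (mm)
axis_coords <- function(vol, axis) {
  n <- dim(vol$labels)[axis]
  vol$origin[axis] + (seq_len(n) - 1L) * vol$spacing
}

# array of squared distances from a world point, same dims as the volume
dist2_from <- function(vol, centre) {
  d <- dim(vol$labels)
  dx2 <- (axis_coords(vol, 1L) - centre[1])^2
  dy2 <- (axis_coords(vol, 2L) - centre[2])^2
  dz2 <- (axis_coords(vol, 3L) - centre[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`)
}

# world coordinates (n x 3) of 1-based linear voxel indices
voxel_world <- function(vol, lin_idx) {
  d <- dim(vol$labels)
  idx <- arrayInd(lin_idx, d)
  cbind(vol$origin[1] + (idx[, 1] - 1L) * vol$spacing,
        vol$origin[2] + (idx[, 2] - 1L) * vol$spacing,
        vol$origin[3] + (idx[, 3] - 1L) * vol$spacing)
}

label_name_of <- function(vol, id) {
  nm <- names(vol$label_map)[match(id, vol$label_map)]
  ifelse(is.na(nm), sprintf("id_%d", id), nm)
}

#' Logical mask of one tissue
#'
#' @param vol a `label_volume`.
#' @param tissue tissue name present in the volume's label map.
#' @return logical 3-D array.
#' @export
tissue_mask <- function(vol, tissue) {
  if (!tissue %in% names(vol$label_map))
    stop("unknown tissue name: ", tissue)
  vol$labels == vol$label_map[[tissue]]
}

#' Write / read a label volume as NIfTI plus JSON sidecar
#'
#' The labels are stored as int16 NIfTI with the voxel spacing in the header;
#' the sidecar (`<path>.json`) records the label map, origin and any
#' construction metadata so a round trip reproduces the object.
#'
#' @param vol a `label_volume`.
#' @param path output path, extension `.nii` added if absent.
#' @return `write_label_volume` returns the path invisibly;
#'   `read_label_volume` returns a `label_volume`.
#' @export
write_label_volume <- function(vol, path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii")
  img <- RNifti::asNifti(vol$labels)
  RNifti::pixdim(img) <- rep(vol$spacing, 3)
  RNifti::writeNifti(img, path, datatype = "int16")
  sidecar <- list(spacing_mm = vol$spacing, origin_mm = vol$origin,
                  label_map = as.list(vol$label_map),
                  geometry = vol$geometry)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lm <- unlist(side$label_map)
  storage.mode(lm) <- "integer"
  geom <- side$geometry
  if (!is.null(geom)) geom <- rapply(geom, unlist, how = "replace")
  label_volume(array(as.integer(img), dim = dim(img)),
               spacing = side$spacing_mm, origin = unlist(side$origin_mm),
               label_map = lm, geometry = geom)
}

#' 6-connected component reachable from seed voxels
#'
#' @param mask logical 3-D array.
#' @param seeds 1-based linear indices of seed voxels.
#' @return logical array of the same shape marking the reached component.
#' @export
flood_fill <- function(mask, seeds) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  out <- .flood_fill6(as.vector(mask), dim(mask), as.integer(seeds))
  array(out, dim = dim(mask))
}
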