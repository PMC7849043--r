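#' @rdname Volume-class
#' @param object,x an object
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname Volume-class
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname DisplacementField-class
#' @export
setGeneric("fieldVectors", function(x) standardGeneric("fieldVectors"))

#' Sample a volume at continuous voxel coordinates
#'
#' Trilinear interpolation of the 8 surrounding grid values; coordinates
#' outside the grid are clamped to the boundary voxel (border replicate).
#' Coordinates are 1-based: grid nodes sit at integers 1..n.
#'
#' @param vol a [Volume].
#' @param points numeric 3-vector or (m x 3) matrix of voxel coordinates.
#' @return numeric vector of interpolated intensities.
#' @examples
#' v <- Volume(array(seq_len(27), c(3, 3, 3)))
#' sampleTrilinear(v, c(2, 2, 2))       # exactly the stored value
#' sampleTrilinear(v, c(1.5, 1, 1))     # midpoint of two nodes
#' @export
setGeneric("sampleTrilinear",
           function(vol, points) standardGeneric("sampleTrilinear"))

#' Warp a volume through a displacement field
#'
#' Output voxel v takes the value of the source sampled at v + u(v)
#' (pull-back convention). The output grid is the field's grid. Scalar
#' volumes are interpolated trilinearly; label volumes use nearest-neighbor
#' sampling so no new label values can appear.
#'
#' @param src a [Volume] or [LabelVolume] to resample.
#' @param field a [DisplacementField] on the output grid.
#' @return a [Volume] (or [LabelVolume]) on the field's grid.
#' @export
setGeneric("warpVolume", function(src, field) standardGeneric("warpVolume"))

#' @rdname RegistrationResult-class
#' @export
setGeneric("resultField", function(x) standardGeneric("resultField"))

#' @rdname RegistrationResult-class
#' @export
setGeneric("sweepReports", function(x) standardGeneric("sweepReports"))
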