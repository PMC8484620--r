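# Exact Euclidean distance transform in pixel units.
# fg: logical matrix, TRUE = foreground (forest). If pad_nonforest, a virtual
# ring of background pixels borders the grid (the nearest virtual background
# pixel to any interior cell always lies in the first ring, so one ring gives
# the exact distance to the infinite outside). Background pixels get 0;
# all-foreground with no padding gets +Inf.
edt_pixels <- function(fg, pad_nonforest = TRUE) {
  nr <- nrow(fg); nc <- ncol(fg)
  if (pad_nonforest) {
    m <- matrix(0, nr + 2L, nc + 2L)
    m[2:(nr + 1L), 2:(nc + 1L)] <- as.numeric(fg)
    d <- EBImage::imageData(EBImage::distmap(m, metric = "euclidean"))
    d[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
  } else {
    if (all(fg)) return(matrix(Inf, nr, nc))
    EBImage::imageData(EBImage::distmap(matrix(as.numeric(fg), nr, nc),
                                        metric = "euclidean"))
  }
}

#' Distance from each forest pixel to the nearest non-forest pixel
#'
#' Centre-to-centre Euclidean distance in metres. Nodata cells are treated as
#' non-forest. Under `boundary_policy = "outside_is_nonforest"` virtual
#' non-forest pixels border the grid; under `"outside_is_forest"` the world
#' beyond the grid is forest, and an all-forest grid yields `+Inf`.
#' Non-forest pixels have distance 0.
#'
#' @param landscape A [binary_landscape()].
#' @param params A [frag_params()] (only `boundary_policy` is used).
#' @return Numeric matrix of distances in metres.
#' @export
distance_to_nonforest <- function(landscape, params = frag_params()) {
  stopifnot(inherits(landscape, "binary_landscape"), inherits(params, "frag_params"))
  fg <- landscape$values == 1L
  fg[is.na(fg)] <- FALSE
  d <- edt_pixels(fg, pad_nonforest = params$boundary_policy == "outside_is_nonforest")
  d * landscape$pixel_size
}
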