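# Binary-mask primitives: shifts, diamond morphology, connected components,
# hole filling. Masks are logical matrices (rows = image y, cols = image x,
# i.e. cols run along the walkway axis). Pixels outside the image are
# background for every operation here.

#' Shift a binary mask
#'
#' Translates a logical matrix by whole pixels; vacated positions become
#' `FALSE` (out-of-image is background).
#'
#' @param mask logical matrix.
#' @param dr,dc integer shift in rows / columns (positive = down / right).
#' @return logical matrix of the same shape.
#' @keywords internal
shift_mask <- function(mask, dr, dc) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  sr <- max(1L, 1L + dr):min(nr, nr + dr)
  sc <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(sr) == 0L || length(sc) == 0L) return(out)
  out[sr, sc] <- mask[sr - dr, sc - dc, drop = FALSE]
  out
}

erode_cross1 <- function(mask) {
  mask & shift_mask(mask, 1L, 0L) & shift_mask(mask, -1L, 0L) &
    shift_mask(mask, 0L, 1L) & shift_mask(mask, 0L, -1L)
}

dilate_cross1 <- function(mask) {
  mask | shift_mask(mask, 1L, 0L) | shift_mask(mask, -1L, 0L) |
    shift_mask(mask, 0L, 1L) | shift_mask(mask, 0L, -1L)
}

#' Erode / dilate with a diamond (Manhattan ball) of radius `r`
#'
#' A Manhattan ball of radius r is the r-fold Minkowski sum of the unit
#' cross, so erosion/dilation iterate the 5-pixel cross r times; this is
#' exactly equivalent to using the full diamond in one pass.
#'
#' @param mask logical matrix.
#' @param r integer radius >= 0; r = 0 is the identity.
#' @return logical matrix.
#' @keywords internal
mask_erode <- function(mask, r) {
  r <- as.integer(r)
  if (r < 0L) stopf("erosion radius must be >= 0")
  for (i in seq_len(r)) {
    if (!any(mask)) break
    mask <- erode_cross1(mask)
  }
  mask
}

#' @rdname mask_erode
#' @keywords internal
mask_dilate <- function(mask, r) {
  r <- as.integer(r)
  for (i in seq_len(r)) mask <- dilate_cross1(mask)
  mask
}

#' Morphological opening with a diamond structuring element
#'
#' Erosion followed by dilation: removes any structure whose cross-section
#' is narrower than the structuring-element diameter (here, the rodent's
#' tail) while preserving the main body up to corner rounding.
#'
#' @param mask logical matrix (foreground mask, stage `FG`).
#' @param se a [make_diamond_se()] object, or an integer pixel radius.
#' @return logical matrix, stage `T`. Empty input gives empty output.
#' @export
open_remove_tail <- function(mask, se) {
  r <- if (inherits(se, "diamond_se")) se$r_d_px else as.integer(se)
  out <- mask_dilate(mask_erode(mask, r), r)
  attr(out, "stage") <- "T"
  out
}

#' Label connected components of a binary mask
#'
#' Iterative minimum-label propagation with pointer compression. Labels are
#' renumbered 1..k in order of each component's smallest column-major pixel
#' index; background is 0.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of component labels.
#' @keywords internal
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (!any(mask)) return(matrix(0L, nr, nc))
  offs <- if (connectivity == 4L) {
    list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  } else if (connectivity == 8L) {
    list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
         c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))
  } else stopf("connectivity must be 4 or 8")
  lab <- matrix(Inf, nr, nc)
  fg <- which(mask)
  lab[fg] <- fg
  repeat {
    nb <- lab
    for (o in offs) {
      sh <- matrix(Inf, nr, nc)
      sr <- max(1L, 1L + o[1]):min(nr, nr + o[1])
      sc <- max(1L, 1L + o[2]):min(nc, nc + o[2])
      sh[sr, sc] <- lab[sr - o[1], sc - o[2], drop = FALSE]
      nb <- pmin(nb, sh)
    }
    nb[!mask] <- Inf
    v <- nb[fg]              # candidate root per fg pixel (a linear index)
    v <- nb[v]; v <- nb[v]   # pointer compression accelerates convergence
    changed <- any(v != lab[fg])
    lab[fg] <- v
    if (!changed) break
  }
  out <- matrix(0L, nr, nc)
  out[fg] <- as.integer(factor(lab[fg], levels = sort(unique(lab[fg]))))
  out
}

#' Fill holes in a binary mask
#'
#' Every background region not 4-connected to the image border becomes
#' foreground; background channels that reach the border are untouched.
#'
#' @param mask logical matrix (stage `T`).
#' @return logical matrix, stage `H`.
#' @export
fill_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- !mask
  lab <- label_components(bg, 4L)
  border <- unique(c(lab[1L, ], lab[nr, ], lab[, 1L], lab[, nc]))
  border <- setdiff(border, 0L)
  out <- mask | (bg & !(lab %in% border))
  dim(out) <- dim(mask)
  attr(out, "stage") <- "H"
  out
}

#' Retain the largest connected object
#'
#' Keeps only the 8-connected component with the most pixels; this is the
#' body silhouette once the tail has been opened away. Equal-size ties keep
#' the component whose first pixel occurs earliest in row-major scan order.
#'
#' @param mask logical matrix (stage `H`) with at least one foreground pixel.
#' @return logical matrix, stage `R`.
#' @export
retain_largest_object <- function(mask) {
  if (!any(mask)) stopf("no silhouette: mask has no foreground pixels")
  lab <- label_components(mask, 8L)
  sizes <- tabulate(lab[lab > 0L])
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    # earliest first pixel in row-major order breaks the tie
    rm_idx <- (row(lab) - 1L) * ncol(lab) + col(lab)
    first <- vapply(cand, function(k) min(rm_idx[lab == k]), numeric(1))
    cand <- cand[which.min(first)]
  }
  out <- lab == cand[1L]
  attr(out, "stage") <- "R"
  out
}
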