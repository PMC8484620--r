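#' Label connected components of a binary mask
#'
#' Maximal connected components under 4- or 8-connectivity, with labels
#' assigned 1..K in deterministic row-major order of each component's first
#' pixel (scanning row 1 left to right, then row 2, ...). The 4-connected
#' base labelling comes from `EBImage::bwlabel`; 8-connectivity merges base
#' labels across diagonal adjacencies with a union-find pass.
#'
#' @param mask Logical matrix (`NA` treated as `FALSE`).
#' @param connectivity 4 or 8.
#' @return List with `labels` (integer matrix, 0 = background), `sizes`
#'   (pixel counts per label) and `n` (number of components).
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  m <- mask
  m[is.na(m)] <- FALSE
  storage.mode(m) <- "double"
  if (!any(m == 1)) {
    return(list(labels = matrix(0L, nrow(mask), ncol(mask)),
                sizes = integer(0), n = 0L))
  }
  lab <- EBImage::imageData(EBImage::bwlabel(m))
  storage.mode(lab) <- "integer"
  k <- max(lab)
  if (connectivity == 8 && k > 1L) {
    # union base labels that touch diagonally
    nr <- nrow(lab); nc <- ncol(lab)
    pairs <- NULL
    if (nr > 1L && nc > 1L) {
      a <- lab[-nr, -nc]; b <- lab[-1, -1]   # down-right diagonal
      c_ <- lab[-nr, -1]; d <- lab[-1, -nc]  # down-left diagonal
      sel1 <- a > 0L & b > 0L & a != b
      sel2 <- c_ > 0L & d > 0L & c_ != d
      pairs <- rbind(cbind(a[sel1], b[sel1]), cbind(c_[sel2], d[sel2]))
    }
    if (!is.null(pairs) && nrow(pairs) > 0L) {
      parent <- seq_len(k)
      find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
      for (i in seq_len(nrow(pairs))) {
        ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(k), find, integer(1))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  relabel_row_major(lab)
}

# Canonicalise labels to 1..K by row-major first-pixel order and tabulate sizes.
relabel_row_major <- function(lab) {
  pos <- which(lab > 0L)
  if (length(pos) == 0L)
    return(list(labels = lab, sizes = integer(0), n = 0L))
  nr <- nrow(lab)
  r <- (pos - 1L) %% nr + 1L
  c_ <- (pos - 1L) %/% nr + 1L
  rowmajor <- (r - 1L) * ncol(lab) + c_
  first <- tapply(rowmajor, lab[pos], min)
  old <- as.integer(names(first))
  newlab <- integer(max(old))
  newlab[old[order(first)]] <- seq_along(old)
  lab[pos] <- newlab[lab[pos]]
  sizes <- tabulate(lab[pos], nbins = length(old))
  list(labels = lab, sizes = sizes, n = length(old))
}
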