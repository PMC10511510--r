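## 3D connected-component labeling over foreground voxels.
## Neighborhood graphs are built on foreground voxels only and components
## come from igraph, so cost scales with lesion size, not volume size.

neighbor_offsets <- function(connectivity = 26L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("'connectivity' must be 6, 18 or 26", call. = FALSE)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1L, "18" = ord >= 1L & ord <= 2L,
                 "26" = ord >= 1L)
  off[keep, , drop = FALSE]
}

#' Label connected components of a binary 3D array
#'
#' @param arr 3D array; voxels with value > 0 are foreground.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (full).
#' @return Integer array of the same shape: 0 background, components
#'   labeled 1..n in order of first (column-major) foreground voxel.
#' @export
label_components <- function(arr, connectivity = 26L) {
  dm <- dim(arr)
  if (length(dm) != 3L) stop("'arr' must be a 3D array", call. = FALSE)
  fg <- which(arr > 0)
  out <- array(0L, dm)
  if (length(fg) == 0L) return(out)
  id <- integer(prod(dm))
  id[fg] <- seq_along(fg)
  coord <- arrayInd(fg, dm)
  off <- neighbor_offsets(connectivity)
  ## half the offsets suffice: each neighbor pair is seen from one side
  off <- off[off[, 3L] > 0L | (off[, 3L] == 0L & off[, 2L] > 0L) |
               (off[, 3L] == 0L & off[, 2L] == 0L & off[, 1L] > 0L), ,
             drop = FALSE]
  edges <- vector("list", nrow(off))
  for (r in seq_len(nrow(off))) {
    nb <- coord + matrix(off[r, ], nrow(coord), 3L, byrow = TRUE)
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= dm[1L] &
          nb[, 2L] >= 1L & nb[, 2L] <= dm[2L] &
          nb[, 3L] >= 1L & nb[, 3L] <= dm[3L]
    lin <- (nb[ok, 3L] - 1L) * dm[1L] * dm[2L] +
           (nb[ok, 2L] - 1L) * dm[1L] + nb[ok, 1L]
    tgt <- id[lin]
    src <- id[fg[ok]]
    hit <- tgt > 0L
    edges[[r]] <- cbind(src[hit], tgt[hit])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  ## relabel components by order of first appearance for determinism
  relab <- integer(max(memb))
  relab[unique(memb)] <- seq_along(unique(memb))
  out[fg] <- relab[memb]
  out
}
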