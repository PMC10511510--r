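## Independent brute-force oracles used to check the package's
## implementations. These deliberately share no code with the package
## internals: flood fill is a stack-based sweep, quantiles are computed
## from a full sort, and Dice/overlap counts come from plain arithmetic
## on logical arrays.

## stack-based flood fill labeling (no graph library)
oracle_flood_fill <- function(arr, connectivity = 26L) {
  dm <- dim(arr)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ord <- rowSums(abs(off))
  off <- switch(as.character(connectivity),
                "6" = off[ord == 1, , drop = FALSE],
                "18" = off[ord >= 1 & ord <= 2, , drop = FALSE],
                "26" = off[ord >= 1, , drop = FALSE])
  lab <- array(0L, dm)
  nxt <- 0L
  fg <- which(arr > 0)
  for (start in fg) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      co <- arrayInd(cur, dm)
      for (r in seq_len(nrow(off))) {
        nb <- co + off[r, ]
        if (any(nb < 1L) || any(nb > dm)) next
        lin <- nb[1L] + (nb[2L] - 1L) * dm[1L] + (nb[3L] - 1L) * dm[1L] * dm[2L]
        if (arr[lin] > 0 && lab[lin] == 0L) {
          lab[lin] <- nxt
          stack <- c(stack, lin)
        }
      }
    }
  }
  lab
}

oracle_dice_pct <- function(a, b, both_empty = 100) {
  a <- a > 0; b <- b > 0
  if (sum(a) + sum(b) == 0) return(both_empty)
  100 * 2 * sum(a & b) / (sum(a) + sum(b))
}

## type-7 quantile from a full sort, written out longhand
oracle_sorted_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
}

## object-wise recall/precision by pairwise overlap of oracle components
oracle_objectwise <- function(gt_arr, pred_arr, connectivity = 26L) {
  gl <- oracle_flood_fill(gt_arr, connectivity)
  pl <- oracle_flood_fill(pred_arr, connectivity)
  ng <- max(gl); np <- max(pl)
  recalled <- 0L
  if (ng > 0) for (gi in seq_len(ng))
    if (any(pl[gl == gi] > 0)) recalled <- recalled + 1L
  hits <- 0L
  if (np > 0) for (pj in seq_len(np))
    if (any(gl[pl == pj] > 0)) hits <- hits + 1L
  list(recall = if (ng > 0) 100 * recalled / ng else NA_real_,
       precision = if (np > 0) 100 * hits / np else NA_real_,
       ng = ng, np = np)
}

## count of foreground voxels touching background or the volume edge
## (6-neighborhood); bounds the rasterization error of a smooth shape
oracle_surface_voxels <- function(arr) {
  dm <- dim(arr)
  fg <- arr > 0
  surf <- array(FALSE, dm)
  shift <- function(a, d, k) {
    out <- array(FALSE, dim(a))
    idx_src <- lapply(dim(a), seq_len)
    idx_dst <- idx_src
    n <- dim(a)[d]
    if (k > 0) { idx_dst[[d]] <- (1 + k):n; idx_src[[d]] <- 1:(n - k) }
    else { idx_dst[[d]] <- 1:(n + k); idx_src[[d]] <- (1 - k):n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (d in 1:3) for (k in c(-1L, 1L))
    surf <- surf | (fg & shift(!fg, d, k))
  ## voxels on the volume boundary also count as surface
  boundary <- array(FALSE, dm)
  boundary[c(1, dm[1]), , ] <- TRUE
  boundary[, c(1, dm[2]), ] <- TRUE
  boundary[, , c(1, dm[3])] <- TRUE
  sum(surf | (fg & boundary))
}

## convenience builders
grid_image <- function(shape, spacing = c(1, 1, 1), values = 0) {
  volumetric_image(array(values, shape), spacing = spacing)
}

mask_on <- function(arr, grid, kind = "tumor") {
  label_mask(array(as.integer(arr > 0), dim(arr)), grid, kind = kind)
}

## a random connected-ish blob mask: union of a few random boxes
random_mask_array <- function(shape, n_boxes = 3, p_empty = 0) {
  if (stats::runif(1) < p_empty) return(array(0L, shape))
  arr <- array(0L, shape)
  for (b in seq_len(sample(n_boxes, 1))) {
    lo <- pmax(1L, sapply(shape, function(n) sample(n, 1)) - sample(2:5, 3, TRUE))
    hi <- pmin(shape, lo + sample(1:6, 3, TRUE))
    arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
  }
  arr
}
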