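# Vectorized 3-D binary morphology on logical arrays.
#
# Everything here works by whole-array shifts, so costs scale with the number
# of sweeps (~object diameter in voxels), not with per-voxel loops. Used by
# the region-growing segmentation and the phantom pipeline.

# shift a 3-D array by (dx, dy, dz), padding with `fill`
.shift3 <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

.OFFSETS6 <- rbind(
  c(1, 0, 0), c(-1, 0, 0),
  c(0, 1, 0), c(0, -1, 0),
  c(0, 0, 1), c(0, 0, -1)
)

.offsets26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}
.OFFSETS26 <- .offsets26()

.offsets_for <- function(connectivity) {
  if (connectivity == 6L) .OFFSETS6
  else if (connectivity == 26L) .OFFSETS26
  else stop("connectivity must be 6 or 26")
}

# one dilation step with the given neighbourhood
.dilate1 <- function(mask, connectivity = 6L) {
  off <- .offsets_for(connectivity)
  out <- mask
  for (i in seq_len(nrow(off)))
    out <- out | .shift3(mask, off[i, 1], off[i, 2], off[i, 3])
  out
}

.erode1 <- function(mask, connectivity = 6L) {
  !.dilate1(!mask, connectivity)
}

# Approximately Euclidean dilation by `r` voxels: Minkowski sums of
# face-connected (octahedral) and fully-connected (cubic) unit balls in a
# ~1.73 : 1 ratio give an octagonal ball whose corner and axis radii agree.
.dilate_ball <- function(mask, r) {
  r <- as.integer(round(r))
  if (r <= 0) return(mask)
  m <- as.integer(round(r / 2.732))
  k <- r - m
  out <- mask
  if (k > 0) for (i in seq_len(k)) out <- .dilate1(out, 6L)
  if (m > 0) for (i in seq_len(m)) out <- .dilate1(out, 26L)
  out
}

.erode_ball <- function(mask, r) {
  !.dilate_ball(!mask, r)
}

# morphological closing, radius in voxels
.close_ball <- function(mask, r = 1L) {
  if (r <= 0) return(mask)
  .erode_ball(.dilate_ball(mask, r), r)
}

# linear-index offsets of a neighbourhood in an array padded by one voxel
.lin_offsets <- function(dp, connectivity) {
  off <- .offsets_for(connectivity)
  off[, 1] + off[, 2] * dp[1] + off[, 3] * dp[1] * dp[2]
}

# pad a logical array with one layer of FALSE on every side
.pad_false <- function(a) {
  d <- dim(a)
  out <- array(FALSE, dim = d + 2L)
  out[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
  out
}

.unpad <- function(a, d) a[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]

# Geodesic propagation: grow `seed_mask` inside `allowed` until fixed
# point — the engine behind seeded region growing. Frontier-based BFS on
# linear indices of a padded copy, so each voxel is touched once.
.propagate <- function(seed_mask, allowed, connectivity = 6L) {
  d <- dim(seed_mask)
  allowed_p <- .pad_false(allowed)
  visited <- .pad_false(seed_mask & allowed)
  offs <- .lin_offsets(d + 2L, connectivity)
  frontier <- which(visited)
  while (length(frontier)) {
    cand <- unique(as.vector(outer(frontier, offs, "+")))
    cand <- cand[allowed_p[cand] & !visited[cand]]
    visited[cand] <- TRUE
    frontier <- cand
  }
  .unpad(visited, d)
}

# Connected-component labelling by successive BFS floods.
# Returns an integer array: 0 outside the mask, component ids >= 1 inside.
.label_components <- function(mask, connectivity = 6L) {
  d <- dim(mask)
  maskp <- .pad_false(mask)
  lab <- array(0L, dim = d + 2L)
  offs <- .lin_offsets(d + 2L, connectivity)
  todo <- which(maskp)
  next_id <- 0L
  while (length(todo)) {
    seedi <- todo[1]
    if (lab[seedi] == 0L) {
      next_id <- next_id + 1L
      frontier <- seedi
      lab[seedi] <- next_id
      while (length(frontier)) {
        cand <- unique(as.vector(outer(frontier, offs, "+")))
        cand <- cand[maskp[cand] & lab[cand] == 0L]
        lab[cand] <- next_id
        frontier <- cand
      }
    }
    todo <- todo[lab[todo] == 0L]
  }
  .unpad(lab, d)
}

# drop connected components smaller than min_voxels
.drop_small_components <- function(mask, min_voxels, connectivity = 6L) {
  if (min_voxels <= 1L || !any(mask)) return(mask)
  lab <- .label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_voxels)
  array(lab %in% keep, dim = dim(mask))
}

# largest connected component (empty mask returned unchanged)
.largest_component <- function(mask, connectivity = 6L) {
  if (!any(mask)) return(mask)
  lab <- .label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0])
  array(lab == which.max(sizes), dim = dim(mask))
}
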