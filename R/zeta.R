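# Patch-based zeta anomaly scoring: for each voxel, the 3x3x3 (27-voxel)
# neighbourhood patch of a subject's deviation map is compared with the same
# patch across a reference set of other subjects; the zeta score is the
# Euclidean distance to the nearest of k cluster centroids formed from the
# reference patches. This suppresses single-voxel false positives without
# smoothing the underlying Z data.

patch_offsets <- function(radius = 1) {
  r <- radius
  as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))  # x varies fastest
}

#' Extract a flattened cubic patch around a voxel
#'
#' The 3x3x3 neighbourhood is flattened in fixed x-fastest order, so the
#' centre voxel is element 14 (1-based; 13 when counting from 0). Out-of-grid
#' neighbours are clamped to the border (replicate-nearest); with
#' `edge = "zero"` any invalid neighbour is zero-filled instead. Neighbours
#' inside the grid but outside `mask` take the centre voxel's value under the
#' replicate policy.
#'
#' @param volume 3-D array.
#' @param voxel Integer (x, y, z), 1-based, inside the mask.
#' @param radius Patch radius (default 1, i.e. 27 voxels).
#' @param mask Optional logical volume restricting valid neighbours.
#' @param edge `"replicate"` (default) or `"zero"`.
#' @return Numeric vector of length `(2*radius+1)^3`.
#' @export
extract_patch <- function(volume, voxel, radius = 1, mask = NULL,
                          edge = c("replicate", "zero")) {
  edge <- match.arg(edge)
  gs <- dim(volume)
  off <- patch_offsets(radius)
  pts <- sweep(off, 2, as.integer(voxel), "+")
  ing <- pts[, 1] >= 1 & pts[, 1] <= gs[1] & pts[, 2] >= 1 & pts[, 2] <= gs[2] &
    pts[, 3] >= 1 & pts[, 3] <= gs[3]
  cl <- cbind(pmin(pmax(pts[, 1], 1), gs[1]), pmin(pmax(pts[, 2], 1), gs[2]),
              pmin(pmax(pts[, 3], 1), gs[3]))
  vals <- volume[cl]
  valid <- if (is.null(mask)) ing else (ing & mask[cl])
  if (edge == "zero") {
    vals[!valid] <- 0
  } else {
    centre <- volume[matrix(as.integer(voxel), 1)]
    if (!is.null(mask)) vals[!(ing & mask[cl])] <- centre
    # pure out-of-grid clamping already replicates the border
  }
  as.numeric(vals)
}

# Patches of all reference maps at all mask voxels: array [n_ref, 27, nv].
gather_patches <- function(maps, coords, gs, mask, edge) {
  off <- patch_offsets(1)
  nv <- nrow(coords); nr <- length(maps)
  out <- array(0, c(nr, nrow(off), nv))
  centre_idx <- vox_index(coords, gs)
  for (o in seq_len(nrow(off))) {
    pts <- sweep(coords, 2, off[o, ], "+")
    ing <- pts[, 1] >= 1 & pts[, 1] <= gs[1] & pts[, 2] >= 1 & pts[, 2] <= gs[2] &
      pts[, 3] >= 1 & pts[, 3] <= gs[3]
    cl <- cbind(pmin(pmax(pts[, 1], 1), gs[1]), pmin(pmax(pts[, 2], 1), gs[2]),
                pmin(pmax(pts[, 3], 1), gs[3]))
    idx <- vox_index(cl, gs)
    inmask <- ing & mask[idx]
    for (r in seq_len(nr)) {
      vals <- maps[[r]][idx]
      if (edge == "zero") vals[!inmask] <- 0
      else vals[!inmask] <- maps[[r]][centre_idx[!inmask]]
      out[r, o, ] <- vals
    }
  }
  out
}

#' Build the per-voxel patch reference (k-means centroids)
#'
#' Samples `n_ref` reference deviation maps (the subject being scored must not
#' be among them), collects their 27-voxel patches at every mask voxel and
#' fits per-voxel k-means with `k` clusters. When fewer than `k` distinct
#' patches exist the distinct patches themselves become the centroids.
#'
#' @param deviation_maps List of 3-D Z volumes (reference subjects).
#' @param mask Logical volume.
#' @param n_ref Reference-set size (default 80; clamped with a warning when
#'   fewer maps are available).
#' @param k Number of clusters (default 8; clamped to `n_ref` with a warning).
#' @param seed Integer seed (reference sampling and k-means).
#' @param edge Edge policy for patch extraction.
#' @return Object of class `patch_reference`: per-voxel centroid matrices.
#' @export
build_reference <- function(deviation_maps, mask, n_ref = 80, k = 8, seed = 1,
                            edge = c("replicate", "zero")) {
  edge <- match.arg(edge)
  nav <- length(deviation_maps)
  if (nav < 1) stop_arg("no reference maps supplied")
  if (n_ref > nav) {
    warning(sprintf("n_ref = %d clamped to %d available reference subjects", n_ref, nav),
            call. = FALSE)
    n_ref <- nav
  }
  if (k > n_ref) {
    warning(sprintf("k = %d clamped to n_ref = %d", k, n_ref), call. = FALSE)
    k <- n_ref
  }
  gs <- dim(mask)
  coords <- which(mask, arr.ind = TRUE)
  sel <- with_seed(derive_seed(seed, 11), sample.int(nav, n_ref))
  patches <- gather_patches(deviation_maps[sel], coords, gs, mask, edge)
  nv <- nrow(coords)
  centroids <- vector("list", nv)
  for (v in seq_len(nv)) {
    P <- patches[, , v, drop = FALSE]
    dim(P) <- dim(P)[1:2]
    Pu <- unique(P)
    centroids[[v]] <- if (nrow(Pu) <= k) Pu else
      with_seed(derive_seed(seed, 100000 + v),
                stats::kmeans(P, centers = k, iter.max = 25, nstart = 1)$centers)
  }
  structure(list(centroids = centroids, coords = coords, k = k, n_ref = n_ref,
                 metric = "euclidean", edge = edge, grid_shape = gs),
            class = "patch_reference")
}

#' Zeta score of one patch against a voxel's reference
#'
#' Euclidean distance from the patch to the nearest reference cluster
#' centroid; larger values are more anomalous.
#'
#' @param patch Numeric 27-vector.
#' @param centroids `k x 27` centroid matrix for the voxel.
#' @return Non-negative scalar.
#' @export
zeta_score <- function(patch, centroids) {
  d2 <- rowSums(sweep(centroids, 2, patch)^2)
  sqrt(min(d2))
}

#' Zeta anomaly map of a deviation map
#'
#' Scores every mask voxel of `subject_map` against per-voxel references
#' built from `reference_maps`. The default variant is
#' distance-to-nearest-centroid after per-voxel k-means; `variant = "knn"`
#' instead uses the mean distance to the k nearest reference patches minus
#' the mean pairwise distance among those k (a kNN zeta).
#'
#' @param subject_map 3-D Z volume of the subject being scored (must not be in
#'   `reference_maps`).
#' @param reference_maps List of 3-D Z volumes.
#' @param mask Logical volume.
#' @param k Clusters / neighbours (default 8).
#' @param n_ref Reference-set size (default 80).
#' @param seed Integer seed.
#' @param variant `"centroid"` (default) or `"knn"`.
#' @param edge Edge policy.
#' @param reference Optional prebuilt `patch_reference` (centroid variant
#'   only); skips resampling.
#' @return 3-D volume of zeta scores, zero outside the mask.
#' @export
zeta_map <- function(subject_map, reference_maps, mask, k = 8, n_ref = 80,
                     seed = 1, variant = c("centroid", "knn"),
                     edge = c("replicate", "zero"), reference = NULL) {
  variant <- match.arg(variant); edge <- match.arg(edge)
  gs <- dim(mask)
  coords <- which(mask, arr.ind = TRUE)
  out <- array(0, gs)
  if (variant == "centroid") {
    ref <- reference %||% build_reference(reference_maps, mask, n_ref = n_ref,
                                          k = k, seed = seed, edge = edge)
    for (v in seq_len(nrow(coords))) {
      p <- extract_patch(subject_map, coords[v, ], mask = mask, edge = edge)
      out[matrix(coords[v, ], 1)] <- zeta_score(p, ref$centroids[[v]])
    }
  } else {
    nav <- length(reference_maps)
    n_ref <- min(n_ref, nav); k <- min(k, n_ref)
    sel <- with_seed(derive_seed(seed, 11), sample.int(nav, n_ref))
    patches <- gather_patches(reference_maps[sel], coords, gs, mask, edge)
    for (v in seq_len(nrow(coords))) {
      P <- patches[, , v, drop = FALSE]; dim(P) <- dim(P)[1:2]
      p <- extract_patch(subject_map, coords[v, ], mask = mask, edge = edge)
      d <- sqrt(rowSums(sweep(P, 2, p)^2))
      nn <- order(d)[seq_len(k)]
      Pk <- P[nn, , drop = FALSE]
      within <- if (k > 1) mean(stats::dist(Pk)) else 0
      out[matrix(coords[v, ], 1)] <- mean(d[nn]) - within
    }
  }
  out
}
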