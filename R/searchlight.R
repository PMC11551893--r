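#' Construct a 3D volume mask
#'
#' @param grid 3D logical array; TRUE marks in-mask voxels.
#' @param voxel_size_mm positive length-3 voxel dimensions in mm (default
#'   2 mm isotropic, the functional resolution the analyses assume).
#' @return an object of class `volume_mask`.
#' @export
volume_mask <- function(grid, voxel_size_mm = c(2, 2, 2)) {
  grid <- as.array(grid)
  if (length(dim(grid)) != 3L) stop("grid must be a 3D array")
  storage.mode(grid) <- "logical"
  if (!any(grid)) stop("mask must contain at least one voxel")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop("voxel size must be strictly positive")
  structure(list(grid = grid, voxel_size_mm = voxel_size_mm),
            class = "volume_mask")
}

#' A filled box mask (convenience constructor, mainly for simulations)
#' @param dims length-3 grid dimensions.
#' @param voxel_size_mm voxel size in mm.
#' @param box optional 3 x 2 matrix of inclusive index ranges; only voxels
#'   inside the box are in-mask (default: whole grid).
#' @return a `volume_mask`.
#' @export
box_mask <- function(dims, voxel_size_mm = c(2, 2, 2), box = NULL) {
  grid <- array(FALSE, dims)
  if (is.null(box)) box <- cbind(c(1, 1, 1), dims)
  grid[box[1, 1]:box[1, 2], box[2, 1]:box[2, 2], box[3, 1]:box[3, 2]] <- TRUE
  volume_mask(grid, voxel_size_mm)
}

# offsets within max_radius_mm, sorted by physical distance then
# lexicographic coordinate order (deterministic tie-breaking)
searchlight_offsets <- function(voxel_size_mm, max_radius_mm) {
  rng <- lapply(voxel_size_mm, function(v) {
    m <- floor(max_radius_mm / v)
    (-m):m
  })
  off <- as.matrix(expand.grid(dx = rng[[1]], dy = rng[[2]], dz = rng[[3]]))
  d2 <- (off[, 1] * voxel_size_mm[1])^2 + (off[, 2] * voxel_size_mm[2])^2 +
    (off[, 3] * voxel_size_mm[3])^2
  keep <- d2 <= max_radius_mm^2 + 1e-9
  off <- off[keep, , drop = FALSE]
  d2 <- d2[keep]
  ord <- order(d2, off[, 1], off[, 2], off[, 3])
  list(offsets = off[ord, , drop = FALSE], dist_mm = sqrt(d2[ord]))
}

#' Define ROI-constrained volumetric searchlights
#'
#' For every in-mask voxel, a searchlight is formed from the in-mask voxels
#' sorted by physical distance from the center (ties broken by lexicographic
#' coordinate order) and truncated at whichever comes first: the target voxel
#' count or the maximum radius. At 2 mm isotropic resolution a 6 mm radius
#' admits at most 123 voxels, so with the defaults the radius cap binds.
#'
#' @param mask a [volume_mask()].
#' @param target_size maximum voxels per searchlight (default 160).
#' @param max_radius_mm maximum center-to-member distance in mm (default 6).
#' @return list of searchlights, each with `center` (length-3 integer),
#'   `members` (m x 3 integer matrix, center first), `radius_used_mm`.
#' @export
define_searchlights <- function(mask, target_size = 160, max_radius_mm = 6) {
  stopifnot(inherits(mask, "volume_mask"))
  if (target_size < 1 || max_radius_mm <= 0)
    stop("invalid config: target_size and max_radius_mm must be positive")
  off <- searchlight_offsets(mask$voxel_size_mm, max_radius_mm)
  dims <- dim(mask$grid)
  centers <- which(mask$grid, arr.ind = TRUE)
  ord <- order(centers[, 1], centers[, 2], centers[, 3])
  centers <- centers[ord, , drop = FALSE]
  lapply(seq_len(nrow(centers)), function(ci) {
    ctr <- centers[ci, ]
    cand <- sweep(off$offsets, 2, ctr, "+")
    ok <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
      cand[, 2] >= 1 & cand[, 2] <= dims[2] &
      cand[, 3] >= 1 & cand[, 3] <= dims[3]
    ok[ok] <- mask$grid[cand[ok, , drop = FALSE]]
    keep <- which(ok)
    if (length(keep) > target_size) keep <- keep[seq_len(target_size)]
    list(center = unname(ctr),
         members = unname(cand[keep, , drop = FALSE]),
         radius_used_mm = max(off$dist_mm[keep]))
  })
}

#' Map an analysis over searchlights of a volumetric dataset
#'
#' Applies `analysis_fn` to the dataset restricted to each searchlight's
#' member voxels and stores the scalar result at the searchlight's center
#' voxel. Voxels outside the mask (and searchlights whose analysis fails) are
#' `NA`.
#'
#' @param ds a volumetric `pattern_dataset` (with `voxel_coordinates`), e.g.
#'   from [embed_in_volume()].
#' @param searchlights list from [define_searchlights()].
#' @param analysis_fn function taking a `pattern_dataset` and returning a
#'   scalar (e.g. `function(d) decode_sequences(d, "order")$z`).
#' @param dims grid dimensions of the output map; inferred from the
#'   coordinates when omitted.
#' @return 3D numeric array of analysis values.
#' @export
run_searchlight <- function(ds, searchlights, analysis_fn, dims = NULL) {
  if (is.null(ds$voxel_coordinates))
    stop("dataset must be volumetric (voxel_coordinates attached)")
  coords <- ds$voxel_coordinates
  if (is.null(dims)) dims <- apply(coords, 2, max)
  col_of <- array(NA_integer_, dims)
  col_of[coords] <- seq_len(nrow(coords))
  out <- array(NA_real_, dims)
  n_failed <- 0L
  for (sl in searchlights) {
    cols <- col_of[sl$members]
    cols <- cols[!is.na(cols)]
    if (length(cols) < 2L) next
    val <- tryCatch(analysis_fn(subset_dataset(ds, voxels = cols)),
                    error = function(e) { n_failed <<- n_failed + 1L; NA_real_ })
    out[sl$center[1], sl$center[2], sl$center[3]] <- val
  }
  if (n_failed > 0L)
    warning(n_failed, " searchlight(s) failed and were recorded as NA")
  out
}

#' Group-level random-effects t-map with suprathreshold clusters
#'
#' Voxelwise one-sample t-test of per-subject maps against `mu`;
#' suprathreshold voxels (default t > 3.48, the p < 0.001 cutoff for 23
#' degrees of freedom) are grouped into 26-connected clusters.
#'
#' @param maps list of aligned 3D arrays, one per subject.
#' @param mu null value (default 0).
#' @param t_threshold cluster-forming threshold.
#' @return list with `t_map` (3D array, `NA` where any subject is `NA`),
#'   `threshold`, and `clusters`: a data.frame with cluster id, extent,
#'   peak t and peak coordinates, sorted by extent.
#' @export
group_t_map <- function(maps, mu = 0, t_threshold = 3.48) {
  stopifnot(length(maps) >= 2L)
  dims <- dim(maps[[1]])
  if (!all(vapply(maps, function(m) identical(dim(m), dims), logical(1))))
    stop("shape error: subject maps must share a grid")
  Y <- vapply(maps, as.vector, numeric(prod(dims)))  # voxels x subjects
  n <- ncol(Y)
  m <- rowMeans(Y)
  s <- sqrt(pmax(rowSums((Y - m)^2) / (n - 1), 0))
  tvals <- (m - mu) / (s / sqrt(n))
  tvals[s == 0] <- NA_real_
  t_map <- array(tvals, dims)
  supra <- which(!is.na(t_map) & t_map > t_threshold, arr.ind = TRUE)
  clusters <- label_clusters(supra, dims)
  if (nrow(supra) > 0) {
    tab <- lapply(sort(unique(clusters)), function(id) {
      vox <- supra[clusters == id, , drop = FALSE]
      tv <- t_map[vox]
      pk <- which.max(tv)
      data.frame(cluster = id, extent = nrow(vox), peak_t = tv[pk],
                 peak_x = vox[pk, 1], peak_y = vox[pk, 2], peak_z = vox[pk, 3])
    })
    tab <- do.call(rbind, tab)
    tab <- tab[order(-tab$extent), , drop = FALSE]
    tab$cluster <- seq_len(nrow(tab))
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(cluster = integer(), extent = integer(),
                      peak_t = numeric(), peak_x = integer(),
                      peak_y = integer(), peak_z = integer())
  }
  list(t_map = t_map, threshold = t_threshold, clusters = tab)
}

# 26-connected component labeling of a voxel coordinate list (BFS)
label_clusters <- function(voxels, dims) {
  n <- nrow(voxels)
  if (n == 0) return(integer(0))
  lin <- (voxels[, 3] - 1L) * dims[1] * dims[2] +
    (voxels[, 2] - 1L) * dims[1] + voxels[, 1]
  idx_of <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(lin[i]), i, envir = idx_of)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  labels <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (labels[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      neigh <- sweep(nb, 2, as.numeric(voxels[v, ]), "+")
      keep <- neigh[, 1] >= 1 & neigh[, 1] <= dims[1] &
        neigh[, 2] >= 1 & neigh[, 2] <= dims[2] &
        neigh[, 3] >= 1 & neigh[, 3] <= dims[3]
      neigh <- neigh[keep, , drop = FALSE]
      nlin <- (neigh[, 3] - 1) * dims[1] * dims[2] +
        (neigh[, 2] - 1) * dims[1] + neigh[, 1]
      for (l in nlin) {
        j <- idx_of[[as.character(l)]]
        if (!is.null(j) && labels[j] == 0L) {
          labels[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}
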