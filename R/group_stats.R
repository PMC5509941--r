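# Group-level inference on searchlight maps, following the
# permutation-bootstrap scheme: per-subject randomized-target null models,
# subject-wise bootstrap of group-mean null maps, voxel-wise p < 0.001
# thresholding, and FWE cluster-size correction at p < 0.05.

#' Build randomized-target null searchlight maps for one subject
#'
#' Each null model draws a random permutation of the stimulus-to-feature
#' assignment (which feature vector labels which stimulus) and reruns the
#' searchlight, reusing the true map's scatter offset so null and true maps
#' share the same center lattice. Repetitions are reduced relative to the
#' true map purely for runtime; the identity permutation with matching
#' repetitions reproduces the true map.
#'
#' @param bp,features,mask as in [run_searchlight()].
#' @param n_null number of null models (desk-scale default 20; the reference
#'   analysis used 100).
#' @param rng_seed integer seed.
#' @param repetitions cross-validation repetitions per null model (default 2).
#' @param offset scatter offset of the true map (required for comparability).
#' @param spheres optional precomputed sphere set (see [enumerate_spheres()]).
#' @param ... further arguments passed to the searchlight engine.
#' @return `null_map_set`: list with `maps` (n_null x centers matrix),
#'   `centers`, `offset`, `mask`, `n_null`.
#' @export
make_null_maps <- function(bp, features, mask = bp$mask, n_null = 20L,
                           rng_seed = 1L, repetitions = 2L, offset = c(0, 0, 0),
                           spheres = NULL, ...) {
  n_stim <- dim(bp$betas)[1L]
  perms <- lapply(seq_len(n_null), function(j)
    with_seed(derive_seed(rng_seed, j), sample.int(n_stim)))
  eng <- searchlight_engine(bp, features, perms, mask = mask,
                            repetitions = repetitions,
                            rng_seed = derive_seed(rng_seed, 777L),
                            offset = offset, spheres = spheres, ...)
  structure(list(maps = eng$values, centers = eng$centers, offset = offset,
                 mask = mask, n_null = n_null),
            class = "null_map_set")
}

#' Bootstrap the group-level null distribution
#'
#' Each bootstrap sample draws, independently for every subject, one of that
#' subject's null maps, and averages across subjects, accumulating per-center
#' empirical null distributions of the group-mean accuracy.
#'
#' @param nulls list of `null_map_set`, one per subject (>= 2), sharing one
#'   center lattice.
#' @param n_bootstrap number of bootstrap samples (desk-scale default 10000;
#'   the reference analysis used 100000). Below 1000 a warning is issued:
#'   the p < 0.001 tail is unstable.
#' @param rng_seed integer seed.
#' @return `bootstrap_null`: list with `boot` (n_bootstrap x centers matrix
#'   of group-mean null maps), `centers`, `n_bootstrap`.
#' @export
bootstrap_group_null <- function(nulls, n_bootstrap = 10000L, rng_seed = 1L) {
  if (length(nulls) < 2L) stop("need at least 2 subjects")
  if (n_bootstrap < 1000L)
    warning("n_bootstrap < 1000: tail quantiles will be unstable")
  nc <- ncol(nulls[[1L]]$maps)
  if (!all(vapply(nulls, function(x) ncol(x$maps), 0L) == nc))
    stop("null map sets differ in center count")
  with_seed(rng_seed, {
    rows <- vapply(nulls, function(x)
      sample.int(nrow(x$maps), n_bootstrap, replace = TRUE),
      integer(n_bootstrap))
    boot <- boot_group_means(lapply(nulls, `[[`, "maps"), rows)
    structure(list(boot = boot, centers = nulls[[1L]]$centers,
                   n_bootstrap = n_bootstrap),
              class = "bootstrap_null")
  })
}

# Per-center (1 - voxel_p) quantile of the bootstrap null (type-1 empirical
# quantile: order statistic at ceiling((1-p) * B)).
null_quantiles <- function(boot_null, voxel_p = 0.001) {
  B <- nrow(boot_null$boot)
  k <- min(max(ceiling((1 - voxel_p) * B), 1L), B)
  col_order_stat(boot_null$boot, as.integer(k))
}

# Connected components (face connectivity by default) of a set of voxel
# array-indices in a grid of dimensions dims. Returns a list of integer
# vectors of array indices.
connected_components <- function(idx, dims, connectivity = 6L) {
  if (length(idx) == 0L) return(list())
  neigh <- switch(as.character(connectivity),
    "6" = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1)),
    "18" = { g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
             g[rowSums(abs(g)) %in% 1:2, , drop = FALSE] },
    "26" = { g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
             g[rowSums(abs(g)) > 0, , drop = FALSE] },
    stop("connectivity must be 6, 18 or 26"))
  coords <- arrayInd(idx, dims)
  key <- function(m) (m[, 3L] - 1L) * dims[1L] * dims[2L] +
    (m[, 2L] - 1L) * dims[1L] + m[, 1L]
  inset <- new.env(hash = TRUE, size = length(idx) * 2L)
  for (i in seq_along(idx)) assign(as.character(key(coords[i, , drop = FALSE])), i, inset)
  visited <- logical(length(idx))
  comps <- list()
  for (i in seq_along(idx)) {
    if (visited[i]) next
    queue <- i; visited[i] <- TRUE; comp <- integer(0)
    while (length(queue) > 0L) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      comp <- c(comp, cur)
      pts <- sweep(neigh, 2L, coords[cur, ], "+")
      ok <- pts[, 1L] >= 1L & pts[, 1L] <= dims[1L] &
        pts[, 2L] >= 1L & pts[, 2L] <= dims[2L] &
        pts[, 3L] >= 1L & pts[, 3L] <= dims[3L]
      for (kk in key(pts[ok, , drop = FALSE])) {
        j <- inset[[as.character(kk)]]
        if (!is.null(j) && !visited[j]) { visited[j] <- TRUE; queue <- c(queue, j) }
      }
    }
    comps[[length(comps) + 1L]] <- idx[comp]
  }
  comps
}

# Expand a suprathreshold center set to the filled volume: all in-mask voxels
# whose nearest center is suprathreshold.
expand_centers <- function(supra_centers, fill_index, mask_voxels) {
  mask_voxels[fill_index %in% supra_centers]
}

#' Threshold a group map against the bootstrap null and extract clusters
#'
#' Centers whose group-mean accuracy exceeds the (1 - `voxel_p`) quantile of
#' their bootstrap null distribution survive; the surviving set is expanded
#' to the filled volume (nearest computed center) and partitioned into
#' face-connected components.
#'
#' @param group_values group-mean accuracy per center.
#' @param boot_null a `bootstrap_null` (or precomputed quantiles via
#'   `thresholds`).
#' @param slmap a `searchlight_map` providing mask/centers (any subject's, or
#'   the group's; only geometry is used).
#' @param voxel_p voxel-wise threshold probability (default 0.001).
#' @param connectivity 6, 18 or 26 (default 6, faces).
#' @param thresholds optional per-center thresholds overriding `boot_null`.
#' @return list with `supra_centers` (indices), `binary` volume, `clusters`
#'   (list of array-index vectors), `thresholds`, `fill`.
#' @export
threshold_and_cluster <- function(group_values, boot_null, slmap,
                                  voxel_p = 0.001, connectivity = 6L,
                                  thresholds = NULL) {
  if (is.null(thresholds)) thresholds <- null_quantiles(boot_null, voxel_p)
  fill <- fill_searchlight_map(slmap)
  mask_vox <- which(slmap$mask)
  supra <- which(group_values > thresholds)
  dims <- dim(slmap$mask)
  binary <- array(FALSE, dims)
  clusters <- list()
  if (length(supra) > 0L) {
    vox <- expand_centers(supra, fill$fill_index, mask_vox)
    binary[vox] <- TRUE
    clusters <- connected_components(vox, dims, connectivity)
  }
  list(supra_centers = supra, binary = binary, clusters = clusters,
       thresholds = thresholds, fill = fill)
}

#' FWE-corrected cluster records
#'
#' Builds the null distribution of the maximum suprathreshold cluster size by
#' thresholding every bootstrap null map exactly as the true map, and assigns
#' each observed cluster `p_cluster = (r + 1) / (B + 1)` where `r` is the
#' number of null maxima at least as large. Clusters with
#' `p_cluster < cluster_p` are reported with size, accuracy statistics, and
#' center of mass (unweighted, voxel coordinates and mm via the affine).
#'
#' @param clustering result of [threshold_and_cluster()] on the true group
#'   map.
#' @param group_values group-mean accuracy per center (for cluster stats).
#' @param boot_null the `bootstrap_null` used for thresholding.
#' @param slmap geometry provider (see [threshold_and_cluster()]).
#' @param cluster_p cluster-level FWE threshold (default 0.05).
#' @param connectivity as in [threshold_and_cluster()].
#' @param affine 4x4 voxel-to-mm map for reported coordinates (default from
#'   `slmap` if present, else identity).
#' @param label_volume optional integer/character array naming structures.
#' @param keep_all report all clusters regardless of significance.
#' @return data.frame (`cluster_table`): columns `cluster`, `voxels`, `max`,
#'   `mean`, `std`, `x`, `y`, `z` (center of mass, mm), `p_cluster`,
#'   `label`, voxel-space center of mass (`com_i/j/k`), and `component`
#'   (index into `clustering$clusters`); attribute `null_max_sizes`.
#' @export
cluster_fwe <- function(clustering, group_values, boot_null, slmap,
                        cluster_p = 0.05, connectivity = 6L, affine = NULL,
                        label_volume = NULL, keep_all = FALSE) {
  affine <- affine %||% slmap$affine %||% diag(4)
  dims <- dim(slmap$mask)
  mask_vox <- which(slmap$mask)
  fill <- clustering$fill
  thr <- clustering$thresholds
  B <- nrow(boot_null$boot)
  if (connectivity == 6L && all(slmap$mask)) {
    # fast path: on a full-volume lattice, fill regions of two suprathreshold
    # centers are face-connected iff the centers are lattice neighbors, so
    # clustering can run on the center lattice with fill-region sizes
    fill_count <- tabulate(fill$fill_index, nbins = nrow(slmap$centers))
    null_max <- boot_null_max_cluster(boot_null$boot, thr, slmap$centers,
                                      dim(slmap$mask), fill_count,
                                      as.integer(slmap$scatter_step))
  } else {
    null_max <- integer(B)
    for (b in seq_len(B)) {
      supra <- which(boot_null$boot[b, ] > thr)
      if (length(supra) == 0L) next
      vox <- expand_centers(supra, fill$fill_index, mask_vox)
      comps <- connected_components(vox, dims, connectivity)
      null_max[b] <- max(lengths(comps))
    }
  }
  filled_vol <- fill$volume
  recs <- lapply(seq_along(clustering$clusters), function(ci) {
    vox <- clustering$clusters[[ci]]
    vals <- filled_vol[vox]
    com <- colMeans(arrayInd(vox, dims))
    com_mm <- as.vector(affine %*% c(com - 1, 1))[1:3]
    p_cl <- (sum(null_max >= length(vox)) + 1) / (B + 1)
    lab <- NA_character_
    if (!is.null(label_volume)) {
      labs <- label_volume[vox]
      labs <- labs[!is.na(labs) & labs != 0]
      if (length(labs) > 0L)
        lab <- as.character(names(sort(table(labs), decreasing = TRUE))[1L])
    }
    data.frame(voxels = length(vox), max = max(vals), mean = mean(vals),
               std = stats::sd(vals), x = com_mm[1L], y = com_mm[2L],
               z = com_mm[3L], p_cluster = p_cl, label = lab,
               com_i = com[1L], com_j = com[2L], com_k = com[3L],
               component = ci)
  })
  tab <- do.call(rbind, recs)
  if (is.null(tab)) {
    tab <- data.frame(voxels = integer(0), max = numeric(0), mean = numeric(0),
                      std = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), p_cluster = numeric(0),
                      label = character(0), com_i = numeric(0),
                      com_j = numeric(0), com_k = numeric(0),
                      component = integer(0))
  }
  tab <- tab[order(-tab$voxels), , drop = FALSE]
  if (!keep_all) tab <- tab[tab$p_cluster < cluster_p, , drop = FALSE]
  if (nrow(tab) > 0L) tab <- cbind(cluster = seq_len(nrow(tab)), tab)
  else tab <- cbind(cluster = integer(0), tab)
  rownames(tab) <- NULL
  class(tab) <- c("cluster_table", "data.frame")
  attr(tab, "null_max_sizes") <- null_max
  tab
}

#' Full group-level inference on searchlight maps
#'
#' Convenience wrapper chaining [bootstrap_group_null()],
#' [threshold_and_cluster()] and [cluster_fwe()] on per-subject true maps and
#' null map sets.
#'
#' @param true_maps list of `searchlight_map`, one per subject.
#' @param nulls list of `null_map_set`, one per subject.
#' @param n_bootstrap,voxel_p,cluster_p,connectivity inference parameters.
#' @param rng_seed seed for the bootstrap.
#' @param ... passed to [cluster_fwe()] (e.g. `label_volume`, `affine`).
#' @return list with `group_values`, `thresholds`, `clustering`, `table`.
#' @export
group_cluster_inference <- function(true_maps, nulls, n_bootstrap = 10000L,
                                    voxel_p = 0.001, cluster_p = 0.05,
                                    connectivity = 6L, rng_seed = 1L, ...) {
  gv <- Reduce(`+`, lapply(true_maps, function(m) m$center_values)) /
    length(true_maps)
  bn <- bootstrap_group_null(nulls, n_bootstrap, rng_seed)
  cl <- threshold_and_cluster(gv, bn, true_maps[[1L]], voxel_p, connectivity)
  tab <- cluster_fwe(cl, gv, bn, true_maps[[1L]], cluster_p, connectivity, ...)
  list(group_values = gv, thresholds = cl$thresholds, clustering = cl,
       table = tab, bootstrap = bn)
}

#' Write / read a cluster table as CSV
#'
#' The CSV mirrors the usual cluster-report columns (#, Voxels, Max, Mean,
#' Std, X, Y, Z, p_cluster, Structure) and round-trips exactly.
#'
#' @param tab a `cluster_table`.
#' @param path CSV path.
#' @return `path` / the re-read `cluster_table`.
#' @export
write_cluster_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cluster_table
#' @export
read_cluster_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(label = "character"))
  class(tab) <- c("cluster_table", "data.frame")
  tab
}
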