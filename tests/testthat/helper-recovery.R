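# Region-recovery replicate used by the acceptance suite.
#
# World: three planted 12 x 12 x 2 slabs (one per feature kind) centered in
# the x/y plane of a 24^3 grid, so that regions dilated by the searchlight
# radius still leave a majority of genuinely background volume.
#
# Searchlight: exhaustive centers (scatter_step = 1). The random scatter
# lattice is a compute-saving device whose alignment relative to a 2-voxel
# slab systematically biases cluster centers of mass at this scale.
#
# Pass criteria per replicate:
#  * for every feature kind, at least one significant cluster whose center
#    of mass lies inside that kind's planted region;
#  * no significant cluster entirely outside the planted regions dilated by
#    the sphere radius. A searchlight map value at voxel v reflects the
#    sphere around v, so detections within one radius of a region are
#    signal-driven; a spurious noise cluster would sit in the undilated
#    background. Clusters overlapping a different kind's region are genuine
#    cross-feature detections (the synthetic chromagram embeds the melody).
region_recovery_replicate <- function(seed, n_sub = 6L, shape = c(24L, 24L, 24L),
                                      snr = 5, reps_true = 5L, n_null = 12L,
                                      reps_null = 1L, n_bootstrap = 2000L,
                                      radius = 3) {
  kinds <- c("melody_abs", "melody_rel", "chroma")
  xy <- 7:18
  zs <- list(5:6, 12:13, 19:20)
  regions <- lapply(seq_along(kinds), function(i) {
    m <- array(FALSE, shape); m[xy, xy, zs[[i]]] <- TRUE
    list(name = paste0("slab_", kinds[i]), kind = kinds[i], voxels = m)
  })
  mask <- array(TRUE, shape)
  spheres <- enumerate_spheres(mask, radius = radius, scatter_step = 1L)
  true_maps <- list(); nulls <- list()
  brain <- NULL
  for (s in seq_len(n_sub)) {
    subj <- simulate_subject(rng_seed = derive_seed(seed, s), shape = shape,
                             snr = snr, regions = regions,
                             epi_format = "matrix")
    brain <- subj$brain
    bp <- fit_betas(subj$session, subject_id = sprintf("sub-%02d", s))
    for (kd in kinds) {
      true_maps[[kd]][[s]] <- run_searchlight(
        bp, subj$features[[kd]], repetitions = reps_true,
        rng_seed = derive_seed(seed, 100L + s), radius = radius,
        scatter_step = 1L, spheres = spheres)
      nulls[[kd]][[s]] <- make_null_maps(
        bp, subj$features[[kd]], n_null = n_null,
        rng_seed = derive_seed(seed, 200L + s), repetitions = reps_null,
        radius = radius, scatter_step = 1L, spheres = spheres)
    }
  }
  lab <- brain$region_labels
  # regions dilated by the searchlight radius (information spillover zone)
  dil <- array(FALSE, shape)
  offs <- sphere_offsets(radius)
  reg_coords <- which(lab > 0, arr.ind = TRUE)
  for (j in seq_len(nrow(offs))) {
    pts <- sweep(reg_coords, 2L, offs[j, ], "+")
    ok <- pts[, 1] >= 1 & pts[, 1] <= shape[1] & pts[, 2] >= 1 &
      pts[, 2] <= shape[2] & pts[, 3] >= 1 & pts[, 3] <= shape[3]
    dil[pts[ok, , drop = FALSE]] <- TRUE
  }
  kind_of_label <- vapply(brain$region_encoding, function(r) r$kind, "")
  per_kind <- lapply(kinds, function(kd) {
    gi <- group_cluster_inference(true_maps[[kd]], nulls[[kd]],
                                  n_bootstrap = n_bootstrap,
                                  rng_seed = derive_seed(seed, 13L),
                                  affine = diag(4))
    tab <- gi$table
    found_own <- FALSE; any_bg <- FALSE
    for (i in seq_len(nrow(tab))) {
      vox <- gi$clustering$clusters[[tab$component[i]]]
      if (!any(dil[vox])) any_bg <- TRUE      # spurious background cluster
      com <- pmin(pmax(round(c(tab$com_i[i], tab$com_j[i], tab$com_k[i])), 1L),
                  shape)
      l <- lab[com[1], com[2], com[3]]
      if (l > 0L && kind_of_label[l] == kd) found_own <- TRUE
    }
    list(found_own = found_own, any_bg = any_bg, table = tab)
  })
  names(per_kind) <- kinds
  list(ok = all(vapply(per_kind, function(x) x$found_own && !x$any_bg, TRUE)),
       per_kind = per_kind)
}
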