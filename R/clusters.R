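neighbor_offsets <- function(connectivity = 26) {
  if (connectivity == 6) {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
          c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  } else if (connectivity == 26) {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    unname(g[rowSums(abs(g)) > 0, , drop = FALSE])
  } else stop("connectivity must be 6 or 26")
}

#' Extract suprathreshold clusters from a Z map
#'
#' Finds connected components (26-neighbour connectivity by default) of
#' voxels with |Z| above threshold.
#'
#' @param z 3-D array of Z values (NA treated as sub-threshold).
#' @param z_thresh Threshold on |Z| (default 2.57).
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return List of clusters, each a list with `voxels` (linear indices),
#'   `size`, and `sign` (sign of the mean Z inside the cluster).
#' @export
extract_clusters <- function(z, z_thresh = 2.57, connectivity = 26) {
  stopifnot(z_thresh > 0)
  d <- dim(z)
  stopifnot(length(d) == 3)
  above <- !is.na(z) & abs(z) > z_thresh
  if (!any(above)) return(list())
  offs <- neighbor_offsets(connectivity)
  lab <- array(0L, d)
  clusters <- list()
  nc <- 0L
  for (start in which(above)) {
    if (lab[start] > 0L) next
    nc <- nc + 1L
    lab[start] <- nc
    queue <- start
    members <- integer(0)
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      members <- c(members, cur)
      co <- arrayInd(cur, d)
      nb <- sweep(offs, 2, as.integer(co), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
            nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      if (any(ok)) {
        lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] +
          (nb[ok, 3] - 1L) * d[1] * d[2]
        new <- lin[above[lin] & lab[lin] == 0L]
        if (length(new) > 0) {
          lab[new] <- nc
          queue <- c(queue, new)
        }
      }
    }
    clusters[[nc]] <- list(voxels = members, size = length(members),
                           sign = sign(mean(z[members])))
  }
  clusters
}

#' Mask of voxels surviving a cluster-size threshold
#'
#' @param z 3-D Z map.
#' @param z_thresh Voxel threshold on |Z|.
#' @param min_cluster_voxels Minimum surviving cluster size.
#' @param connectivity Cluster connectivity.
#' @return Logical 3-D array.
#' @export
cluster_mask <- function(z, z_thresh = 2.57, min_cluster_voxels = 1,
                         connectivity = 26) {
  cl <- extract_clusters(z, z_thresh, connectivity)
  out <- array(FALSE, dim(z))
  for (c in cl) if (c$size >= min_cluster_voxels) out[c$voxels] <- TRUE
  out
}

#' Resampling-based cluster-size threshold
#'
#' Builds the null distribution of the maximum suprathreshold cluster size
#' by refitting the GLM after randomizing the sequence of each parametric
#' regressor's amplitudes across trials (within run/block), keeping the
#' amplitude distributions intact.  The corrected threshold is the
#' smallest cluster size whose probability of occurring anywhere in a null
#' map is below `p`.
#'
#' @param Y A [volume_series()].
#' @param session A `session_data` supplying event onsets and run (block)
#'   structure.
#' @param amplitudes Named list of per-trial parametric amplitude vectors
#'   (e.g. the EEG valence STV, model surprise, EEG surprise STV).
#' @param n_iter Number of resampling iterations (default 100).
#' @param z_thresh Voxel threshold on |Z| (default 2.57).
#' @param p Cluster-level significance (default 0.05).
#' @param connectivity Cluster connectivity (default 26).
#' @param motion Optional nuisance matrix.
#' @param duration Event duration in seconds.
#' @param dt Fine-grid step for convolution.
#' @param seed Optional integer seed.
#' @return An object of class `cluster_threshold`: `z_thresh`,
#'   `min_cluster_voxels`, `null_sizes` (max null cluster size per
#'   iteration), `p`, `n_iter`.
#' @export
resample_cluster_threshold <- function(Y, session, amplitudes, n_iter = 100,
                                       z_thresh = 2.57, p = 0.05,
                                       connectivity = 26, motion = NULL,
                                       duration = 0.1, dt = 0.1,
                                       seed = NULL) {
  trials <- session$trials
  n_vol <- dim(Y$data)[4]
  blocks <- trials$block
  with_seed(seed, {
    null_sizes <- vapply(seq_len(n_iter), function(it) {
      perm_amps <- lapply(amplitudes, function(a) {
        out <- a
        for (b in unique(blocks)) {
          idx <- which(blocks == b)
          out[idx] <- a[idx][sample.int(length(idx))]
        }
        out - mean(out)
      })
      regs <- c(list(event_regressor(trials$onset_s, duration, 1, "UM")),
                lapply(names(perm_amps), function(nm)
                  event_regressor(trials$onset_s, duration, perm_amps[[nm]],
                                  nm)),
                list(event_regressor(trials$dec_onset_s, duration, 1,
                                     "DEC")))
      des <- build_design(regs, Y$TR, n_vol, nuisance = motion, dt = dt)
      fit <- bold_glm(Y, des)
      sizes <- unlist(lapply(names(perm_amps), function(nm) {
        cl <- extract_clusters(z_map(fit, nm), z_thresh, connectivity)
        vapply(cl, function(c) c$size, numeric(1))
      }))
      if (length(sizes) == 0) 0 else max(sizes)
    }, numeric(1))
    thr <- 1L
    while (mean(null_sizes >= thr) >= p) thr <- thr + 1L
    structure(list(z_thresh = z_thresh, min_cluster_voxels = thr,
                   null_sizes = null_sizes, p = p, n_iter = n_iter),
              class = "cluster_threshold")
  })
}

#' @export
print.cluster_threshold <- function(x, ...) {
  cat("Resampling cluster threshold (", x$n_iter, " iterations):\n", sep = "")
  cat("  |Z| >", x$z_thresh, "and cluster size >=", x$min_cluster_voxels,
      "voxels (P <", x$p, ")\n")
  invisible(x)
}

#' Conjunction of thresholded statistical maps
#'
#' Voxelwise intersection (logical AND) of surviving-voxel masks.
#'
#' @param masks List of logical arrays on the same grid.
#' @return Logical array.
#' @export
conjunction <- function(masks) {
  stopifnot(length(masks) >= 2)
  d <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) identical(dim(m), d), logical(1))))
    stop("masks are not on the same grid")
  Reduce(`&`, masks)
}
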