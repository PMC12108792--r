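#' @title GROMOS neighbor-counting trajectory clustering
#' @description Pairwise-RMSD clustering of trajectory frames by the greedy
#'   neighbor-counting rule: the frame with the most neighbors within the
#'   cutoff becomes a cluster center, it and its neighbors are removed, and
#'   the rule repeats on the remainder. Ties in neighbor count go to the
#'   lowest frame index so the partition is deterministic.
#' @name clustering
NULL

#' Pairwise superposed-RMSD matrix of a trajectory
#'
#' Entry (i, j) is the RMSD of the selected atoms between frames i and j,
#' after optimal rigid superposition when `superpose = TRUE`. Superposed
#' RMSD is not a metric, so only symmetry and nonnegativity are guaranteed.
#'
#' @param traj a Trajectory (>= 2 frames).
#' @param selection atom selection (indices or selector list); default all
#'   atoms.
#' @param superpose least-squares superpose each pair first?
#' @return object of class `RMSDMatrix`: list(n, values (nm), selection).
#' @export
rmsd_matrix <- function(traj, selection = NULL, superpose = TRUE) {
  nf <- n_frames(traj)
  if (nf < 2L) stop("need at least 2 frames")
  idx <- if (is.null(selection)) seq_len(n_atoms(traj$topology)) else
    resolve_selection(traj$topology, selection)
  if (length(idx) == 0L) stop("anchor error: empty selection")
  mats <- lapply(traj$frames, function(x) x[idx, , drop = FALSE])
  M <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      r <- if (superpose) kabsch(mats[[i]], mats[[j]])$rmsd
           else raw_rmsd(mats[[i]], mats[[j]])
      M[i, j] <- M[j, i] <- r * NM_PER_ANGSTROM
    }
  }
  structure(list(n = nf, values = M, selection = idx), class = "RMSDMatrix")
}

#' GROMOS clustering of an RMSD matrix
#'
#' @param matrix an [rmsd_matrix()] (or a plain symmetric matrix in nm).
#' @param cutoff neighbor cutoff in nm (default 0.45).
#' @return object of class `Clustering`: `clusters` is an ordered list of
#'   list(center = frame index, members = indices including the center),
#'   sorted by decreasing size with ties by lower center index; `cutoff`.
#' @export
gromos_cluster <- function(matrix, cutoff = 0.45) {
  M <- if (inherits(matrix, "RMSDMatrix")) matrix$values else as.matrix(matrix)
  stopifnot(nrow(M) == ncol(M), cutoff > 0)
  n <- nrow(M)
  remaining <- seq_len(n)
  clusters <- list()
  while (length(remaining) > 0L) {
    sub <- M[remaining, remaining, drop = FALSE]
    counts <- rowSums(sub <= cutoff)        # includes self
    center_pos <- which.max(counts)         # ties -> lowest index
    members <- remaining[sub[center_pos, ] <= cutoff]
    clusters[[length(clusters) + 1L]] <-
      list(center = remaining[center_pos], members = members)
    remaining <- setdiff(remaining, members)
  }
  sizes <- vapply(clusters, function(cl) length(cl$members), 0L)
  centers <- vapply(clusters, function(cl) cl$center, 0L)
  ord <- order(-sizes, centers)
  structure(list(clusters = clusters[ord], cutoff = cutoff, n = n),
            class = "Clustering")
}

#' @export
print.Clustering <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), 0L)
  cat(sprintf("<Clustering> %d frames -> %d clusters at %.2f nm (sizes: %s)\n",
              x$n, length(x$clusters), x$cutoff,
              paste(utils::head(sizes, 8L), collapse = ", ")))
  invisible(x)
}

#' Most-representative frame of a clustering
#'
#' Returns the center frame of the largest cluster (ties by lower center
#' index) as a StructureModel.
#'
#' @param clustering a [gromos_cluster()] result.
#' @param traj the Trajectory it was computed from.
#' @return StructureModel of the best cluster center.
#' @export
best_cluster_frame <- function(clustering, traj) {
  if (length(clustering$clusters) == 0L) stop("empty clustering")
  frame_model(traj, clustering$clusters[[1L]]$center)
}

#' Serialize a clustering as JSON
#' @param clustering a Clustering.
#' @param path output path.
#' @export
write_clustering <- function(clustering, path) {
  jsonlite::write_json(
    list(cutoff = clustering$cutoff, n_frames = clustering$n,
         clusters = lapply(clustering$clusters, function(cl)
           list(center = cl$center, size = length(cl$members),
                members = cl$members))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
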