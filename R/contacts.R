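#' Ligand part definition
#'
#' Splits the ligand atoms into three named, pairwise-disjoint groups:
#' `head` (the bulky aromatic moiety), `tail` (the aliphatic chain), and
#' `bridge` (the polar segment linking them).
#'
#' @param head,tail,bridge non-empty integer index vectors.
#' @return A list of class `ligand_parts`.
#' @export
ligand_parts <- function(head, tail, bridge) {
  parts <- list(head = as.integer(head), tail = as.integer(tail),
                bridge = as.integer(bridge))
  if (any(lengths(parts) == 0L)) stop("every ligand part must be non-empty")
  all_idx <- unlist(parts)
  if (anyDuplicated(all_idx)) stop("ligand parts must be pairwise disjoint")
  structure(parts, class = "ligand_parts")
}

#' Minimum residue-to-ligand-part distances in one frame
#'
#' Entry (r, p) is the minimum over all atom pairs of the Euclidean
#' distance between residue r and ligand part p.
#'
#' @param frame n x 3 coordinate matrix.
#' @param residues named list of non-empty atom-index vectors, one per
#'   residue.
#' @param parts a [ligand_parts()].
#' @return Numeric matrix, residues x parts (angstrom), with dimnames.
#' @export
part_min_distances <- function(frame, residues, parts) {
  stopifnot(inherits(parts, "ligand_parts"))
  frame <- as.matrix(frame)
  if (!length(residues) || any(lengths(residues) == 0L))
    stop("residues must be a non-empty list of non-empty index vectors")
  out <- matrix(NA_real_, length(residues), length(parts),
                dimnames = list(names(residues), names(parts)))
  for (p in seq_along(parts)) {
    pc <- frame[parts[[p]], , drop = FALSE]
    for (r in seq_along(residues)) {
      rc <- frame[residues[[r]], , drop = FALSE]
      d2 <- outer(rowSums(rc^2), rowSums(pc^2), "+") - 2 * rc %*% t(pc)
      out[r, p] <- sqrt(max(min(d2), 0))
    }
  }
  out
}

#' Logistic contact transform
#'
#' Maps a distance to a contact value in (-1, 1) through
#' `f(d) = 2 / (1 + exp((d - d0) / lam)) - 1`: +1 at contact, 0 at the
#' midpoint `d0`, -1 far away, strictly decreasing and odd around `d0`.
#'
#' @param d distance(s), angstrom.
#' @param d0 midpoint, angstrom. Default 4.5 (typical heavy-atom contact
#'   scale).
#' @param lam steepness, angstrom (> 0). Default 1.
#' @return Contact value(s) in (-1, 1).
#' @export
logistic_contact <- function(d, d0 = 4.5, lam = 1.0) {
  if (lam <= 0) stop("lam must be positive")
  2 / (1 + exp((d - d0) / lam)) - 1
}

#' Residue-ligand contact series over a trajectory
#'
#' For every frame, minimum distances from each residue to each ligand
#' part are passed through [logistic_contact()]; channels are labelled
#' `residue:part`.
#'
#' @param traj a [trajectory()].
#' @param residues named list of atom-index vectors (default: group the
#'   non-ligand atoms by residue number).
#' @param parts a [ligand_parts()].
#' @param d0,lam logistic parameters, see [logistic_contact()].
#' @return Numeric matrix time x channel of class `contact_series`.
#' @export
contact_series <- function(traj, residues = NULL, parts, d0 = 4.5, lam = 1.0) {
  stopifnot(inherits(traj, "trajectory"), inherits(parts, "ligand_parts"))
  if (is.null(residues)) {
    lig <- unlist(parts)
    prot <- setdiff(seq_len(n_atoms(traj)), lig)
    residues <- split(prot, traj$atoms$resno[prot])
    names(residues) <- paste0("R", names(residues))
  }
  nf <- n_frames(traj)
  labels <- as.vector(outer(names(residues), names(parts), paste, sep = ":"))
  out <- matrix(NA_real_, nf, length(labels), dimnames = list(NULL, labels))
  for (f in seq_len(nf)) {
    dm <- part_min_distances(get_frame(traj, f), residues, parts)
    out[f, ] <- as.vector(logistic_contact(dm, d0, lam))
  }
  structure(out, class = c("contact_series", "matrix"))
}

#' Covariance of a contact series
#'
#' Sample covariance over time between every pair of (residue, part)
#' channels; strongly co-varying channels indicate residues whose
#' interaction with the ligand switches together.
#'
#' @param series matrix time x channel (a `contact_series`).
#' @return Symmetric covariance matrix with channel dimnames.
#' @export
contact_covariance <- function(series) {
  m <- unclass(series)
  if (!is.matrix(m)) stop("series must be a time x channel matrix")
  if (nrow(m) < 2L) stop("need at least 2 time points for a covariance")
  cv <- cov(m)
  (cv + t(cv)) / 2
}

#' Hierarchical clustering of contact channels and residues
#'
#' Agglomerative (average-linkage) clustering of the contact-covariance
#' channels with distance `1 - cov / max|cov|`, cut at `n_clusters`.
#' Residues are then assigned the cluster of their strongest part
#' channel (largest maximum |covariance| with any other channel).
#'
#' @param cov covariance matrix from [contact_covariance()], with
#'   `residue:part` dimnames.
#' @param n_clusters number of clusters, between 1 and the number of
#'   channels.
#' @param linkage linkage method for [stats::hclust()]. Default
#'   "average".
#' @return List with `channel_clusters` (named integer vector),
#'   `residue_clusters` (named integer vector, when channel labels have
#'   the `residue:part` form), and the `hclust` tree.
#' @export
cluster_residues <- function(cov, n_clusters, linkage = "average") {
  if (!is.matrix(cov) || nrow(cov) != ncol(cov))
    stop("cov must be a square matrix")
  n <- nrow(cov)
  if (n_clusters < 1L || n_clusters > n)
    stop("n_clusters must be between 1 and the number of channels")
  scale <- max(abs(cov))
  d <- if (scale > 0) 1 - cov / scale else matrix(0, n, n)
  tree <- hclust(as.dist(d), method = linkage)
  channel <- cutree(tree, k = n_clusters)
  labels <- colnames(cov)
  if (!is.null(labels)) names(channel) <- labels

  residue_clusters <- NULL
  if (!is.null(labels) && all(grepl(":", labels))) {
    res <- sub(":.*", "", labels)
    offdiag <- abs(cov); diag(offdiag) <- 0
    strength <- apply(offdiag, 1L, max)
    residue_clusters <- vapply(split(seq_len(n), res), function(idx) {
      channel[idx[which.max(strength[idx])]]
    }, integer(1))
    # keep original residue order
    residue_clusters <- residue_clusters[unique(res)]
  }
  list(channel_clusters = channel, residue_clusters = residue_clusters,
       tree = tree)
}
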