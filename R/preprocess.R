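#' Filter probes on detection quality and a blacklist
#'
#' Removes probes whose detection p-value exceeds the threshold in more than
#' \code{max_fail_fraction} of samples (default 0: failure in any one sample
#' removes the probe, the strictest reading of a "detection P value > 0.01"
#' rule), then removes probes on a user-supplied blacklist (e.g. probes
#' overlapping common SNPs). Detection filtering is applied first, so the
#' two removal sets are disjoint and a probe failing both rules is counted
#' under detection.
#'
#' @param beta beta matrix (probes x samples).
#' @param detection_p optional same-shape matrix of detection p-values.
#' @param blacklist optional character vector of probe ids to drop;
#'   ids absent from the matrix produce a warning, not an error.
#' @param detection_threshold detection p threshold (default 0.01).
#' @param max_fail_fraction fraction of samples allowed to fail detection
#'   before the probe is dropped (default 0).
#' @return list with \code{beta} (filtered matrix) and \code{report}, a list
#'   with counts \code{n_input}, \code{n_removed_detection},
#'   \code{n_removed_blacklist}, \code{n_retained} and the removed ids by
#'   reason.
#' @export
filter_probes <- function(beta, detection_p = NULL, blacklist = NULL,
                          detection_threshold = 0.01,
                          max_fail_fraction = 0) {
  n_input <- nrow(beta)
  removed_detection <- character(0)
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(beta))) {
      stop("detection_p must have the same shape as beta")
    }
    if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE)) {
      stop("detection p-values must lie in [0, 1]")
    }
    fail_frac <- rowMeans(detection_p > detection_threshold)
    removed_detection <- rownames(beta)[fail_frac > max_fail_fraction]
  }
  keep <- setdiff(rownames(beta), removed_detection)
  removed_blacklist <- character(0)
  if (!is.null(blacklist) && length(blacklist) > 0) {
    unknown <- setdiff(blacklist, rownames(beta))
    if (length(unknown) > 0) {
      warning(length(unknown), " blacklist id(s) absent from the matrix")
    }
    removed_blacklist <- intersect(keep, blacklist)
    keep <- setdiff(keep, removed_blacklist)
  }
  out <- beta[keep, , drop = FALSE]
  report <- list(n_input = n_input,
                 n_removed_detection = length(removed_detection),
                 n_removed_blacklist = length(removed_blacklist),
                 n_retained = nrow(out),
                 removed_detection = removed_detection,
                 removed_blacklist = removed_blacklist)
  stopifnot(report$n_input ==
            report$n_retained + report$n_removed_detection +
            report$n_removed_blacklist)
  list(beta = out, report = report)
}

#' Classical MDS of samples over a probe subset
#'
#' Torgerson (classical metric) multidimensional scaling of the samples,
#' using Euclidean distances between their beta-value vectors over the given
#' probe subset — typically the CpGs significant in the differential
#' analysis. Deterministic up to the sign of each axis.
#'
#' @param beta beta matrix.
#' @param probe_subset probe ids defining the distance space; non-empty.
#' @param k number of dimensions (default 3); must be <= n_samples - 1.
#' @return list with \code{points} (samples x k coordinates) and \code{eig}
#'   (eigenvalues).
#' @export
mds_embed <- function(beta, probe_subset, k = 3) {
  if (length(probe_subset) == 0) stop("probe_subset must be non-empty")
  if (!all(probe_subset %in% rownames(beta))) {
    stop("probe_subset contains ids absent from the beta matrix")
  }
  ns <- ncol(beta)
  if (k > ns - 1) stop("k must be at most n_samples - 1")
  d <- stats::dist(t(beta[probe_subset, , drop = FALSE]))
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < k) {  # degenerate geometry: pad zero axes
    pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  }
  rownames(pts) <- colnames(beta)
  list(points = pts, eig = fit$eig)
}
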