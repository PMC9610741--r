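# Rigid superposition (Kabsch) and coarse-grain -> full-atom backmapping.
# The atomistic pose is recovered by least-squares fitting the reference
# C-alpha set onto the coarse-grained backbone beads and applying that
# single rigid transform to the whole reference structure.

#' Optimal rigid superposition of two point sets
#'
#' Least-squares proper rotation + translation taking `moving` onto
#' `target` (Kabsch, SVD form with the smallest singular vector
#' sign-corrected so reflections are never returned).
#'
#' @param moving,target N x 3 coordinate matrices, N >= 3, non-collinear.
#' @return Object of class `rigid_fit`: `rotation` (3 x 3, det +1),
#'   `translation` (applied after rotation), `rmsd_nm`, `n_points`.
#' @export
kabsch_fit <- function(moving, target) {
  moving <- as.matrix(moving); target <- as.matrix(target)
  if (nrow(moving) != nrow(target) || ncol(moving) != 3 || ncol(target) != 3)
    stop("moving and target must be N x 3 with equal N")
  n <- nrow(moving)
  if (n < 3) stop("need at least 3 points for a rigid fit")
  cm <- colMeans(moving); ct <- colMeans(target)
  P <- sweep(moving, 2, cm)
  Q <- sweep(target, 2, ct)
  sv <- svd(crossprod(P, Q))          # H = P^T Q = U D V^T
  if (sv$d[2] < 1e-12)
    stop("degenerate (collinear) point set: rotation is not determined")
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(list(rotation = R, translation = as.numeric(ct - R %*% cm),
                 rmsd_nm = rmsd, n_points = n),
            class = "rigid_fit")
}

#' Apply a rigid fit to coordinates
#'
#' @param fit a `rigid_fit`.
#' @param xyz N x 3 coordinates.
#' @return Transformed N x 3 coordinates.
#' @export
apply_fit <- function(fit, xyz) {
  stopifnot(inherits(fit, "rigid_fit"))
  sweep(as.matrix(xyz) %*% t(fit$rotation), 2, fit$translation, "+")
}

#' @export
print.rigid_fit <- function(x, ...) {
  cat(sprintf("<rigid_fit> %d points, rmsd %.4g nm\n", x$n_points, x$rmsd_nm))
  invisible(x)
}

#' Backmap a coarse-grained pose onto an atomistic reference
#'
#' Pairs the reference C-alpha atoms with the coarse-grained backbone beads
#' by residue index, computes the optimal rigid fit of the C-alpha set onto
#' the beads, and applies the transform to the entire reference structure.
#' A single rigid body suffices when the internal structure barely changed
#' during the coarse-grained run; the residual C-alpha/bead rmsd is
#' reported so that assumption can be checked.
#'
#' @param fa_reference atomistic `md_structure`; its protein "CA" atoms are
#'   the fit set.
#' @param cg_frame n x 3 coordinate matrix of the coarse-grained frame, nm.
#' @param cg_topology `md_structure` of the coarse-grained system; its
#'   protein "BB" beads are the fit targets.
#' @return The posed atomistic `md_structure`, with attribute `fit` (the
#'   `rigid_fit`).
#' @export
backmap_protein <- function(fa_reference, cg_frame, cg_topology) {
  stopifnot(inherits(fa_reference, "md_structure"),
            inherits(cg_topology, "md_structure"))
  fa <- fa_reference$particles
  ca_sel <- fa$segment == "protein" & toupper(fa$name) == "CA"
  cg <- cg_topology$particles
  bb_sel <- cg$segment == "protein" & toupper(cg$name) %in% c("BB", "CA")
  ca_res <- fa$residue_index[ca_sel]
  bb_res <- cg$residue_index[bb_sel]
  unmatched <- c(setdiff(ca_res, bb_res), setdiff(bb_res, ca_res))
  if (length(unmatched))
    stop("C-alpha/backbone residue sets differ; unmatched residues: ",
         paste(sort(unique(unmatched)), collapse = ", "))
  ord_ca <- which(ca_sel)[order(ca_res)]
  ord_bb <- which(bb_sel)[order(bb_res)]
  fit <- kabsch_fit(as.matrix(fa[ord_ca, c("x", "y", "z")]),
                    cg_frame[ord_bb, , drop = FALSE])
  posed <- set_coords(fa_reference, apply_fit(fit, coords(fa_reference)))
  attr(posed, "fit") <- fit
  posed
}
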