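#' Orthogonal Procrustes fit of a gradient set to a reference
#'
#' Finds the orthogonal n x n matrix T minimizing ||A T - B||_F between a
#' subject gradient matrix A (parcels x n) and a reference B of the same
#' shape, via SVD of the cross-covariance C = (B'A)' = A'B: C = U S V',
#' T = U V' (the Schoenemann closed-form solution). No centering and no
#' isotropic scaling are applied, and the reference is never updated from
#' the subjects (pairwise, not generalized, Procrustes).
#'
#' @param A,B numeric matrices or \code{\link{gradient_set}} objects with
#'   equal dimensions (m parcels x n components).
#' @return object of class \code{procrustes_result}: list with
#'   \code{transform} (T), \code{singular_values} (descending, of C),
#'   \code{cross_covariance} (C), \code{u}, \code{v}, \code{n_align}.
#' @export
fit_procrustes <- function(A, B) {
  A <- .grad_matrix(A)
  B <- .grad_matrix(B)
  if (!all(dim(A) == dim(B))) stop("A and B must have equal dimensions")
  C <- crossprod(A, B)  # (B'A)' = A'B
  sv <- svd(C)
  if (min(sv$d) < 1e-12 * max(sv$d, 1))
    warning("rank-deficient cross-covariance; transform defined via SVD convention")
  structure(list(transform = sv$u %*% t(sv$v), singular_values = sv$d,
                 cross_covariance = C, u = sv$u, v = sv$v,
                 n_align = ncol(A)),
            class = "procrustes_result")
}

.grad_matrix <- function(x) {
  if (inherits(x, "gradient_set")) x$components else as.matrix(x)
}

#' Apply a Procrustes transformation
#'
#' Replaces the components of \code{A} by \code{A T}; eigenvalue metadata is
#' carried through unchanged and the result is flagged as aligned.
#'
#' @param A \code{\link{gradient_set}} (or matrix).
#' @param result \code{procrustes_result} from \code{\link{fit_procrustes}}.
#' @return aligned \code{\link{gradient_set}} (or matrix if \code{A} was one).
#' @export
apply_transform <- function(A, result) {
  m <- .grad_matrix(A)
  if (ncol(m) != nrow(result$transform)) stop("dimension mismatch with transform")
  out <- m %*% result$transform
  if (inherits(A, "gradient_set")) {
    A$components <- out
    A$aligned <- TRUE
    A
  } else out
}

#' Correspondence between the unaligned and aligned principal gradient
#'
#' The ratio of the maximum to the sum of absolute values in the first
#' column of the transformation matrix. Values near 1 mean a single
#' unaligned gradient dominates the aligned principal gradient; values near
#' 1/n mean a distributed adjustment over all gradients used.
#'
#' @param result \code{procrustes_result}.
#' @return scalar in [1/n, 1].
#' @export
correspondence <- function(result) {
  col1 <- abs(result$transform[, 1])
  s <- sum(col1)
  if (s == 0) stop("all-zero first column: corrupted transformation matrix")
  max(col1) / s
}

#' Transformation-magnitude descriptors
#'
#' Heuristic magnitudes of the Procrustes transformation: the sum of
#' absolute values over the whole transformation matrix (total) and over its
#' first column (the column that determines the aligned principal gradient).
#' Note that for a 2 x 2 rotation this quantity is non-monotone in the
#' rotation angle; it is an exploratory descriptor of relative change.
#'
#' @param result \code{procrustes_result}.
#' @return list with \code{trans_total} and \code{trans_pg}.
#' @export
transformation_magnitudes <- function(result) {
  list(trans_total = sum(abs(result$transform)),
       trans_pg = sum(abs(result$transform[, 1])))
}

#' Subspace similarity between two gradient sets
#'
#' Two complementary descriptors of the similarity between the column spans
#' of A and B: the l2-norm of the raw singular values of the Procrustes
#' cross-covariance (high when the subspaces are similar), and the principal
#' angles between the orthonormalized column spans (Bjorck-Golub: arccos of
#' the singular values of Qa' Qb, clipped to [0, 1]) summarized by their
#' l2-norm (low when the subspaces are similar).
#'
#' @param A,B matrices or \code{\link{gradient_set}} objects, m x n.
#' @return list with \code{w_norm}, \code{theta_vector} (radians, ascending)
#'   and \code{theta_norm}.
#' @export
subspace_similarity <- function(A, B) {
  Am <- .grad_matrix(A)
  Bm <- .grad_matrix(B)
  if (!all(dim(Am) == dim(Bm))) stop("A and B must have equal dimensions")
  n <- ncol(Am)
  if (qr(Am)$rank < n) stop("rank-deficient gradient set A")
  if (qr(Bm)$rank < n) stop("rank-deficient gradient set B")
  w <- svd(crossprod(Am, Bm), nu = 0, nv = 0)$d
  qa <- qr.Q(qr(Am))
  qb <- qr.Q(qr(Bm))
  s <- svd(crossprod(qa, qb), nu = 0, nv = 0)$d
  s <- pmin(pmax(s, 0), 1)
  theta <- sort(acos(s))
  list(w_norm = sqrt(sum(w^2)), theta_vector = theta,
       theta_norm = sqrt(sum(theta^2)))
}

#' Align a subject gradient set to a reference
#'
#' Selects the first \code{n_align} components of both sets (or an explicit
#' ordered index subset, e.g. 20:k for a reversed cumulative analysis), fits
#' the orthogonal Procrustes transformation, applies it, and computes the
#' full panel of alignment diagnostics. Downstream analyses consume only the
#' first column of the aligned set (the aligned principal gradient).
#'
#' @param subject,reference \code{\link{gradient_set}} objects with at least
#'   \code{n_align} components (or covering \code{component_indices}).
#' @param n_align number of gradients used in alignment.
#' @param component_indices optional ordered index vector overriding
#'   \code{1:n_align}.
#' @return list with \code{aligned} (\code{gradient_set}), \code{result}
#'   (\code{procrustes_result}) and \code{diagnostics} (list:
#'   \code{correspondence}, \code{trans_total}, \code{trans_pg},
#'   \code{w_norm}, \code{theta_norm}, \code{n_align}).
#' @export
align_to_reference <- function(subject, reference, n_align,
                               component_indices = NULL) {
  idx <- if (is.null(component_indices)) seq_len(n_align) else as.integer(component_indices)
  if (max(idx) > ncol(subject$components) || max(idx) > ncol(reference$components))
    stop("n_align / component_indices exceed available components")
  A <- subject$components[, idx, drop = FALSE]
  B <- reference$components[, idx, drop = FALSE]
  res <- fit_procrustes(A, B)
  aligned <- subject
  aligned$components <- A %*% res$transform
  aligned$eigenvalues <- subject$eigenvalues[idx]
  aligned$aligned <- TRUE
  aligned$params <- c(subject$params, list(n_align = length(idx),
                                           component_indices = idx))
  mags <- transformation_magnitudes(res)
  sub <- subspace_similarity(A, B)
  diagnostics <- list(correspondence = correspondence(res),
                      trans_total = mags$trans_total,
                      trans_pg = mags$trans_pg,
                      w_norm = sub$w_norm,
                      theta_norm = sub$theta_norm,
                      n_align = length(idx))
  list(aligned = aligned, result = res, diagnostics = diagnostics)
}
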