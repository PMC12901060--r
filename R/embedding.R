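#' Gradient set container
#'
#' A set of connectivity gradients: a parcels x components matrix with the
#' eigenvalue (or explained-variance) spectrum of the spectral embedding that
#' produced it. Columns are ordered by decreasing importance: descending
#' eigenvalue for diffusion map embedding and PCA, ascending Laplacian
#' eigenvalue for Laplacian eigenmaps.
#'
#' @param components P x K numeric matrix.
#' @param eigenvalues length-K numeric vector.
#' @param method one of \code{"dm"}, \code{"pca"}, \code{"le"}.
#' @param params list of provenance (kernel, sparsity, ...).
#' @param subject_id,session_id identifiers (\code{"reference"} for a group
#'   reference set).
#' @param aligned logical provenance flag.
#' @return object of class \code{gradient_set}.
#' @export
gradient_set <- function(components, eigenvalues, method,
                         params = list(), subject_id = NA_character_,
                         session_id = NA_character_, aligned = FALSE) {
  components <- as.matrix(components)
  if (ncol(components) != length(eigenvalues))
    stop("column count must equal eigenvalue count")
  if (anyNA(components) || anyNA(eigenvalues))
    stop("gradient set contains missing values")
  structure(list(components = components, eigenvalues = as.numeric(eigenvalues),
                 method = method, params = params, subject_id = subject_id,
                 session_id = session_id, aligned = aligned),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("gradient_set: %d parcels x %d components (%s%s)\n",
              nrow(x$components), ncol(x$components), x$method,
              if (isTRUE(x$aligned)) ", aligned" else ""))
  invisible(x)
}

#' Row-wise sparsification of a connectivity matrix
#'
#' Within each row independently, entries strictly below that row's
#' \code{sparsity} quantile are set to 0; surviving entries keep their
#' values. The output need not be symmetric.
#'
#' @param fc P x P numeric matrix.
#' @param sparsity fraction in [0, 1) of entries to drop per row.
#' @return sparsified P x P matrix.
#' @export
sparsify_rows <- function(fc, sparsity) {
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must be in [0, 1)")
  fc <- as.matrix(fc)
  if (sparsity == 0) return(fc)
  thr <- apply(fc, 1L, stats::quantile, probs = sparsity, type = 7)
  out <- fc
  out[fc < thr[row(fc)]] <- 0
  out
}

# rank with average ties, matching the usual Spearman definition
.colwise_ranks <- function(m) apply(m, 1L, rank)  # returns P x P with ranks per row in columns

#' Affinity matrix between sparsified connectivity rows
#'
#' Computes A(i, j) between row vectors i and j of \code{m} under the named
#' kernel: \code{gaussian} exp(-gamma * ||x - y||^2); \code{cosine}
#' x.y/(||x|| ||y||); \code{normalized_angle} 1 - acos(cossim)/pi;
#' \code{pearson} the correlation of the rows; \code{spearman} the
#' correlation of within-row ranks; \code{none} passes the matrix through
#' unchanged.
#'
#' @param m P x P matrix (typically the output of
#'   \code{\link{sparsify_rows}}).
#' @param kernel_name kernel identifier.
#' @param gamma inverse kernel width for the Gaussian kernel; defaults to
#'   1/P when unspecified.
#' @return list of class \code{affinity_matrix} with \code{values},
#'   \code{kernel_name}, \code{gamma}.
#' @export
affinity <- function(m, kernel_name = c("normalized_angle", "gaussian", "cosine",
                                        "pearson", "spearman", "none"),
                     gamma = NULL) {
  kernel_name <- match.arg(kernel_name)
  m <- as.matrix(m)
  p <- nrow(m)
  vals <- switch(kernel_name,
    none = m,
    gaussian = {
      if (is.null(gamma)) gamma <- 1 / p
      sq <- rowSums(m^2)
      d2 <- outer(sq, sq, "+") - 2 * tcrossprod(m)
      d2[d2 < 0] <- 0
      exp(-gamma * d2)
    },
    cosine = .cosine_sim(m),
    normalized_angle = {
      cs <- .cosine_sim(m)
      cs <- pmin(pmax(cs, -1), 1)
      1 - acos(cs) / pi
    },
    pearson = stats::cor(t(m)),
    spearman = stats::cor(t(m), method = "spearman")
  )
  if (kernel_name %in% c("cosine", "normalized_angle")) {
    nrm <- sqrt(rowSums(m^2))
    if (any(nrm == 0)) stop("zero-norm row(s): ", paste(which(nrm == 0), collapse = ", "))
  }
  if (kernel_name %in% c("pearson", "spearman") && anyNA(vals))
    stop("constant row(s) give undefined correlation affinity")
  vals <- (vals + t(vals)) / 2  # enforce exact symmetry
  structure(list(values = vals, kernel_name = kernel_name,
                 gamma = if (kernel_name == "gaussian") gamma else NULL),
            class = "affinity_matrix")
}

.cosine_sim <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("zero-norm row(s): ", paste(which(nrm == 0), collapse = ", "))
  tcrossprod(m / nrm)
}

# non-negative symmetric matrix for spectral methods; clip negatives to 0
.spectral_weights <- function(aff) {
  w <- if (inherits(aff, "affinity_matrix")) aff$values else as.matrix(aff)
  if (max(abs(w - t(w))) > 1e-8) stop("affinity matrix is not symmetric")
  w[w < 0] <- 0
  w
}

# connected-components check on the support graph (simple BFS)
.check_connected <- function(w) {
  p <- nrow(w)
  adj <- w > 0
  diag(adj) <- TRUE
  seen <- logical(p)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  if (!all(seen))
    stop("affinity graph is disconnected; lower the sparsity or change the kernel")
}

# orient each column so its maximum-absolute entry is positive
# (ties broken by lowest parcel index); removes eigenvector sign ambiguity
.fix_signs <- function(v) {
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  v
}

#' Diffusion map embedding of an affinity matrix
#'
#' Anisotropic normalization with alpha = 0.5 (W = D^-a A D^-a), conversion
#' to a transition operator, eigendecomposition via the symmetric conjugate,
#' removal of the trivial constant eigenvector and scaling of the remaining
#' eigenvectors by lambda/(1 - lambda) (automatic diffusion time).
#'
#' @param aff \code{affinity_matrix} (or non-negative symmetric matrix).
#' @param n_components number of gradients to return.
#' @param alpha anisotropic normalization exponent (default 0.5).
#' @return \code{\link{gradient_set}} with method \code{"dm"} and
#'   eigenvalues strictly decreasing in (0, 1).
#' @export
diffusion_map <- function(aff, n_components, alpha = 0.5) {
  w <- .spectral_weights(aff)
  .check_connected(w)
  d <- rowSums(w)
  w1 <- w / outer(d^alpha, d^alpha)
  d1 <- rowSums(w1)
  ms <- w1 / sqrt(outer(d1, d1))
  ms <- (ms + t(ms)) / 2
  e <- eigen(ms, symmetric = TRUE)
  psi <- e$vectors / sqrt(d1)          # right eigenvectors of the transition operator
  psi <- psi / psi[, 1]                # normalize against the trivial eigenvector
  lam <- e$values
  keep <- which(lam[-1] > 1e-12) + 1L  # drop trivial lambda ~ 1, reject degenerate
  if (length(keep) < n_components)
    stop("fewer than n_components non-degenerate diffusion eigenvalues")
  keep <- keep[seq_len(n_components)]
  lam_k <- lam[keep]
  comp <- psi[, keep, drop = FALSE] * rep(lam_k / (1 - lam_k), each = nrow(psi))
  comp <- .fix_signs(comp)
  gradient_set(comp, lam_k, method = "dm", params = list(alpha = alpha))
}

#' PCA embedding
#'
#' Standard principal component scores of the (column-centred) input matrix:
#' left singular vectors scaled by their singular values. Eigenvalues are
#' the explained variances, descending.
#'
#' @param m P x P numeric matrix (rows are observations).
#' @param n_components number of components, at most P.
#' @return \code{\link{gradient_set}} with method \code{"pca"}.
#' @export
pca_embed <- function(m, n_components) {
  m <- if (inherits(m, "affinity_matrix")) m$values else as.matrix(m)
  if (n_components > ncol(m)) stop("n_components exceeds matrix dimension")
  x <- scale(m, center = TRUE, scale = FALSE)
  sv <- svd(x, nu = n_components, nv = 0)
  comp <- sv$u * rep(sv$d[seq_len(n_components)], each = nrow(x))
  comp <- .fix_signs(comp)
  expl <- sv$d[seq_len(n_components)]^2 / (nrow(x) - 1)
  gradient_set(comp, expl, method = "pca")
}

#' Laplacian eigenmaps embedding
#'
#' Solves the generalized eigenproblem L v = lambda D v with L = D - A,
#' drops the trivial constant eigenvector (lambda = 0) and returns the
#' eigenvectors of smallest nonzero eigenvalue, most important (smallest
#' lambda) first.
#'
#' @inheritParams diffusion_map
#' @return \code{\link{gradient_set}} with method \code{"le"}; eigenvalues
#'   ascending in (0, 2].
#' @export
laplacian_eigenmaps <- function(aff, n_components) {
  w <- .spectral_weights(aff)
  .check_connected(w)
  d <- rowSums(w)
  lsym <- diag(nrow(w)) - w / sqrt(outer(d, d))
  lsym <- (lsym + t(lsym)) / 2
  e <- eigen(lsym, symmetric = TRUE)
  lam <- rev(e$values)                       # ascending
  vec <- e$vectors[, rev(seq_along(lam)), drop = FALSE]
  keep <- which(lam > 1e-12)
  if (length(keep) < n_components)
    stop("fewer than n_components nonzero Laplacian eigenvalues")
  keep <- keep[seq_len(n_components)]
  comp <- (vec / sqrt(d))[, keep, drop = FALSE]
  comp <- .fix_signs(comp)
  gradient_set(comp, lam[keep], method = "le")
}

#' Extract connectivity gradients from an FC matrix
#'
#' Composition of \code{\link{sparsify_rows}}, \code{\link{affinity}} and the
#' chosen spectral reduction, with the deterministic sign convention (each
#' component oriented so its maximum-absolute entry is positive). The
#' field-standard parameterization is \code{normalized_angle} kernel,
#' sparsity 0.9 and diffusion map embedding.
#'
#' @param fc P x P functional connectivity matrix.
#' @param kernel_name affinity kernel (see \code{\link{affinity}}).
#' @param sparsity row-wise sparsification fraction in [0, 1).
#' @param approach one of \code{"dm"}, \code{"pca"}, \code{"le"}.
#' @param n_components number of gradients to extract.
#' @param gamma Gaussian kernel width (optional).
#' @param subject_id,session_id provenance identifiers.
#' @return \code{\link{gradient_set}} carrying full parameter provenance.
#' @export
extract_gradients <- function(fc, kernel_name = "normalized_angle",
                              sparsity = 0.9, approach = c("dm", "pca", "le"),
                              n_components = 20, gamma = NULL,
                              subject_id = NA_character_,
                              session_id = NA_character_) {
  approach <- match.arg(approach)
  sp <- sparsify_rows(fc, sparsity)
  aff <- affinity(sp, kernel_name, gamma = gamma)
  g <- switch(approach,
              dm = diffusion_map(aff, n_components),
              pca = pca_embed(aff, n_components),
              le = laplacian_eigenmaps(aff, n_components))
  g$params <- c(g$params, list(kernel = aff$kernel_name, sparsity = sparsity,
                               approach = approach, n_components = n_components))
  g$subject_id <- subject_id
  g$session_id <- session_id
  rownames(g$components) <- rownames(as.matrix(fc))
  g
}

#' Write / read a gradient set as delimited text
#'
#' The file carries a header block of \code{# key: value} lines (method,
#' kernel, sparsity, subject, session, aligned, eigenvalues) followed by a
#' tab-separated parcels x components matrix.
#'
#' @param g \code{\link{gradient_set}}.
#' @param path output file.
#' @return \code{write_gradient_set} returns \code{path} invisibly;
#'   \code{read_gradient_set} the reconstructed \code{gradient_set}.
#' @export
write_gradient_set <- function(g, path) {
  stopifnot(inherits(g, "gradient_set"))
  hdr <- c(
    paste0("# method: ", g$method),
    paste0("# kernel: ", if (is.null(g$params$kernel)) "NA" else g$params$kernel),
    paste0("# sparsity: ", if (is.null(g$params$sparsity)) "NA" else g$params$sparsity),
    paste0("# subject_id: ", g$subject_id),
    paste0("# session_id: ", g$session_id),
    paste0("# aligned: ", isTRUE(g$aligned)),
    paste0("# eigenvalues: ",
           paste(format(g$eigenvalues, digits = 17, trim = TRUE), collapse = "\t")))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(g$components, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_gradient_set
#' @export
read_gradient_set <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  val <- function(key) sub(paste0("^# ", key, ": "), "",
                           grep(paste0("^# ", key, ":"), hdr, value = TRUE))
  ev <- as.numeric(strsplit(val("eigenvalues"), "\t")[[1]])
  body <- lines[!startsWith(lines, "# ")]
  comp <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  kernel <- val("kernel"); sparsity <- val("sparsity")
  gradient_set(comp, ev, method = val("method"),
               params = list(kernel = if (kernel == "NA") NULL else kernel,
                             sparsity = if (sparsity == "NA") NULL
                                        else as.numeric(sparsity)),
               subject_id = val("subject_id"), session_id = val("session_id"),
               aligned = identical(val("aligned"), "TRUE"))
}
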