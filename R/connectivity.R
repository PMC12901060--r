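#' Functional connectivity from a parcellated time series
#'
#' Computes the pairwise Pearson correlation between parcel (column) time
#' series, the standard subject-by-session functional connectivity (FC)
#' matrix. The diagonal is set to exactly 1.
#'
#' @param ts Numeric matrix, frames x parcels (T x P). Column names, when
#'   present, are carried over as parcel labels.
#' @return P x P symmetric correlation matrix with unit diagonal.
#' @export
pearson_fc <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L || ncol(ts) < 2L)
    stop("time series must have at least 3 frames and 2 parcels")
  if (anyNA(ts)) stop("time series contains missing values")
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    labs <- colnames(ts)[bad]
    if (is.null(labs)) labs <- as.character(bad)
    stop("zero-variance parcel(s): ", paste(labs, collapse = ", "))
  }
  fc <- stats::cor(ts)
  diag(fc) <- 1
  fc
}

#' Fisher r-to-z transform
#'
#' Correlations with absolute value >= 1 are clipped to +/- (1 - 1e-7) with a
#' warning so that group averaging stays finite.
#'
#' @param r numeric vector of correlations.
#' @return atanh(r) after clipping.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("correlation(s) with |r| >= 1 clipped to +/-(1 - 1e-7) before atanh")
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  }
  atanh(r)
}

#' Inverse Fisher transform
#' @param z numeric vector.
#' @return tanh(z).
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Group-average functional connectivity
#'
#' Averages FC matrices in Fisher z space: off-diagonal entries are
#' z-transformed, averaged elementwise, and mapped back through tanh. The
#' diagonal is set to 1.
#'
#' @param matrices list of P x P FC matrices with matching dimensions.
#' @return P x P group-average FC matrix.
#' @export
group_mean_fc <- function(matrices) {
  if (!length(matrices)) stop("empty list of connectivity matrices")
  dims <- vapply(matrices, function(m) dim(m), integer(2))
  if (any(dims != dims[1, 1])) stop("connectivity matrices differ in dimension")
  zsum <- 0
  for (m in matrices) {
    m <- as.matrix(m)
    diag(m) <- 0
    zsum <- zsum + fisher_z(m)
  }
  avg <- inverse_fisher_z(zsum / length(matrices))
  diag(avg) <- 1
  dimnames(avg) <- dimnames(matrices[[1]])
  avg
}

#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style FD: sum of absolute backward differences of the three
#' translations (mm) plus the three rotations (radians) converted to arc
#' length on a sphere of radius \code{head_radius}. FD is undefined at the
#' first frame and set to 0 there; \code{mean_fd} excludes the first frame.
#'
#' @param translations T x 3 matrix, mm.
#' @param rotations T x 3 matrix, radians.
#' @param head_radius sphere radius in mm used to convert rotations
#'   (default 50).
#' @return object of class \code{motion_series}: list with
#'   \code{translations}, \code{rotations}, \code{fd_series}, \code{mean_fd}.
#' @export
framewise_displacement <- function(translations, rotations, head_radius = 50) {
  translations <- as.matrix(translations)
  rotations <- as.matrix(rotations)
  if (ncol(translations) != 3L || ncol(rotations) != 3L)
    stop("translations and rotations must each have 3 columns")
  if (nrow(translations) != nrow(rotations))
    stop("translations and rotations must have equal frame counts")
  dt <- abs(diff(translations))
  dr <- abs(diff(rotations)) * head_radius
  fd <- c(0, rowSums(dt) + rowSums(dr))
  motion_series(translations = translations, rotations = rotations,
                fd_series = fd)
}

#' Motion series container
#'
#' @param fd_series length-T non-negative FD values in mm; the first entry
#'   must be 0 (FD is undefined at frame 1).
#' @param translations,rotations optional T x 3 rigid-body parameter
#'   matrices.
#' @return list of class \code{motion_series} with \code{mean_fd}, the mean
#'   of \code{fd_series[-1]}.
#' @export
motion_series <- function(fd_series, translations = NULL, rotations = NULL) {
  fd_series <- as.numeric(fd_series)
  if (length(fd_series) < 2L) stop("fd_series must have length >= 2")
  if (fd_series[1] != 0) stop("fd_series[1] must be 0 (FD undefined at frame 1)")
  if (any(fd_series < 0)) stop("fd_series must be non-negative")
  structure(list(translations = translations, rotations = rotations,
                 fd_series = fd_series, mean_fd = mean(fd_series[-1])),
            class = "motion_series")
}

upper_tri_vec <- function(m) m[upper.tri(m)]

#' Typicality of functional connectivity (TFC)
#'
#' TFC_i = (1 + r(FC_i, FCbar)) / 2 where r is the Pearson correlation of the
#' vectorized upper-triangle off-diagonal entries of the subject and
#' group-average FC matrices. Bounded in [0, 1]; low values flag atypical
#' (often high-motion) connectivity.
#'
#' @param fc subject FC matrix.
#' @param group_fc group-average FC matrix of matching dimension.
#' @return scalar in [0, 1].
#' @export
tfc <- function(fc, group_fc) {
  if (!all(dim(fc) == dim(group_fc))) stop("dimension mismatch between fc and group_fc")
  a <- upper_tri_vec(as.matrix(fc))
  b <- upper_tri_vec(as.matrix(group_fc))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant upper triangle: correlation undefined")
  (1 + stats::cor(a, b)) / 2
}

#' Parcel-wise BOLD-FD correlations
#'
#' Correlates each parcel's time series with the framewise-displacement
#' series, dropping the first frame (where FD is undefined). Used to check
#' for residual motion signal in denoised data: for independent series the
#' pooled distribution is centred at 0 with standard deviation approximately
#' 1/sqrt(T - 3).
#'
#' @param ts frames x parcels matrix.
#' @param motion \code{motion_series} with \code{fd_series} of length
#'   \code{nrow(ts)}.
#' @return length-P vector of correlations; parcels with zero variance are
#'   returned as \code{NA} (flagged for exclusion downstream).
#' @export
bold_fd_correlations <- function(ts, motion) {
  ts <- as.matrix(ts)
  fd <- motion$fd_series
  if (length(fd) != nrow(ts)) stop("fd_series length does not match frame count")
  fd <- fd[-1]
  x <- ts[-1, , drop = FALSE]
  if (stats::sd(fd) == 0) stop("constant FD series: correlation undefined")
  sds <- apply(x, 2L, stats::sd)
  out <- rep(NA_real_, ncol(x))
  ok <- sds > 0
  if (any(ok)) out[ok] <- drop(stats::cor(x[, ok, drop = FALSE], fd))
  names(out) <- colnames(ts)
  out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares the shapes of two samples of correlation values, optionally after
#' mapping both through the Fisher r-to-z transform (the transform is
#' monotone, so D is unchanged, but it matches how such comparisons are
#' reported).
#'
#' @param sample_a,sample_b numeric vectors.
#' @param fisher_transform apply \code{\link{fisher_z}} to both samples first.
#' @return list with \code{statistic} (D) and \code{p_value} (asymptotic).
#' @export
ks_compare <- function(sample_a, sample_b, fisher_transform = FALSE) {
  if (!length(sample_a) || !length(sample_b)) stop("empty sample")
  if (fisher_transform) {
    sample_a <- fisher_z(sample_a)
    sample_b <- fisher_z(sample_b)
  }
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}
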