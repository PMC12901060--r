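#' Parameterization of the synthetic multi-session cohort generator
#'
#' Defines the generative model used to emulate the statistical structure of
#' a multi-session resting-state cohort: each subject owns a gradient basis
#' derived from a common group basis by a small random parcel-space rotation
#' (direction partly linked to a latent age factor); each session perturbs it
#' with arbitrary sign flips, adjacent-component swaps and a component-space
#' rotation, emulating the sign/order/rotation instability of independent
#' per-session gradient extraction; a per-subject motion level produces an
#' autocorrelated framewise-displacement trace and injects motion-coupled
#' rotations into the connectivity structure, preferentially (weight
#' \code{trailing_emphasis}) within the span of components 2..K.
#'
#' @param n_subjects,n_parcels,n_sessions,n_latent,n_frames cohort sizes
#'   (P parcels, K generative components, T frames; K < P, T >= 30).
#' @param eigen_decay geometric decay rate of the component variances.
#' @param subject_rotation_scale,session_rotation_scale rotation angle scales
#'   in radians: the subject rotation acts in parcel space (stable individual
#'   differences), the session rotation in component space (extraction
#'   instability alignment can correct).
#' @param motion_location,motion_scale location and spread (mm) of the
#'   per-subject mean-FD distribution.
#' @param motion_coupling strength (beta) with which subject motion perturbs
#'   the connectivity structure.
#' @param trailing_emphasis fraction in [0, 1] of the motion perturbation
#'   directed at components beyond the first.
#' @param noise_sd standard deviation of additive white measurement noise.
#' @param flip_prob per-component probability of a sign flip and of an
#'   adjacent swap in the subject basis.
#' @param phenotype_model list of coefficients linking a latent age factor
#'   to mean FD, a fluid-intelligence-like score and the subject rotation
#'   direction: \code{age_mean}, \code{age_sd}, \code{fd_age} (correlation
#'   of motion with the age factor), \code{score_age} (slope of score on the
#'   age factor), \code{score_sd}, \code{gradient_age} (weight of the shared
#'   age-linked rotation direction).
#' @param seed integer RNG seed.
#' @return list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 60, n_parcels = 100, n_sessions = 2,
                        n_latent = 20, n_frames = 300, eigen_decay = 0.8,
                        subject_rotation_scale = 0.4,
                        session_rotation_scale = 0.2,
                        motion_location = 0.15, motion_scale = 0.08,
                        motion_coupling = 1.5, trailing_emphasis = 0.8,
                        noise_sd = 0.3, flip_prob = 0.3,
                        phenotype_model = list(age_mean = 50, age_sd = 15,
                                               fd_age = 0.5, score_age = -10,
                                               score_sd = 5,
                                               gradient_age = 0.7),
                        seed = 1L) {
  stopifnot(n_latent < n_parcels, n_frames >= 30, n_subjects >= 1,
            n_sessions >= 1, eigen_decay > 0,
            subject_rotation_scale >= 0, session_rotation_scale >= 0,
            motion_location >= 0, motion_scale >= 0, motion_coupling >= 0,
            trailing_emphasis >= 0, trailing_emphasis <= 1, noise_sd >= 0,
            flip_prob >= 0, flip_prob <= 1)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Random group gradient basis with geometric variance spectrum
#'
#' @param P,K parcel and component counts (K < P).
#' @param seed RNG seed.
#' @param eigen_decay geometric decay rate; variances are
#'   \code{eigen_decay^(0:(K-1))}.
#' @return list with \code{basis} (P x K, orthonormal columns, deterministic
#'   sign convention) and \code{variances} (strictly decreasing).
#' @export
generate_group_basis <- function(P, K, seed, eigen_decay = 0.8) {
  if (K >= P) stop("invalid dimensions: K must be smaller than P")
  if (eigen_decay <= 0 || eigen_decay >= 1)
    stop("eigen_decay must be in (0, 1) for a strictly decreasing spectrum")
  set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(P * K), P, K)))
  list(basis = .fix_signs(q), variances = eigen_decay^(0:(K - 1)))
}

# random rotation with controlled magnitude: matrix exponential of a random
# antisymmetric generator scaled so its spectral norm (= largest principal
# rotation angle) equals `angle`
.random_rotation <- function(n, angle) {
  if (angle == 0) return(diag(n))
  m <- matrix(stats::rnorm(n * n), n, n)
  a <- m - t(m)
  a <- a / norm(a, "2") * angle
  as.matrix(Matrix::expm(a))
}

.unit_antisym <- function(a) {
  nrm <- norm(a, "2")
  if (nrm == 0) a else a / nrm
}

# T x K latent signal matrix with exactly unit sample covariance
# (centred, orthonormalized, scaled), so that with zero noise the sample FC
# is a deterministic function of the session basis
.exact_latents <- function(T, K) {
  m <- matrix(stats::rnorm(T * K), T, K)
  m <- scale(m, center = TRUE, scale = FALSE)
  qr.Q(qr(m)) * sqrt(T - 1)
}

# |AR(1)| trace rescaled to the subject mean; fd[1] = 0 by convention
.fd_trace <- function(T, mean_fd, phi = 0.4) {
  e <- numeric(T)
  e[1] <- stats::rnorm(1)
  innov <- stats::rnorm(T - 1)
  for (t in 2:T) e[t] <- phi * e[t - 1] + sqrt(1 - phi^2) * innov[t - 1]
  f <- abs(e)
  f <- f * mean_fd / mean(f[-1])
  f[1] <- 0
  f
}

#' Generate a synthetic multi-session cohort
#'
#' Deterministic given the spec (including its seed). See
#' \code{\link{cohort_spec}} for the generative model.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return list of records, one per subject x session, each a list with
#'   \code{subject_id}, \code{session_id}, \code{time_series} (T x P matrix
#'   with parcel labels), \code{motion} (\code{\link{motion_series}}) and
#'   \code{phenotypes} (list with \code{age}, \code{score}; identical across
#'   a subject's sessions).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  P <- spec$n_parcels; K <- spec$n_latent; T <- spec$n_frames
  pm <- spec$phenotype_model
  group <- generate_group_basis(P, K, spec$seed, spec$eigen_decay)
  set.seed(spec$seed + 1L)
  sqrt_v <- sqrt(group$variances)
  parcel_labels <- sprintf("parcel_%03d", seq_len(P))

  # shared age-linked rotation direction (antisymmetric, unit spectral norm)
  m0 <- matrix(stats::rnorm(P * P), P, P)
  a_shared <- .unit_antisym(m0 - t(m0))

  records <- vector("list", spec$n_subjects * spec$n_sessions)
  idx <- 0L
  for (s in seq_len(spec$n_subjects)) {
    subject_id <- sprintf("sub-%03d", s)
    z <- stats::rnorm(1)  # latent age factor
    age <- pm$age_mean + pm$age_sd * z
    score <- 100 + pm$score_age * z + pm$score_sd * stats::rnorm(1)
    eps <- stats::rnorm(1)
    mean_fd <- max(spec$motion_location +
                     spec$motion_scale * (pm$fd_age * z +
                                          sqrt(1 - pm$fd_age^2) * eps),
                   0.01)

    # subject basis: small rotation (direction partly age-linked) + flips/swaps
    mi <- matrix(stats::rnorm(P * P), P, P)
    a_idio <- .unit_antisym(mi - t(mi))
    gen <- .unit_antisym(pm$gradient_age * z * a_shared +
                           sqrt(max(0, 1 - pm$gradient_age^2)) * a_idio)
    r_subj <- if (spec$subject_rotation_scale == 0) diag(P) else
      as.matrix(Matrix::expm(gen * spec$subject_rotation_scale))
    basis_s <- r_subj %*% group$basis

    for (ses in seq_len(spec$n_sessions)) {
      # per-session sign flips and adjacent-component swaps: emulate the
      # arbitrary sign and eigenvalue-order instability of independent
      # per-session gradient extraction, the distortions alignment exists
      # to correct
      flips <- ifelse(stats::runif(K) < spec$flip_prob, -1, 1)
      basis_ses <- basis_s * rep(flips, each = P)
      k <- 1L
      while (k < K) {
        if (stats::runif(1) < spec$flip_prob) {
          basis_ses[, c(k, k + 1L)] <- basis_ses[, c(k + 1L, k)]
          k <- k + 2L
        } else k <- k + 1L
      }
      session_id <- sprintf("ses-%02d", ses)
      fd <- .fd_trace(T, mean_fd)
      # session rotation in component space: emulates the eigenvector mixing
      # (sign/order/rotation instability) that session noise induces within
      # the subject's gradient subspace -- the disturbance Procrustes
      # alignment exists to correct
      r_sess <- .random_rotation(K, spec$session_rotation_scale)
      # motion-coupled rotation in component space; the trailing part leaves
      # component 1 untouched
      mt <- matrix(stats::rnorm(K * K), K, K)
      a_all <- .unit_antisym(mt - t(mt))
      a_tr <- mt - t(mt)
      a_tr[1, ] <- 0; a_tr[, 1] <- 0
      a_tr <- .unit_antisym(a_tr)
      angle_m <- spec$motion_coupling * mean_fd
      r_m <- if (angle_m == 0) diag(K) else
        as.matrix(Matrix::expm((spec$trailing_emphasis * a_tr +
                                  (1 - spec$trailing_emphasis) * a_all) * angle_m))
      basis_st <- basis_ses %*% (r_sess %*% r_m)

      S <- .exact_latents(T, K)
      # scale so the average per-parcel signal variance is 1 (realistic SNR
      # against noise_sd and the motion artifact)
      X <- S %*% (t(basis_st) * sqrt_v) * sqrt(P / sum(group$variances))
      map <- stats::rnorm(P)
      X <- X + spec$motion_coupling * outer(fd, map)
      if (spec$noise_sd > 0)
        X <- X + matrix(stats::rnorm(T * P, sd = spec$noise_sd), T, P)
      colnames(X) <- parcel_labels

      idx <- idx + 1L
      records[[idx]] <- list(subject_id = subject_id, session_id = session_id,
                             time_series = X,
                             motion = motion_series(fd),
                             phenotypes = list(age = age, score = score))
    }
  }
  records
}

#' Write a synthetic cohort as the pipeline's input file tree
#'
#' One time-series TSV and one confounds TSV per record
#' (\code{sub-<ID>_ses-<ID>_timeseries.tsv},
#' \code{sub-<ID>_ses-<ID>_confounds.tsv}; the confounds file carries a
#' \code{framewise_displacement} column with \code{n/a} at the first frame,
#' fMRIPrep-style), plus \code{phenotypes.csv} and a \code{manifest.json}.
#' Round-trips losslessly through \code{\link{read_cohort_dir}}.
#'
#' @param records list of records from \code{\link{generate_cohort}}.
#' @param directory output directory (created if absent).
#' @return invisibly, the manifest list.
#' @export
cohort_to_files <- function(records, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  phen <- list()
  for (rec in records) {
    stem <- sprintf("%s_%s", rec$subject_id, rec$session_id)
    ts_file <- file.path(directory, paste0(stem, "_timeseries.tsv"))
    utils::write.table(format(rec$time_series, digits = 17, trim = TRUE,
                              scientific = FALSE),
                       ts_file, sep = "\t", quote = FALSE, row.names = FALSE)
    fd_chr <- c("n/a", format(rec$motion$fd_series[-1], digits = 17,
                              trim = TRUE, scientific = FALSE))
    conf_file <- file.path(directory, paste0(stem, "_confounds.tsv"))
    utils::write.table(data.frame(framewise_displacement = fd_chr),
                       conf_file, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, basename(ts_file), basename(conf_file))
    phen[[rec$subject_id]] <- data.frame(subject_id = rec$subject_id,
                                         age = rec$phenotypes$age,
                                         score = rec$phenotypes$score)
  }
  if (length(phen)) {
    ptab <- do.call(rbind, phen)
    utils::write.csv(ptab, file.path(directory, "phenotypes.csv"),
                     row.names = FALSE)
    files <- c(files, "phenotypes.csv")
  }
  manifest <- list(n_records = length(records), files = files)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
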