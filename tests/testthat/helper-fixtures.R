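# shared fixtures, all generated in code

# small cohort for fast end-to-end tests
small_cohort_spec <- function(seed = 3, n_subjects = 10, n_sessions = 2,
                              n_parcels = 40, n_latent = 10, n_frames = 100) {
  cohort_spec(n_subjects = n_subjects, n_parcels = n_parcels,
              n_sessions = n_sessions, n_latent = n_latent,
              n_frames = n_frames, seed = seed)
}

# fc[[subject]][[session]] from a record list
cohort_fc <- function(records) {
  fc <- list()
  for (r in records) fc[[r$subject_id]][[r$session_id]] <- pearson_fc(r$time_series)
  fc
}

# per-subject-session gradient sets for the given subjects
cohort_gradients <- function(fc, subjects, n_components = 10,
                             kernel_name = "normalized_angle",
                             sparsity = 0.9, approach = "dm") {
  grads <- list()
  for (s in subjects) for (ses in names(fc[[s]]))
    grads[[s]][[ses]] <- extract_gradients(fc[[s]][[ses]],
                                           kernel_name = kernel_name,
                                           sparsity = sparsity,
                                           approach = approach,
                                           n_components = n_components,
                                           subject_id = s, session_id = ses)
  grads
}

# random matrix with orthonormal columns
rand_orthonormal <- function(m, n) qr.Q(qr(matrix(rnorm(m * n), m, n)))

# random orthogonal n x n matrix (uniform-ish via QR with sign fix)
rand_orthogonal <- function(n) {
  q <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
  q
}
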