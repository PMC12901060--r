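#' Gradient bank: principal gradients of one session across subjects
#'
#' @param session_id session identifier.
#' @param vectors P x S numeric matrix with one column per subject (column
#'   names are subject ids).
#' @param n_align number of gradients that were used in alignment
#'   (provenance).
#' @return object of class \code{gradient_bank}.
#' @export
gradient_bank <- function(session_id, vectors, n_align = NA_integer_) {
  vectors <- as.matrix(vectors)
  if (is.null(colnames(vectors))) stop("vectors must carry subject ids as column names")
  if (ncol(vectors) < 2L) stop("at least 2 subjects required")
  structure(list(session_id = session_id, vectors = vectors,
                 n_align = n_align), class = "gradient_bank")
}

.bank_cross_cor <- function(bank_a, bank_b) {
  if (!identical(sort(colnames(bank_a$vectors)), sort(colnames(bank_b$vectors))))
    stop("mismatched subject sets between banks")
  ids <- colnames(bank_a$vectors)
  stats::cor(bank_a$vectors, bank_b$vectors[, ids, drop = FALSE])
}

#' Subject identification accuracy between two sessions
#'
#' For each subject in one session, the best-matching subject in the other
#' session is the one whose principal gradient has the highest Pearson
#' correlation; a subject is correctly identified when that match is itself.
#' Both lookup directions are computed and their proportions averaged
#' (ties broken toward the lowest subject index, with a warning).
#'
#' @param bank_a,bank_b \code{\link{gradient_bank}} objects over identical
#'   subject sets.
#' @return list with \code{accuracy} (mean of the two directions),
#'   \code{accuracy_ab}, \code{accuracy_ba}.
#' @export
identification_accuracy <- function(bank_a, bank_b) {
  cc <- .bank_cross_cor(bank_a, bank_b)
  dir_acc <- function(m) {
    hits <- vapply(seq_len(nrow(m)), function(i) {
      best <- which(m[i, ] == max(m[i, ]))
      if (length(best) > 1L) warning("tie in identification; lowest index used")
      best[1L] == i
    }, logical(1))
    mean(hits)
  }
  ab <- dir_acc(cc)
  ba <- dir_acc(t(cc))
  list(accuracy = (ab + ba) / 2, accuracy_ab = ab, accuracy_ba = ba)
}

#' Differential identifiability between two sessions
#'
#' I_self is the mean correlation of each subject's principal gradient with
#' its own gradient in the other session; I_other the mean over all ordered
#' pairs of distinct subjects (both off-diagonal triangles of the
#' cross-session correlation matrix). I_diff = (I_self - I_other) x 100.
#' With \code{fisher_z_applied}, every correlation is r-to-z transformed
#' before averaging (correlations at +/-1 are clipped as in
#' \code{\link{fisher_z}}).
#'
#' @param bank_a,bank_b \code{\link{gradient_bank}} objects over identical
#'   subject sets.
#' @param fisher_z_applied transform correlations before averaging.
#' @return list with \code{i_self}, \code{i_other}, \code{i_diff},
#'   \code{fisher_z_applied}.
#' @export
differential_identifiability <- function(bank_a, bank_b,
                                         fisher_z_applied = FALSE) {
  cc <- .bank_cross_cor(bank_a, bank_b)
  if (fisher_z_applied) cc <- suppressWarnings(fisher_z(cc))
  i_self <- mean(diag(cc))
  i_other <- mean(cc[row(cc) != col(cc)])
  list(i_self = i_self, i_other = i_other,
       i_diff = (i_self - i_other) * 100,
       fisher_z_applied = fisher_z_applied)
}

#' Identifiability sweep over session pairs and alignment dimensionality
#'
#' For every unordered session pair and every number of gradients used in
#' alignment, aligns each subject's session gradients to the reference via
#' \code{\link{align_to_reference}}, banks the aligned principal gradients,
#' and reports identification accuracy and differential identifiability
#' (raw and Fisher-z variants) together with the mean alignment diagnostics.
#' With S sessions the output has \code{choose(S, 2)} session-pair rows per
#' \code{n_align} value.
#'
#' @param gradients nested list \code{gradients[[subject_id]][[session_id]]}
#'   of \code{\link{gradient_set}} objects; every subject must have every
#'   session.
#' @param reference \code{\link{gradient_set}} with at least
#'   \code{max(n_align_values)} components.
#' @param n_align_values integer vector of alignment dimensionalities.
#' @return data.frame with columns session_a, session_b, n_align, accuracy,
#'   i_self, i_other, i_diff, variant ("raw"/"z"), mean_correspondence.
#' @export
sweep_identifiability <- function(gradients, reference, n_align_values) {
  subjects <- names(gradients)
  sessions <- sort(unique(unlist(lapply(gradients, names))))
  missing <- subjects[!vapply(gradients, function(g)
    all(sessions %in% names(g)), logical(1))]
  if (length(missing))
    stop("subjects missing sessions: ", paste(missing, collapse = ", "))
  if (length(sessions) < 2L) stop("at least 2 sessions required")
  pairs <- utils::combn(sessions, 2L)
  rows <- list()
  for (n_align in n_align_values) {
    banks <- list()
    corr_by_ses <- list()
    for (ses in sessions) {
      vecs <- vapply(subjects, function(sid) {
        al <- align_to_reference(gradients[[sid]][[ses]], reference, n_align)
        corr_by_ses[[ses]] <<- c(corr_by_ses[[ses]],
                                 al$diagnostics$correspondence)
        al$aligned$components[, 1]
      }, numeric(nrow(reference$components)))
      banks[[ses]] <- gradient_bank(ses, vecs, n_align)
    }
    for (p in seq_len(ncol(pairs))) {
      a <- pairs[1, p]; b <- pairs[2, p]
      acc <- identification_accuracy(banks[[a]], banks[[b]])
      mc <- mean(c(corr_by_ses[[a]], corr_by_ses[[b]]))
      for (variant in c("raw", "z")) {
        di <- differential_identifiability(banks[[a]], banks[[b]],
                                           fisher_z_applied = variant == "z")
        rows[[length(rows) + 1L]] <- data.frame(
          session_a = a, session_b = b, n_align = n_align,
          accuracy = acc$accuracy, i_self = di$i_self, i_other = di$i_other,
          i_diff = di$i_diff, variant = variant, mean_correspondence = mc)
      }
    }
  }
  do.call(rbind, rows)
}
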