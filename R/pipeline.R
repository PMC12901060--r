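#' Run configuration for the full study
#'
#' @param input_dir directory containing the cohort file tree (see
#'   \code{\link{cohort_to_files}} for the formats).
#' @param output_dir directory for result tables, manifest and log.
#' @param holdout_fraction fraction of subjects reserved to build the group
#'   reference (default 0.2).
#' @param seed integer seed governing the holdout split and all seeded
#'   downstream stages.
#' @param kernel_name,sparsity,approach gradient-extraction parameters
#'   (defaults: normalized_angle, 0.9, diffusion map embedding).
#' @param n_components_extracted number of gradients extracted per subject
#'   and for the reference (default 20).
#' @param n_align_values numbers of gradients used in alignment to sweep
#'   (default 1..20; must be within 1..n_components_extracted).
#' @param reversed_cumulative also run the reversed cumulative alignment
#'   (components 20..k) as a supplementary sweep.
#' @param fdr_q Benjamini-Hochberg significance threshold (default 0.05).
#' @param prediction_scenarios named list of confound-column subsets for the
#'   prediction stage, e.g. \code{list(none = character(0), fd = "fd")}.
#' @param prediction_n_align n_align values at which prediction is run
#'   (defaults to \code{max(n_align_values)}).
#' @param prediction_targets which continuous phenotypes to predict.
#' @param run_prediction logical; the prediction stage is the most expensive
#'   and can be disabled.
#' @param cv \code{\link{cv_config}} for the prediction stage.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(input_dir, output_dir,
                       holdout_fraction = 0.2, seed = 1L,
                       kernel_name = "normalized_angle", sparsity = 0.9,
                       approach = "dm", n_components_extracted = 20L,
                       n_align_values = seq_len(n_components_extracted),
                       reversed_cumulative = FALSE, fdr_q = 0.05,
                       prediction_scenarios = list(none = character(0),
                                                   fd = "fd",
                                                   fd_age = c("fd", "age")),
                       prediction_n_align = max(n_align_values),
                       prediction_targets = c("score", "age"),
                       run_prediction = TRUE,
                       cv = cv_config(seed = seed)) {
  stopifnot(holdout_fraction > 0, holdout_fraction < 1,
            all(n_align_values >= 1),
            all(n_align_values <= n_components_extracted))
  structure(as.list(environment()), class = "run_config")
}

#' Read a parcellated time-series TSV
#' @param path TSV with a header row of parcel labels, one row per frame.
#' @return frames x parcels numeric matrix.
#' @export
read_timeseries_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  as.matrix(df)
}

#' Read an fMRIPrep-style confounds TSV
#'
#' When a \code{framewise_displacement} column is present it is used
#' verbatim (\code{n/a} at the first frame is accepted and set to 0);
#' otherwise FD is computed from the six rigid-body columns
#' \code{trans_x..rot_z} via \code{\link{framewise_displacement}}.
#'
#' @param path TSV path.
#' @return \code{\link{motion_series}}.
#' @export
read_confounds_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          na.strings = c("n/a", "NA"), check.names = FALSE)
  if ("framewise_displacement" %in% names(df)) {
    fd <- as.numeric(df$framewise_displacement)
    if (is.na(fd[1])) fd[1] <- 0
    if (anyNA(fd)) stop("missing FD values beyond the first frame in ", path)
    motion_series(fd)
  } else {
    need <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
    if (!all(need %in% names(df)))
      stop("confounds file lacks framewise_displacement and rigid-body columns: ",
           path)
    framewise_displacement(as.matrix(df[, need[1:3]]),
                           as.matrix(df[, need[4:6]]))
  }
}

#' Read a cohort directory written by \code{\link{cohort_to_files}}
#'
#' @param directory input directory.
#' @return list of records (subject_id, session_id, time_series, motion,
#'   phenotypes), as produced by \code{\link{generate_cohort}}.
#' @export
read_cohort_dir <- function(directory) {
  ts_files <- sort(list.files(directory, pattern = "_timeseries\\.tsv$"))
  phen_path <- file.path(directory, "phenotypes.csv")
  phen <- if (file.exists(phen_path))
    utils::read.csv(phen_path, stringsAsFactors = FALSE) else NULL
  lapply(ts_files, function(f) {
    stem <- sub("_timeseries\\.tsv$", "", f)
    parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
    sid <- parts[1]; ses <- parts[2]
    conf <- file.path(directory, paste0(stem, "_confounds.tsv"))
    ph <- if (!is.null(phen) && sid %in% phen$subject_id) {
      row <- phen[phen$subject_id == sid, , drop = FALSE][1, ]
      as.list(row[setdiff(names(row), "subject_id")])
    } else list()
    list(subject_id = sid, session_id = ses,
         time_series = read_timeseries_tsv(file.path(directory, f)),
         motion = if (file.exists(conf)) read_confounds_tsv(conf) else NULL,
         phenotypes = ph)
  })
}

#' Seeded holdout split of subject ids
#'
#' @param subject_ids character vector (>= 5 subjects).
#' @param fraction holdout fraction in (0, 1); the holdout size is
#'   \code{round(fraction * n)}.
#' @param seed RNG seed.
#' @return list with \code{analysis} and \code{holdout} id vectors
#'   (disjoint, exhaustive).
#' @export
holdout_split <- function(subject_ids, fraction, seed) {
  subject_ids <- unique(subject_ids)
  n <- length(subject_ids)
  if (n < 5L) stop("need at least 5 subjects to split")
  k <- round(fraction * n)
  if (k < 1L || k >= n) stop("fraction yields an empty partition")
  set.seed(seed)
  hold <- sort(sample(subject_ids, k))
  list(analysis = setdiff(subject_ids, hold), holdout = hold)
}

#' Build the group reference gradient set from holdout FC matrices
#'
#' Averages the holdout FC matrices (all sessions pooled) in Fisher z space
#' and extracts gradients from the average with the study's extraction
#' parameters.
#'
#' @param fc_list non-empty list of FC matrices from holdout subjects.
#' @param kernel_name,sparsity,approach,n_components extraction parameters.
#' @return \code{\link{gradient_set}} tagged \code{"reference"}.
#' @export
build_reference <- function(fc_list, kernel_name = "normalized_angle",
                            sparsity = 0.9, approach = "dm",
                            n_components = 20) {
  avg <- group_mean_fc(fc_list)
  extract_gradients(avg, kernel_name = kernel_name, sparsity = sparsity,
                    approach = approach, n_components = n_components,
                    subject_id = "reference", session_id = "reference")
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Standard step-up procedure: with m ascending p-values, reject the k
#' smallest where k is the largest index with p_(k) <= k q / m. Adjusted
#' p-values follow the cumulative-minimum formula.
#'
#' @param p_values numeric vector in [0, 1].
#' @param q significance threshold (default 0.05).
#' @return list with \code{significant} (logical) and \code{adjusted}
#'   (numeric), in input order.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  adjusted <- stats::p.adjust(p_values, method = "BH")
  list(significant = !is.na(adjusted) & adjusted <= q, adjusted = adjusted)
}

#' Correlation sweep between motion metrics and alignment diagnostics
#'
#' Per session and per number of gradients used in alignment, the Pearson
#' correlation across subjects between each motion metric (mean FD, TFC) and
#' each alignment diagnostic (trans_total, trans_pg, w_norm, theta_norm),
#' with two-tailed p-values. BH correction is applied per metric pair within
#' each session across n_align values; \code{significant_all_sessions}
#' flags (session-pair, n_align) cells whose correlation survives FDR in
#' every session.
#'
#' @param diagnostics data.frame with columns subject_id, session_id,
#'   n_align, trans_total, trans_pg, w_norm, theta_norm (one row per subject
#'   x session x n_align; see \code{\link{alignment_sweep}}).
#' @param motion_table data.frame with columns subject_id, session_id,
#'   mean_fd, tfc.
#' @param fdr_q BH threshold.
#' @return data.frame with one row per session x n_align x metric pair:
#'   motion_metric, diagnostic, pearson_r, p_value, fdr_significant,
#'   significant_all_sessions.
#' @export
motion_correlation_sweep <- function(diagnostics, motion_table,
                                     fdr_q = 0.05) {
  diag_names <- c("trans_total", "trans_pg", "w_norm", "theta_norm")
  motion_names <- c("mean_fd", "tfc")
  merged <- merge(diagnostics, motion_table,
                  by = c("subject_id", "session_id"))
  rows <- list()
  for (ses in sort(unique(merged$session_id))) {
    dses <- merged[merged$session_id == ses, ]
    for (mm in motion_names) for (dn in diag_names) {
      for (na_val in sort(unique(dses$n_align))) {
        d <- dses[dses$n_align == na_val, ]
        if (nrow(d) < 4L) stop("fewer than 4 subjects: correlation unstable")
        x <- d[[mm]]; y <- d[[dn]]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            session_id = ses, n_align = na_val, motion_metric = mm,
            diagnostic = dn, n_subjects = nrow(d), pearson_r = NA_real_,
            p_value = NA_real_, degenerate = TRUE)
        } else {
          ct <- stats::cor.test(x, y, method = "pearson")
          rows[[length(rows) + 1L]] <- data.frame(
            session_id = ses, n_align = na_val, motion_metric = mm,
            diagnostic = dn, n_subjects = nrow(d),
            pearson_r = unname(ct$estimate), p_value = ct$p.value,
            degenerate = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$fdr_significant <- FALSE
  for (ses in unique(out$session_id)) for (mm in motion_names)
    for (dn in diag_names) {
      sel <- out$session_id == ses & out$motion_metric == mm &
        out$diagnostic == dn & !out$degenerate
      if (any(sel))
        out$fdr_significant[sel] <- bh_fdr(out$p_value[sel], fdr_q)$significant
    }
  key <- interaction(out$n_align, out$motion_metric, out$diagnostic,
                     drop = TRUE)
  all_sig <- tapply(out$fdr_significant & !out$degenerate, key, all)
  out$significant_all_sessions <- as.logical(all_sig[key])
  rownames(out) <- NULL
  out
}

#' Alignment sweep across subjects, sessions and n_align values
#'
#' Aligns every subject x session gradient set to the reference for each
#' n_align value and collects the alignment diagnostics (and, optionally,
#' the aligned principal gradients).
#'
#' @param gradients nested list \code{gradients[[subject]][[session]]} of
#'   \code{\link{gradient_set}} objects.
#' @param reference reference \code{\link{gradient_set}}.
#' @param n_align_values integer vector.
#' @param component_sets optional named list overriding the index sets used
#'   per sweep value (for reversed cumulative alignment); names label the
#'   rows.
#' @param keep_gradients also return the aligned principal gradients.
#' @return list with \code{diagnostics} (tidy data.frame) and, when
#'   requested, \code{principal} (\code{principal[[n_align]][[session]]} =
#'   P x subjects matrix).
#' @export
alignment_sweep <- function(gradients, reference, n_align_values,
                            component_sets = NULL, keep_gradients = FALSE) {
  rows <- list()
  principal <- list()
  sweep_sets <- if (is.null(component_sets)) {
    stats::setNames(lapply(n_align_values, seq_len),
                    as.character(n_align_values))
  } else component_sets
  for (lab in names(sweep_sets)) {
    idx <- sweep_sets[[lab]]
    pg <- list()
    for (sid in names(gradients)) for (ses in names(gradients[[sid]])) {
      al <- align_to_reference(gradients[[sid]][[ses]], reference,
                               n_align = length(idx),
                               component_indices = idx)
      d <- al$diagnostics
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, session_id = ses, sweep = lab,
        n_align = d$n_align, correspondence = d$correspondence,
        trans_total = d$trans_total, trans_pg = d$trans_pg,
        w_norm = d$w_norm, theta_norm = d$theta_norm)
      if (keep_gradients)
        pg[[ses]][[sid]] <- al$aligned$components[, 1]
    }
    if (keep_gradients)
      principal[[lab]] <- lapply(pg, function(v) do.call(cbind, v))
  }
  out <- list(diagnostics = do.call(rbind, rows))
  if (keep_gradients) out$principal <- principal
  out
}

.log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  writeLines(msg, con)
  message(msg)
}

#' Run the full study on a cohort directory
#'
#' Executes the complete pipeline: read the cohort, compute FC and motion
#' metrics (FD, TFC against the holdout group mean), split off the holdout,
#' build the group reference gradients, extract per subject-session
#' gradients, sweep the alignment over n_align (and, if requested, the
#' reversed cumulative index sets), run the identifiability sweep, the
#' motion-correlation sweep with BH-FDR correction, and (optionally) the
#' confound-scenario prediction stage. Writes tidy CSVs, a JSON run manifest
#' carrying all parameters and seeds, and a log; a rerun with the same
#' configuration is byte-identical.
#'
#' @param config \code{\link{run_config}}.
#' @return invisibly, a list with the in-memory result tables.
#' @export
run_full_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(config$output_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  stage <- function(name, expr) {
    .log_line(log_con, "stage: ", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  records <- stage("read", read_cohort_dir(config$input_dir))
  if (!length(records)) stop("[stage read] no records found in input directory")
  subjects <- sort(unique(vapply(records, `[[`, "", "subject_id")))
  sessions <- sort(unique(vapply(records, `[[`, "", "session_id")))

  fc <- stage("connectivity", {
    out <- list()
    for (rec in records)
      out[[rec$subject_id]][[rec$session_id]] <- pearson_fc(rec$time_series)
    out
  })

  split <- stage("holdout", holdout_split(subjects, config$holdout_fraction,
                                          config$seed))
  reference <- stage("reference", {
    hold_fc <- unlist(lapply(split$holdout, function(s) fc[[s]]),
                      recursive = FALSE)
    build_reference(hold_fc, config$kernel_name, config$sparsity,
                    config$approach, config$n_components_extracted)
  })

  motion_table <- stage("motion", {
    group_fc <- group_mean_fc(unlist(lapply(split$holdout,
                                            function(s) fc[[s]]),
                                     recursive = FALSE))
    do.call(rbind, lapply(records, function(rec) data.frame(
      subject_id = rec$subject_id, session_id = rec$session_id,
      mean_fd = rec$motion$mean_fd,
      tfc = tfc(fc[[rec$subject_id]][[rec$session_id]], group_fc))))
  })

  gradients <- stage("gradients", {
    out <- list()
    for (sid in split$analysis) for (ses in names(fc[[sid]]))
      out[[sid]][[ses]] <- extract_gradients(
        fc[[sid]][[ses]], kernel_name = config$kernel_name,
        sparsity = config$sparsity, approach = config$approach,
        n_components = config$n_components_extracted,
        subject_id = sid, session_id = ses)
    out
  })

  sweep <- stage("alignment_sweep",
                 alignment_sweep(gradients, reference, config$n_align_values,
                                 keep_gradients = TRUE))
  reversed <- NULL
  if (isTRUE(config$reversed_cumulative)) {
    reversed <- stage("reversed_cumulative", {
      kmax <- config$n_components_extracted
      sets <- lapply(rev(seq_len(kmax)), function(k) kmax:k)
      names(sets) <- vapply(sets, length, integer(1))
      alignment_sweep(gradients, reference, NULL,
                      component_sets = sets)$diagnostics
    })
  }

  ident <- stage("identifiability",
                 if (length(sessions) >= 2L)
                   sweep_identifiability(gradients, reference,
                                         config$n_align_values)
                 else NULL)

  motion_sweep <- stage("motion_sweep", {
    d <- sweep$diagnostics
    d <- d[d$subject_id %in% split$analysis, ]
    motion_correlation_sweep(d,
                             motion_table[motion_table$subject_id %in% split$analysis, ],
                             fdr_q = config$fdr_q)
  })

  prediction <- NULL
  if (isTRUE(config$run_prediction)) {
    prediction <- stage("prediction", {
      phen <- do.call(rbind, lapply(records, function(rec)
        data.frame(subject_id = rec$subject_id,
                   age = rec$phenotypes$age, score = rec$phenotypes$score)))
      phen <- unique(phen)
      fd_by_subj <- tapply(motion_table$mean_fd, motion_table$subject_id, mean)
      rows <- list()
      for (na_val in config$prediction_n_align) {
        pg_all <- sweep$principal[[as.character(na_val)]]
        feats <- Reduce(`+`, pg_all) / length(pg_all)  # mean over sessions
        feats <- t(feats)                              # subjects x parcels
        ids <- rownames(feats)
        ph <- phen[match(ids, phen$subject_id), ]
        conf <- cbind(fd = unname(fd_by_subj[ids]), age = ph$age)
        for (target in config$prediction_targets) {
          for (scen_name in names(config$prediction_scenarios)) {
            scen <- config$prediction_scenarios[[scen_name]]
            if (target == "age") scen <- setdiff(scen, "age")
            tab <- feature_table(feats, ph[[target]],
                                 confounds = conf, subject_ids = ids)
            res <- nested_cv_regression(tab, config$cv, scenario = scen)
            rows[[length(rows) + 1L]] <- data.frame(
              task = target, n_align = na_val, scenario = scen_name,
              model = "ridge", mean_score = res$mean_score,
              sd_score = res$sd_score)
          }
        }
        cls_tab <- feature_table(feats,
                                 binarize_by_median(unname(fd_by_subj[ids])),
                                 confounds = conf, subject_ids = ids)
        cls <- nested_cv_classification(cls_tab, config$cv, model = "ridge")
        rows[[length(rows) + 1L]] <- data.frame(
          task = "motion_class", n_align = na_val, scenario = "none",
          model = "ridge", mean_score = cls$mean_score,
          sd_score = cls$sd_score)
      }
      do.call(rbind, rows)
    })
  }

  stage("write", {
    wcsv <- function(df, name) if (!is.null(df))
      utils::write.csv(df, file.path(config$output_dir, name),
                       row.names = FALSE)
    diag_out <- sweep$diagnostics
    diag_out$kernel <- config$kernel_name
    diag_out$sparsity <- config$sparsity
    diag_out$approach <- config$approach
    diag_out$seed <- config$seed
    wcsv(diag_out, "alignment_diagnostics.csv")
    wcsv(motion_table, "motion_metrics.csv")
    wcsv(ident, "identifiability.csv")
    wcsv(motion_sweep, "motion_correlations.csv")
    wcsv(prediction, "prediction.csv")
    wcsv(reversed, "reversed_cumulative_diagnostics.csv")
    manifest <- config
    manifest$cv <- unclass(config$cv)
    manifest <- unclass(manifest)
    manifest$holdout_subjects <- split$holdout
    manifest$analysis_subjects <- split$analysis
    manifest$sessions <- sessions
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  })
  .log_line(log_con, "done")
  invisible(list(split = split, reference = reference,
                 motion_table = motion_table,
                 diagnostics = sweep$diagnostics, identifiability = ident,
                 motion_correlations = motion_sweep,
                 prediction = prediction, reversed = reversed))
}
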