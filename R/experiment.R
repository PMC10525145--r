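#' Sampling plan for the classification protocol
#'
#' Trial-average mode: per participant, one rare sample averaged from all
#' `n_per_average` rare trials and one frequent sample drawn per iteration
#' from the participant's non-overlapping `n_per_average`-trial frequent
#' subsets (`floor(n_frequent / n_per_average)` candidates, subset membership
#' fixed per cohort). Single-trial mode: all rare trials plus an equal number
#' of randomly selected frequent trials per participant.
#'
#' @param mode `"trial_average"` or `"single_trial"`.
#' @param n_per_average trials per average (default 24, the rare-condition
#'   maximum).
#' @param test_fraction held-out fraction per iteration (default 0.25, i.e.
#'   a 100/300 split for a 400-sample dataset).
#' @param n_iterations repetitions of the full procedure (default 200).
#' @param seed master seed for subset partitions, per-iteration draws,
#'   splits and training.
#' @return object of class `sampling_plan`.
#' @export
sampling_plan <- function(mode = c("trial_average", "single_trial"),
                          n_per_average = 24, test_fraction = 0.25,
                          n_iterations = 200, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(test_fraction > 0, test_fraction < 1, n_per_average >= 1,
            n_iterations >= 1)
  structure(list(mode = mode, n_per_average = as.integer(n_per_average),
                 test_fraction = test_fraction,
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)),
            class = "sampling_plan")
}

#' Number of non-overlapping frequent-trial subsets
#' @param n_frequent frequent trials per participant.
#' @param n_per_average trials per average.
#' @return `floor(n_frequent / n_per_average)` (5 for 135 trials of 24).
#' @export
n_frequent_subsets <- function(n_frequent, n_per_average = 24) {
  as.integer(n_frequent %/% n_per_average)
}

#' Feature-extraction configuration for the experiment pipeline
#'
#' @param freqs wavelet analysis frequencies, Hz (default 2-30 Hz in 1-Hz
#'   steps; tests use a 6-frequency 4-14 Hz grid).
#' @param decay Morlet time-decay parameter (default 0.5).
#' @param baseline pre-stimulus baseline window, ms.
#' @param crop classifier analysis window, ms (default \[-500, 1500\],
#'   keeping coefficients away from epoch edges).
#' @return object of class `feature_config`.
#' @export
feature_config <- function(freqs = 2:30, decay = 0.5,
                           baseline = c(-200, 0), crop = c(-500, 1500)) {
  structure(list(freqs = as.numeric(freqs), decay = decay,
                 baseline = baseline_spec(baseline), crop = as.numeric(crop)),
            class = "feature_config")
}

# fixed per-cohort partition of one participant's frequent trials into
# non-overlapping n_per_average-trial subsets
frequent_partition <- function(rec, plan, participant_num) {
  freq_idx <- which(rec$labels == "frequent")
  n_sub <- n_frequent_subsets(length(freq_idx), plan$n_per_average)
  if (n_sub < 1)
    stop("participant ", rec$participant_id,
         ": insufficient frequent trials for one subset")
  set.seed(substream_seed(plan$seed, participant_num, 99))
  shuffled <- sample(freq_idx)
  lapply(seq_len(n_sub), function(i)
    sort(shuffled[((i - 1) * plan$n_per_average + 1):(i * plan$n_per_average)]))
}

flatten_feature <- function(tensor, times, crop) {
  as.numeric(crop_time(tensor, times, crop)$x)
}

# trial-average features of one trial subset: named list of flattened vectors
subset_features <- function(rec, dec, subset, fc, features) {
  out <- list()
  if ("erp" %in% features)
    out$erp <- flatten_feature(
      compute_erp(rec, subset, fc$baseline)$tensor, rec_times(rec), fc$crop)
  if ("tf_power" %in% features)
    out$tf_power <- flatten_feature(
      tf_power(dec, subset, fc$baseline)$tensor, dec$times, fc$crop)
  if ("phase_sync" %in% features)
    out$phase_sync <- flatten_feature(
      phase_synchronization(dec, subset, fc$baseline)$tensor,
      dec$times, fc$crop)
  out
}

#' Precompute per-participant trial-average feature candidates
#'
#' Computes, once per cohort, the rare-condition feature sample (all rare
#' trials) and every frequent-subset candidate for each participant, so that
#' iterations of the procedure only redraw which frequent candidate is used.
#'
#' @param cohort list of [epoched_recording]s.
#' @param plan a [sampling_plan()].
#' @param fc a [feature_config()].
#' @param features subset of `c("erp", "tf_power", "phase_sync")`.
#' @param verbose print progress.
#' @return an opaque feature bank consumed by [build_average_dataset()].
#' @export
build_feature_bank <- function(cohort, plan, fc = feature_config(),
                               features = c("erp", "tf_power", "phase_sync"),
                               verbose = FALSE) {
  need_cwt <- any(c("tf_power", "phase_sync") %in% features)
  banks <- vector("list", length(cohort))
  for (p in seq_along(cohort)) {
    rec <- cohort[[p]]
    rare_idx <- which(rec$labels == "rare")
    if (length(rare_idx) < plan$n_per_average)
      stop("participant ", rec$participant_id,
           ": insufficient rare trials (", length(rare_idx), " < ",
           plan$n_per_average, ")")
    subsets <- frequent_partition(rec, plan, p)
    dec <- NULL
    if (need_cwt)
      dec <- cwt(rec, wavelet_spec(fc$freqs, rec$srate, fc$decay))
    banks[[p]] <- list(
      id = rec$participant_id,
      rare = subset_features(rec, dec, rare_idx, fc, features),
      freq_candidates = lapply(subsets, subset_features, rec = rec, dec = dec,
                               fc = fc, features = features))
    ef_log(verbose, "feature bank: participant %d/%d done", p, length(cohort))
  }
  structure(list(participants = banks, features = features, plan_seed = plan$seed),
            class = "feature_bank")
}

#' Assemble one iteration's trial-average dataset
#'
#' Per participant: the rare sample (all rare trials averaged) plus one
#' frequent candidate drawn for this iteration from the fixed non-overlapping
#' subsets — 2 samples per participant, exactly class-balanced (400 samples
#' for a 200-participant cohort).
#'
#' @param cohort list of [epoched_recording]s.
#' @param plan a [sampling_plan()].
#' @param iteration_seed integer distinguishing iterations.
#' @param fc a [feature_config()].
#' @param features feature kinds to compute; `character(0)` gives a
#'   count-only dataset (labels and provenance, no tensors).
#' @param bank optional precomputed [build_feature_bank()] result.
#' @return list with `X` (named list of samples x dims matrices, or NULL),
#'   integer labels `y` (0 = frequent, 1 = rare), `participant`, and `n`.
#' @export
build_average_dataset <- function(cohort, plan, iteration_seed,
                                  fc = feature_config(),
                                  features = c("erp", "tf_power", "phase_sync"),
                                  bank = NULL) {
  n_p <- length(cohort)
  y <- rep(c(1L, 0L), n_p)
  participant <- rep(vapply(cohort, `[[`, "", "participant_id"), each = 2)
  if (length(features) == 0) {
    n_cand <- vapply(seq_len(n_p), function(p)
      length(frequent_partition(cohort[[p]], plan, p)), 1L)
    set.seed(substream_seed(plan$seed, iteration_seed, 7))
    picks <- vapply(n_cand, function(k) sample.int(k, 1L), 1L)
    return(list(X = NULL, y = y, participant = participant, n = 2L * n_p,
                picks = picks))
  }
  if (is.null(bank))
    bank <- build_feature_bank(cohort, plan, fc, features)
  n_cand <- vapply(bank$participants, function(b) length(b$freq_candidates), 1L)
  set.seed(substream_seed(plan$seed, iteration_seed, 7))
  picks <- vapply(n_cand, function(k) sample.int(k, 1L), 1L)
  X <- list()
  for (kind in bank$features) {
    rows <- vector("list", 2L * n_p)
    for (p in seq_len(n_p)) {
      rows[[2 * p - 1]] <- bank$participants[[p]]$rare[[kind]]
      rows[[2 * p]] <- bank$participants[[p]]$freq_candidates[[picks[p]]][[kind]]
    }
    X[[kind]] <- do.call(rbind, rows)
  }
  list(X = X, y = y, participant = participant, n = 2L * n_p, picks = picks)
}

#' Assemble one iteration's single-trial dataset
#'
#' Per participant: every rare trial plus an equal number of frequent trials
#' drawn for this iteration (24 + 24 by default; 4800 + 4800 samples for a
#' 200-participant cohort). Single-trial features: the baselined epoch
#' waveform (`erp`), per-trial wavelet amplitude (`tf_power`), and the raw
#' wavelet phase angle (`tf_phase`).
#'
#' @inheritParams build_average_dataset
#' @param features subset of `c("erp", "tf_power", "tf_phase")`, or
#'   `character(0)` for a count-only dataset.
#' @return as [build_average_dataset()].
#' @export
build_single_trial_dataset <- function(cohort, plan, iteration_seed,
                                       fc = feature_config(),
                                       features = c("erp", "tf_power", "tf_phase")) {
  n_p <- length(cohort)
  need_cwt <- any(c("tf_power", "tf_phase") %in% features)
  Xl <- list(); yl <- list(); pl <- list()
  for (p in seq_len(n_p)) {
    rec <- cohort[[p]]
    rare_idx <- which(rec$labels == "rare")
    freq_idx <- which(rec$labels == "frequent")
    n_take <- length(rare_idx)
    if (length(freq_idx) < n_take)
      stop("participant ", rec$participant_id,
           ": fewer frequent than rare trials")
    set.seed(substream_seed(plan$seed, iteration_seed, p, 11))
    take_freq <- sort(sample(freq_idx, n_take))
    trials <- c(rare_idx, take_freq)
    yl[[p]] <- rep(c(1L, 0L), c(n_take, n_take))
    pl[[p]] <- rep(rec$participant_id, 2 * n_take)
    if (length(features) == 0) next
    times <- rec_times(rec)
    dec <- NULL
    if (need_cwt)
      dec <- cwt(rec, wavelet_spec(fc$freqs, rec$srate, fc$decay))
    Xp <- list()
    if ("erp" %in% features) {
      bl <- baseline_correct(rec$data[trials, , , drop = FALSE], times,
                             fc$baseline)
      Xp$erp <- t(vapply(seq_along(trials), function(i) {
        x <- bl[i, , , drop = FALSE]
        dim(x) <- dim(bl)[2:3]
        flatten_feature(x, times, fc$crop)
      }, numeric(length(flatten_feature(matrix(0, dim(bl)[2], dim(bl)[3]),
                                        times, fc$crop)))))
    }
    if ("tf_power" %in% features) {
      amp <- tf_power(dec, trials, fc$baseline, average = FALSE)
      Xp$tf_power <- t(vapply(seq_along(trials), function(i) {
        x <- amp[i, , , , drop = FALSE]
        dim(x) <- dim(amp)[2:4]
        flatten_feature(x, dec$times, fc$crop)
      }, numeric(ncol_after_crop(dim(amp)[2:4], dec$times, fc$crop))))
    }
    if ("tf_phase" %in% features) {
      Xp$tf_phase <- t(vapply(trials, function(tr)
        flatten_feature(tf_phase(dec, tr)$tensor, dec$times, fc$crop),
        numeric(ncol_after_crop(dim(dec$coeffs)[2:4], dec$times, fc$crop))))
    }
    Xl[[p]] <- Xp
  }
  y <- unlist(yl)
  participant <- unlist(pl)
  if (length(features) == 0)
    return(list(X = NULL, y = y, participant = participant, n = length(y)))
  X <- list()
  for (kind in features)
    X[[kind]] <- do.call(rbind, lapply(Xl, `[[`, kind))
  list(X = X, y = y, participant = participant, n = length(y))
}

ncol_after_crop <- function(dims, times, crop) {
  prod(dims[-length(dims)]) * sum(times >= crop[1] & times <= crop[2])
}

#' Random train/test split
#'
#' Sample-level uniform split without replacement (a participant's samples
#' may straddle the two sides, as in the reference protocol); set
#' `grouped = TRUE` for a leakage-safe participant-level split.
#'
#' @param n number of samples.
#' @param test_fraction fraction held out, in (0, 1).
#' @param seed split seed.
#' @param grouped split by participant instead of by sample.
#' @param participant participant id per sample (required when grouped).
#' @return list with integer index vectors `train` and `test`.
#' @export
split_samples <- function(n, test_fraction, seed, grouped = FALSE,
                          participant = NULL) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  set.seed(seed)
  if (grouped) {
    if (is.null(participant)) stop("grouped split needs participant ids")
    ids <- unique(participant)
    test_ids <- sample(ids, max(1, round(length(ids) * test_fraction)))
    test <- which(participant %in% test_ids)
  } else {
    n_test <- round(n * test_fraction)
    if (n_test < 1 || n_test >= n)
      stop("degenerate split: ", n_test, " of ", n, " samples in test")
    test <- sort(sample.int(n, n_test))
  }
  if (length(test) == 0 || length(test) == n)
    stop("degenerate split: one side is empty")
  list(train = setdiff(seq_len(n), test), test = test)
}

#' All single and composite feature sets
#' @param features ordered feature kinds.
#' @return list of character vectors: each single, each pair, the full set.
#' @export
model_feature_sets <- function(features) {
  k <- length(features)
  sets <- list()
  for (size in seq_len(k))
    sets <- c(sets, utils::combn(features, size, simplify = FALSE))
  sets
}

set_name <- function(kinds) paste(kinds, collapse = "+")

#' Run the full iterated train/test procedure
#'
#' For every iteration: redraw the per-participant frequent samples, re-split
#' train/test, train the single-feature models, transfer-initialize each
#' composite from its trained constituents and train it, and record held-out
#' accuracy after every training epoch. Fully deterministic given the plan
#' seed.
#'
#' @param cohort list of [epoched_recording]s.
#' @param plan a [sampling_plan()] (its `mode` selects trial-average or
#'   single-trial datasets and feature kinds).
#' @param fc a [feature_config()].
#' @param tc a [training_config()] (its seed field is overridden per
#'   iteration from the plan seed).
#' @param features feature kinds (defaults by mode: trial-average
#'   erp/tf_power/phase_sync, single-trial erp/tf_power/tf_phase).
#' @param grouped use participant-grouped splits.
#' @param verbose print progress.
#' @return list with `results` (data frame: iteration, model, epoch,
#'   accuracy), `models` (trained models of the last iteration), `plan`,
#'   `features`.
#' @export
run_procedure <- function(cohort, plan, fc = feature_config(),
                          tc = training_config(), features = NULL,
                          grouped = FALSE, verbose = FALSE) {
  if (is.null(features)) {
    features <- if (plan$mode == "trial_average")
      c("erp", "tf_power", "phase_sync") else c("erp", "tf_power", "tf_phase")
  }
  sets <- model_feature_sets(features)
  bank <- NULL
  if (plan$mode == "trial_average") {
    ef_log(verbose, "building feature bank (%d participants)", length(cohort))
    bank <- build_feature_bank(cohort, plan, fc, features, verbose = verbose)
  }
  records <- vector("list", plan$n_iterations)
  models <- NULL
  for (it in seq_len(plan$n_iterations)) {
    ds <- if (plan$mode == "trial_average")
      build_average_dataset(cohort, plan, it, fc, features, bank = bank)
    else
      build_single_trial_dataset(cohort, plan, it, fc, features)
    sp <- split_samples(ds$n, plan$test_fraction,
                        seed = substream_seed(plan$seed, it, 2),
                        grouped = grouped, participant = ds$participant)
    Xtr <- lapply(ds$X, function(m) m[sp$train, , drop = FALSE])
    Xte <- lapply(ds$X, function(m) m[sp$test, , drop = FALSE])
    ytr <- ds$y[sp$train]; yte <- ds$y[sp$test]
    dims <- vapply(ds$X, ncol, 1L)

    singles <- list(); recs_it <- list()
    for (kind in features) {
      m0 <- classifier_model(dims[kind],
                             seed = substream_seed(plan$seed, it, 3, match(kind, features)))
      tc_it <- tc; tc_it$seed <- substream_seed(plan$seed, it, 4, match(kind, features))
      fit <- suppressWarnings(
        train_model(m0, Xtr[kind], ytr, tc_it, Xte[kind], yte))
      singles[[kind]] <- fit$model
      recs_it[[set_name(kind)]] <- fit$val_accuracy
    }
    for (s in sets[lengths(sets) > 1]) {
      comp <- transfer_init(singles[s])
      tc_it <- tc; tc_it$seed <- substream_seed(plan$seed, it, 5,
                                                sum(match(s, features)))
      fit <- suppressWarnings(
        train_model(comp, Xtr[s], ytr, tc_it, Xte[s], yte))
      singles[[set_name(s)]] <- fit$model
      recs_it[[set_name(s)]] <- fit$val_accuracy
    }
    records[[it]] <- do.call(rbind, lapply(names(recs_it), function(nm)
      data.frame(iteration = it, model = nm,
                 epoch = seq_along(recs_it[[nm]]),
                 accuracy = recs_it[[nm]])))
    models <- singles
    ef_log(verbose, "iteration %d/%d done", it, plan$n_iterations)
  }
  list(results = do.call(rbind, records), models = models, plan = plan,
       features = features)
}

#' Aggregate accuracy trajectories across iterations
#'
#' @param results the `results` data frame of [run_procedure()] (columns
#'   iteration, model, epoch, accuracy), from at least 2 iterations.
#' @param final_window number of final epochs averaged into each iteration's
#'   summary accuracy (1 for trial-average runs, 20 for single-trial runs).
#' @return list with `trajectory` (per model and epoch, mean accuracy over
#'   iterations) and `summary` (per model: mean and standard error of the
#'   final-window accuracy across iterations).
#' @export
aggregate_results <- function(results, final_window = 1) {
  n_iter <- length(unique(results$iteration))
  if (n_iter < 2) stop("need at least 2 iterations to aggregate")
  trajectory <- stats::aggregate(accuracy ~ model + epoch, results, mean)
  names(trajectory)[3] <- "mean_accuracy"
  n_epochs <- max(results$epoch)
  finals <- results[results$epoch > n_epochs - final_window, ]
  per_iter <- stats::aggregate(accuracy ~ model + iteration, finals, mean)
  agg <- function(f) stats::aggregate(accuracy ~ model, per_iter, f)
  summary <- agg(mean)
  names(summary)[2] <- "mean_accuracy"
  summary$sem <- agg(stats::sd)$accuracy / sqrt(n_iter)
  summary$n_iterations <- n_iter
  list(trajectory = trajectory, summary = summary)
}
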