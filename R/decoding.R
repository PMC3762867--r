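## Pairwise phoneme-identity decoding: feature assembly, per-fold z-scoring,
## train-set PCA at 95% retained variance, regularized two-class LDA under
## stratified twofold cross-validation.

#' Precompute per-trial, per-electrode spectrograms
#'
#' Spectrograms are the expensive part of feature assembly; computing them
#' once and passing the cache to [build_features()] lets the decoding and
#' information-flow analyses reuse them across feature windows.
#'
#' @param epochs list of [epoch_array()].
#' @param electrodes electrode indices.
#' @param spec_cfg a [spectrogram_config()].
#' @return nested list: `[[trial]][[as.character(electrode)]]` spectrogram.
#' @export
compute_spectrograms <- function(epochs, electrodes,
                                 spec_cfg = spectrogram_config()) {
  lapply(epochs, function(ep) {
    out <- lapply(electrodes, function(e)
      multitaper_spectrogram(ep, e, spec_cfg))
    names(out) <- as.character(electrodes)
    out
  })
}

#' Assemble the trial x feature matrix
#'
#' One row per trial, concatenating for each selected electrode the raw
#' voltage trace and the unwrapped spectrogram cells over the feature window
#' (default: video onset to phoneme offset, -1.0 to +0.5 s). Column order is
#' deterministic and identical across trials; the column catalog maps every
#' column to (electrode, kind, time, frequency).
#'
#' @param epochs list of [epoch_array()] sharing one time grid.
#' @param trials trial metadata (rows parallel to `epochs`).
#' @param electrodes electrode indices to include.
#' @param spec_cfg spectrogram parameters for the power features.
#' @param window feature window (s re audio onset).
#' @param spectrograms optional cache from [compute_spectrograms()].
#' @return a `feature_matrix`: list with `X` (matrix), `catalog`
#'   (data.frame), `window`.
#' @export
build_features <- function(epochs, trials, electrodes,
                           spec_cfg = spectrogram_config(fmin = 75, fmax = 200,
                                                         step_s = 0.05),
                           window = c(-1.0, 0.5),
                           spectrograms = NULL) {
  missing_ep <- which(vapply(epochs, is.null, logical(1)))
  if (length(missing_ep) > 0L)
    stop_stgflow("missing epochs for trial_ids: ",
                 paste(trials$trial_id[missing_ep], collapse = ", "))
  if (nrow(trials) != length(epochs))
    stop_stgflow("trials and epochs must be parallel")
  ref <- epochs[[1]]
  vidx <- epoch_window_idx(ref, window[1], window[2])
  vtimes <- epoch_times(ref)[vidx]
  if (is.null(spectrograms))
    spectrograms <- compute_spectrograms(epochs, electrodes, spec_cfg)
  sref <- spectrograms[[1]][[as.character(electrodes[1])]]
  tsel <- sref$times >= window[1] & sref$times <= window[2]
  stimes <- sref$times[tsel]
  sfreqs <- sref$freqs

  rows <- lapply(seq_along(epochs), function(i) {
    ep <- epochs[[i]]
    unlist(lapply(electrodes, function(e) {
      sp <- spectrograms[[i]][[as.character(e)]]
      c(ep$data[vidx, e], as.vector(sp$power[tsel, , drop = FALSE]))
    }), use.names = FALSE)
  })
  X <- do.call(rbind, rows)
  catalog <- do.call(rbind, lapply(electrodes, function(e) {
    rbind(
      data.frame(electrode = e, kind = "voltage", time = vtimes,
                 freq = NA_real_),
      data.frame(electrode = e, kind = "power",
                 time = rep(stimes, times = length(sfreqs)),
                 freq = rep(sfreqs, each = length(stimes)))
    )
  }))
  if (nrow(catalog) != ncol(X))
    stop_stgflow("internal error: catalog does not match feature columns")
  structure(list(X = X, catalog = catalog, window = window),
            class = "feature_matrix")
}

feature_X <- function(features) {
  if (inherits(features, "feature_matrix")) features$X else as.matrix(features)
}

## train-only transform: z-score by training mean/SD, then project on the
## leading principal axes reaching >= variance_kept cumulative variance
fit_transform <- function(Xtr, variance_kept) {
  ntr <- nrow(Xtr)
  mu <- colMeans(Xtr)
  v <- colMeans(Xtr^2) - mu^2
  sdv <- sqrt(pmax(v, 0) * ntr / (ntr - 1))
  keep <- which(sdv > 1e-12)
  Z <- sweep(sweep(Xtr[, keep, drop = FALSE], 2L, mu[keep]), 2L, sdv[keep], `/`)
  sv <- svd(Z)
  lam <- sv$d^2
  pos <- lam > max(lam) * 1e-12
  cum <- cumsum(lam[pos]) / sum(lam[pos])
  k <- which(cum >= variance_kept)[1]
  V <- sv$v[, seq_len(k), drop = FALSE]
  list(mu = mu[keep], sd = sdv[keep], keep = keep, rotation = V, k = k,
       n_dropped = ncol(Xtr) - length(keep))
}

apply_transform <- function(tr, X) {
  Z <- sweep(sweep(X[, tr$keep, drop = FALSE], 2L, tr$mu), 2L, tr$sd, `/`)
  Z %*% tr$rotation
}

## two-class LDA, pooled covariance, equal priors, ridge shrinkage toward
## the scaled identity (feature count >> trial count makes the raw pooled
## covariance ill-conditioned)
fit_lda <- function(S0, S1, m0, m1, n0, n1, ridge) {
  Sp <- ((n0 - 1) * S0 + (n1 - 1) * S1) / (n0 + n1 - 2)
  k <- length(m0)
  Sr <- (1 - ridge) * Sp + ridge * mean(diag(Sp)) * diag(k)
  w <- solve(Sr, m1 - m0)
  list(w = w, threshold = sum(w * (m0 + m1)) / 2)
}

## one train/predict pass shared by the CV and cross-condition decoders
train_predict <- function(Xtr, ytr, Xte, pair, variance_kept, ridge) {
  trans <- fit_transform(Xtr, variance_kept)
  Str <- apply_transform(trans, Xtr)
  Ste <- apply_transform(trans, Xte)
  i0 <- ytr == pair[1]
  m0 <- colMeans(Str[i0, , drop = FALSE])
  m1 <- colMeans(Str[!i0, , drop = FALSE])
  cv <- function(M) if (nrow(M) > 1) cov(M) else matrix(0, ncol(M), ncol(M))
  lda <- fit_lda(cv(Str[i0, , drop = FALSE]), cv(Str[!i0, , drop = FALSE]),
                 m0, m1, sum(i0), sum(!i0), ridge)
  sc <- as.vector(Ste %*% lda$w)
  list(pred = ifelse(sc > lda$threshold, pair[2], pair[1]),
       transform = trans)
}

#' Pairwise twofold cross-validated classification
#'
#' Trials of the two labels are split into two stratified, seeded folds. Per
#' fold, the z-scoring statistics and principal axes are computed on the
#' training half only (retaining the minimal number of leading components
#' whose cumulative variance reaches `variance_kept`); the test half is
#' projected with the training transform and classified by a regularized
#' two-class linear discriminant. Confusion counts are accumulated over both
#' folds.
#'
#' @param features a `feature_matrix` or plain matrix (rows = trials).
#' @param labels character vector of trial labels.
#' @param pair length-2 character vector: the two labels to discriminate.
#' @param variance_kept cumulative variance retained by the train-fold PCA.
#' @param seed integer seed for the fold split.
#' @param ridge shrinkage weight toward the scaled identity in the pooled
#'   covariance.
#' @return a `confusion_table`: 2x2 `counts` (true x predicted), the label
#'   `pair`, per-trial `predictions` (row, truth, predicted, fold), per-fold
#'   `transform` digests, and `accuracy`.
#' @export
fit_predict_pairwise <- function(features, labels, pair,
                                 variance_kept = 0.95, seed = 1L,
                                 ridge = 0.1) {
  X <- feature_X(features)
  if (length(labels) != nrow(X))
    stop_stgflow("labels must match feature rows")
  rows <- which(labels %in% pair)
  y <- labels[rows]
  if (any(table(factor(y, levels = pair)) < 2L))
    stop_stgflow("need at least 2 trials per label in the pair")
  fold <- integer(length(rows))
  with_seed(seed, {
    for (lab in pair) {
      ii <- sample(which(y == lab))
      fold[ii] <- rep_len(1:2, length(ii))
    }
  })
  preds <- character(length(rows))
  transforms <- vector("list", 2L)
  dropped <- 0L
  for (f in 1:2) {
    te <- which(fold == f)
    tr <- which(fold != f)
    if (length(unique(y[tr])) < 2L || length(unique(y[te])) < 2L)
      stop_stgflow("a cross-validation fold contains a single class")
    fitted <- train_predict(X[rows[tr], , drop = FALSE], y[tr],
                            X[rows[te], , drop = FALSE], pair,
                            variance_kept, ridge)
    preds[te] <- fitted$pred
    trans <- fitted$transform
    dropped <- dropped + trans$n_dropped
    transforms[[f]] <- list(k = trans$k,
                            mu_digest = sum(trans$mu),
                            sd_digest = sum(trans$sd),
                            rot_digest = sum(abs(trans$rotation)))
  }
  counts <- table(true = factor(y, levels = pair),
                  predicted = factor(preds, levels = pair))
  counts <- matrix(as.integer(counts), 2, 2,
                   dimnames = list(true = pair, predicted = pair))
  structure(list(counts = counts, labels = pair,
                 predictions = data.frame(row = rows, truth = y,
                                          predicted = preds, fold = fold),
                 transforms = transforms,
                 n_dropped_columns = dropped,
                 accuracy = sum(diag(counts)) / sum(counts)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> %s vs %s, accuracy %.1f%%\n",
              x$labels[1], x$labels[2], 100 * x$accuracy))
  print(x$counts)
  invisible(x)
}

#' Classification accuracy of a confusion table
#'
#' @param cm a `confusion_table` or plain counts matrix.
#' @return fraction of correctly classified test trials.
#' @export
cm_accuracy <- function(cm) {
  counts <- if (inherits(cm, "confusion_table")) cm$counts else cm
  sum(diag(counts)) / sum(counts)
}

## Subsample trial indices so the non-target attribute's label distribution
## is identical between the two classes of a pair. On incongruent trials the
## video and audio labels are structurally correlated (they can never
## coincide), so without matching, a purely video-driven neural code makes
## the *audio* labels partially decodable (and vice versa); matching removes
## that design confound so accuracy reflects neural coding of the target
## attribute alone.
balance_pair_confound <- function(idx, target_labels, confound_labels, pair,
                                  seed) {
  kept <- integer(0)
  with_seed(seed, {
    for (cl in unique(confound_labels)) {
      i1 <- idx[target_labels[idx] == pair[1] & confound_labels[idx] == cl]
      i2 <- idx[target_labels[idx] == pair[2] & confound_labels[idx] == cl]
      m <- min(length(i1), length(i2))
      if (m > 0L)
        kept <- c(kept, sample(i1, m), sample(i2, m))
    }
  })
  sort(kept)
}

#' Decode stimulus identity over all label pairs
#'
#' Runs [fit_predict_pairwise()] for every unordered pair of labels present
#' under the chosen target labeling (video or audio identity), optionally
#' restricted to one or more trial categories (e.g. McGurk trials only).
#' Chance performance is 50% for every pairwise classification.
#'
#' Three pair schemes control which trials enter each pairwise comparison:
#'
#' * `"balanced"` (default): all trials with a target label in the pair,
#'   subsampled so the non-target attribute's label distribution is
#'   identical between the two classes. This removes the design confound
#'   that video and audio identity never coincide on incongruent trials
#'   (which would otherwise let a purely video-driven code predict audio
#'   labels above chance), so accuracy reflects neural coding of the target
#'   attribute alone.
#' * `"within_pair"`: only trials whose video *and* audio identity both lie
#'   in the tested pair - for McGurk trials, the reciprocal incongruent
#'   combinations, on which the two attribute labelings are exactly
#'   complementary.
#' * `"all"`: every trial with a target label in the pair, unadjusted.
#'
#' @param features a `feature_matrix` (rows parallel to `trials`).
#' @param trials trial metadata.
#' @param target `"video"` or `"audio"`: which stimulus identity labels the
#'   trials.
#' @param category optional character vector of categories to keep.
#' @param pair_scheme trial selection per pair, see above.
#' @param variance_kept,seed,ridge passed to [fit_predict_pairwise()].
#' @return list with `target`, `pair_accuracies` (data.frame), `confusions`
#'   (named list of `confusion_table`s) and `mean_accuracy`.
#' @export
decode_stimulus_identity <- function(features, trials,
                                     target = c("video", "audio"),
                                     category = NULL,
                                     pair_scheme = c("balanced",
                                                     "within_pair", "all"),
                                     variance_kept = 0.95, seed = 1L,
                                     ridge = 0.1) {
  target <- match.arg(target)
  pair_scheme <- match.arg(pair_scheme)
  X <- feature_X(features)
  keep <- rep(TRUE, nrow(trials))
  if (!is.null(category)) {
    if (anyNA(trials$category))
      stop_stgflow("trials must be categorized before filtering by category")
    keep <- trials$category %in% category
  }
  labels <- trials[[paste0(target, "_phoneme")]]
  confound <- trials[[paste0(setdiff(c("video", "audio"), target),
                             "_phoneme")]]
  labs <- sort(unique(labels[keep]))
  if (length(labs) < 2L)
    stop_stgflow("fewer than 2 labels present after filtering")
  pairs <- combn(labs, 2L)
  res <- list()
  acc <- NULL
  for (j in seq_len(ncol(pairs))) {
    pair <- pairs[, j]
    pname <- paste(pair, collapse = "-")
    idx <- which(keep & labels %in% pair)
    if (pair_scheme == "within_pair")
      idx <- idx[confound[idx] %in% pair]
    else if (pair_scheme == "balanced")
      idx <- balance_pair_confound(idx, labels, confound, pair,
                                   seed = sub_seed(seed, paste0("bal_", pname)))
    nmin <- if (length(idx)) min(table(factor(labels[idx], levels = pair)))
            else 0L
    if (nmin < 2L) {
      warning("skipping pair ", pname, ": fewer than 2 trials per label",
              call. = FALSE)
      next
    }
    cm <- fit_predict_pairwise(X[idx, , drop = FALSE], labels[idx], pair,
                               variance_kept = variance_kept,
                               seed = sub_seed(seed, pname), ridge = ridge)
    res[[pname]] <- cm
    acc <- rbind(acc, data.frame(pair = pname, n_test = sum(cm$counts),
                                 accuracy = cm$accuracy))
  }
  if (length(res) == 0L) stop_stgflow("no decodable pairs")
  list(target = target, pair_accuracies = acc, confusions = res,
       mean_accuracy = mean(acc$accuracy))
}

#' Which stimulus attribute do McGurk-trial representations follow?
#'
#' For each unordered phoneme pair, a discriminant is trained on the matched
#' trials of the two phonemes - where video and audio agree, so the phoneme
#' identity of the neural pattern is unambiguous - and applied to the
#' reciprocal McGurk trials of the pair (video A & audio B, video B &
#' audio A). Each held-out prediction is then scored twice: against the
#' trial's video identity and against its audio identity. Because the two
#' labelings are complementary on reciprocal trials, a representation that
#' follows the video stimulus yields video-identity accuracy above 50% and
#' audio-identity accuracy below 50% (the classifier consistently picks the
#' wrong auditory identity), and conversely for an audio-driven code.
#'
#' @param features a `feature_matrix` (rows parallel to `trials`).
#' @param trials categorized trial metadata.
#' @param variance_kept,ridge classifier settings (see
#'   [fit_predict_pairwise()]).
#' @return list with `pair_accuracies` (data.frame: pair, n_test,
#'   video_accuracy, audio_accuracy), overall `video_accuracy` and
#'   `audio_accuracy` (means across pairs).
#' @export
decode_mcgurk_identity <- function(features, trials, variance_kept = 0.95,
                                   ridge = 0.1) {
  if (anyNA(trials$category))
    stop_stgflow("trials must be categorized first")
  X <- feature_X(features)
  labs <- sort(unique(c(trials$video_phoneme, trials$audio_phoneme)))
  pairs <- combn(labs, 2L)
  acc <- NULL
  for (j in seq_len(ncol(pairs))) {
    pair <- pairs[, j]
    pname <- paste(pair, collapse = "-")
    tr <- which(trials$category == "matched" &
                  trials$video_phoneme %in% pair)
    te <- which(trials$category == "mcgurk" &
                  trials$video_phoneme %in% pair &
                  trials$audio_phoneme %in% pair)
    if (length(te) == 0L ||
        any(table(factor(trials$video_phoneme[tr], levels = pair)) < 2L)) {
      warning("skipping pair ", pname,
              ": insufficient matched or McGurk trials", call. = FALSE)
      next
    }
    fitted <- train_predict(X[tr, , drop = FALSE],
                            trials$video_phoneme[tr],
                            X[te, , drop = FALSE], pair,
                            variance_kept, ridge)
    acc <- rbind(acc, data.frame(
      pair = pname, n_test = length(te),
      video_accuracy = mean(fitted$pred == trials$video_phoneme[te]),
      audio_accuracy = mean(fitted$pred == trials$audio_phoneme[te])))
  }
  if (is.null(acc)) stop_stgflow("no decodable McGurk pairs")
  list(pair_accuracies = acc,
       video_accuracy = mean(acc$video_accuracy),
       audio_accuracy = mean(acc$audio_accuracy))
}
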