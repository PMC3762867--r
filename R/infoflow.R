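## Conditional mutual information between stimulus identity and decoded
## responses on pairs of electrodes, and the directed "information tendency"
## over task intervals.

#' Joint distribution over (stimulus, response on X, response on Y)
#'
#' Builds p(s, r_x, r_y) = p(s) p(r_x|s) p(r_y|s) from the two electrodes'
#' confusion tables, i.e. assuming the decoded responses are conditionally
#' independent given the stimulus - the structure available when only
#' per-electrode classification frequencies are tabulated. Per-electrode
#' conditionals are the row-normalized confusion counts (optionally with
#' additive smoothing); the stimulus prior defaults to the empirical label
#' frequencies.
#'
#' @param cm_x,cm_y `confusion_table`s (or plain true x predicted count
#'   matrices) over the same label pair with identical per-label trial
#'   counts.
#' @param prior optional stimulus prior (sums to 1).
#' @param smoothing additive pseudo-count per cell (default 0: the
#'   0 log 0 = 0 convention handles empty cells).
#' @return a `joint_sr` array with dimensions (S, Rx, Ry).
#' @export
joint_from_confusions <- function(cm_x, cm_y, prior = NULL, smoothing = 0) {
  cx <- if (inherits(cm_x, "confusion_table")) cm_x$counts else as.matrix(cm_x)
  cy <- if (inherits(cm_y, "confusion_table")) cm_y$counts else as.matrix(cm_y)
  labs <- rownames(cx) %||% as.character(seq_len(nrow(cx)))
  laby <- rownames(cy) %||% as.character(seq_len(nrow(cy)))
  if (!identical(dim(cx), dim(cy)) || !identical(labs, laby))
    stop_stgflow("confusion tables are over different label sets")
  rx <- rowSums(cx); ry <- rowSums(cy)
  if (!isTRUE(all.equal(rx, ry)))
    stop_stgflow("per-label trial counts differ between the two tables")
  if (any(rx == 0))
    stop_stgflow("stimulus label(s) with zero trials: ",
                 paste(labs[rx == 0], collapse = ", "))
  cx <- cx + smoothing; cy <- cy + smoothing
  px <- cx / rowSums(cx)
  py <- cy / rowSums(cy)
  if (is.null(prior)) prior <- rx / sum(rx)
  if (abs(sum(prior) - 1) > 1e-9) stop_stgflow("prior must sum to 1")
  nl <- length(labs)
  p <- array(0, dim = c(nl, nl, nl),
             dimnames = list(S = labs, Rx = labs, Ry = labs))
  for (s in seq_len(nl))
    p[s, , ] <- prior[s] * outer(px[s, ], py[s, ])
  p <- p / sum(p)
  structure(p, class = c("joint_sr", "array"))
}

#' Joint distribution from paired per-trial predictions
#'
#' The alternative to [joint_from_confusions()] when per-trial predictions
#' on both electrodes are available (always true for synthetic data): the
#' empirical joint relative frequency of (truth, prediction on X,
#' prediction on Y), which does not assume conditional independence.
#'
#' @param truth,pred_x,pred_y parallel character vectors.
#' @param labels the label set (default: sorted unique truth values).
#' @return a `joint_sr` array.
#' @export
joint_from_predictions <- function(truth, pred_x, pred_y,
                                   labels = sort(unique(truth))) {
  stopifnot(length(truth) == length(pred_x),
            length(truth) == length(pred_y))
  tab <- table(S = factor(truth, levels = labels),
               Rx = factor(pred_x, levels = labels),
               Ry = factor(pred_y, levels = labels))
  p <- array(as.numeric(tab), dim = dim(tab), dimnames = dimnames(tab))
  structure(p / sum(p), class = c("joint_sr", "array"))
}

validate_joint <- function(joint) {
  p <- unclass(joint)
  if (length(dim(p)) != 3L) stop_stgflow("joint must be a 3-d array (S, Rx, Ry)")
  if (any(p < 0)) stop_stgflow("joint has negative entries")
  if (abs(sum(p) - 1) > 1e-12) stop_stgflow("joint does not sum to 1")
  p
}

## Shannon entropy (bits) of a (possibly unnormalized-margin) probability
## array, with 0 log 0 = 0.
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Conditional mutual information I(S; R | R') in bits
#'
#' Plug-in estimate of the additional information one electrode's decoded
#' response carries about the stimulus beyond what the other electrode's
#' response already provides: with `conditioned = "Ry"` this is
#' I(S; Rx | Ry) = H(S, Ry) + H(Rx, Ry) - H(S, Rx, Ry) - H(Ry). Always
#' non-negative; 0 log 0 = 0.
#'
#' @param joint a `joint_sr` array over (S, Rx, Ry).
#' @param conditioned which response variable is conditioned on: `"Ry"`
#'   gives I(S;Rx|Ry), `"Rx"` gives I(S;Ry|Rx).
#' @return conditional mutual information in bits.
#' @export
conditional_mutual_information <- function(joint,
                                           conditioned = c("Ry", "Rx")) {
  conditioned <- match.arg(conditioned)
  p <- validate_joint(joint)
  ## orient so the conditioning variable is the 3rd axis
  if (conditioned == "Rx") p <- aperm(p, c(1, 3, 2))
  h_sy  <- entropy_bits(apply(p, c(1, 3), sum))   # H(S, Rcond)
  h_xy  <- entropy_bits(apply(p, c(2, 3), sum))   # H(Rother, Rcond)
  h_sxy <- entropy_bits(p)                        # H(S, Rx, Ry)
  h_y   <- entropy_bits(apply(p, 3, sum))         # H(Rcond)
  max(h_sy + h_xy - h_sxy - h_y, 0)
}

#' Directed information tendency between two electrodes
#'
#' The net directional information transfer toward electrode X:
#' I(S;Rx|Ry) - I(S;Ry|Rx) (bits). Positive values indicate transfer from
#' electrode Y (source) to electrode X (destination); calling with the
#' caudal electrode as Y and the rostral one as X makes positive values
#' caudal-to-rostral. Exactly antisymmetric under argument swap.
#'
#' @param cm_x destination-electrode confusion table.
#' @param cm_y source-electrode confusion table.
#' @param prior optional stimulus prior.
#' @param smoothing additive smoothing for the conditionals.
#' @return signed tendency in bits.
#' @export
information_tendency <- function(cm_x, cm_y, prior = NULL, smoothing = 0) {
  j <- joint_from_confusions(cm_x, cm_y, prior = prior, smoothing = smoothing)
  conditional_mutual_information(j, "Ry") -
    conditional_mutual_information(j, "Rx")
}

## tendency from per-trial prediction vectors (used by the permutation null)
tendency_from_predictions <- function(truth, pred_dst, pred_src, labels) {
  cm <- function(pred) {
    t0 <- table(factor(truth, levels = labels), factor(pred, levels = labels))
    matrix(as.integer(t0), length(labels), length(labels),
           dimnames = list(true = labels, predicted = labels))
  }
  information_tendency(cm(pred_dst), cm(pred_src))
}

#' Interval-resolved directed information transfer
#'
#' For each one-second task interval, each edge along the superior temporal
#' gyrus (posterior to middle, middle to anterior) and each stimulus
#' attribute (video or audio identity), single-electrode pairwise classifiers
#' are fitted on interval-limited features, per-electrode confusion tables
#' are formed, and the information tendency is computed per label pair
#' (edge convention: positive = caudal-to-rostral). Per-pair values are the
#' replicates summarized by the mean.
#'
#' @param dataset an `ecog_dataset` (epochs at the analysis rate).
#' @param roles named electrode indices (posterior, middle, anterior); by
#'   default the generator's designated roles.
#' @param spec_cfg spectrogram parameters for the power features.
#' @param intervals named list of length-2 interval bounds (s).
#' @param attributes stimulus attributes to analyze.
#' @param variance_kept,seed,ridge classifier settings.
#' @param spectrograms optional cache from [compute_spectrograms()]
#'   (full-epoch; sliced per interval internally).
#' @return a `tendency_result`: `summary` (interval, edge, attribute, mean
#'   tendency_bits, n_pairs), `detail` (per-pair rows) and the per-condition
#'   prediction sets used by [tendency_null_band()].
#' @export
interval_analysis <- function(dataset,
                              roles = dataset$config$role_electrodes,
                              spec_cfg = spectrogram_config(fmin = 75,
                                                            fmax = 200,
                                                            step_s = 0.05),
                              intervals = list(
                                baseline = interval_bounds("baseline"),
                                video_only = interval_bounds("video_only"),
                                audio_video = interval_bounds("audio_video")),
                              attributes = c("video", "audio"),
                              variance_kept = 0.95, seed = 1L, ridge = 0.1,
                              spectrograms = NULL) {
  if (is.null(roles) ||
      !all(c("posterior", "middle", "anterior") %in% names(roles)))
    stop_stgflow("roles must name posterior, middle and anterior electrodes")
  ep1 <- dataset$epochs[[1]]
  tt <- epoch_times(ep1)
  for (iv in intervals)
    if (iv[1] < tt[1] - 1e-9 || iv[2] > tt[length(tt)] + 1/ep1$fs)
      stop_stgflow("interval [", iv[1], ", ", iv[2],
                   "] outside epoch support")
  electrodes <- unname(roles[c("posterior", "middle", "anterior")])
  if (is.null(spectrograms))
    spectrograms <- compute_spectrograms(dataset$epochs, electrodes, spec_cfg)
  edges <- list(
    c(source = "posterior", destination = "middle"),
    c(source = "middle", destination = "anterior")
  )
  detail <- NULL
  predsets <- list()
  for (iv_name in names(intervals)) {
    iv <- intervals[[iv_name]]
    feats <- lapply(names(roles), function(r) {
      build_features(dataset$epochs, dataset$trials, roles[[r]],
                     spec_cfg = spec_cfg, window = iv,
                     spectrograms = spectrograms)
    })
    names(feats) <- names(roles)
    for (attr_name in attributes) {
      labels <- dataset$trials[[paste0(attr_name, "_phoneme")]]
      labs <- sort(unique(labels))
      pairs <- combn(labs, 2L)
      for (j in seq_len(ncol(pairs))) {
        pair <- pairs[, j]
        pname <- paste(pair, collapse = "-")
        pseed <- sub_seed(seed, paste(iv_name, attr_name, pname))
        cms <- lapply(names(roles), function(r)
          fit_predict_pairwise(feats[[r]], labels, pair,
                               variance_kept = variance_kept,
                               seed = pseed, ridge = ridge))
        names(cms) <- names(roles)
        key <- paste(iv_name, attr_name, pname, sep = "|")
        predsets[[key]] <- list(
          interval = iv_name, attribute = attr_name, pair = pname,
          truth = cms$posterior$predictions$truth,
          preds = lapply(cms, function(cm) cm$predictions$predicted),
          labels = pair)
        for (ed in edges) {
          tend <- information_tendency(cms[[ed["destination"]]],
                                       cms[[ed["source"]]])
          detail <- rbind(detail, data.frame(
            interval = iv_name,
            edge = paste(ed["source"], ed["destination"], sep = "->"),
            attribute = attr_name, pair = pname, tendency_bits = tend))
        }
      }
    }
  }
  summary <- aggregate(tendency_bits ~ interval + edge + attribute,
                       data = detail, FUN = mean)
  summary$n_pairs <- aggregate(tendency_bits ~ interval + edge + attribute,
                               data = detail, FUN = length)$tendency_bits
  structure(list(summary = summary, detail = detail, predsets = predsets,
                 edges = edges),
            class = "tendency_result")
}

#' @export
print.tendency_result <- function(x, ...) {
  cat("<tendency_result>\n")
  print(x$summary)
  invisible(x)
}

#' Permutation-null band for interval tendencies
#'
#' Two exchangeability nulls are available. `"signflip"` (the default)
#' permutes the assignment of the two electrodes within each edge and label
#' pair, which flips the sign of that pair's tendency: it is the null of
#' directional symmetry (no net transfer) while preserving each electrode's
#' information content, and is the appropriate reference for asking whether
#' an observed net direction is real. `"label"` permutes the true-label
#' vector against the held-out predictions (jointly for the electrodes of an
#' edge): the stricter null of no stimulus information at all. Either way the
#' per-pair values are aggregated exactly as in the observed summary and the
#' band reported is the pooled min-max over all conditions and permutations
#' (a max-statistic band controlling the familywise rate across the
#' interval x edge x attribute grid).
#'
#' @param res a `tendency_result`.
#' @param n_perm number of permutations.
#' @param method `"signflip"` or `"label"` (see above).
#' @param seed RNG seed.
#' @return list with the pooled `lo`/`hi` band, the per-permutation
#'   `values` matrix (permutations x conditions), and per-condition
#'   two-sided permutation `p_values` comparing each observed mean tendency
#'   with its own condition's null.
#' @export
tendency_null_band <- function(res, n_perm = 200L,
                               method = c("signflip", "label"), seed = 1L) {
  method <- match.arg(method)
  conds <- res$summary[, c("interval", "edge", "attribute")]
  vals <- matrix(NA_real_, n_perm, nrow(conds))
  colnames(vals) <- paste(conds$interval, conds$edge, conds$attribute,
                          sep = "|")
  det_key <- paste(res$detail$interval, res$detail$edge,
                   res$detail$attribute, sep = "|")
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      if (method == "signflip") {
        flipped <- res$detail$tendency_bits *
          sample(c(-1, 1), nrow(res$detail), replace = TRUE)
        agg <- tapply(flipped, det_key, mean)
        vals[b, names(agg)] <- agg
      } else {
        det <- NULL
        for (ps in res$predsets) {
          perm <- sample(ps$truth)
          for (ed in res$edges) {
            tend <- tendency_from_predictions(
              perm, ps$preds[[ed["destination"]]], ps$preds[[ed["source"]]],
              ps$labels)
            det <- rbind(det, data.frame(
              interval = ps$interval,
              edge = paste(ed["source"], ed["destination"], sep = "->"),
              attribute = ps$attribute, tendency_bits = tend))
          }
        }
        agg <- aggregate(tendency_bits ~ interval + edge + attribute,
                         data = det, FUN = mean)
        key <- paste(agg$interval, agg$edge, agg$attribute, sep = "|")
        vals[b, key] <- agg$tendency_bits
      }
    }
  })
  obs <- setNames(res$summary$tendency_bits,
                  paste(res$summary$interval, res$summary$edge,
                        res$summary$attribute, sep = "|"))
  pvals <- vapply(colnames(vals), function(k) {
    (1 + sum(abs(vals[, k]) >= abs(obs[[k]]))) / (n_perm + 1)
  }, numeric(1))
  list(lo = min(vals), hi = max(vals), values = vals,
       p_values = pvals, method = method)
}
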