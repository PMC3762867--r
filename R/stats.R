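## Hypothesis tests applied to pipeline outputs. Two-sided by default; exact
## small-sample distributions where n permits (base R's implementations).

test_result <- function(test, statistic, p_value, n, comparison) {
  data.frame(test = test, statistic = statistic, p_value = p_value,
             n = n, comparison = comparison, stringsAsFactors = FALSE)
}

#' One-way ANOVA across trial categories with Tukey contrasts
#'
#' Tests per-trial correctness (response equals audio identity) across
#' behavioral categories with a one-way ANOVA, followed by all pairwise
#' Tukey honest-significant-difference comparisons (the Tukey-Kramer
#' procedure for unequal group sizes).
#'
#' @param correct numeric or logical vector of per-trial correctness.
#' @param category parallel vector of category labels (>= 2 levels with
#'   >= 2 trials each).
#' @return data.frame of test results: the omnibus F test, then one row per
#'   Tukey pairwise comparison (statistic = mean difference, p = adjusted).
#' @export
anova_tukey <- function(correct, category) {
  category <- factor(category)
  if (nlevels(category) < 2L)
    stop_stgflow("need at least 2 categories")
  if (any(table(category) < 2L))
    stop_stgflow("each category needs at least 2 trials")
  d <- data.frame(y = as.numeric(correct), g = category)
  fit <- aov(y ~ g, data = d)
  s <- summary(fit)[[1]]
  out <- test_result("anova", s[["F value"]][1], s[["Pr(>F)"]][1],
                     nrow(d), "omnibus across categories")
  tk <- TukeyHSD(fit)$g
  for (i in seq_len(nrow(tk))) {
    out <- rbind(out, test_result("tukey_kramer", tk[i, "diff"],
                                  tk[i, "p adj"], nrow(d),
                                  rownames(tk)[i]))
  }
  out
}

#' Mann-Whitney U test on difference-spectrogram statistics
#'
#' Two-sided rank-sum test comparing the per-electrode (or per-patient)
#' difference-spectrogram statistics of the same-video comparisons against
#' those of the same-audio comparisons.
#'
#' @param same_video_diffs,same_audio_diffs non-empty numeric samples.
#' @return one-row test-result data.frame (statistic = Mann-Whitney U of the
#'   first sample).
#' @export
mannwhitney_diffspec <- function(same_video_diffs, same_audio_diffs) {
  if (length(same_video_diffs) == 0L || length(same_audio_diffs) == 0L)
    stop_stgflow("both samples must be non-empty")
  wt <- suppressWarnings(
    wilcox.test(same_video_diffs, same_audio_diffs,
                alternative = "two.sided"))
  test_result("mann_whitney_u", unname(wt$statistic), wt$p.value,
              length(same_video_diffs) + length(same_audio_diffs),
              "same-video vs same-audio difference statistics")
}

#' One-sample Wilcoxon signed-rank test against chance
#'
#' Tests whether classification accuracies come from a distribution with
#' median equal to chance (50% for pairwise decoding). Degenerate input
#' (every accuracy exactly at chance) is reported with p = 1.
#'
#' @param accuracies numeric vector (>= 5 values).
#' @param chance chance level.
#' @return one-row test-result data.frame.
#' @export
wilcoxon_vs_chance <- function(accuracies, chance = 0.5) {
  if (length(accuracies) < 5L)
    stop_stgflow("need at least 5 accuracy values")
  if (all(accuracies == chance))
    return(test_result("wilcoxon_signed_rank", NA_real_, 1,
                       length(accuracies),
                       sprintf("accuracies vs chance = %g (degenerate)",
                               chance)))
  wt <- suppressWarnings(
    wilcox.test(accuracies, mu = chance, alternative = "two.sided"))
  test_result("wilcoxon_signed_rank", unname(wt$statistic), wt$p.value,
              length(accuracies),
              sprintf("accuracies vs chance = %g", chance))
}
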