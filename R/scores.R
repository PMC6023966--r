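## Boolean-setting error rates and continuous-setting circuit scores.
##
## The continuous scores view the classifier through a mechanistic lens: each
## gate responds to real-valued miRNA levels through a saturating (Hill-type)
## activation, the circuit output is the product of gate activations, and the
## scores (AUC, margins) summarize how well that output concentration
## separates positive from negative samples.

#' Scoring configuration
#'
#' Bundles the weight of the margin score, the circuit output model and its
#' response parameters.
#'
#' @param lambda weight in `[0, 1]` of the average margin in the combined
#'   margin score `s_m = lambda * ma + (1 - lambda) * mw`; default 0.5 (both
#'   margins equally relevant).
#' @param K response threshold(s) in expression units: a scalar applied to all
#'   miRNAs or a named vector per miRNA.  A natural choice is the dataset's
#'   binarization threshold.
#' @param k Hill steepness (dimensionless, default 4); large values approach
#'   the Boolean step response.
#' @param ymax maximal circuit output (arbitrary concentration units,
#'   default 1).
#' @param margin_transform `"ratio"` (margins are output ratios, default) or
#'   `"log-ratio"` (their natural logarithm).
#' @param output_model the circuit output model: a
#'   `function(classifier, profile, cfg)` returning a positive scalar.
#'   Defaults to [default_output_model()]; a different mechanistic model can
#'   be plugged in here.
#' @return An object of class `"scoring_config"`.
#' @export
scoring_config <- function(lambda = 0.5, K = 1, k = 4, ymax = 1,
                           margin_transform = c("ratio", "log-ratio"),
                           output_model = default_output_model) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("lambda must be a single number in [0, 1]", call. = FALSE)
  stopifnot(all(K > 0), k > 0, ymax > 0, is.function(output_model))
  structure(list(lambda = lambda, K = K, k = k, ymax = ymax,
                 margin_transform = match.arg(margin_transform),
                 output_model = output_model),
            class = "scoring_config")
}

#' Boolean-setting error rates
#'
#' The false negative rate is the fraction of positive samples classified
#' negative, the false positive rate the fraction of negative samples
#' classified positive.  Full precision is retained; textual reports round to
#' 2 decimals (half-up) via [round_half_up()].
#'
#' @param c a [classifier()].
#' @param ds a [binarized_dataset()] with at least one positive and one
#'   negative sample.
#' @return A list with numeric fields `fn_rate` and `fp_rate`.
#' @export
boolean_rates <- function(c, ds) {
  stopifnot(inherits(ds, "binarized_dataset"))
  npos <- sum(ds$annots == 1L)
  nneg <- sum(ds$annots == 0L)
  if (npos == 0L || nneg == 0L)
    stop("error rates are undefined: dataset must contain both classes",
         call. = FALSE)
  e <- count_errors(c, ds)
  list(fn_rate = e$fn / npos, fp_rate = e$fp / nneg)
}

#' Round half away from zero
#'
#' Reporting convention for score tables: 2 decimals, halves rounded up
#' (unlike base R's round-half-even).
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Default circuit output model
#'
#' A saturating surrogate for the mechanistic circuit response: each literal
#' contributes a Hill activation `x^k / (x^k + K^k)` (non-negated input) or
#' repression `K^k / (x^k + K^k)` (negated input); a gate's activation is the
#' maximum over its literals (OR), and the circuit output is `ymax` times the
#' product of gate activations (AND).  In the saturating limit (steepness
#' `k -> Inf`, inputs away from thresholds) the output approaches `ymax`
#' exactly when the Boolean evaluation is 1 and 0 otherwise.  The model is
#' strictly positive and monotone in each input in the direction implied by
#' the literal sign.
#'
#' @param c a [classifier()].
#' @param profile named numeric vector of non-negative expression levels
#'   covering the classifier's markers.
#' @param cfg a [scoring_config()] providing `K`, `k` and `ymax`.
#' @return A positive scalar output concentration.
#' @export
default_output_model <- function(c, profile, cfg) {
  out <- cfg$ymax
  for (g in c$gates) {
    acts <- vapply(seq_along(g$markers), function(j) {
      m <- g$markers[j]
      K <- if (length(cfg$K) > 1L || !is.null(names(cfg$K))) {
        if (!m %in% names(cfg$K))
          stop("no response threshold K configured for marker '", m, "'",
               call. = FALSE)
        cfg$K[[m]]
      } else cfg$K
      h <- profile[[m]]^cfg$k / (profile[[m]]^cfg$k + K^cfg$k)
      if (g$negated[j]) 1 - h else h
    }, numeric(1L))
    out <- out * max(acts)
  }
  # keep the output strictly positive (ratios must be well defined)
  max(out, .Machine$double.xmin)
}

#' Predict the continuous circuit output for one sample
#'
#' @param c a [classifier()].
#' @param profile named numeric vector of expression levels covering the
#'   classifier's markers.
#' @param cfg a [scoring_config()].
#' @return A positive scalar.
#' @export
circuit_output <- function(c, profile, cfg = scoring_config()) {
  stopifnot(is_classifier(c))
  missing <- setdiff(classifier_markers(c), names(profile))
  if (length(missing))
    stop("profile lacks marker(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  cfg$output_model(c, profile, cfg)
}

circuit_outputs <- function(c, cds, cfg) {
  vapply(seq_len(nrow(cds$x)), function(i)
    circuit_output(c, stats::setNames(cds$x[i, ], colnames(cds$x)), cfg),
    numeric(1L))
}

apply_margin_transform <- function(v, cfg) {
  switch(cfg$margin_transform, "ratio" = v, "log-ratio" = log(v))
}

#' Average and worst output margins
#'
#' The average margin `ma` is the overall ratio between the circuit output in
#' the positive versus the negative class (ratio of class means); the worst
#' margin `mw` is the smallest output ratio among any pair of one positive
#' and one negative sample, i.e. `min(positive outputs) / max(negative
#' outputs)`, which captures the outliers.  Under the ratio transform
#' `mw <= ma` always holds for positive outputs.
#'
#' @param c a [classifier()].
#' @param cds a [continuous_dataset()] with both classes present.
#' @param cfg a [scoring_config()].
#' @return A list with numeric fields `ma` and `mw` (transformed according to
#'   `cfg$margin_transform`).
#' @export
margins <- function(c, cds, cfg = scoring_config()) {
  stopifnot(inherits(cds, "continuous_dataset"))
  pos <- cds$annots == 1L
  if (!any(pos) || all(pos))
    stop("margins are undefined: dataset must contain both classes",
         call. = FALSE)
  out <- circuit_outputs(c, cds, cfg)
  list(ma = apply_margin_transform(mean(out[pos]) / mean(out[!pos]), cfg),
       mw = apply_margin_transform(min(out[pos]) / max(out[!pos]), cfg))
}

#' Weighted margin score
#'
#' The convex combination `s_m = lambda * ma + (1 - lambda) * mw` of the
#' average and worst margins.
#'
#' @param ma,mw margins as returned by [margins()].
#' @param lambda weight in `[0, 1]`.
#' @return A scalar.
#' @export
s_m <- function(ma, mw, lambda = 0.5) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("lambda must be a single number in [0, 1]", call. = FALSE)
  lambda * ma + (1 - lambda) * mw
}

#' Area under the ROC curve of the circuit output
#'
#' Uses the continuous circuit output as a ranking score for the positive
#' class; ties are handled by the midpoint (mid-rank) convention, so constant
#' outputs give 0.5.
#'
#' @inheritParams margins
#' @return AUC in `[0, 1]`.
#' @export
s_auc <- function(c, cds, cfg = scoring_config()) {
  stopifnot(inherits(cds, "continuous_dataset"))
  pos <- cds$annots == 1L
  if (!any(pos) || all(pos))
    stop("AUC is undefined: dataset must contain both classes", call. = FALSE)
  out <- circuit_outputs(c, cds, cfg)
  auc_midrank(out[pos], out[!pos])
}

# Mann-Whitney AUC with mid-rank tie handling.
auc_midrank <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Full score report for one classifier
#'
#' Boolean rates always; continuous scores when a continuous dataset is given
#' (they are omitted as `NA`, never fabricated, otherwise).
#'
#' @param c a [classifier()].
#' @param ds a [binarized_dataset()].
#' @param cds optional [continuous_dataset()] aligned with `ds`.
#' @param cfg a [scoring_config()].
#' @return A one-row data frame with columns `classifier`, `fn_rate`,
#'   `fp_rate`, `s_auc`, `ma`, `mw`, `s_m`.
#' @export
score_report <- function(c, ds, cds = NULL, cfg = scoring_config()) {
  rates <- boolean_rates(c, ds)
  if (is.null(cds)) {
    auc <- ma <- mw <- sm <- NA_real_
  } else {
    auc <- s_auc(c, cds, cfg)
    mg <- margins(c, cds, cfg)
    ma <- mg$ma; mw <- mg$mw
    sm <- s_m(ma, mw, cfg$lambda)
  }
  data.frame(classifier = format_classifier(c),
             fn_rate = rates$fn_rate, fp_rate = rates$fp_rate,
             s_auc = auc, ma = ma, mw = mw, s_m = sm,
             stringsAsFactors = FALSE)
}

#' Rank a set of optimal classifiers by continuous scores
#'
#' To choose among classifiers that are all optimal in the Boolean setting,
#' candidates are ordered by highest AUC first, then highest weighted margin
#' score, with the canonical classifier text as a deterministic tie-break.
#'
#' @param solutions a list of [classifier()] objects (or a [solution_set()]).
#' @param ds a [binarized_dataset()] for the Boolean rates.
#' @param cds a [continuous_dataset()] for the continuous scores.
#' @param cfg a [scoring_config()].
#' @return A data frame of score reports, one row per classifier, in rank
#'   order; the classifiers themselves are attached as the
#'   `"classifiers"` attribute.
#' @export
rank_solutions <- function(solutions, ds, cds, cfg = scoring_config()) {
  if (inherits(solutions, "solution_set")) solutions <- solutions$classifiers
  if (!length(solutions)) stop("no solutions to rank", call. = FALSE)
  solutions <- lapply(solutions, canonicalize)
  reports <- do.call(rbind, lapply(solutions, score_report, ds = ds, cds = cds,
                                   cfg = cfg))
  o <- order(-reports$s_auc, -reports$s_m, reports$classifier,
             method = "radix")
  reports <- reports[o, , drop = FALSE]
  rownames(reports) <- NULL
  attr(reports, "classifiers") <- solutions[o]
  reports
}

#' Write a score table as CSV
#'
#' Columns mirror the standard evaluation table (classifier, FN rate, FP
#' rate, AUC, weighted margin score, plus the two margins), with values
#' rounded to 2 decimals half-up.
#'
#' @param reports data frame from [score_report()] or [rank_solutions()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(reports, path) {
  out <- data.frame(
    Classifier = reports$classifier,
    `FN rate` = round_half_up(reports$fn_rate),
    `FP rate` = round_half_up(reports$fp_rate),
    S_AUC = round_half_up(reports$s_auc),
    S_m = round_half_up(reports$s_m),
    Ma = round_half_up(reports$ma),
    Mw = round_half_up(reports$mw),
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
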