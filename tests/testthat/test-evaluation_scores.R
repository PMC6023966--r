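test_that("error rates normalize by class size and report at two decimals", {
  # 167 positives with 4 false negatives, 11 negatives with 3 false positives
  # under the single-gate classifier (!m)
  x <- matrix(c(rep(0L, 163), rep(1L, 4),   # positives: 4 have m high
                rep(1L, 8), rep(0L, 3)),    # negatives: 3 have m low
              ncol = 1, dimnames = list(NULL, "m"))
  ds <- binarized_dataset(x, c(rep(1L, 167), rep(0L, 11)))
  r <- boolean_rates(classifier(gate("m", TRUE)), ds)
  expect_equal(r$fn_rate, 4 / 167)
  expect_equal(r$fp_rate, 3 / 11)
  expect_equal(round_half_up(r$fn_rate), 0.02)
  expect_equal(round_half_up(r$fp_rate), 0.27)

  perfect <- parse_classifier("(g1 | g3) & !g2")
  p <- boolean_rates(perfect, fig3_dataset())
  expect_equal(c(p$fn_rate, p$fp_rate), c(0, 0))

  all_pos <- binarized_dataset(matrix(1L, 2, 1, dimnames = list(NULL, "g1")),
                               c(1, 1))
  expect_error(boolean_rates(classifier(gate("g1")), all_pos), "both classes")
})

test_that("report rounding is half-up, not banker's", {
  expect_equal(round_half_up(0.025), 0.03)
  expect_equal(round_half_up(0.265), 0.27)
  expect_equal(round_half_up(-0.025), -0.03)
  expect_equal(round_half_up(0.2649), 0.26)
})

test_that("the saturating output model approaches the Boolean evaluation", {
  cfg <- scoring_config(K = 1, k = 40)
  act <- classifier(gate("g1"))
  expect_gt(circuit_output(act, c(g1 = 100), cfg), 0.999)
  expect_lt(circuit_output(act, c(g1 = 0.01), cfg), 1e-3)
  rep_ <- classifier(gate("g1", TRUE))
  expect_lt(circuit_output(rep_, c(g1 = 100), cfg), 1e-3)
  expect_gt(circuit_output(rep_, c(g1 = 0.01), cfg), 0.999)
})

test_that("multi-gate outputs are products of per-gate Hill activations", {
  cfg <- scoring_config(K = 2, k = 4, ymax = 3)
  cl <- parse_classifier("(g1 | g2) & !g3")
  prof <- c(g1 = 1, g2 = 4, g3 = 2)
  h <- function(x, K, k) x^k / (x^k + K^k)
  expected <- 3 * max(h(1, 2, 4), h(4, 2, 4)) * (1 - h(2, 2, 4))
  expect_equal(circuit_output(cl, prof, cfg), expected)
  expect_error(circuit_output(cl, prof, scoring_config(K = c(g1 = 2))),
               "no response threshold")
})

test_that("the output model is monotone in the literal direction", {
  cfg <- scoring_config(K = 1, k = 4)
  cl <- parse_classifier("(g1) & !g2")
  lo <- circuit_output(cl, c(g1 = 0.5, g2 = 1), cfg)
  hi <- circuit_output(cl, c(g1 = 2.0, g2 = 1), cfg)
  expect_gt(hi, lo)
  up <- circuit_output(cl, c(g1 = 1, g2 = 0.5), cfg)
  dn <- circuit_output(cl, c(g1 = 1, g2 = 2.0), cfg)
  expect_gt(up, dn)
})

test_that("margins follow the class-mean and worst-pair ratios", {
  cds <- continuous_dataset(
    matrix(c(4, 2, 1, 1), ncol = 1, dimnames = list(NULL, "o")),
    c(1, 1, 0, 0))
  cl <- classifier(gate("o"))
  m <- margins(cl, cds, passthrough_config())
  expect_equal(m$ma, 3)
  expect_equal(m$mw, 2)

  flat <- continuous_dataset(
    matrix(c(5, 5, 5, 5), ncol = 1, dimnames = list(NULL, "o")),
    c(1, 1, 0, 0))
  mf <- margins(cl, flat, passthrough_config())
  expect_equal(c(mf$ma, mf$mw), c(1, 1))
  cfg_log <- passthrough_config()
  cfg_log$margin_transform <- "log-ratio"
  ml <- margins(cl, flat, cfg_log)
  expect_equal(c(ml$ma, ml$mw), c(0, 0))
})

test_that("the worst margin never exceeds the average margin", {
  withr::with_seed(77, {
    cl <- classifier(gate("o"))
    for (rep in 1:200) {
      out <- runif(8, 0.01, 10)
      cds <- continuous_dataset(
        matrix(out, ncol = 1, dimnames = list(NULL, "o")),
        c(rep(1, 4), rep(0, 4)))
      m <- margins(cl, cds, passthrough_config())
      expect_lte(m$mw, m$ma)
    }
  })
})

test_that("s_m is the exact convex combination with monotone endpoints", {
  expect_equal(s_m(0.5, 0.1, 0.5), 0.3)
  expect_equal(s_m(0.7, 0.2, 1), 0.7)
  expect_equal(s_m(0.7, 0.2, 0), 0.2)
  expect_equal(s_m(0.4, 0.4, 0.5), 0.4)
  expect_error(s_m(1, 1, 1.5), "lambda")
  expect_gt(s_m(0.6, 0.2, 0.5), s_m(0.5, 0.2, 0.5))
  expect_gt(s_m(0.6, 0.3, 0.5), s_m(0.6, 0.2, 0.5))
})

test_that("AUC separates, ties at one half, and counts concordant pairs", {
  cl <- classifier(gate("o"))
  sep <- continuous_dataset(
    matrix(c(9, 8, 1, 2), ncol = 1, dimnames = list(NULL, "o")), c(1, 1, 0, 0))
  expect_equal(s_auc(cl, sep, passthrough_config()), 1.0)
  flat <- continuous_dataset(
    matrix(rep(3, 4), ncol = 1, dimnames = list(NULL, "o")), c(1, 1, 0, 0))
  expect_equal(s_auc(cl, flat, passthrough_config()), 0.5)
  mix <- continuous_dataset(
    matrix(c(0.9, 0.4, 0.5, 0.1), ncol = 1, dimnames = list(NULL, "o")),
    c(1, 1, 0, 0))
  expect_equal(s_auc(cl, mix, passthrough_config()), 0.75)
})

test_that("a perfect Boolean classifier scores AUC 1 under saturating response", {
  ds <- fig3_dataset()
  # continuous levels that binarize to the Boolean fixture at threshold 10
  cds <- continuous_dataset(ds$x * 100 + 0.1, ds$annots,
                            threshold = 10)
  cl <- parse_classifier("(g1 | g3) & !g2")
  cfg <- scoring_config(K = 10, k = 30)
  expect_equal(s_auc(cl, cds, cfg), 1.0)
})

test_that("rates recomputed from count_errors match boolean_rates", {
  withr::with_seed(31, {
    for (rep in 1:1000) {
      ds <- random_small_instance(sample.int(1e6, 1), n_samples = 10L)
      if (length(unique(ds$annots)) < 2L) next
      cl <- random_small_classifier(6L)
      e <- count_errors(cl, ds)
      r <- boolean_rates(cl, ds)
      expect_equal(r$fn_rate, e$fn / sum(ds$annots == 1L))
      expect_equal(r$fp_rate, e$fp / sum(ds$annots == 0L))
    }
  })
})

test_that("solutions are ranked by AUC, then margin score, then text", {
  # outputs via passthrough pseudo-markers: a and b rank equally by AUC,
  # but a has the better margin score
  x <- matrix(c(10, 8, 1, 2,        # a: clean separation, wide margins
                10, 8, 4, 5), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  cds <- continuous_dataset(x, c(1, 1, 0, 0))
  bds <- binarized_dataset((x >= 6) * 1L, c(1, 1, 0, 0))
  cfg <- scoring_config(K = 6, k = 30)
  ranked <- rank_solutions(list(classifier(gate("b")), classifier(gate("a"))),
                           bds, cds, cfg)
  expect_equal(ranked$classifier, c("(a)", "(b)"))
  expect_equal(ranked$s_auc, c(1, 1))
  expect_gt(ranked$s_m[1], ranked$s_m[2])

  # equal scores fall back to canonical text order
  tie <- rank_solutions(list(classifier(gate("b")), classifier(gate("b")),
                             classifier(gate("a"))),
                        bds, cds, cfg)
  expect_equal(tie$classifier[1], "(a)")
})

test_that("score reports omit continuous scores without continuous data", {
  rep1 <- score_report(parse_classifier("(g1 | g3) & !g2"), fig3_dataset())
  expect_true(is.na(rep1$s_auc) && is.na(rep1$s_m))
  expect_equal(rep1$fn_rate, 0)
  f <- tempfile(fileext = ".csv")
  write_score_report(rep1, f)
  tab <- utils::read.csv(f, check.names = FALSE)
  expect_equal(names(tab)[1:5],
               c("Classifier", "FN rate", "FP rate", "S_AUC", "S_m"))
})
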