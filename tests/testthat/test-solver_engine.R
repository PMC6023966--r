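test_that("a single-literal optimum is found and certified", {
  # positives are exactly the rows with g2 = 0
  withr::with_seed(7, {
    x <- matrix(sample(0:1, 24, replace = TRUE), nrow = 8)
    colnames(x) <- paste0("g", 1:3)
  })
  ds <- binarized_dataset(x, 1L - x[, "g2"])
  res <- find_optimal(ds, core_profile(), "opt3", enumerate_all = TRUE)
  expect_equal(res$status, "OPTIMAL")
  expect_equal(res$objective, list(inputs = 1L, gates = 1L))
  expect_true("(!g2)" %in% solution_texts(res))
  # cross-module contract: enumerated optima violate nothing
  for (cl in res$classifiers)
    expect_length(validate_classifier(cl, core_profile()), 0L)
})

test_that("contradictory profiles are infeasible at zero error bounds", {
  ds <- contradictory_dataset()
  res <- find_optimal(ds, core_profile(), "opt3")
  expect_equal(res$status, "INFEASIBLE")
  expect_length(res$classifiers, 0L)
  expect_equal(brute_force_oracle(ds, reduced_profile(), "opt3")$status,
               "INFEASIBLE")
})

test_that("engine and oracle agree across strategies on seeded instances", {
  key <- function(sol) paste(solution_texts(sol), collapse = ";")
  for (seed in 1:25) {
    ds <- random_small_instance(seed, planted = seed %% 2 == 0)
    p <- reduced_profile(fn_bound = seed %% 2, fp_bound = (seed %/% 2) %% 2)
    for (s in c("feasible", "opt1", "opt2", "opt3", "opt4")) {
      a <- find_optimal(ds, p, s, enumerate_all = TRUE)
      b <- brute_force_oracle(ds, p, s)
      expect_equal(a$status, b$status, info = paste("seed", seed, s))
      expect_equal(key(a), key(b), info = paste("seed", seed, s))
      expect_equal(a$objective, b$objective, info = paste("seed", seed, s))
    }
  }
})

test_that("bi-level optima carry optimality certificates", {
  for (seed in c(3, 8, 15)) {
    ds <- random_small_instance(seed, planted = TRUE)
    res <- find_optimal(ds, reduced_profile(), "opt3", enumerate_all = TRUE)
    expect_equal(res$status, "OPTIMAL")
    I <- res$objective$inputs
    if (I > 1L) {
      tighter <- reduced_profile()
      tighter$max_inputs <- I - 1L
      expect_equal(find_optimal(ds, tighter, "opt3")$status, "INFEASIBLE")
    }
    G <- find_optimal(ds, reduced_profile(), "opt4")$objective$gates
    if (G > 1L) {
      tighter <- reduced_profile()
      tighter$max_gates <- G - 1L
      expect_equal(find_optimal(ds, tighter, "opt4")$status, "INFEASIBLE")
    }
  }
})

test_that("enlarging error bounds never worsens the optimum", {
  for (seed in 1:8) {
    ds <- random_small_instance(seed + 100)
    prev <- NULL
    for (total in 0:2) {
      res <- find_optimal(ds, reduced_profile(fn_bound = total, fp_bound = total),
                          "opt1")
      if (res$status == "OPTIMAL") {
        if (!is.null(prev)) expect_lte(res$objective$inputs, prev)
        prev <- res$objective$inputs
      }
    }
  }
})

test_that("the solver is deterministic", {
  ds <- random_small_instance(55, planted = TRUE)
  a <- find_optimal(ds, reduced_profile(), "opt3", enumerate_all = TRUE)
  b <- find_optimal(ds, reduced_profile(), "opt3", enumerate_all = TRUE)
  expect_equal(solution_texts(a), solution_texts(b))
  expect_equal(a$objective, b$objective)
})

test_that("the relaxation schedule follows total-ascending, FN-first order", {
  sched <- relaxation_schedule(max_total = 2)
  expect_equal(sched, list(c(fn = 0L, fp = 0L), c(fn = 1L, fp = 0L),
                           c(fn = 0L, fp = 1L), c(fn = 2L, fp = 0L),
                           c(fn = 1L, fp = 1L), c(fn = 0L, fp = 2L)))
  expect_equal(relaxation_schedule(relaxation_policy(forbid_fp = TRUE), 2),
               list(c(fn = 0L, fp = 0L), c(fn = 1L, fp = 0L),
                    c(fn = 2L, fp = 0L)))
  expect_equal(relaxation_schedule(relaxation_policy(forbid_fn = TRUE), 2),
               list(c(fn = 0L, fp = 0L), c(fn = 0L, fp = 1L),
                    c(fn = 0L, fp = 2L)))
  expect_equal(relaxation_schedule(max_total = 0), list(c(fn = 0L, fp = 0L)))
  expect_error(
    relaxation_schedule(relaxation_policy(forbid_fp = TRUE, forbid_fn = TRUE), 2),
    "both error types")
})

test_that("relaxation returns the perfect-classifier solution when one exists", {
  ds <- fig3_dataset()
  direct <- find_optimal(ds, core_profile(), "opt3", enumerate_all = TRUE)
  relaxed <- relax_and_solve(ds, core_profile(), "opt3", enumerate_all = TRUE)
  expect_equal(relaxed$bounds_used, c(fn = 0L, fp = 0L))
  expect_equal(solution_texts(relaxed), solution_texts(direct))
})

test_that("one contradictory pair forces exactly one admitted error", {
  ds <- contradictory_dataset()
  res <- relax_and_solve(ds, core_profile(), "opt3")
  expect_equal(res$status, "OPTIMAL")
  expect_equal(sum(res$bounds_used), 1L)
  e <- count_errors(res$classifiers[[1]], ds)
  expect_equal(e$fn + e$fp, 1L)

  fp_free <- relax_and_solve(ds, core_profile(), "opt3",
                             relaxation_policy(forbid_fp = TRUE))
  expect_equal(fp_free$bounds_used[["fp"]], 0L)
  expect_gte(fp_free$bounds_used[["fn"]], 1L)
  e2 <- count_errors(fp_free$classifiers[[1]], ds)
  expect_equal(e2$fp, 0L)
})

test_that("a zero time budget reports TIMEOUT, not infeasibility", {
  ds <- random_small_instance(9, n_markers = 6L, n_samples = 8L)
  res <- find_optimal(ds, reduced_profile(), "opt3", time_limit = 0)
  expect_equal(res$status, "TIMEOUT")
  expect_length(res$classifiers, 0L)
})

test_that("input weights steer the optimum away from penalized miRNAs", {
  # positives are the rows with g1 = 1, which equals g2 on this fixture:
  # two single-input optima exist; penalizing g1 must select g2
  x <- matrix(c(1, 1, 0,
                1, 1, 1,
                0, 0, 1,
                0, 0, 0), nrow = 4, byrow = TRUE,
              dimnames = list(NULL, c("g1", "g2", "g3")))
  ds <- binarized_dataset(x, c(1, 1, 0, 0))
  plain <- find_optimal(ds, reduced_profile(), "opt1", enumerate_all = TRUE)
  expect_setequal(solution_texts(plain), c("(g1)", "(g2)"))
  steered <- find_optimal(ds, reduced_profile(), "opt1", enumerate_all = TRUE,
                          weights = c(g1 = 10))
  expect_equal(solution_texts(steered), "(g2)")
})

test_that("feasibility search handles one-class datasets", {
  # all samples positive: any gate true on every row is a solution
  ones <- matrix(1L, nrow = 3, ncol = 2, dimnames = list(NULL, c("g1", "g2")))
  ds <- binarized_dataset(ones, c(1, 1, 1))
  res <- find_optimal(ds, reduced_profile(), "opt1")
  expect_equal(res$status, "OPTIMAL")
  expect_equal(res$objective$inputs, 1L)
  expect_equal(count_errors(res$classifiers[[1]], ds)$fn, 0L)

  # all samples negative: a never-true gate must be found
  ds2 <- binarized_dataset(ones, c(0, 0, 0))
  res2 <- find_optimal(ds2, reduced_profile(), "feasible")
  expect_equal(res2$status, "FEASIBLE")
  expect_equal(count_errors(res2$classifiers[[1]], ds2)$fp, 0L)
})
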