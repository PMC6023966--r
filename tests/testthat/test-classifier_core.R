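test_that("evaluate implements CNF semantics on the worked example", {
  cl <- parse_classifier("(g1 | g3) & !g2")
  expect_equal(evaluate(cl, c(g1 = 1, g2 = 0, g3 = 0)), 1L)
  expect_equal(evaluate(cl, c(g1 = 0, g2 = 1, g3 = 1)), 0L)
  neg <- classifier(gate("g1", TRUE))
  expect_equal(evaluate(neg, c(g1 = 0)), 1L)
  expect_equal(evaluate(neg, c(g1 = 1)), 0L)
  expect_error(evaluate(cl, c(g1 = 1, g2 = 0)), "lacks marker")
})

test_that("evaluate agrees with an expression-based truth-table oracle", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      cl <- random_small_classifier(5L)
      grid <- expand.grid(rep(list(0:1), 5))
      names(grid) <- paste0("g", 1:5)
      for (i in seq_len(nrow(grid))) {
        prof <- unlist(grid[i, ])
        expect_equal(evaluate(cl, prof), eval_via_expression(cl, prof))
      }
    }
  })
})

test_that("count_errors counts false negatives and positives per annotation", {
  ds <- fig3_dataset()
  perfect <- parse_classifier("(g1 | g3) & !g2")
  expect_equal(count_errors(perfect, ds), list(fn = 0L, fp = 0L))

  # 5 samples: positives with g1 = 1,1,0; negatives with g1 = 0,1
  x <- matrix(c(1, 1, 0, 0, 1), ncol = 1, dimnames = list(NULL, "g1"))
  ds5 <- binarized_dataset(x, c(1, 1, 1, 0, 0))
  e <- count_errors(classifier(gate("g1")), ds5)
  expect_equal(e, list(fn = 1L, fp = 1L))
  expect_error(count_errors(classifier(gate("g9")), ds5), "lacks classifier marker")
})

test_that("the planted annotator is error-free on the dataset it annotated", {
  mat <- generate_matrix(40, 12, seed = 31)
  ann <- generate_annotation_classifier(1, 12, seed = 32)
  ds <- annotate(mat, ann)
  expect_equal(count_errors(ann, ds), list(fn = 0L, fp = 0L))
})

test_that("classifier text parses in ASCII and Unicode and round-trips", {
  a <- parse_classifier("(g1 | g3) & !g2")
  b <- parse_classifier("(g1 ∨ g3) ∧ ¬g2")
  d <- parse_classifier("(g1 OR g3) AND NOT g2")
  expect_equal(mirdesign:::classifier_key(a <- canonicalize(a)), mirdesign:::classifier_key(canonicalize(b)))
  expect_equal(mirdesign:::classifier_key(a), mirdesign:::classifier_key(canonicalize(d)))
  expect_equal(n_gates(a), 2L)
  expect_equal(n_inputs(a), 3L)

  hy <- parse_classifier("(miR-21) & (!miR-320-RNASEN)")
  expect_equal(n_gates(hy), 2L)
  expect_equal(n_inputs(hy), 2L)
  expect_setequal(classifier_markers(hy), c("miR-21", "miR-320-RNASEN"))

  # format ∘ parse preserves the Boolean function
  rt <- parse_classifier(format_classifier(a))
  grid <- expand.grid(g1 = 0:1, g2 = 0:1, g3 = 0:1)
  for (i in seq_len(nrow(grid))) {
    prof <- unlist(grid[i, ])
    expect_equal(evaluate(rt, prof), evaluate(a, prof))
  }
})

test_that("syntax and structural errors are reported with positions", {
  expect_error(parse_classifier("()"), "syntax error at position 2")
  expect_error(parse_classifier(""), "empty classifier")
  expect_error(parse_classifier("(g1 | g1)"), "twice in one gate")
  expect_error(parse_classifier("(g1 |) & g2"), "syntax error")
  expect_error(classifier(list()), "at least one gate")
  expect_error(gate(character(0)), "at least one literal")
})

test_that("canonicalize is idempotent, order-normalizing and function-preserving", {
  base <- parse_classifier(
    "(miR-24-1 | miR-103-2) & !miR-144 & !miR-378 & !miR-10b")
  variant <- parse_classifier(
    "(miR-103-2 | miR-24-1) & !miR-378 & !miR-10b & !miR-144")
  expect_equal(canonicalize(base), canonicalize(variant))
  expect_equal(canonicalize(canonicalize(base)), canonicalize(base))

  withr::with_seed(41, {
    for (rep in 1:10) {
      cl <- random_small_classifier(6L)
      canon <- canonicalize(cl)
      for (p in 1:5) {
        shuffled <- classifier(lapply(sample(cl$gates), function(g) {
          o <- sample(seq_along(g$markers))
          gate(g$markers[o], g$negated[o])
        }))
        expect_equal(canonicalize(shuffled), canon)
      }
      grid <- expand.grid(rep(list(0:1), 6))
      names(grid) <- paste0("g", 1:6)
      for (i in seq_len(nrow(grid))) {
        prof <- unlist(grid[i, ])
        expect_equal(evaluate(canon, prof), evaluate(cl, prof))
      }
    }
  })
})

test_that("error counts are invariant under canonicalization and row shuffles", {
  withr::with_seed(43, {
    ds <- random_small_instance(43)
    cl <- random_small_classifier(6L)
    ref <- count_errors(cl, ds)
    expect_equal(count_errors(canonicalize(cl), ds), ref)
    p <- sample.int(length(ds$sample_ids))
    shuffled <- binarized_dataset(ds$x[p, , drop = FALSE], ds$annots[p],
                                  ds$sample_ids[p])
    expect_equal(count_errors(cl, shuffled), ref)
  })
})

test_that("isomorphic copies reduce to a single representative", {
  base <- parse_classifier(
    "(miR-24-1 | miR-103-2) & !miR-144 & !miR-378 & !miR-10b")
  not_gates <- base$gates[2:4]
  copies <- lapply(perms(1:3), function(p)
    classifier(c(base$gates[1], not_gates[p])))
  expect_equal(length(copies), 6L)
  reps <- reduce_to_isomorphism_classes(copies)
  expect_equal(length(reps), 1L)
  expect_equal(reps[[1]], canonicalize(base))

  distinct <- list(parse_classifier("(g1)"), parse_classifier("(g2)"))
  expect_equal(length(reduce_to_isomorphism_classes(distinct)), 2L)

  # k! permutations of k single-input NOT gates collapse to one class
  k4 <- lapply(perms(1:4), function(p)
    classifier(lapply(paste0("g", p), gate, negated = TRUE)))
  expect_equal(length(k4), 24L)
  expect_equal(length(reduce_to_isomorphism_classes(k4)), 1L)
})

test_that("isomorphic labeling counts multiply factorials of interchangeable groups", {
  bc_all <- parse_classifier(
    "(miR-24-1 | miR-103-2) & !miR-144 & !miR-378 & !miR-10b")
  expect_equal(count_isomorphic_labelings(bc_all), 6)
  expect_equal(count_isomorphic_labelings(parse_classifier("(!g1)")), 1)
  four_not <- classifier(lapply(paste0("g", 1:4), gate, negated = TRUE))
  expect_equal(count_isomorphic_labelings(four_not), 24)

  # independent enumeration: identifier assignments reachable by permuting
  # IDs among the interchangeable NOT gates
  labelings <- unique(vapply(perms(1:3), function(p) {
    ids <- c(1L, p + 1L)
    paste(ids, collapse = "-")
  }, character(1)))
  expect_equal(length(labelings), count_isomorphic_labelings(bc_all))
})

test_that("DOT export names all inputs and gates", {
  dot <- classifier_to_dot(parse_classifier("(g1 | g3) & !g2"))
  expect_true(any(grepl("digraph", dot)))
  expect_equal(sum(grepl("-> output", dot)), 2L)
  expect_true(any(grepl("\"g3\" -> gate1", dot)))
  expect_true(any(grepl("arrowhead=tee", dot)))
})
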