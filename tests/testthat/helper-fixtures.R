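# Shared fixtures and small independent oracles, all built in code.

# Running-example dataset: 3 samples (2 negative, 1 positive) over g1..g3,
# perfectly separated by (g1 | g3) & !g2.
fig3_dataset <- function() {
  x <- matrix(c(1, 1, 0,
                0, 1, 1,
                1, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(NULL, c("g1", "g2", "g3")))
  binarized_dataset(x, c(0, 0, 1))
}

fig3_csv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c("ID,Annots,g1,g2,g3",
               "1,0,1,1,0",
               "2,0,0,1,1",
               "3,1,1,0,0"), path)
  path
}

# Dataset whose first two samples share a profile but differ in annotation,
# with the rest separable.
contradictory_dataset <- function() {
  x <- matrix(c(1, 0,
                1, 0,
                0, 1,
                0, 0), nrow = 4, byrow = TRUE,
              dimnames = list(NULL, c("g1", "g2")))
  binarized_dataset(x, c(1, 0, 1, 0))
}

# Reduced constraint profile for oracle-checked searches: up to 3 gates,
# up to 4 total inputs, OR-of-activators and single-input-NOT gate types.
reduced_profile <- function(fn_bound = 0L, fp_bound = 0L) {
  constraint_profile(
    max_gates = 3L, max_inputs = 4L,
    gate_types = list(gate_type(1L, 1L, 4L, 0L, 0L, 3L),
                      gate_type(2L, 0L, 0L, 1L, 1L, 3L)),
    fn_bound = fn_bound, fp_bound = fp_bound)
}

# Random small instance within the oracle guard.
random_small_instance <- function(seed, n_markers = 6L, n_samples = 8L,
                                  planted = FALSE) {
  withr::with_seed(seed, {
    x <- matrix(sample(0:1, n_samples * n_markers, replace = TRUE),
                nrow = n_samples)
    colnames(x) <- paste0("g", seq_len(n_markers))
    annots <- if (planted) {
      ann <- random_small_classifier(n_markers)
      evaluate_rows(ann, x)
    } else sample(0:1, n_samples, replace = TRUE)
  })
  binarized_dataset(x, annots)
}

# Small random classifier compatible with reduced_profile().
random_small_classifier <- function(n_markers) {
  g <- sample(1:2, 1)
  gates <- lapply(seq_len(g), function(i) {
    if (sample(0:1, 1) == 1L) {
      gate(paste0("g", sample.int(n_markers, 1)), TRUE)
    } else {
      k <- sample(1:2, 1)
      gate(paste0("g", sample.int(n_markers, k)), rep(FALSE, k))
    }
  })
  keys <- vapply(gates, mirdesign:::gate_key, character(1))
  classifier(gates[!duplicated(keys)])
}

# Independent truth-table evaluator: translate the classifier text to an R
# logical expression and eval() it, bypassing evaluate().
eval_via_expression <- function(cl, profile) {
  txt <- format_classifier(cl)
  markers <- classifier_markers(cl)
  env <- new.env()
  for (m in markers) assign(m, profile[[m]] == 1, envir = env)
  # marker tokens may contain '-': replace them by syntactic names
  safe <- paste0("m", seq_along(markers))
  for (i in seq_along(markers)) {
    assign(safe[i], profile[[markers[i]]] == 1, envir = env)
    txt <- gsub(markers[i], safe[i], txt, fixed = TRUE)
  }
  as.integer(eval(parse(text = txt), envir = env))
}

# All permutations of a vector (small n), for symmetry checks.
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# Scoring configuration whose output model reads a designated pseudo-marker
# column directly, for margin/AUC arithmetic with hand-chosen outputs.
passthrough_config <- function(column = "o", lambda = 0.5) {
  scoring_config(lambda = lambda,
                 output_model = function(c, profile, cfg) profile[[column]])
}

solution_texts <- function(sol)
  vapply(sol$classifiers, format_classifier, character(1))
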