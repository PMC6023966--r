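## Synthetic benchmark instances and conservative cross-validation.
##
## Benchmark data are random 0-1 matrices annotated by a hidden "annotation
## classifier" (a planted solution).  Setup 1 plants a classifier that
## satisfies the core laboratory constraints, which guarantees that a
## feasible solution exists for every instance; Setup 2 builds the annotator
## by fair coin tosses over a gate/input template scaled with the number of
## miRNAs, so feasibility under the core constraints is not guaranteed.

#' Generate a random binary expression matrix
#'
#' Entries are independent fair Bernoulli draws (0 and 1 equally likely).
#' Columns are named `g1, g2, ...`; reproducible given the seed.
#'
#' @param n_rows,n_cols positive dimensions (samples x miRNAs).
#' @param seed integer seed.
#' @return An integer 0/1 matrix with named columns.
#' @export
generate_matrix <- function(n_rows, n_cols, seed) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  withr::with_seed(as.integer(seed), {
    m <- matrix(sample(0:1, n_rows * n_cols, replace = TRUE),
                nrow = n_rows, ncol = n_cols)
  })
  colnames(m) <- paste0("g", seq_len(n_cols))
  rownames(m) <- as.character(seq_len(n_rows))
  storage.mode(m) <- "integer"
  m
}

#' Generate a random annotation classifier
#'
#' The annotation classifier is the hidden ground truth used to label
#' benchmark samples.
#' \describe{
#'   \item{Setup 1}{draws a classifier satisfying the core constraints by
#'     uniform choices: a uniform gate count, a uniform admissible gate type
#'     per gate, a uniform input count within the type bounds and the
#'     remaining input budget, and uniformly chosen markers.  By construction
#'     the planted classifier is a zero-error solution for any dataset it
#'     annotates, so such instances are never infeasible.}
#'   \item{Setup 2}{uses a coin-toss template: up to `floor(n_mirnas / 10)`
#'     gates (at least 1 is enforced, since annotation requires a function)
#'     and up to 5 inputs per gate, where each gate and each input slot
#'     exists with probability 1/2; literal signs are fair coin tosses and
#'     marker assignment is uniform.  Feasibility under the core constraints
#'     is deliberately not guaranteed.}
#' }
#'
#' @param setup 1 or 2.
#' @param n_mirnas number of miRNA columns the matrix will have.
#' @param profile constraint profile for Setup 1 (default [core_profile()]).
#' @param seed integer seed.
#' @return A [classifier()] over markers `g1..g<n_mirnas>`.
#' @export
generate_annotation_classifier <- function(setup, n_mirnas,
                                           profile = core_profile(), seed) {
  stopifnot(setup %in% c(1L, 2L), n_mirnas >= 1)
  markers <- paste0("g", seq_len(n_mirnas))
  withr::with_seed(as.integer(seed), {
    if (setup == 1L) cl <- random_core_classifier(markers, profile)
    else cl <- random_coin_classifier(markers)
  })
  cl
}

# Uniform draws of a classifier feasible under `profile` (rejection-sampled
# against validate_classifier, which essentially never rejects by
# construction).
random_core_classifier <- function(markers, profile) {
  n <- length(markers)
  for (attempt in seq_len(1000L)) {
    g <- sample.int(profile$max_gates, 1L)
    rem <- profile$max_inputs
    gates <- vector("list", g)
    ok <- TRUE
    for (i in seq_len(g)) {
      avail <- rem - (g - i)          # later gates need >= 1 input each
      if (avail < 1L) { ok <- FALSE; break }
      t <- profile$gate_types[[sample.int(length(profile$gate_types), 1L)]]
      npos_max <- min(t$ub_pos, avail, n)
      nneg_max <- min(t$ub_neg, avail, n)
      if (t$lb_pos > npos_max || t$lb_neg > nneg_max) { ok <- FALSE; break }
      npos <- if (npos_max >= t$lb_pos && npos_max > 0L)
        sample(t$lb_pos:npos_max, 1L) else t$lb_pos
      nneg_cap <- min(nneg_max, avail - npos)
      if (t$lb_neg > nneg_cap) { ok <- FALSE; break }
      nneg <- if (nneg_cap >= t$lb_neg && nneg_cap > 0L)
        sample(t$lb_neg:nneg_cap, 1L) else t$lb_neg
      if (npos + nneg < 1L) { ok <- FALSE; break }
      mk <- sample(markers, npos + nneg)
      gates[[i]] <- gate(mk, c(rep(FALSE, npos), rep(TRUE, nneg)))
      rem <- rem - npos - nneg
    }
    if (!ok) next
    keys <- vapply(gates, gate_key, character(1L))
    if (anyDuplicated(keys)) next
    cl <- classifier(gates)
    if (!length(validate_classifier(cl, profile))) return(cl)
  }
  stop("could not draw a profile-feasible annotation classifier", call. = FALSE)
}

# Coin-toss template of Setup 2: <= floor(n/10) gates, <= 5 inputs per gate,
# each included with probability 1/2; signs are fair coins too.
random_coin_classifier <- function(markers) {
  n <- length(markers)
  max_g <- max(1L, n %/% 10L)
  for (attempt in seq_len(1000L)) {
    gates <- list()
    for (i in seq_len(max_g)) {
      if (sample(0:1, 1L) == 0L) next          # gate does not exist
      slots <- sample(0:1, 5L, replace = TRUE) # input slots
      k <- min(sum(slots), n)
      if (k == 0L) next                        # empty gate: dropped
      mk <- sample(markers, k)
      gates[[length(gates) + 1L]] <- gate(mk, sample(c(FALSE, TRUE), k,
                                                     replace = TRUE))
    }
    if (!length(gates)) {                      # enforce at least one gate
      k <- max(1L, min(sum(sample(0:1, 5L, replace = TRUE)), n))
      gates <- list(gate(sample(markers, k),
                         sample(c(FALSE, TRUE), k, replace = TRUE)))
    }
    keys <- vapply(gates, gate_key, character(1L))
    if (anyDuplicated(keys)) next
    return(classifier(gates))
  }
  stop("could not draw a coin-toss annotation classifier", call. = FALSE)
}

#' Annotate a matrix with a planted classifier
#'
#' Each row is labeled by the annotation classifier's Boolean output, so the
#' annotator itself is a feasible zero-error solution for the resulting
#' dataset.
#'
#' @param mat 0/1 matrix with named columns (see [generate_matrix()]).
#' @param annot_classifier a [classifier()] over the matrix columns.
#' @return A [binarized_dataset()].
#' @export
annotate <- function(mat, annot_classifier) {
  stopifnot(is_classifier(annot_classifier))
  missing <- setdiff(classifier_markers(annot_classifier), colnames(mat))
  if (length(missing))
    stop("matrix lacks annotator marker(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  binarized_dataset(mat, evaluate_rows(annot_classifier, mat))
}

#' Benchmark configuration
#'
#' @param row_dims,col_dims dimension grids (samples / miRNAs); the reference
#'   grid is both axes 10 to 500 in steps of 10, giving 2,500 instances.
#' @param setup 1 or 2 (see [generate_annotation_classifier()]).
#' @param strategy solver strategy per instance (default plain feasibility,
#'   i.e. time-to-first-solution).
#' @param time_limit per-instance wall-clock budget in seconds.
#' @param seed master seed; per-instance seeds are derived deterministically.
#' @return An object of class `"benchmark_config"`.
#' @export
benchmark_config <- function(row_dims = seq(10L, 500L, by = 10L),
                             col_dims = seq(10L, 500L, by = 10L),
                             setup = 1L, strategy = "feasible",
                             time_limit = 600, seed = 1L) {
  stopifnot(all(row_dims >= 1), all(col_dims >= 1), time_limit > 0)
  structure(list(row_dims = as.integer(row_dims),
                 col_dims = as.integer(col_dims),
                 setup = as.integer(setup),
                 strategy = normalize_strategy(strategy),
                 time_limit = time_limit, seed = as.integer(seed)),
            class = "benchmark_config")
}

#' Enumerate the benchmark instance grid
#'
#' One instance per (rows, cols) pair, in deterministic row-major order, with
#' the derived per-instance seed.
#'
#' @param cfg a [benchmark_config()].
#' @return A data frame with columns `instance`, `n_rows`, `n_cols`, `seed`.
#' @export
benchmark_instances <- function(cfg) {
  stopifnot(inherits(cfg, "benchmark_config"))
  grid <- expand.grid(n_cols = cfg$col_dims, n_rows = cfg$row_dims,
                      KEEP.OUT.ATTRS = FALSE)[, c("n_rows", "n_cols")]
  grid$instance <- seq_len(nrow(grid))
  grid$seed <- (cfg$seed + 7919L * grid$instance) %% .Machine$integer.max
  grid[, c("instance", "n_rows", "n_cols", "seed")]
}

#' Run the timed benchmark grid
#'
#' For each grid instance: generate the matrix and annotation classifier,
#' annotate, and measure the solver on the resulting dataset under the core
#' constraints.  Per-instance failures and timeouts are recorded, never
#' raised.  With a checkpoint file the run is resumable at instance
#' granularity.
#'
#' @param cfg a [benchmark_config()].
#' @param profile constraint profile (default [core_profile()]).
#' @param checkpoint optional CSV path; completed instances are appended and
#'   skipped on re-run.
#' @return A data frame with one row per instance: dims, status, elapsed
#'   seconds, objective inputs/gates.
#' @export
run_benchmark <- function(cfg, profile = core_profile(), checkpoint = NULL) {
  inst <- benchmark_instances(cfg)
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.csv(checkpoint, stringsAsFactors = FALSE)
    inst <- inst[!inst$instance %in% done$instance, , drop = FALSE]
  }
  rows <- vector("list", nrow(inst))
  for (i in seq_len(nrow(inst))) {
    r <- inst[i, ]
    rec <- tryCatch({
      mat <- generate_matrix(r$n_rows, r$n_cols, r$seed)
      annot <- generate_annotation_classifier(cfg$setup, r$n_cols, profile,
                                              seed = r$seed + 1L)
      ds <- annotate(mat, annot)
      res <- find_optimal(ds, profile, cfg$strategy,
                          time_limit = cfg$time_limit)
      data.frame(instance = r$instance, n_rows = r$n_rows, n_cols = r$n_cols,
                 status = res$status, elapsed = res$elapsed,
                 inputs = if (length(res$classifiers))
                   n_inputs(res$classifiers[[1L]]) else NA_integer_,
                 gates = if (length(res$classifiers))
                   n_gates(res$classifiers[[1L]]) else NA_integer_,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(instance = r$instance, n_rows = r$n_rows, n_cols = r$n_cols,
                 status = "ERROR", elapsed = NA_real_, inputs = NA_integer_,
                 gates = NA_integer_, stringsAsFactors = FALSE))
    rows[[i]] <- rec
    if (!is.null(checkpoint)) {
      new_file <- !file.exists(checkpoint)
      utils::write.table(rec, checkpoint, sep = ",", row.names = FALSE,
                         col.names = new_file, append = !new_file)
    }
  }
  out <- do.call(rbind, c(list(done), rows))
  out[order(out$instance), , drop = FALSE]
}

#' Conservative k-fold cross-validation
#'
#' Rows are shuffled by the seed and split into k contiguous folds whose
#' sizes differ by at most one (no stratification by class, matching the
#' study design; an optional stratified mode is available).  For each fold a
#' classifier is learned on the remaining k-1 folds with the full relaxation
#' procedure, and its predictions are compared with the given annotations on
#' the held-out fold.  The validation is conservative: a fold whose solve
#' exhausts the time budget counts its entire test set as mispredicted.  The
#' generalization error is the total mismatch count divided by the sample
#' size.
#'
#' @param ds a [binarized_dataset()].
#' @param k fold count (>= 2, <= sample count).
#' @param profile a [constraint_profile()].
#' @param strategy solver strategy (default `"opt3"`).
#' @param policy a [relaxation_policy()].
#' @param time_limit per-fold wall-clock budget in seconds.
#' @param seed integer seed for the fold shuffle.
#' @param stratified logical; when `TRUE`, positives and negatives are
#'   distributed evenly across folds (off by default).
#' @return An object of class `"cv_result"`: `generalization_error`, and a
#'   per-fold data frame with test sizes, mismatch counts and timeout flags.
#' @export
cross_validate <- function(ds, k = 10L, profile = core_profile(),
                           strategy = "opt3", policy = relaxation_policy(),
                           time_limit = 600, seed = 1L, stratified = FALSE) {
  n <- length(ds$sample_ids)
  if (k < 2L || k > n)
    stop("fold count k must satisfy 2 <= k <= sample count", call. = FALSE)
  fold_of <- integer(n)
  withr::with_seed(as.integer(seed), {
    if (stratified) {
      for (cls in c(1L, 0L)) {
        idx <- sample(which(ds$annots == cls))
        fold_of[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      sizes <- rep(n %/% k, k)
      extra <- n %% k
      if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      fold_of[sample.int(n)] <- rep(seq_len(k), times = sizes)
    }
  })
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test <- which(fold_of == f)
    train <- which(fold_of != f)
    train_ds <- binarized_dataset(ds$x[train, , drop = FALSE],
                                  ds$annots[train], ds$sample_ids[train])
    res <- relax_and_solve(train_ds, profile, strategy, policy,
                           time_limit = time_limit)
    timeout <- res$status == "TIMEOUT"
    mismatches <- if (timeout || !length(res$classifiers)) {
      length(test)   # conservative: unlearnable fold counts fully wrong
    } else {
      pred <- evaluate_rows(res$classifiers[[1L]], ds$x[test, , drop = FALSE])
      sum(pred != ds$annots[test])
    }
    per_fold[[f]] <- data.frame(fold = f, test_size = length(test),
                                mismatches = mismatches, timeout = timeout,
                                bounds_fn = res$bounds_used[[1L]],
                                bounds_fp = res$bounds_used[[2L]],
                                stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, per_fold)
  structure(list(generalization_error = sum(folds$mismatches) / n,
                 folds = folds, k = k, seed = as.integer(seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(x$k, "-fold cross-validation: generalization error ",
      format(x$generalization_error, digits = 4), "\n", sep = "")
  cat(sum(x$folds$timeout), "fold(s) timed out (counted as mispredicted)\n")
  invisible(x)
}
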