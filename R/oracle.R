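## Exhaustive verification oracle.  Deliberately naive and independent of the
## clause-pool engine: it enumerates every structurally valid classifier over
## the full marker set, evaluates each one on the data, and reads the optima
## off the resulting table.  Intended for cross-checking find_optimal() on
## small instances.

#' Exhaustive brute-force solver (verification oracle)
#'
#' Enumerates all classifiers that satisfy the structural constraints
#' (distinct sign-feasible clauses, gate count and total-input bounds, gate
#' type occurrence caps, optional unique-input rule), evaluates every one of
#' them on the dataset, keeps those within the error bounds, and returns all
#' optima under the chosen strategy.  The search space grows steeply, so the
#' oracle refuses instances beyond a small guard (more than 8 markers or a
#' total-input bound above 4); within the guard it is an independent reference
#' for [find_optimal()].
#'
#' @inheritParams find_optimal
#' @return A [solution_set()] with the same conventions as [find_optimal()]:
#'   all optima in canonical lexicographic order, objective entries `NA` for
#'   dimensions the strategy does not optimize.
#' @export
brute_force_oracle <- function(ds, profile, strategy = "opt3") {
  stopifnot(inherits(ds, "binarized_dataset"),
            inherits(profile, "constraint_profile"))
  strategy <- normalize_strategy(strategy)
  n <- length(ds$mirna_ids)
  if (n > 8L || profile$max_inputs > 4L)
    stop("oracle refuses large search spaces (limit: 8 markers, max_inputs 4); ",
         "got ", n, " markers, max_inputs ", profile$max_inputs, call. = FALSE)
  t0 <- Sys.time()
  x <- ds$x
  m <- nrow(x)
  markers <- ds$mirna_ids
  widest <- max(vapply(profile$gate_types, function(t) t$ub_pos + t$ub_neg,
                       integer(1L)))

  # every sign-feasible clause, as gate objects plus truth over all samples
  gates <- list(); truths <- list(); keys <- character(0)
  for (k in seq_len(min(profile$max_inputs, widest, n))) {
    for (combo in utils::combn(n, k, simplify = FALSE)) {
      signs <- expand.grid(rep(list(c(FALSE, TRUE)), k))
      for (r in seq_len(nrow(signs))) {
        neg <- as.logical(signs[r, ])
        g <- gate(markers[combo], neg)
        if (!length(gate_feasible_types(g, profile))) next
        sat <- rep(FALSE, m)
        for (j in seq_len(k))
          sat <- sat | (if (neg[j]) x[, combo[j]] == 0L else x[, combo[j]] == 1L)
        gates[[length(gates) + 1L]] <- g
        truths[[length(truths) + 1L]] <- sat
        keys <- c(keys, gate_key(g))
      }
    }
  }
  o <- order(vapply(gates, function(g) length(g$markers), integer(1L)), keys,
             method = "radix")
  gates <- gates[o]; truths <- truths[o]
  nlit <- vapply(gates, function(g) length(g$markers), integer(1L))
  P <- length(gates)
  annots <- ds$annots

  feasible <- list()   # each: list(idx, inputs, gates)
  consider <- function(idx) {
    cl <- classifier(gates[idx])
    if (length(validate_classifier(cl, profile))) return(invisible(NULL))
    pred <- rep(TRUE, m)
    for (i in idx) pred <- pred & truths[[i]]
    fn <- sum(annots == 1L & !pred)
    fp <- sum(annots == 0L & pred)
    if (fn <= profile$fn_bound && fp <= profile$fp_bound)
      feasible[[length(feasible) + 1L]] <<- list(
        idx = idx, inputs = sum(nlit[idx]), gates = length(idx))
    invisible(NULL)
  }
  rec <- function(start, idx, lits) {
    if (length(idx)) consider(idx)
    if (length(idx) == profile$max_gates || start > P) return(invisible(NULL))
    for (i in start:P) {
      if (lits + nlit[i] > profile$max_inputs) break  # sorted by nlit
      rec(i + 1L, c(idx, i), lits + nlit[i])
    }
    invisible(NULL)
  }
  if (P > 0L) rec(1L, integer(0), 0L)

  bounds <- c(fn = profile$fn_bound, fp = profile$fp_bound)
  elapsed <- function() as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (!length(feasible))
    return(solution_set(list(), list(inputs = NA, gates = NA), "INFEASIBLE",
                        bounds, elapsed(), strategy))
  ins <- vapply(feasible, `[[`, integer(1L), "inputs")
  gts <- vapply(feasible, `[[`, integer(1L), "gates")
  keep <- switch(strategy,
    feasible = rep(TRUE, length(feasible)),
    opt1 = ins == min(ins),
    opt2 = gts == min(gts),
    opt3 = ins == min(ins) & gts == min(gts[ins == min(ins)]),
    opt4 = gts == min(gts) & ins == min(ins[gts == min(gts)]))
  objective <- switch(strategy,
    feasible = list(inputs = NA, gates = NA),
    opt1 = list(inputs = min(ins), gates = NA),
    opt2 = list(inputs = NA, gates = min(gts)),
    opt3 = list(inputs = min(ins), gates = min(gts[ins == min(ins)])),
    opt4 = list(inputs = min(ins[gts == min(gts)]), gates = min(gts)))
  sols <- reduce_to_isomorphism_classes(
    lapply(feasible[keep], function(f) classifier(gates[f$idx])))
  status <- if (strategy == "feasible") "FEASIBLE" else "OPTIMAL"
  solution_set(sols, objective, status, bounds, elapsed(), strategy)
}
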