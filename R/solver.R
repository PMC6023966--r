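## Complete, globally optimal search for CNF classifiers under a constraint
## profile.  The engine works on a clause-pool reduction: under false-negative
## bound f, every solution classifier must have all of its gates true on the
## positives outside some misclassified set F (|F| <= f), so the search
## enumerates, for each maximal F, all sign-feasible clauses true on P \ F and
## then selects gate sets that falsify enough negatives ("cover" them) within
## the structural budgets.  Optimization is realized by iterative deepening on
## the objective, which yields global optimality certificates: level k is only
## accepted after level k-1 has been exhausted without a solution.

SOLVER_STATUSES <- c("OPTIMAL", "FEASIBLE", "INFEASIBLE", "TIMEOUT")

#' Construct a solution set
#'
#' Container for the result of a solver run: the enumerated classifiers (in
#' canonical form, deduplicated by isomorphism class), the achieved objective,
#' a status flag, the error bounds in force, and the elapsed wall time
#' (informational only).
#'
#' @param classifiers list of canonical-form [classifier()] objects.
#' @param objective list with fields `inputs` and `gates`; entries are `NA`
#'   for dimensions the strategy does not optimize.
#' @param status one of `"OPTIMAL"`, `"FEASIBLE"`, `"INFEASIBLE"`, `"TIMEOUT"`.
#' @param bounds_used integer vector `c(fn, fp)` of the error bounds in force.
#' @param elapsed seconds of wall time.
#' @param strategy the normalized strategy name.
#' @return An object of class `"solution_set"`.
#' @export
solution_set <- function(classifiers, objective, status, bounds_used,
                         elapsed = NA_real_, strategy = NA_character_) {
  status <- match.arg(status, SOLVER_STATUSES)
  if (status == "INFEASIBLE" && length(classifiers))
    stop("INFEASIBLE solution set cannot carry classifiers", call. = FALSE)
  structure(list(classifiers = classifiers, objective = objective,
                 status = status, bounds_used = bounds_used,
                 elapsed = elapsed, strategy = strategy),
            class = "solution_set")
}

#' @export
print.solution_set <- function(x, ...) {
  cat("Solution set [", x$status, "], strategy ", x$strategy,
      ", bounds (fn<=", x$bounds_used[1L], ", fp<=", x$bounds_used[2L], ")\n",
      sep = "")
  if (!is.null(x$objective) && !all(is.na(unlist(x$objective))))
    cat("Objective: inputs =", x$objective$inputs, ", gates =",
        x$objective$gates, "\n")
  cat(length(x$classifiers), "classifier(s)\n")
  for (cl in utils::head(x$classifiers, 10L))
    cat("  ", format_classifier(cl), "\n", sep = "")
  if (length(x$classifiers) > 10L) cat("  ...\n")
  invisible(x)
}

normalize_strategy <- function(s) {
  key <- gsub("[^a-z0-9]", "", tolower(s))
  map <- c(feasible = "feasible", feasibleonly = "feasible",
           opt1 = "opt1", opt1mininputs = "opt1", mininputs = "opt1",
           opt2 = "opt2", opt2mingates = "opt2", mingates = "opt2",
           opt3 = "opt3", opt3inputsthengates = "opt3",
           inputsthengates = "opt3",
           opt4 = "opt4", opt4gatestheninputs = "opt4",
           gatestheninputs = "opt4")
  if (!key %in% names(map))
    stop("unknown optimization strategy: ", s, call. = FALSE)
  unname(map[key])
}

# Shared mutable search state: deadline handling and node counting.
new_search_state <- function(deadline) {
  e <- new.env(parent = emptyenv())
  e$deadline <- deadline
  e$nodes <- 0L
  e$timed_out <- FALSE
  e
}

check_deadline <- function(st) {
  st$nodes <- st$nodes + 1L
  if (st$timed_out) return(TRUE)
  if (st$nodes %% 256L == 1L && Sys.time() > st$deadline) {
    st$timed_out <- TRUE
  }
  st$timed_out
}

# Exact search for a gate-type assignment given per-gate feasible type index
# sets and per-type occurrence caps.
assign_from_feasible <- function(feas, caps) {
  n <- length(feas)
  rec <- function(i, used) {
    if (i > n) return(TRUE)
    for (t in feas[[i]]) {
      if (used[t] < caps[t]) {
        used[t] <- used[t] + 1L
        if (rec(i + 1L, used)) return(TRUE)
        used[t] <- used[t] - 1L
      }
    }
    FALSE
  }
  rec(1L, integer(length(caps)))
}

# -- clause pool -------------------------------------------------------------

# Enumerate every sign-feasible clause with at most max_lits literals that is
# true on all rows `prows` of the binary matrix x.  Literals are indexed
# 1..n (non-negated) and n+1..2n (negated).  Truth-on-prows is an upward
# closed property (adding literals to a disjunction preserves truth), so a
# depth-first enumeration over literal indices with a reachability prune is
# complete.  Returns a list of clauses with canonical ordering metadata.
enum_clauses <- function(x, prows, max_lits, profile, st) {
  n <- ncol(x)
  npr <- length(prows)
  if (npr > 0L) {
    xp <- x[prows, , drop = FALSE]
    hits <- rbind(t(xp == 1L), t(xp == 0L))   # 2n x npr
    maxhit <- apply(hits, 2L, function(col) {
      w <- which(col); if (length(w)) max(w) else 0L })
  } else {
    hits <- NULL
    maxhit <- integer(0)
  }
  types <- profile$gate_types
  maxp <- max(vapply(types, `[[`, integer(1L), "ub_pos"))
  maxn <- max(vapply(types, `[[`, integer(1L), "ub_neg"))
  cap <- min(max_lits,
             max(vapply(types, function(t) t$ub_pos + t$ub_neg, integer(1L))))
  if (cap < 1L) return(list())
  sign_ok <- function(np, nn) {
    for (t in types)
      if (np >= t$lb_pos && np <= t$ub_pos && nn >= t$lb_neg && nn <= t$ub_neg)
        return(TRUE)
    FALSE
  }
  acc <- new.env(parent = emptyenv())
  acc$lst <- list(); acc$k <- 0L
  used_m <- logical(n)
  rec <- function(start, lits, unhit, np, nn) {
    if (check_deadline(st)) return(invisible(NULL))
    if (length(lits) && !any(unhit) && sign_ok(np, nn)) {
      acc$k <- acc$k + 1L
      acc$lst[[acc$k]] <- lits
    }
    if (length(lits) >= cap || start > 2L * n) return(invisible(NULL))
    if (any(unhit & (maxhit < start))) return(invisible(NULL))
    for (l in start:(2L * n)) {
      m <- if (l <= n) l else l - n
      if (used_m[m]) next
      if (l <= n && np >= maxp) next
      if (l > n && nn >= maxn) next
      used_m[m] <<- TRUE
      new_unhit <- if (npr) unhit & !hits[l, ] else unhit
      rec(l + 1L, c(lits, l), new_unhit, np + (l <= n), nn + (l > n))
      used_m[m] <<- FALSE
      if (st$timed_out) return(invisible(NULL))
    }
    invisible(NULL)
  }
  rec(1L, integer(0), rep(TRUE, npr), 0L, 0L)
  acc$lst
}

# Build pool metadata: canonical keys, literal counts, per-clause feasible
# types, covered negatives.  Pool is sorted by (nlit, canonical key) so the
# cover search can break early on the input budget while staying
# deterministic.
build_pool <- function(clauses, x, nrows_neg, markers, profile) {
  n <- ncol(x)
  if (!length(clauses))
    return(list(nlit = integer(0), keys = character(0), lits = list(),
                mk = list(), covers = list(), feas = list()))
  if (length(nrows_neg)) {
    xn <- x[nrows_neg, , drop = FALSE]
    lit_true_neg <- rbind(t(xn == 1L), t(xn == 0L))   # 2n x nneg
  } else lit_true_neg <- NULL
  info <- lapply(clauses, function(lits) {
    posm <- lits[lits <= n]
    negm <- lits[lits > n] - n
    g <- gate(markers[c(posm, negm)],
              c(rep(FALSE, length(posm)), rep(TRUE, length(negm))))
    cover <- if (length(nrows_neg))
      which(colSums(lit_true_neg[lits, , drop = FALSE]) == 0L)
    else integer(0)
    list(lits = lits, gate = g, key = gate_key(g), nlit = length(lits),
         mk = c(posm, negm), cover = cover,
         feas = gate_feasible_types(g, profile))
  })
  nlit <- vapply(info, `[[`, integer(1L), "nlit")
  keys <- vapply(info, `[[`, character(1L), "key")
  o <- order(nlit, keys, method = "radix")
  info <- info[o]
  list(nlit = nlit[o], keys = keys[o],
       lits = lapply(info, `[[`, "lits"),
       gates = lapply(info, `[[`, "gate"),
       mk = lapply(info, `[[`, "mk"),
       covers = lapply(info, `[[`, "cover"),
       feas = lapply(info, `[[`, "feas"))
}

# -- cover search over a pool ------------------------------------------------

# Depth-first search over index-ascending gate sets drawn from the pool.
# Records every gate set that covers (falsifies) at least `need_cover`
# negatives within the budgets, matches the exact totals when requested, and
# admits a gate-type assignment under the occurrence caps.  Exact and
# complete: the only prunes are the monotone budget/coverage bounds.
search_pool <- function(pool, n_neg, need_cover, max_gates, max_inputs,
                        exact_gates = NA_integer_, exact_inputs = NA_integer_,
                        unique_input = FALSE, profile, stop_first, st) {
  npool <- length(pool$nlit)
  res <- new.env(parent = emptyenv())
  res$sets <- list(); res$k <- 0L; res$stop <- FALSE
  if (npool == 0L) return(res)
  caps <- vapply(profile$gate_types, `[[`, integer(1L), "max_occurrences")
  caps_bind <- any(caps < max_gates)
  maxcov <- integer(n_neg)
  if (n_neg > 0L)
    for (i in seq_len(npool))
      maxcov[pool$covers[[i]]] <- pmax(maxcov[pool$covers[[i]]], i)
  covered0 <- logical(n_neg)

  rec <- function(start, chosen, inputs, covered, used_m) {
    if (check_deadline(st)) { res$stop <- TRUE; return(invisible(NULL)) }
    g <- length(chosen)
    if (g >= 1L && sum(covered) >= need_cover &&
        (is.na(exact_gates) || g == exact_gates) &&
        (is.na(exact_inputs) || inputs == exact_inputs)) {
      ok <- if (caps_bind) assign_from_feasible(pool$feas[chosen], caps) else TRUE
      if (ok) {
        res$k <- res$k + 1L
        res$sets[[res$k]] <- chosen
        if (stop_first) { res$stop <- TRUE; return(invisible(NULL)) }
      }
    }
    if (g == max_gates) return(invisible(NULL))
    if (n_neg > 0L) {
      reach <- sum(covered) + sum(!covered & maxcov >= start)
      if (reach < need_cover) return(invisible(NULL))
    }
    if (start > npool) return(invisible(NULL))
    for (i in start:npool) {
      if (inputs + pool$nlit[i] > max_inputs) break   # pool sorted by nlit
      if (unique_input && any(pool$mk[[i]] %in% used_m)) next
      if (caps_bind && !assign_from_feasible(pool$feas[c(chosen, i)], caps))
        next
      cov2 <- covered
      cov2[pool$covers[[i]]] <- TRUE
      rec(i + 1L, c(chosen, i), inputs + pool$nlit[i], cov2,
          c(used_m, pool$mk[[i]]))
      if (res$stop) return(invisible(NULL))
    }
    invisible(NULL)
  }
  rec(1L, integer(0), 0L, covered0, integer(0))
  res
}

# Enumerate the maximal false-negative sets: all subsets of the positive rows
# of size min(fn_bound, npos).  Constraining the gates to be true only on the
# positives outside a *maximal* set is the weakest form of the constraint, so
# the union of searches over maximal sets finds every classifier with
# fn <= fn_bound.
fn_subsets <- function(pos_rows, fn_bound) {
  f <- min(fn_bound, length(pos_rows))
  if (f == 0L) return(list(integer(0)))
  utils::combn(pos_rows, f, simplify = FALSE)
}

# Run the pooled search across all maximal FN sets.  Returns canonicalized,
# deduplicated classifiers plus a timeout flag.
engine_search <- function(ds, profile, max_gates, max_inputs,
                          exact_gates = NA_integer_, exact_inputs = NA_integer_,
                          stop_first = FALSE, st) {
  x <- ds$x
  pos <- which(ds$annots == 1L)
  neg <- which(ds$annots == 0L)
  need_cover <- max(0L, length(neg) - profile$fp_bound)
  out <- list(); seen <- character(0)
  for (F in fn_subsets(pos, profile$fn_bound)) {
    prows <- setdiff(pos, F)
    clauses <- enum_clauses(x, prows, max_inputs, profile, st)
    if (st$timed_out) break
    pool <- build_pool(clauses, x, neg, ds$mirna_ids, profile)
    res <- search_pool(pool, length(neg), need_cover, max_gates, max_inputs,
                       exact_gates, exact_inputs, profile$unique_input,
                       profile, stop_first, st)
    for (set in res$sets) {
      cl <- canonicalize(classifier(pool$gates[set]))
      key <- classifier_key(cl)
      if (!key %in% seen) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- cl
      }
      if (stop_first) break
    }
    if (st$timed_out || (stop_first && length(out))) break
  }
  if (length(out)) {
    keys <- vapply(out, classifier_key, character(1L))
    out <- out[order(keys, method = "radix")]
  }
  list(classifiers = out, timeout = st$timed_out)
}

# -- lazy feasibility search -------------------------------------------------

# Feasibility search that never materializes the full clause pool: branch on
# the first uncovered negative and lazily enumerate the clauses that falsify
# it while staying true on all required positives (minimal hitting sets over
# the literals that are false on the target negative).  Complete for
# feasibility under sign-monotone profiles such as the core constraints,
# where any sub-clause of a feasible clause that still hits the positives
# remains assignable to a gate type.  Used for the plain feasibility strategy
# on instances too large for pooled enumeration.
lazy_feasible <- function(x, prows, nrows_neg, profile, st) {
  n <- ncol(x)
  npr <- length(prows)
  types <- profile$gate_types
  maxp <- max(vapply(types, `[[`, integer(1L), "ub_pos"))
  maxn <- max(vapply(types, `[[`, integer(1L), "ub_neg"))
  clause_cap <- max(vapply(types, function(t) t$ub_pos + t$ub_neg, integer(1L)))
  caps <- vapply(types, `[[`, integer(1L), "max_occurrences")
  sign_feas <- function(np, nn)
    which(vapply(types, function(t)
      np >= t$lb_pos && np <= t$ub_pos && nn >= t$lb_neg && nn <= t$ub_neg,
      logical(1L)))
  hits <- if (npr) {
    xp <- x[prows, , drop = FALSE]
    rbind(t(xp == 1L), t(xp == 0L))
  } else NULL
  lit_true_neg <- if (length(nrows_neg)) {
    xn <- x[nrows_neg, , drop = FALSE]
    rbind(t(xn == 1L), t(xn == 0L))
  } else NULL
  need_cover <- max(0L, length(nrows_neg) - profile$fp_bound)

  found <- new.env(parent = emptyenv())
  found$sol <- NULL

  # Enumerate clauses over the literal universe `univ` (indices into 1..2n)
  # that hit every required positive; for each complete clause call `cont`.
  # The exclusion discipline (literals tried at a branch are barred from
  # later branches) visits each inclusion-minimal clause exactly once.
  clause_dfs <- function(univ, lits, unhit, np, nn, max_lits, cont) {
    if (check_deadline(st)) return(invisible(NULL))
    if (!any(unhit)) {
      if (length(lits)) {
        if (length(sign_feas(np, nn))) cont(lits)
      } else {
        # no positives need hitting: any single admissible literal forms a gate
        for (l in sort(univ)) {
          ok <- if (l <= n) length(sign_feas(1L, 0L)) else length(sign_feas(0L, 1L))
          if (ok) cont(l)
          if (!is.null(found$sol) || st$timed_out) break
        }
      }
      return(invisible(NULL))
    }
    if (length(lits) >= max_lits) return(invisible(NULL))
    p <- which(unhit)[1L]
    cand <- univ[hits[univ, p]]
    if (!length(cand)) return(invisible(NULL))
    # branch on the literal hitting the most still-unhit positives first
    gain <- vapply(cand, function(l) sum(hits[l, ] & unhit), integer(1L))
    cand <- cand[order(-gain, cand)]
    barred <- integer(0)
    for (l in cand) {
      m <- if (l <= n) l else l - n
      if (l <= n && np >= maxp) next
      if (l > n && nn >= maxn) next
      univ2 <- setdiff(univ, c(barred, l, m, m + n))
      clause_dfs(univ2, c(lits, l), unhit & !hits[l, ],
                 np + (l <= n), nn + (l > n), max_lits, cont)
      if (!is.null(found$sol) || st$timed_out) return(invisible(NULL))
      barred <- c(barred, l)
    }
    invisible(NULL)
  }

  cover_rec <- function(gates_lits, inputs, covered, occupied) {
    if (check_deadline(st)) return(invisible(NULL))
    if (length(gates_lits) >= 1L && sum(covered) >= need_cover) {
      feas <- lapply(gates_lits, function(lits)
        sign_feas(sum(lits <= n), sum(lits > n)))
      if (assign_from_feasible(feas, caps)) {
        found$sol <- gates_lits
        return(invisible(NULL))
      }
    }
    if (length(gates_lits) >= profile$max_gates) return(invisible(NULL))
    rem <- profile$max_inputs - inputs
    if (rem < 1L) return(invisible(NULL))
    if (sum(covered) >= need_cover) {
      # coverage complete but no admissible gate yet (all-positive data):
      # add one clause over the full literal universe
      if (length(gates_lits) == 0L)
        clause_dfs(seq_len(2L * n), integer(0), rep(TRUE, npr), 0L, 0L,
                   min(rem, clause_cap), function(lits)
                     cover_rec(list(lits), length(lits), covered, occupied))
      return(invisible(NULL))
    }
    j <- which(!covered)[1L]
    # literals false on negative j: non-negated where j is low, negated where high
    univ <- c(which(!lit_true_neg[seq_len(n), j]),
              n + which(!lit_true_neg[n + seq_len(n), j]))
    if (profile$unique_input) univ <- univ[!((univ - 1L) %% n + 1L) %in% occupied]
    clause_dfs(univ, integer(0), rep(TRUE, npr), 0L, 0L,
               min(rem, clause_cap), function(lits) {
      key_new <- paste(sort(lits), collapse = ",")
      keys_old <- vapply(gates_lits, function(g) paste(sort(g), collapse = ","),
                         character(1L))
      if (key_new %in% keys_old) return(invisible(NULL))
      cov2 <- covered
      if (length(nrows_neg))
        cov2[colSums(lit_true_neg[lits, , drop = FALSE]) == 0L] <- TRUE
      if (!cov2[j]) return(invisible(NULL))
      cover_rec(c(gates_lits, list(lits)), inputs + length(lits), cov2,
                c(occupied, (lits - 1L) %% n + 1L))
    })
    invisible(NULL)
  }

  cover_rec(list(), 0L, logical(length(nrows_neg)), integer(0))
  if (is.null(found$sol)) return(NULL)
  markers <- colnames(x)
  classifier(lapply(found$sol, function(lits) {
    posm <- lits[lits <= n]; negm <- lits[lits > n] - n
    gate(markers[c(posm, negm)],
         c(rep(FALSE, length(posm)), rep(TRUE, length(negm))))
  }))
}

# -- public solver interface -------------------------------------------------

#' Find globally optimal classifiers
#'
#' Complete search for classifiers that satisfy a constraint profile
#' (structural bounds, gate types, error bounds) and are globally optimal
#' under the chosen strategy:
#' \describe{
#'   \item{`"feasible"`}{any classifier satisfying the constraints.}
#'   \item{`"opt1"`}{minimize the total number of inputs.}
#'   \item{`"opt2"`}{minimize the number of gates.}
#'   \item{`"opt3"`}{minimize inputs, then gates (bi-level).}
#'   \item{`"opt4"`}{minimize gates, then inputs (bi-level).}
#' }
#' Global optimality means that if the optimum has, say, 7 inputs, then no
#' feasible classifier with fewer than 7 inputs exists for this dataset and
#' profile.  With `enumerate_all = TRUE` the solution set contains all optima,
#' reduced to isomorphism-class representatives in deterministic
#' (lexicographic) order.
#'
#' @param ds a [binarized_dataset()].
#' @param profile a [constraint_profile()]; its `fn_bound`/`fp_bound` fields
#'   are the error bounds in force.
#' @param strategy one of `"feasible"`, `"opt1"`..`"opt4"` (long spellings
#'   such as `"opt3_inputs_then_gates"` are accepted).
#' @param enumerate_all logical; enumerate all optima instead of one.
#' @param time_limit wall-clock budget in seconds (default unlimited).  On
#'   expiry the status is `"TIMEOUT"` (or `"FEASIBLE"` when an incumbent was
#'   found but completeness is unproven).
#' @param weights optional named non-negative weight per marker; when given,
#'   input minimization minimizes the weighted sum of input costs (weight 1
#'   for unnamed markers).  Supported on small instances via exhaustive
#'   enumeration.
#' @param seed reserved for backend randomization; the engine itself is
#'   deterministic and ignores it.
#' @return A [solution_set()].
#' @seealso [brute_force_oracle()], [relax_and_solve()]
#' @export
find_optimal <- function(ds, profile, strategy = "opt3", enumerate_all = FALSE,
                         time_limit = Inf, weights = NULL, seed = 0L) {
  stopifnot(inherits(ds, "binarized_dataset"),
            inherits(profile, "constraint_profile"))
  if (profile$max_inputs < 1L || profile$max_gates < 1L)
    stop("contradictory profile: max_inputs and max_gates must be >= 1",
         call. = FALSE)
  strategy <- normalize_strategy(strategy)
  t0 <- Sys.time()
  st <- new_search_state(t0 + time_limit)
  bounds <- c(fn = profile$fn_bound, fp = profile$fp_bound)
  finish <- function(classifiers, objective, status)
    solution_set(classifiers, objective, status, bounds,
                 elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                 strategy = strategy)

  if (!is.null(weights))
    return(find_optimal_weighted(ds, profile, strategy, enumerate_all, st,
                                 weights, finish))

  if (strategy == "feasible") {
    if (enumerate_all) {
      r <- engine_search(ds, profile, profile$max_gates, profile$max_inputs,
                         stop_first = FALSE, st = st)
      status <- if (length(r$classifiers)) "FEASIBLE"
                else if (r$timeout) "TIMEOUT" else "INFEASIBLE"
      return(finish(r$classifiers, list(inputs = NA, gates = NA), status))
    }
    # the lazy cover search restricts itself to inclusion-minimal clauses;
    # its infeasibility proof is complete when no gate type demands more than
    # one input of a given sign (true for the core constraints)
    monotone <- all(vapply(profile$gate_types, function(t)
      t$lb_pos <= 1L && t$lb_neg <= 1L, logical(1L)))
    if (monotone) {
      pos <- which(ds$annots == 1L); neg <- which(ds$annots == 0L)
      for (F in fn_subsets(pos, profile$fn_bound)) {
        sol <- lazy_feasible(ds$x, setdiff(pos, F), neg, profile, st)
        if (!is.null(sol))
          return(finish(list(canonicalize(sol)), list(inputs = NA, gates = NA),
                        "FEASIBLE"))
        if (st$timed_out)
          return(finish(list(), list(inputs = NA, gates = NA), "TIMEOUT"))
      }
      return(finish(list(), list(inputs = NA, gates = NA), "INFEASIBLE"))
    }
    r <- engine_search(ds, profile, profile$max_gates, profile$max_inputs,
                       stop_first = TRUE, st = st)
    status <- if (length(r$classifiers)) "FEASIBLE"
              else if (r$timeout) "TIMEOUT" else "INFEASIBLE"
    return(finish(r$classifiers, list(inputs = NA, gates = NA), status))
  }

  # iterative deepening helpers; each level is a complete search, so the
  # first level with a solution is the global optimum.
  deepen <- function(budget_seq, search_at) {
    for (b in budget_seq) {
      r <- search_at(b)
      if (length(r$classifiers)) return(list(value = b, hit = r))
      if (r$timeout) return(list(value = NA_integer_, hit = NULL, timeout = TRUE))
    }
    list(value = NA_integer_, hit = NULL, timeout = FALSE)
  }
  min_inputs <- function(gate_budget) deepen(seq_len(profile$max_inputs),
    function(b) engine_search(ds, profile, gate_budget, b, stop_first = TRUE, st = st))
  min_gates <- function(input_budget) deepen(seq_len(profile$max_gates),
    function(b) engine_search(ds, profile, b, input_budget, stop_first = TRUE, st = st))

  timeout_result <- function() finish(list(), list(inputs = NA, gates = NA), "TIMEOUT")
  infeasible_result <- function() finish(list(), list(inputs = NA, gates = NA), "INFEASIBLE")

  if (strategy %in% c("opt1", "opt3")) {
    d1 <- min_inputs(profile$max_gates)
    if (is.na(d1$value))
      return(if (isTRUE(d1$timeout)) timeout_result() else infeasible_result())
    I <- d1$value
    if (strategy == "opt1") {
      if (!enumerate_all)
        return(finish(d1$hit$classifiers[1L], list(inputs = I, gates = NA),
                      "OPTIMAL"))
      r <- engine_search(ds, profile, profile$max_gates, I,
                         exact_inputs = I, stop_first = FALSE, st = st)
      return(finish(r$classifiers, list(inputs = I, gates = NA),
                    if (r$timeout) "FEASIBLE" else "OPTIMAL"))
    }
    d2 <- min_gates(I)
    if (is.na(d2$value))
      return(if (isTRUE(d2$timeout)) timeout_result() else infeasible_result())
    G <- d2$value
    if (!enumerate_all)
      return(finish(d2$hit$classifiers[1L], list(inputs = I, gates = G),
                    "OPTIMAL"))
    r <- engine_search(ds, profile, G, I, exact_gates = G, exact_inputs = I,
                       stop_first = FALSE, st = st)
    return(finish(r$classifiers, list(inputs = I, gates = G),
                  if (r$timeout) "FEASIBLE" else "OPTIMAL"))
  }

  # opt2 / opt4
  d1 <- min_gates(profile$max_inputs)
  if (is.na(d1$value))
    return(if (isTRUE(d1$timeout)) timeout_result() else infeasible_result())
  G <- d1$value
  if (strategy == "opt2") {
    if (!enumerate_all)
      return(finish(d1$hit$classifiers[1L], list(inputs = NA, gates = G),
                    "OPTIMAL"))
    r <- engine_search(ds, profile, G, profile$max_inputs,
                       exact_gates = G, stop_first = FALSE, st = st)
    return(finish(r$classifiers, list(inputs = NA, gates = G),
                  if (r$timeout) "FEASIBLE" else "OPTIMAL"))
  }
  d2 <- deepen(seq_len(profile$max_inputs), function(b)
    engine_search(ds, profile, G, b, stop_first = TRUE, st = st))
  if (is.na(d2$value))
    return(if (isTRUE(d2$timeout)) timeout_result() else infeasible_result())
  I <- d2$value
  if (!enumerate_all)
    return(finish(d2$hit$classifiers[1L], list(inputs = I, gates = G),
                  "OPTIMAL"))
  r <- engine_search(ds, profile, G, I, exact_gates = G, exact_inputs = I,
                     stop_first = FALSE, st = st)
  finish(r$classifiers, list(inputs = I, gates = G),
         if (r$timeout) "FEASIBLE" else "OPTIMAL")
}

# Weighted-input optimization: exhaustive enumeration of all feasible
# classifiers, then minimization of the weighted input cost.  Intended for
# penalizing or favoring specific miRNAs on moderate instances.
find_optimal_weighted <- function(ds, profile, strategy, enumerate_all, st,
                                  weights, finish) {
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (length(ds$mirna_ids) > 14L)
    stop("weighted optimization uses exhaustive enumeration and is limited ",
         "to 14 markers", call. = FALSE)
  w <- rep(1, length(ds$mirna_ids))
  names(w) <- ds$mirna_ids
  w[names(weights)] <- weights
  r <- engine_search(ds, profile, profile$max_gates, profile$max_inputs,
                     stop_first = FALSE, st = st)
  if (st$timed_out) return(finish(list(), list(inputs = NA, gates = NA), "TIMEOUT"))
  if (!length(r$classifiers))
    return(finish(list(), list(inputs = NA, gates = NA), "INFEASIBLE"))
  cost <- vapply(r$classifiers, function(cl)
    sum(w[unlist(lapply(cl$gates, `[[`, "markers"))]), numeric(1L))
  gts <- vapply(r$classifiers, n_gates, integer(1L))
  key <- switch(strategy,
    opt1 = order(cost),
    opt2 = order(gts),
    opt3 = order(cost, gts),
    opt4 = order(gts, cost),
    order(seq_along(cost)))
  best <- r$classifiers[key]
  bc <- cost[key][1L]; bg <- gts[key][1L]
  keep <- switch(strategy,
    opt1 = cost == bc,
    opt2 = gts == bg,
    opt3 = cost == bc & gts == min(gts[cost == bc]),
    opt4 = gts == bg & cost == min(cost[gts == bg]),
    rep(TRUE, length(cost)))
  sols <- r$classifiers[keep]
  if (!enumerate_all) sols <- sols[1L]
  finish(sols, list(inputs = min(cost[keep]), gates = min(gts[keep])), "OPTIMAL")
}

# -- relaxation --------------------------------------------------------------

#' Construct a relaxation policy
#'
#' Controls how the false negative / false positive error bounds are relaxed
#' when no perfect classifier exists.  With `forbid_fp` the schedule raises
#' only the FN bound (no false positives are ever admitted); `forbid_fn` is
#' symmetric.
#'
#' @param forbid_fp,forbid_fn logical switches restricting the schedule to one
#'   error axis.
#' @return An object of class `"relaxation_policy"`.
#' @export
relaxation_policy <- function(forbid_fp = FALSE, forbid_fn = FALSE) {
  structure(list(forbid_fp = isTRUE(forbid_fp), forbid_fn = isTRUE(forbid_fn)),
            class = "relaxation_policy")
}

#' Generate the stepwise error-bound relaxation schedule
#'
#' Starting from the perfect-classifier bounds (0, 0), the default schedule
#' orders the (fn, fp) bound pairs by total allowed errors ascending and, for
#' equal totals, raises the FN bound first: (0,0), (1,0), (0,1), (2,0), (1,1),
#' (0,2), ...  With `forbid_fp` the schedule is (0,0), (1,0), (2,0), ...;
#' `forbid_fn` is symmetric.
#'
#' @param policy a [relaxation_policy()].
#' @param max_total largest total error bound to schedule (>= 0).
#' @return A list of integer vectors `c(fn, fp)`.
#' @export
relaxation_schedule <- function(policy = relaxation_policy(), max_total) {
  stopifnot(inherits(policy, "relaxation_policy"), max_total >= 0)
  if (policy$forbid_fp && policy$forbid_fn && max_total > 0)
    stop("both error types are forbidden but max_total > 0", call. = FALSE)
  steps <- list(c(fn = 0L, fp = 0L))
  if (max_total >= 1L) for (t in seq_len(max_total)) {
    if (policy$forbid_fp) steps <- c(steps, list(c(fn = t, fp = 0L)))
    else if (policy$forbid_fn) steps <- c(steps, list(c(fn = 0L, fp = t)))
    else for (fn in t:0) steps <- c(steps, list(c(fn = fn, fp = t - fn)))
  }
  steps
}

#' Solve with stepwise constraint relaxation
#'
#' First attempts a perfect classifier (error bounds (0,0)); if the problem is
#' infeasible, walks the relaxation schedule, re-solving at each bound pair,
#' and returns the solution set of the first feasible step.  Classifier
#' accuracy thereby stays above structural simplicity in the optimization
#' hierarchy; ties among equal-total alternatives at one step are broken by
#' the chosen strategy (e.g. fewer inputs under `"opt3"`).
#'
#' @inheritParams find_optimal
#' @param policy a [relaxation_policy()].
#' @param max_total largest total error bound to try; defaults to the sample
#'   count (the schedule is then always eventually feasible).
#' @return A [solution_set()]; its `bounds_used` field records the succeeding
#'   step.  Status `"INFEASIBLE"` with the last bounds tried when the schedule
#'   is exhausted, `"TIMEOUT"` when the budget expires first.
#' @export
relax_and_solve <- function(ds, profile, strategy = "opt3",
                            policy = relaxation_policy(), max_total = NULL,
                            enumerate_all = FALSE, time_limit = Inf) {
  stopifnot(inherits(ds, "binarized_dataset"),
            inherits(profile, "constraint_profile"))
  if (is.null(max_total)) max_total <- length(ds$sample_ids)
  t0 <- Sys.time()
  deadline <- t0 + time_limit
  last <- NULL
  for (step in relaxation_schedule(policy, max_total)) {
    p <- profile
    p$fn_bound <- step[["fn"]]
    p$fp_bound <- step[["fp"]]
    remaining <- as.numeric(difftime(deadline, Sys.time(), units = "secs"))
    if (remaining <= 0) {
      res <- solution_set(list(), list(inputs = NA, gates = NA), "TIMEOUT",
                          step, elapsed = as.numeric(
                            difftime(Sys.time(), t0, units = "secs")),
                          strategy = normalize_strategy(strategy))
      return(res)
    }
    res <- find_optimal(ds, p, strategy, enumerate_all,
                        time_limit = remaining)
    if (res$status %in% c("OPTIMAL", "FEASIBLE", "TIMEOUT")) {
      res$elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
      return(res)
    }
    last <- res
  }
  last$elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  last
}
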