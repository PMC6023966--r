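#' Describe one laboratory gate type
#'
#' A gate type is described by five bounds: lower and upper bounds on
#' non-negated (positive) inputs, lower and upper bounds on negated inputs,
#' and an upper bound on how many gates of this type one classifier may
#' contain.
#'
#' @param type_id small integer identifying the type.
#' @param lb_pos,ub_pos bounds on non-negated inputs per gate.
#' @param lb_neg,ub_neg bounds on negated inputs per gate.
#' @param max_occurrences upper bound on gates of this type per classifier.
#' @return An object of class `"gate_type"`.
#' @export
gate_type <- function(type_id, lb_pos, ub_pos, lb_neg, ub_neg, max_occurrences) {
  stopifnot(lb_pos >= 0, ub_pos >= lb_pos, lb_neg >= 0, ub_neg >= lb_neg,
            max_occurrences >= 0)
  if (lb_pos + lb_neg < 1L)
    stop("a gate must have at least one input: lb_pos + lb_neg must be >= 1",
         call. = FALSE)
  structure(list(type_id = as.integer(type_id),
                 lb_pos = as.integer(lb_pos), ub_pos = as.integer(ub_pos),
                 lb_neg = as.integer(lb_neg), ub_neg = as.integer(ub_neg),
                 max_occurrences = as.integer(max_occurrences)),
            class = "gate_type")
}

#' Construct a constraint profile
#'
#' The constraints capture the feasibility of assembling a classifier circuit
#' in the laboratory: upper bounds on the number of gates and the total number
#' of inputs, the admissible gate types, optionally the unique-input rule (no
#' miRNA shared across gates) and upper bounds on false negative / false
#' positive classification errors.
#'
#' @param max_gates maximum number of gates (>= 1).
#' @param max_inputs maximum total number of inputs across gates (>= 1).
#' @param gate_types list of [gate_type()] specifications (at least one).
#' @param unique_input logical; when `TRUE` no marker may appear in more than
#'   one gate.
#' @param fn_bound,fp_bound upper bounds on false negatives / false positives
#'   (counts, default 0 = perfect classifier required).
#' @return An object of class `"constraint_profile"`.
#' @seealso [core_profile()], [validate_classifier()]
#' @export
constraint_profile <- function(max_gates, max_inputs, gate_types,
                               unique_input = FALSE, fn_bound = 0L,
                               fp_bound = 0L) {
  stopifnot(max_gates >= 1, max_inputs >= 1, length(gate_types) >= 1,
            fn_bound >= 0, fp_bound >= 0)
  if (!all(vapply(gate_types, inherits, logical(1L), "gate_type")))
    stop("gate_types must be a list of gate_type objects", call. = FALSE)
  structure(list(max_gates = as.integer(max_gates),
                 max_inputs = as.integer(max_inputs),
                 gate_types = gate_types,
                 unique_input = isTRUE(unique_input),
                 fn_bound = as.integer(fn_bound),
                 fp_bound = as.integer(fp_bound)),
            class = "constraint_profile")
}

#' The core laboratory constraints
#'
#' The default feasibility profile for miRNA classifier circuits: up to 6
#' gates with overall up to 8 inputs, where every gate is either Type 1 (an OR
#' gate with only non-negated inputs) or Type 2 (a NOT gate with exactly one
#' negated input).  Occurrence caps default to the gate bound itself, i.e. the
#' least restrictive choice; both are user-overridable.  Error bounds default
#' to zero (perfect classifier).
#'
#' @param max_gates,max_inputs global bounds; defaults 6 and 8.
#' @param fn_bound,fp_bound error bounds; default 0.
#' @param unique_input logical, default `FALSE`.
#' @return A [constraint_profile()].
#' @export
core_profile <- function(max_gates = 6L, max_inputs = 8L, fn_bound = 0L,
                         fp_bound = 0L, unique_input = FALSE) {
  constraint_profile(
    max_gates = max_gates, max_inputs = max_inputs,
    gate_types = list(
      # Type 1: OR gate, only non-negated inputs
      gate_type(1L, lb_pos = 1L, ub_pos = max_inputs, lb_neg = 0L, ub_neg = 0L,
                max_occurrences = max_gates),
      # Type 2: NOT gate, exactly one negated input
      gate_type(2L, lb_pos = 0L, ub_pos = 0L, lb_neg = 1L, ub_neg = 1L,
                max_occurrences = max_gates)),
    unique_input = unique_input, fn_bound = fn_bound, fp_bound = fp_bound)
}

# Types a single gate can take under the profile, by sign counts alone.
gate_feasible_types <- function(g, profile) {
  npos <- sum(!g$negated); nneg <- sum(g$negated)
  which(vapply(profile$gate_types, function(t)
    npos >= t$lb_pos && npos <= t$ub_pos && nneg >= t$lb_neg && nneg <= t$ub_neg,
    logical(1L)))
}

# Exact search for a gate -> type assignment respecting occurrence caps.
# Returns an integer vector of type indices, or NULL when none exists.
# Gate counts are small (<= max_gates), so exhaustive search is cheap; a
# greedy assignment could falsely reject feasible classifiers.
assign_gate_types <- function(c, profile) {
  feas <- lapply(c$gates, gate_feasible_types, profile = profile)
  if (any(vapply(feas, length, integer(1L)) == 0L)) return(NULL)
  caps <- vapply(profile$gate_types, `[[`, integer(1L), "max_occurrences")
  n <- length(feas)
  assign <- integer(n)
  rec <- function(i, used) {
    if (i > n) return(TRUE)
    for (t in feas[[i]]) {
      if (used[t] < caps[t]) {
        used[t] <- used[t] + 1L
        assign[i] <<- t
        if (rec(i + 1L, used)) return(TRUE)
        used[t] <- used[t] - 1L
      }
    }
    FALSE
  }
  if (rec(1L, integer(length(caps)))) assign else NULL
}

#' Check a classifier against a constraint profile
#'
#' Checks, in order: gate count, total input count, sign-assignability of each
#' gate to some gate type, existence of a type assignment respecting the
#' per-type occurrence caps (found by exact search over assignments), and,
#' when the unique-input rule is active, that no marker appears in more than
#' one gate.  Violations are returned as data, not raised as errors.
#'
#' @param c a [classifier()].
#' @param profile a [constraint_profile()].
#' @return Character vector of violation messages; empty iff the classifier is
#'   feasible under the profile.
#' @export
validate_classifier <- function(c, profile) {
  stopifnot(is_classifier(c), inherits(profile, "constraint_profile"))
  v <- character()
  if (n_gates(c) > profile$max_gates)
    v <- c(v, sprintf("gate count %d > %d", n_gates(c), profile$max_gates))
  if (n_inputs(c) > profile$max_inputs)
    v <- c(v, sprintf("total inputs %d > %d", n_inputs(c), profile$max_inputs))
  feas <- lapply(c$gates, gate_feasible_types, profile = profile)
  bad <- which(vapply(feas, length, integer(1L)) == 0L)
  for (i in bad)
    v <- c(v, sprintf("gate %d (%s) matches no gate type", i,
                      paste(literal_tokens(c$gates[[i]]), collapse = " | ")))
  if (!length(bad) && is.null(assign_gate_types(c, profile)))
    v <- c(v, "no gate-type assignment satisfies the occurrence caps")
  if (profile$unique_input) {
    all_m <- unlist(lapply(c$gates, `[[`, "markers"))
    dup <- unique(all_m[duplicated(all_m)])
    for (m in dup)
      v <- c(v, sprintf("marker %s is shared across gates (unique-input rule)", m))
  }
  v
}

#' Save / load a constraint profile
#'
#' Profiles round-trip through a human-editable YAML file listing the global
#' bounds and flags plus one section per gate type with its five bounds.
#'
#' @param profile a [constraint_profile()].
#' @param path file path.
#' @return `save_constraints()`: `path` invisibly; `load_constraints()`: the
#'   [constraint_profile()].
#' @export
save_constraints <- function(profile, path) {
  stopifnot(inherits(profile, "constraint_profile"))
  obj <- list(max_gates = profile$max_gates, max_inputs = profile$max_inputs,
              unique_input = profile$unique_input,
              fn_bound = profile$fn_bound, fp_bound = profile$fp_bound,
              gate_types = lapply(profile$gate_types, unclass))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname save_constraints
#' @export
load_constraints <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- yaml::read_yaml(path)
  for (f in c("max_gates", "max_inputs", "gate_types"))
    if (is.null(obj[[f]]))
      stop("constraint config lacks required field '", f, "'", call. = FALSE)
  types <- lapply(obj$gate_types, function(t) {
    for (f in c("type_id", "lb_pos", "ub_pos", "lb_neg", "ub_neg",
                "max_occurrences"))
      if (is.null(t[[f]]))
        stop("gate type section lacks field '", f, "'", call. = FALSE)
    tryCatch(
      gate_type(t$type_id, t$lb_pos, t$ub_pos, t$lb_neg, t$ub_neg,
                t$max_occurrences),
      error = function(e)
        stop("invalid gate type ", t$type_id, ": ", conditionMessage(e),
             call. = FALSE))
  })
  constraint_profile(obj$max_gates, obj$max_inputs, types,
                     unique_input = isTRUE(obj$unique_input),
                     fn_bound = obj$fn_bound %||% 0L,
                     fp_bound = obj$fp_bound %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.constraint_profile <- function(x, ...) {
  cat("Constraint profile: <=", x$max_gates, "gates, <=", x$max_inputs,
      "total inputs\n")
  for (t in x$gate_types)
    cat(sprintf("  Type %d: pos inputs [%d,%d], neg inputs [%d,%d], <= %d occurrences\n",
                t$type_id, t$lb_pos, t$ub_pos, t$lb_neg, t$ub_neg,
                t$max_occurrences))
  cat("  unique input:", x$unique_input,
      " error bounds: fn <=", x$fn_bound, ", fp <=", x$fp_bound, "\n")
  invisible(x)
}
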