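#' Construct a single gate (CNF clause)
#'
#' A gate is a disjunction (OR) of signed literals over miRNA markers.  In the
#' laboratory repertoire a gate is typically either an OR of non-negated
#' inputs or a single-input NOT construct; the data model itself allows any
#' mix of signs, and feasibility is checked separately against a
#' [constraint_profile()].
#'
#' @param markers character vector of miRNA identifiers (non-empty, unique
#'   within the gate).
#' @param negated logical vector of the same length; `TRUE` marks a negated
#'   literal.  Defaults to all non-negated.
#' @return An object of class `"gate"`.
#' @export
gate <- function(markers, negated = rep(FALSE, length(markers))) {
  markers <- as.character(markers)
  negated <- as.logical(negated)
  if (length(markers) == 0L)
    stop("a gate must contain at least one literal", call. = FALSE)
  if (length(negated) != length(markers))
    stop("'negated' must have one entry per marker", call. = FALSE)
  if (any(!nzchar(markers)) || anyNA(markers))
    stop("empty marker identifier in gate", call. = FALSE)
  if (anyNA(negated))
    stop("missing sign flag in gate", call. = FALSE)
  if (anyDuplicated(markers))
    stop("marker appears twice in one gate: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "),
         call. = FALSE)
  structure(list(markers = markers, negated = negated), class = "gate")
}

#' Construct a CNF classifier
#'
#' A classifier is a Boolean function f: \{0,1\}^n -> \{0,1\} in conjunctive
#' normal form: a conjunction (AND) of gates, each gate a disjunction (OR) of
#' possibly negated miRNA inputs.  A sample is classified positive exactly
#' when every gate contains at least one satisfied literal.
#'
#' @param gates a list of [gate()] objects (at least one), or several gates
#'   given as separate arguments.
#' @return An object of class `"classifier"`.
#' @examples
#' # (g1 | g3) & !g2
#' cl <- classifier(gate(c("g1", "g3")), gate("g2", TRUE))
#' format_classifier(cl)
#' @export
classifier <- function(...) {
  gates <- list(...)
  if (length(gates) == 1L && !inherits(gates[[1L]], "gate")) gates <- gates[[1L]]
  if (length(gates) == 0L)
    stop("a classifier must contain at least one gate", call. = FALSE)
  if (!all(vapply(gates, inherits, logical(1L), "gate")))
    stop("all elements must be gate objects", call. = FALSE)
  structure(list(gates = gates), class = "classifier")
}

#' @rdname classifier
#' @param x object to test or print.
#' @export
is_classifier <- function(x) inherits(x, "classifier")

#' Number of gates and total inputs of a classifier
#'
#' @param c a [classifier()].
#' @return `n_gates()`: the gate count; `n_inputs()`: the total number of
#'   literals summed over gates.
#' @export
n_gates <- function(c) length(c$gates)

#' @rdname n_gates
#' @export
n_inputs <- function(c) sum(vapply(c$gates, function(g) length(g$markers), integer(1L)))

#' All markers used by a classifier
#' @param c a [classifier()].
#' @return character vector of distinct miRNA identifiers, in order of first use.
#' @export
classifier_markers <- function(c) unique(unlist(lapply(c$gates, `[[`, "markers")))

#' Evaluate a classifier on one binary profile
#'
#' A literal is satisfied when the profile value is 1 and the literal is
#' non-negated, or 0 and negated.  The classifier outputs 1 iff every gate
#' contains at least one satisfied literal.
#'
#' @param c a [classifier()].
#' @param profile named 0/1 vector keyed by miRNA identifier; must cover every
#'   marker used by the classifier.
#' @return 0 or 1.
#' @export
evaluate <- function(c, profile) {
  stopifnot(is_classifier(c))
  need <- classifier_markers(c)
  missing <- setdiff(need, names(profile))
  if (length(missing))
    stop("profile lacks marker(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (g in c$gates) {
    v <- profile[g$markers]
    if (!any(ifelse(g$negated, v == 0, v == 1))) return(0L)
  }
  1L
}

#' Evaluate a classifier on every row of a binary matrix
#'
#' Vectorized form of [evaluate()]: classifies each row of a 0/1 matrix whose
#' named columns cover the classifier's markers.
#'
#' @param c a [classifier()].
#' @param mat 0/1 matrix with named columns.
#' @return Integer 0/1 vector with one entry per row.
#' @export
evaluate_rows <- function(c, mat) {
  out <- rep(TRUE, nrow(mat))
  for (g in c$gates) {
    sub <- mat[, g$markers, drop = FALSE]
    sat <- sweep(sub, 2L, ifelse(g$negated, 0L, 1L), `==`)
    out <- out & (rowSums(sat) > 0L)
  }
  as.integer(out)
}

#' Count classification errors on a binarized dataset
#'
#' False negatives are positive samples classified 0; false positives are
#' negative samples classified 1.  A classifier is perfect for the dataset iff
#' both counts are zero.
#'
#' @param c a [classifier()].
#' @param ds a [binarized_dataset()] whose miRNA columns cover the
#'   classifier's markers.
#' @return A list with integer fields `fn` and `fp`.
#' @export
count_errors <- function(c, ds) {
  stopifnot(is_classifier(c), inherits(ds, "binarized_dataset"))
  missing <- setdiff(classifier_markers(c), ds$mirna_ids)
  if (length(missing))
    stop("dataset lacks classifier marker(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  pred <- evaluate_rows(c, ds$x)
  list(fn = sum(ds$annots == 1L & pred == 0L),
       fp = sum(ds$annots == 0L & pred == 1L))
}

# -- canonical form ----------------------------------------------------------

# Sort key of one literal: marker token ascending, non-negated before negated.
literal_tokens <- function(g) paste0(ifelse(g$negated, "!", ""), g$markers)

sort_gate <- function(g) {
  o <- order(g$markers, g$negated, method = "radix")
  gate(g$markers[o], g$negated[o])
}

gate_key <- function(g) paste(literal_tokens(sort_gate(g)), collapse = "|")

#' Canonicalize a classifier
#'
#' Sorts the literals within each gate (marker token ascending, non-negated
#' before negated), then sorts the gates lexicographically by their sorted
#' literal sequences, reassigning gate identifiers in ascending order while
#' preserving each gate's literal content.  The Boolean function is unchanged
#' and the operation is idempotent.  Two classifiers that differ only in the
#' permutation of interchangeable gate identifiers map to the same canonical
#' form, which makes isomorphic solutions indistinguishable.
#'
#' @param c a [classifier()].
#' @return The canonical-form [classifier()].
#' @export
canonicalize <- function(c) {
  stopifnot(is_classifier(c))
  gates <- lapply(c$gates, sort_gate)
  keys <- vapply(gates, gate_key, character(1L))
  classifier(gates[order(keys, method = "radix")])
}

# Canonical text key identifying the isomorphism class of a classifier.
classifier_key <- function(c) {
  paste(sort(vapply(c$gates, gate_key, character(1L)), method = "radix"),
        collapse = " & ")
}

#' Reduce a solution list to isomorphism-class representatives
#'
#' Solutions that differ only in the order of gates (equivalently, in the
#' permutation of gate identifiers among interchangeable gates) belong to one
#' isomorphism class.  Each class is represented by its canonical form; the
#' output is ordered lexicographically by canonical text and therefore
#' deterministic.
#'
#' @param solutions a list of [classifier()] objects.
#' @return A list of canonical-form representatives, one per distinct class.
#' @export
reduce_to_isomorphism_classes <- function(solutions) {
  if (!length(solutions)) return(list())
  canon <- lapply(solutions, canonicalize)
  keys <- vapply(canon, classifier_key, character(1L))
  keep <- !duplicated(keys)
  canon[keep][order(keys[keep], method = "radix")]
}

#' Count isomorphic gate-identifier labelings
#'
#' A solver that assigns integer identifiers to gates reports any permutation
#' of identifiers among interchangeable gates as a separate solution.  Gates
#' are interchangeable when they can take the same set of gate types under the
#' profile; the number of distinct labeled representations of one classifier
#' is the product of the factorials of the interchangeable-group sizes
#' (duplicate gates are excluded from the data model, so all permutations give
#' distinct labelings).
#'
#' @param c a [classifier()].
#' @param profile a [constraint_profile()] used to type the gates; defaults to
#'   the core laboratory constraints ([core_profile()]).
#' @return Integer count of distinct labeled representations.
#' @examples
#' # one 2-input OR gate plus three single-input NOT gates -> 3! = 6 labelings
#' cl <- parse_classifier(
#'   "(miR-24-1 | miR-103-2) & !miR-144 & !miR-378 & !miR-10b")
#' count_isomorphic_labelings(cl)
#' @export
count_isomorphic_labelings <- function(c, profile = core_profile()) {
  stopifnot(is_classifier(c))
  sig <- vapply(c$gates, function(g) {
    feas <- vapply(profile$gate_types, function(t) {
      npos <- sum(!g$negated); nneg <- sum(g$negated)
      npos >= t$lb_pos && npos <= t$ub_pos && nneg >= t$lb_neg && nneg <= t$ub_neg
    }, logical(1L))
    paste(which(feas), collapse = ",")
  }, character(1L))
  prod(factorial(table(sig)))
}

#' @export
print.gate <- function(x, ...) {
  cat("Gate:", paste(literal_tokens(x), collapse = " | "), "\n")
  invisible(x)
}

#' @export
print.classifier <- function(x, ...) {
  cat("CNF classifier (", n_gates(x), " gates, ", n_inputs(x), " inputs):\n  ",
      format_classifier(x), "\n", sep = "")
  invisible(x)
}
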