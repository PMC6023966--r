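#' Parse a classifier from text
#'
#' The grammar is a conjunction of gates, each gate a (optionally
#' parenthesized) disjunction of optionally negated marker tokens.  Both the
#' Unicode operators (`∧`, `∨`, `¬`) and their ASCII spellings
#' (`&`, `|`, `!`) are accepted, as are the keywords `AND`, `OR`, `NOT`
#' (case-insensitive).  Marker tokens are arbitrary words without whitespace
#' or operator characters, so real miRNA names like `miR-320-RNASEN` work.
#'
#' @param text classifier text, e.g. `"(g1 | g3) & !g2"`.
#' @return A [classifier()].
#' @seealso [format_classifier()]
#' @export
parse_classifier <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- tokenize_classifier(text)
  pos <- 1L
  peek <- function() if (pos <= nrow(toks)) toks$type[pos] else "eof"
  take <- function(expected) {
    if (peek() != expected)
      stop("syntax error at position ", if (pos <= nrow(toks)) toks$at[pos] else nchar(text) + 1L,
           ": expected ", expected, ", found ",
           if (pos <= nrow(toks)) toks$text[pos] else "end of input", call. = FALSE)
    tok <- toks[pos, ]
    pos <<- pos + 1L
    tok
  }
  parse_literal <- function() {
    neg <- FALSE
    while (peek() == "not") { take("not"); neg <- !neg }
    tok <- take("word")
    list(marker = tok$text, negated = neg)
  }
  parse_gate <- function() {
    if (peek() == "lparen") {
      take("lparen")
      lits <- list(parse_literal())
      while (peek() == "or") { take("or"); lits[[length(lits) + 1L]] <- parse_literal() }
      take("rparen")
    } else {
      lits <- list(parse_literal())
      while (peek() == "or") { take("or"); lits[[length(lits) + 1L]] <- parse_literal() }
    }
    gate(vapply(lits, `[[`, character(1L), "marker"),
         vapply(lits, `[[`, logical(1L), "negated"))
  }
  gates <- list(parse_gate())
  while (peek() == "and") { take("and"); gates[[length(gates) + 1L]] <- parse_gate() }
  if (peek() != "eof")
    stop("syntax error at position ", toks$at[pos], ": unexpected ", toks$text[pos],
         call. = FALSE)
  classifier(gates)
}

tokenize_classifier <- function(text) {
  ops <- c("(" = "lparen", ")" = "rparen",
           "&" = "and", "∧" = "and",
           "|" = "or", "∨" = "or",
           "!" = "not", "¬" = "not")
  chars <- strsplit(text, "")[[1L]]
  out <- list(); i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% names(ops)) {
      out[[length(out) + 1L]] <- list(type = ops[[ch]], text = ch, at = i)
      i <- i + 1L
      next
    }
    j <- i
    while (j <= length(chars) && !grepl("^\\s$", chars[j]) &&
           !(chars[j] %in% names(ops))) j <- j + 1L
    word <- paste(chars[i:(j - 1L)], collapse = "")
    type <- switch(toupper(word), AND = "and", OR = "or", NOT = "not", "word")
    out[[length(out) + 1L]] <- list(type = type, text = word, at = i)
    i <- j
  }
  if (!length(out)) stop("syntax error: empty classifier text", call. = FALSE)
  data.frame(type = vapply(out, `[[`, character(1L), "type"),
             text = vapply(out, `[[`, character(1L), "text"),
             at = vapply(out, `[[`, integer(1L), "at"),
             stringsAsFactors = FALSE)
}

#' Format a classifier as text
#'
#' Emits the ASCII spelling: gates joined by `&`, literals within a gate by
#' `|`, negation as `!`, each gate parenthesized.  `parse_classifier()`
#' composed with `format_classifier()` is the identity up to canonical
#' ordering.
#'
#' @param c a [classifier()].
#' @return A single string.
#' @export
format_classifier <- function(c) {
  stopifnot(is_classifier(c))
  paste(vapply(c$gates, function(g)
    paste0("(", paste(literal_tokens(g), collapse = " | "), ")"),
    character(1L)), collapse = " & ")
}

#' Export a classifier as a DOT directed graph
#'
#' Writes the circuit as inputs -> gates -> output, suitable for rendering
#' with Graphviz.
#'
#' @param c a [classifier()].
#' @param path optional file path; when `NULL` the DOT text is returned.
#' @return The DOT source as a character vector (invisibly when written to a
#'   file).
#' @export
classifier_to_dot <- function(c, path = NULL) {
  stopifnot(is_classifier(c))
  lines <- c("digraph classifier {", "  rankdir=LR;",
             "  output [shape=doublecircle];")
  for (m in classifier_markers(c))
    lines <- c(lines, sprintf("  \"%s\" [shape=ellipse];", m))
  for (i in seq_along(c$gates)) {
    g <- c$gates[[i]]
    label <- if (all(g$negated) && length(g$markers) == 1L) "NOT" else "OR"
    gid <- sprintf("gate%d", i)
    lines <- c(lines, sprintf("  %s [shape=box,label=\"%s\"];", gid, label))
    for (k in seq_along(g$markers)) {
      style <- if (g$negated[k]) " [arrowhead=tee]" else ""
      lines <- c(lines, sprintf("  \"%s\" -> %s%s;", g$markers[k], gid, style))
    }
    lines <- c(lines, sprintf("  %s -> output;", gid))
  }
  lines <- c(lines, "}")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
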