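#' Parse a Boolean network from "targets, factors" text
#'
#' Reads the plain-text logical-model format used throughout the logical
#' modelling community: a header line `targets, factors`, then one line per
#' gene of the form `<gene>, <expression>`. Expressions are built from gene
#' names, `!` (not), `&` (and), `|` (or), parentheses and the literals `0`/`1`,
#' with precedence `!` > `&` > `|`. Lines starting with `#` are comments.
#'
#' Each expression is compiled to a truth table by evaluating it over every
#' assignment of its inputs; the input order is the order of first appearance
#' in the expression (first input = most significant bit of the table index).
#' Gene-name matching is case-sensitive.
#'
#' @param text A single multi-line string, or a character vector of lines.
#' @param name Optional model name attached to the result.
#' @return A [boolean_network()].
#' @examples
#' parse_boolnet("targets, factors\nA, B & !C\nB, A\nC, !A | B")
#' @seealso [read_boolnet()], [write_boolnet()]
#' @export
parse_boolnet <- function(text, name = "") {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop("empty network file")
  header <- trimws(lines[idx[1]])
  if (!grepl("^targets\\s*,\\s*factors$", header, ignore.case = TRUE)) {
    stop("line ", idx[1], ": expected header \"targets, factors\", got \"",
         header, "\"")
  }
  body <- idx[-1]
  if (length(body) == 0) stop("no gene lines after header")

  targets <- character(0)
  exprs <- list()
  for (ln in body) {
    line <- lines[ln]
    comma <- regexpr(",", line, fixed = TRUE)
    if (comma < 0) stop("line ", ln, ": expected \"<gene>, <expression>\"")
    target <- trimws(substr(line, 1, comma - 1))
    rhs <- substr(line, comma + 1, nchar(line))
    if (!grepl("^[A-Za-z0-9_.]+$", target)) {
      stop("line ", ln, ": invalid gene name \"", target, "\"")
    }
    if (target %in% targets) stop("line ", ln, ": duplicate target \"", target, "\"")
    targets <- c(targets, target)
    exprs[[target]] <- list(rhs = rhs, line = ln)
  }

  fns <- lapply(targets, function(g) {
    e <- exprs[[g]]
    ast <- parse_bool_expression(e$rhs, line = e$line)
    unknown <- setdiff(ast$inputs, targets)
    if (length(unknown) > 0) {
      stop("line ", e$line, ": unknown gene(s) referenced in function for ", g,
           ": ", paste(unknown, collapse = ", "))
    }
    compile_truth_table(ast)
  })
  names(fns) <- targets
  boolean_network(fns, name = name)
}

#' Read a Boolean network from a file
#'
#' @param path Path to a "targets, factors" file.
#' @return A [boolean_network()] named after the file.
#' @export
read_boolnet <- function(path) {
  parse_boolnet(readLines(path, warn = FALSE),
                name = sub("\\.[^.]*$", "", basename(path)))
}

#' Read a directory of Boolean network files as a collection
#'
#' @param dir Directory containing model files.
#' @param pattern Filename pattern (default: `.bn`, `.txt` or `.boolnet`).
#' @return Named list of [boolean_network()] objects, sorted by filename.
#' @export
read_boolnet_collection <- function(dir, pattern = "\\.(bn|txt|boolnet)$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0) stop("no model files matching `pattern` in ", dir)
  nets <- lapply(files, read_boolnet)
  names(nets) <- vapply(nets, function(x) x$name, character(1))
  nets
}

#' Serialize a Boolean network to "targets, factors" text
#'
#' Functions are printed as full disjunctive normal form over their listed
#' inputs (tautologies/contradictions over the same inputs for all-one /
#' all-zero tables), so re-parsing the output reproduces the truth tables
#' exactly, including input order.
#'
#' @param net A [boolean_network()].
#' @param path Optional file path; when given, the text is written there.
#' @return The serialized text, invisibly when `path` is given.
#' @export
write_boolnet <- function(net, path = NULL) {
  lines <- c("targets, factors",
             vapply(net$genes, function(g) {
               paste0(g, ", ", function_to_expression(net$functions[[g]]))
             }, character(1)))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(text))
  }
  text
}

#' Render a Boolean function as an expression string
#'
#' @param f A [bn_function()].
#' @return A string in the `!`/`&`/`|` grammar whose truth table equals `f`'s.
#' @keywords internal
function_to_expression <- function(f) {
  k <- length(f$inputs)
  if (k == 0) return(as.character(f$table[1L]))
  if (all(f$table == 0L)) {
    # contradiction mentioning every input, preserving input order
    return(paste(sprintf("(%s & !%s)", f$inputs, f$inputs), collapse = " & "))
  }
  if (all(f$table == 1L)) {
    return(paste(sprintf("(%s | !%s)", f$inputs, f$inputs), collapse = " & "))
  }
  rows <- which(f$table == 1L) - 1L
  minterms <- vapply(rows, function(r) {
    bits <- bit_at(r, (k - 1L):0L)
    lits <- ifelse(bits == 1L, f$inputs, paste0("!", f$inputs))
    paste(lits, collapse = " & ")
  }, character(1))
  if (length(minterms) == 1) minterms else
    paste(sprintf("(%s)", minterms), collapse = " | ")
}

bit_at <- function(x, pos) bitwAnd(bitwShiftR(as.integer(x), pos), 1L)

# --- expression grammar -----------------------------------------------------
# expr   := term ('|' term)*
# term   := factor ('&' factor)*
# factor := '!' factor | '(' expr ')' | identifier | '0' | '1'

tokenize_bool <- function(text, line) {
  tokens <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    ws <- regmatches(rest, regexpr("^\\s+", rest))
    if (length(ws) == 1) { pos <- pos + nchar(ws); next }
    ch <- substr(text, pos, pos)
    if (ch %in% c("!", "&", "|", "(", ")")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch, value = ch, pos = pos)
      pos <- pos + 1L
      next
    }
    m <- regmatches(rest, regexpr("^[A-Za-z0-9_.]+", rest))
    if (length(m) == 1) {
      type <- if (m %in% c("0", "1")) "literal" else "ident"
      tokens[[length(tokens) + 1L]] <- list(type = type, value = m, pos = pos)
      pos <- pos + nchar(m)
      next
    }
    stop("line ", line, ", position ", pos,
         ": unexpected character \"", ch, "\" in expression")
  }
  tokens
}

parse_bool_expression <- function(text, line = NA) {
  tokens <- tokenize_bool(text, line)
  if (length(tokens) == 0) stop("line ", line, ": empty expression")
  state <- new.env(parent = emptyenv())
  state$i <- 1L
  state$inputs <- character(0)

  peek <- function() if (state$i <= length(tokens)) tokens[[state$i]] else NULL
  advance <- function() { tok <- tokens[[state$i]]; state$i <- state$i + 1L; tok }
  fail <- function(tok, what) {
    at <- if (is.null(tok)) "end of expression" else
      paste0("position ", tok$pos, " (\"", tok$value, "\")")
    stop("line ", line, ": ", what, " at ", at)
  }

  parse_expr <- function() {
    node <- parse_term()
    while (!is.null(peek()) && peek()$type == "|") {
      advance()
      node <- list(op = "or", lhs = node, rhs = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (!is.null(peek()) && peek()$type == "&") {
      advance()
      node <- list(op = "and", lhs = node, rhs = parse_factor())
    }
    node
  }
  parse_factor <- function() {
    tok <- peek()
    if (is.null(tok)) fail(tok, "expected operand")
    if (tok$type == "!") {
      advance()
      return(list(op = "not", lhs = parse_factor()))
    }
    if (tok$type == "(") {
      advance()
      node <- parse_expr()
      close <- peek()
      if (is.null(close) || close$type != ")") fail(close, "expected \")\"")
      advance()
      return(node)
    }
    if (tok$type == "literal") {
      advance()
      return(list(op = "const", value = as.integer(tok$value)))
    }
    if (tok$type == "ident") {
      advance()
      if (!tok$value %in% state$inputs) state$inputs <- c(state$inputs, tok$value)
      return(list(op = "var", name = tok$value))
    }
    fail(tok, "unexpected token")
  }

  ast <- parse_expr()
  leftover <- peek()
  if (!is.null(leftover)) fail(leftover, "unexpected trailing token")
  list(ast = ast, inputs = state$inputs)
}

eval_ast <- function(node, env) {
  switch(node$op,
    const = node$value,
    var = env[[node$name]],
    not = 1L - eval_ast(node$lhs, env),
    and = eval_ast(node$lhs, env) * eval_ast(node$rhs, env),
    or = {
      a <- eval_ast(node$lhs, env)
      b <- eval_ast(node$rhs, env)
      as.integer(a + b > 0L)
    }
  )
}

compile_truth_table <- function(parsed) {
  inputs <- parsed$inputs
  k <- length(inputs)
  table <- integer(2^k)
  for (row in 0:(2^k - 1)) {
    env <- as.list(bit_at(row, (k - 1L):0L))
    names(env) <- inputs
    table[row + 1L] <- eval_ast(parsed$ast, env)
  }
  bn_function(inputs, table)
}

#' Export a network's interaction structure as an edge list
#'
#' @param net A [boolean_network()].
#' @param mode `"essential"` (default) or `"syntactic"`, see
#'   [build_interaction_graph()].
#' @return A tibble with columns `source` and `target`, one row per edge.
#' @export
as_edge_list <- function(net, mode = c("essential", "syntactic")) {
  mode <- match.arg(mode)
  rows <- purrr::map(net$genes, function(g) {
    ins <- if (mode == "essential") essential_inputs(net$functions[[g]])
           else net$functions[[g]]$inputs
    if (length(ins) == 0) return(NULL)
    tibble::tibble(source = ins, target = g)
  })
  dplyr::bind_rows(rows)
}
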