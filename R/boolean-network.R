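# Bit helpers work on plain doubles so state integers are exact up to 2^50;
# gene i occupies bit i-1 of a packed state.
state_bit <- function(state, i) (state %/% 2^(i - 1)) %% 2

pack_bits <- function(bits) sum(bits * 2^(seq_along(bits) - 1))

unpack_bits <- function(state, n) vapply(seq_len(n),
                                         function(i) state_bit(state, i), numeric(1))

# Truth-table row index for parent bit values; first parent is the most
# significant bit, so rows enumerate parents in listed order: 00, 01, 10, 11.
table_row <- function(parent_bits) {
  k <- length(parent_bits)
  if (k == 0) return(0)
  sum(parent_bits * 2^(k - seq_len(k)))
}

#' Construct a Boolean network
#'
#' A Boolean network assigns each gene a binary state updated by a logical
#' function of its parent genes. Rules are stored as explicit truth tables:
#' for a gene with parents `(p1, ..., pk)` the table has `2^k` output bits,
#' rows ordered by binary counting over the parents with the first parent as
#' the most significant bit (row order `00, 01, 10, 11` for two parents).
#' Clamped genes are held at a fixed value during dynamics and their rules
#' are ignored.
#'
#' @param genes Character vector of gene identifiers (order defines the bit
#'   layout of packed states: gene `i` occupies bit `i - 1`).
#' @param parents Named list mapping each gene to a character vector of its
#'   parents (possibly empty).
#' @param tables Named list mapping each gene to an integer 0/1 vector of
#'   length `2^length(parents[[gene]])`.
#' @param clamped Named integer vector (values 0/1) of genes held constant.
#' @return An object of class `boolean_network`.
#' @seealso [generate_network()], [read_rules()], [successor()]
#' @export
boolean_network <- function(genes, parents, tables, clamped = integer(0)) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  if (!setequal(names(parents), genes) || !setequal(names(tables), genes))
    stop("parents and tables must be named by the network's genes")
  parents <- parents[genes]
  tables <- tables[genes]
  for (g in genes) {
    p <- parents[[g]]
    if (!all(p %in% genes)) stop("unknown parent gene for ", g)
    if (anyDuplicated(p)) stop("duplicate parents for ", g)
    tab <- tables[[g]]
    if (length(tab) != 2^length(p) || !all(tab %in% c(0, 1)))
      stop("truth table for ", g, " must be 0/1 of length 2^|parents|")
    tables[[g]] <- as.integer(tab)
    parents[[g]] <- as.character(p)
  }
  if (length(clamped)) {
    if (is.null(names(clamped)) || !all(names(clamped) %in% genes))
      stop("clamped genes must belong to the network")
    if (!all(clamped %in% c(0, 1))) stop("clamped values must be 0 or 1")
    clamped <- vapply(clamped, as.integer, integer(1))
  } else {
    clamped <- stats::setNames(integer(0), character(0))
  }
  structure(list(genes = genes, parents = parents, tables = tables,
                 clamped = clamped),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("boolean_network: %d genes, %d edges, %d clamped\n",
              length(x$genes), sum(lengths(x$parents)), length(x$clamped)))
  invisible(x)
}

n_genes <- function(net) length(net$genes)

# ---- rule expressions ------------------------------------------------------

# Tokens: gene names, !, &, |, parentheses, constants 0/1.
tokenize_rule <- function(expr) {
  pat <- "[A-Za-z_.][A-Za-z0-9_.-]*|[01]|[!&|()]|\\s+"
  out <- character(0)
  rest <- expr
  while (nchar(rest) > 0) {
    m <- regmatches(rest, regexpr(paste0("^(", pat, ")"), rest))
    if (length(m) == 0 || nchar(m) == 0)
      stop("unexpected character at: ", substr(rest, 1, 10))
    if (!grepl("^\\s+$", m)) out <- c(out, m)
    rest <- substr(rest, nchar(m) + 1, nchar(rest))
  }
  out
}

# Recursive-descent parse into nested lists:
#   list(op = "or"/"and", args = ...), list(op = "not", arg = ...),
#   list(op = "var", name = ...), list(op = "const", value = 0/1)
parse_rule_expr <- function(tokens) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L }
  parse_or <- function() {
    args <- list(parse_and())
    while (identical(peek(), "|")) { advance(); args <- c(args, list(parse_and())) }
    if (length(args) == 1) args[[1]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (identical(peek(), "&")) { advance(); args <- c(args, list(parse_atom())) }
    if (length(args) == 1) args[[1]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    tk <- peek()
    if (is.na(tk)) stop("unexpected end of expression")
    if (tk == "!") { advance(); return(list(op = "not", arg = parse_atom())) }
    if (tk == "(") {
      advance()
      node <- parse_or()
      if (!identical(peek(), ")")) stop("missing closing parenthesis")
      advance()
      return(node)
    }
    if (tk %in% c("0", "1")) { advance(); return(list(op = "const", value = as.integer(tk))) }
    if (grepl("^[A-Za-z_.]", tk)) { advance(); return(list(op = "var", name = tk)) }
    stop("unexpected token '", tk, "'")
  }
  node <- parse_or()
  if (pos <= length(tokens)) stop("trailing tokens from '", tokens[pos], "'")
  node
}

eval_rule_ast <- function(node, env) {
  switch(node$op,
         const = node$value,
         var = env[[node$name]],
         not = 1L - eval_rule_ast(node$arg, env),
         and = { for (a in node$args) if (eval_rule_ast(a, env) == 0) return(0L); 1L },
         or = { for (a in node$args) if (eval_rule_ast(a, env) == 1) return(1L); 0L })
}

ast_vars <- function(node) {
  switch(node$op,
         const = character(0),
         var = node$name,
         not = ast_vars(node$arg),
         unique(unlist(lapply(node$args, ast_vars))))
}

# Compile a rule expression into (parents, truth table); parents appear in
# first-occurrence order and the table enumerates them first-parent-MSB.
compile_rule <- function(expr_text) {
  ast <- parse_rule_expr(tokenize_rule(expr_text))
  parents <- ast_vars(ast)
  k <- length(parents)
  tab <- integer(2^k)
  for (row in 0:(2^k - 1)) {
    bits <- if (k) as.integer(intToBits(row))[k:1] else integer(0)
    env <- stats::setNames(as.list(bits), parents)
    tab[row + 1] <- eval_rule_ast(ast, env)
  }
  list(parents = parents, table = tab)
}

# Render a truth table as an expression (disjunctive normal form over the
# rows with output 1); constants render as "0"/"1".
rule_to_expr <- function(parents, table) {
  k <- length(parents)
  if (k == 0 || all(table == table[1])) return(as.character(table[1]))
  minterms <- character(0)
  for (row in which(table == 1) - 1) {
    bits <- as.integer(intToBits(row))[k:1]
    lits <- ifelse(bits == 1, parents, paste0("!", parents))
    term <- paste(lits, collapse = " & ")
    if (k > 1) term <- paste0("(", term, ")")
    minterms <- c(minterms, term)
  }
  paste(minterms, collapse = " | ")
}

# ---- rule file I/O ---------------------------------------------------------

#' Read and write Boolean rule files
#'
#' The text format follows the convention of Boolean-network tools: a header
#' line `targets, factors`, then one line per gene of the form
#' `gene, expression`, where the expression combines parent genes with `!`,
#' `&`, `|` and parentheses, and `0`/`1` denote constants. Clamped genes and
#' constant rules are written as `0`/`1`. Parents are taken in order of
#' first appearance in the expression.
#'
#' @param path File path.
#' @param net A [boolean_network()].
#' @return `read_rules` returns a [boolean_network()]; `write_rules` returns
#'   `path` invisibly.
#' @examples
#' net <- generate_network(5, 1.5, 2, seed = 1)
#' f <- tempfile(fileext = ".txt")
#' write_rules(net, f)
#' identical(read_rules(f)$tables, net$tables)
#' @export
read_rules <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0 || !grepl("^\\s*targets\\s*,\\s*factors\\s*$", lines[1]))
    stop("rule file must start with a 'targets, factors' header")
  body <- lines[-1]
  genes <- character(0); exprs <- character(0)
  for (i in seq_along(body)) {
    sp <- regexpr(",", body[i], fixed = TRUE)
    if (sp < 0) stop("line ", i + 1, ": expected 'gene, expression'")
    genes <- c(genes, trimws(substr(body[i], 1, sp - 1)))
    exprs <- c(exprs, trimws(substr(body[i], sp + 1, nchar(body[i]))))
  }
  if (anyDuplicated(genes)) stop("duplicate target gene in rule file")
  parents <- list(); tables <- list()
  for (i in seq_along(genes)) {
    comp <- tryCatch(compile_rule(exprs[i]),
                     error = function(e) stop("line ", i + 1, ": ",
                                              conditionMessage(e), call. = FALSE))
    unknown <- setdiff(comp$parents, genes)
    if (length(unknown))
      stop("line ", i + 1, ": undefined gene '", unknown[1], "'")
    parents[[genes[i]]] <- comp$parents
    tables[[genes[i]]] <- comp$table
  }
  boolean_network(genes, parents, tables)
}

#' @rdname read_rules
#' @export
write_rules <- function(net, path) {
  stopifnot(inherits(net, "boolean_network"))
  lines <- "targets, factors"
  for (g in net$genes) {
    expr <- if (g %in% names(net$clamped)) {
      as.character(net$clamped[[g]])
    } else {
      rule_to_expr(net$parents[[g]], net$tables[[g]])
    }
    lines <- c(lines, paste0(g, ", ", expr))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Lossless JSON serialization of a Boolean network
#'
#' Unlike the rule-text format, the JSON form preserves parent order, clamp
#' assignments and redundant parents of constant tables exactly.
#'
#' @param net A [boolean_network()].
#' @param path JSON file path.
#' @return `network_from_json` returns a [boolean_network()].
#' @export
network_to_json <- function(net, path) {
  stopifnot(inherits(net, "boolean_network"))
  obj <- list(genes = net$genes,
              parents = net$parents,
              tables = net$tables,
              clamped = as.list(net$clamped))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname network_to_json
#' @export
network_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  parents <- lapply(obj$parents, as.character)
  if (length(parents) == 0) parents <- stats::setNames(list(), character(0))
  clamped <- stats::setNames(unlist(obj$clamped), names(obj$clamped))
  if (is.null(clamped)) clamped <- integer(0)
  boolean_network(obj$genes, parents, lapply(obj$tables, as.integer), clamped)
}
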