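# Boolean rule expressions
#
# Grammar (precedence low -> high):
#   expr   := term  (('|' | OR)  term)*
#   term   := factor (('&' | AND) factor)*
#   factor := ('!' | NOT) factor | '(' expr ')' | NAME | '0' | '1'
# NAME matches [A-Za-z0-9_]+ but may not be purely numeric; the keywords
# NOT/AND/OR (any case) are operators, never names. Rules are stored as R call
# trees built by this parser (never by R's own parser, so arbitrary code can
# not ride in through a rule file) and evaluated against environments that
# bind each node name to a logical scalar or vector.

.RULE_TOKEN_RX <- "[A-Za-z0-9_]+|!|&|\\||\\(|\\)|\\S"

tokenize_rule <- function(text) {
  m <- gregexpr(.RULE_TOKEN_RX, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(value = character(0), type = character(0),
                      pos = integer(0), stringsAsFactors = FALSE))
  }
  starts <- as.integer(m)
  vals <- substring(text, starts, starts + attr(m, "match.length") - 1L)
  type <- character(length(vals))
  for (i in seq_along(vals)) {
    v <- vals[i]
    type[i] <- if (v %in% c("!", "&", "|", "(", ")")) {
      v
    } else if (toupper(v) == "NOT") {
      "!"
    } else if (toupper(v) == "AND") {
      "&"
    } else if (toupper(v) == "OR") {
      "|"
    } else if (v %in% c("0", "1")) {
      "const"
    } else if (grepl("^[0-9]+$", v)) {
      stop(sprintf("invalid numeric literal '%s' at position %d (only 0/1 allowed)",
                   v, starts[i]), call. = FALSE)
    } else if (grepl("^[A-Za-z0-9_]+$", v)) {
      "name"
    } else {
      stop(sprintf("unexpected character '%s' at position %d", v, starts[i]),
           call. = FALSE)
    }
  }
  data.frame(value = vals, type = type, pos = starts, stringsAsFactors = FALSE)
}

# Parse one rule expression into an R call tree (using !, &, | and TRUE/FALSE).
# Returns list(ast=, refs=character vector of node names referenced).
parse_rule <- function(text) {
  toks <- tokenize_rule(text)
  if (nrow(toks) == 0L) stop("empty rule expression", call. = FALSE)
  i <- 1L
  refs <- character(0)
  peek <- function() if (i <= nrow(toks)) toks$type[i] else "eof"
  take <- function() {
    t <- toks[i, ]
    i <<- i + 1L
    t
  }
  expect <- function(type) {
    if (peek() != type) {
      got <- if (i <= nrow(toks)) {
        sprintf("'%s' at position %d", toks$value[i], toks$pos[i])
      } else "end of input"
      stop(sprintf("expected '%s' but found %s in rule '%s'", type, got, text),
           call. = FALSE)
    }
    take()
  }
  p_factor <- function() {
    t <- peek()
    if (t == "!") {
      take()
      call("!", p_factor())
    } else if (t == "(") {
      take()
      e <- p_expr()
      expect(")")
      e
    } else if (t == "const") {
      take()$value == "1"
    } else if (t == "name") {
      v <- take()$value
      refs <<- c(refs, v)
      as.name(v)
    } else {
      got <- if (i <= nrow(toks)) {
        sprintf("'%s' at position %d", toks$value[i], toks$pos[i])
      } else "end of input"
      stop(sprintf("unexpected %s in rule '%s'", got, text), call. = FALSE)
    }
  }
  p_term <- function() {
    e <- p_factor()
    while (peek() == "&") {
      take()
      e <- call("&", e, p_factor())
    }
    e
  }
  p_expr <- function() {
    e <- p_term()
    while (peek() == "|") {
      take()
      e <- call("|", e, p_term())
    }
    e
  }
  ast <- p_expr()
  if (peek() != "eof") {
    stop(sprintf("trailing input '%s' at position %d in rule '%s'",
                 toks$value[i], toks$pos[i], text), call. = FALSE)
  }
  list(ast = ast, refs = unique(refs))
}

# Canonical text form: operators !, &, |; parentheses only where precedence
# requires them. parse_rule(deparse_rule(ast)) reproduces ast exactly.
deparse_rule <- function(ast) {
  prec <- function(e) {
    if (!is.call(e)) return(4L)
    switch(as.character(e[[1L]]), "!" = 3L, "&" = 2L, "|" = 1L, 4L)
  }
  wrap <- function(e, need) {
    s <- render(e)
    if (prec(e) < need) paste0("(", s, ")") else s
  }
  render <- function(e) {
    if (is.name(e)) return(as.character(e))
    if (is.logical(e)) return(if (e) "1" else "0")
    op <- as.character(e[[1L]])
    switch(op,
      "!" = paste0("!", wrap(e[[2L]], 3L)),
      "&" = paste(wrap(e[[2L]], 2L), "&", wrap(e[[3L]], 2L)),
      "|" = paste(wrap(e[[2L]], 1L), "|", wrap(e[[3L]], 1L)),
      stop("unexpected operator in rule AST: ", op)
    )
  }
  render(ast)
}

# A rule is either an expression over node names or an explicit truth table
# over k regulators (outputs indexed with regulator 1 as least significant
# bit, i.e. outputs[1 + sum(bits * 2^(i-1))]).
new_rule_expr <- function(text) {
  p <- parse_rule(text)
  structure(list(kind = "expr", ast = p$ast, refs = p$refs,
                 text = deparse_rule(p$ast)),
            class = "bool_rule")
}

new_rule_table <- function(regulators, outputs) {
  regulators <- as.character(regulators)
  outputs <- as.integer(outputs)
  if (anyDuplicated(regulators)) stop("duplicate regulators in truth table")
  if (length(outputs) != 2^length(regulators)) {
    stop(sprintf("truth table over %d regulators needs %d outputs, got %d",
                 length(regulators), 2^length(regulators), length(outputs)))
  }
  if (!all(outputs %in% c(0L, 1L))) stop("truth-table outputs must be 0/1")
  structure(list(kind = "table", regulators = regulators, outputs = outputs,
                 refs = regulators),
            class = "bool_rule")
}

# Canonical text for any rule; truth tables are lowered to minterm DNF.
rule_text <- function(rule) {
  if (rule$kind == "expr") return(rule$text)
  k <- length(rule$regulators)
  ones <- which(rule$outputs == 1L) - 1L
  if (length(ones) == 0L) return("0")
  if (length(ones) == 2^k) return("1")
  minterm <- function(code) {
    lits <- vapply(seq_len(k), function(i) {
      on <- bitwAnd(bitwShiftR(code, i - 1L), 1L) == 1L
      if (on) rule$regulators[i] else paste0("!", rule$regulators[i])
    }, character(1))
    paste(lits, collapse = " & ")
  }
  # re-parse so the text is in the same canonical form deparse_rule emits
  # (parentheses only where precedence requires them)
  dnf <- paste(vapply(ones, minterm, character(1)), collapse = " | ")
  deparse_rule(parse_rule(dnf)$ast)
}

# Evaluate a rule in an environment binding node names to logical vectors of
# common length m (or scalars). Returns a logical vector of length m.
eval_rule <- function(rule, env, m) {
  if (rule$kind == "expr") {
    res <- eval(rule$ast, env, baseenv())
    return(rep_len(as.logical(res), m))
  }
  idx <- rep_len(1L, m)
  for (i in seq_along(rule$regulators)) {
    b <- as.integer(rep_len(get(rule$regulators[i], envir = env), m))
    idx <- idx + b * 2L^(i - 1L)
  }
  rule$outputs[idx] == 1L
}

#' @export
print.bool_rule <- function(x, ...) {
  if (x$kind == "expr") {
    cat("<rule> ", x$text, "\n", sep = "")
  } else {
    cat("<rule> truth table over {", paste(x$regulators, collapse = ", "),
        "}: ", paste(x$outputs, collapse = ""), "\n", sep = "")
  }
  invisible(x)
}
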