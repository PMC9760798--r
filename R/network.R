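#' Construct a Boolean network
#'
#' A Boolean network is an ordered set of named nodes, each carrying one
#' Boolean update rule over the node names. Node order is significant: it
#' defines bit positions for the integer state encoding (node 1 is the least
#' significant bit) and is preserved by all serializers.
#'
#' Nodes without a rule model environmental inputs (cytokines of the tumor
#' microenvironment): by default they receive the identity rule, so whatever
#' value they start with is held along the trajectory. In the JSON dialect an
#' input node may instead be pinned to constant 0 or 1.
#'
#' @param nodes character vector of unique node names matching
#'   `[A-Za-z0-9_]+` (Greek letters / hyphens of the literature are expected
#'   to be normalized upstream, e.g. `NF-kB -> NFKB`).
#' @param rules named list (or named character vector) of rules, one per node.
#'   Each rule is either an expression string over node names (operators
#'   `!`/`NOT`, `&`/`AND`, `|`/`OR`, parentheses, constants `0`/`1`) or a
#'   `bool_rule` object. Nodes absent from `rules` get the policy in `inputs`.
#' @param inputs optional named character vector for rule-less nodes:
#'   `"hold"` (identity, default), `"0"` or `"1"` (constant).
#' @param metadata free-form provenance string.
#' @return an object of class `boolean_network` with elements `nodes`,
#'   `rules` (named list of `bool_rule`), `metadata`.
#' @examples
#' net <- boolean_network(c("X", "Y"), list(X = "!Y", Y = "!X"))
#' synchronous_step(net, c(0, 0))
#' @export
boolean_network <- function(nodes, rules = list(), inputs = NULL,
                            metadata = "") {
  nodes <- as.character(nodes)
  if (length(nodes) == 0L) stop("a network needs at least one node")
  bad <- nodes[!grepl("^[A-Za-z0-9_]+$", nodes) | grepl("^[0-9]+$", nodes)]
  if (length(bad)) {
    stop("invalid node name(s): ", paste(bad, collapse = ", "),
         " (must match [A-Za-z0-9_]+ and not be purely numeric)")
  }
  if (anyDuplicated(nodes)) {
    stop("duplicate node name(s): ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  if (is.character(rules)) rules <- as.list(rules)
  if (length(rules) && is.null(names(rules))) stop("rules must be named")
  unknown <- setdiff(names(rules), nodes)
  if (length(unknown)) {
    stop("rule(s) for undeclared node(s): ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(names(rules))) {
    stop("duplicate rule for node(s): ",
         paste(unique(names(rules)[duplicated(names(rules))]), collapse = ", "))
  }
  full <- vector("list", length(nodes))
  names(full) <- nodes
  for (nm in nodes) {
    r <- rules[[nm]]
    if (is.null(r)) {
      policy <- if (!is.null(inputs) && nm %in% names(inputs)) {
        as.character(inputs[[nm]])
      } else "hold"
      full[[nm]] <- switch(policy,
        hold = new_rule_expr(nm),
        "0"  = new_rule_expr("0"),
        "1"  = new_rule_expr("1"),
        stop(sprintf("unknown input policy '%s' for node %s", policy, nm))
      )
    } else if (inherits(r, "bool_rule")) {
      full[[nm]] <- r
    } else {
      full[[nm]] <- new_rule_expr(as.character(r))
    }
  }
  refs <- unique(unlist(lapply(full, `[[`, "refs")))
  miss <- setdiff(refs, nodes)
  if (length(miss)) {
    stop("rule(s) reference undeclared node(s): ", paste(miss, collapse = ", "))
  }
  net <- structure(list(nodes = nodes, rules = full,
                        metadata = as.character(metadata)),
                   class = "boolean_network")
  attr(net, "input_nodes") <- setdiff(nodes, names(rules))
  attr(net, "input_policy") <- inputs
  net
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Boolean network: %d nodes\n", length(x$nodes)))
  if (nzchar(x$metadata)) cat("  ", x$metadata, "\n", sep = "")
  for (nm in x$nodes) cat(sprintf("  %s <- %s\n", nm, rule_text(x$rules[[nm]])))
  invisible(x)
}

validate_state <- function(net, state) {
  n <- length(net$nodes)
  state <- as.integer(state)
  if (length(state) != n) {
    stop(sprintf("state has %d entries but network has %d nodes",
                 length(state), n))
  }
  if (!all(state %in% c(0L, 1L))) stop("state values must be 0/1")
  state
}

# ---- parsing / serialization -------------------------------------------

#' Parse a Boolean network rule file
#'
#' Two dialects are supported. `"bnet"` is BoolNet-style text: a
#' `targets, factors` header, one `node, expression` line per node, `#`
#' comments and blank lines ignored. `"json"` is an object with fields
#' `nodes` (ordered array), `rules` (object mapping node to an expression
#' string or to a truth table `{"regulators": [...], "outputs": [...]}`),
#' optional `inputs` (object mapping rule-less nodes to `"hold"`, `"0"` or
#' `"1"`) and optional `metadata`.
#'
#' @param text file content as a single string or character vector of lines.
#' @param dialect `"bnet"` or `"json"`.
#' @return a [boolean_network()].
#' @seealso [format_network()], [read_network()]
#' @export
parse_network <- function(text, dialect = c("bnet", "json")) {
  dialect <- match.arg(dialect)
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  if (!nzchar(trimws(text))) stop("empty network text")
  if (dialect == "bnet") parse_network_bnet(text) else parse_network_json(text)
}

parse_network_bnet <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  meta <- character(0)
  nodes <- character(0)
  rules <- list()
  rule_line <- integer(0)
  header_seen <- FALSE
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (startsWith(line, "#")) {
      meta <- c(meta, sub("^#\\s?", "", line))
      next
    }
    if (!header_seen) {
      if (!grepl("^targets\\s*,\\s*factors$", line, ignore.case = TRUE)) {
        stop(sprintf("line %d: expected 'targets, factors' header, got '%s'",
                     i, line))
      }
      header_seen <- TRUE
      next
    }
    cm <- regexpr(",", line, fixed = TRUE)
    if (cm == -1L) stop(sprintf("line %d: expected 'node, expression'", i))
    target <- trimws(substr(line, 1L, cm - 1L))
    expr <- trimws(substr(line, cm + 1L, nchar(line)))
    if (target %in% names(rules)) {
      stop(sprintf("line %d: duplicate rule for node %s", i, target))
    }
    rules[[target]] <- tryCatch(new_rule_expr(expr), error = function(e) {
      stop(sprintf("line %d: %s", i, conditionMessage(e)), call. = FALSE)
    })
    nodes <- c(nodes, target)
    rule_line[target] <- i
  }
  if (!header_seen) stop("missing 'targets, factors' header")
  if (length(nodes) == 0L) stop("no rules found")
  for (nm in nodes) {
    miss <- setdiff(rules[[nm]]$refs, nodes)
    if (length(miss)) {
      stop(sprintf("line %d: rule for %s references undeclared node %s",
                   rule_line[nm], nm, miss[1L]))
    }
  }
  boolean_network(nodes, rules,
                  metadata = paste(meta, collapse = " "))
}

parse_network_json <- function(text) {
  obj <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  if (is.null(obj$nodes)) stop("JSON network needs a 'nodes' array")
  nodes <- vapply(obj$nodes, as.character, character(1))
  rules <- list()
  for (nm in names(obj$rules)) {
    r <- obj$rules[[nm]]
    rules[[nm]] <- if (is.list(r)) {
      new_rule_table(unlist(r$regulators), unlist(r$outputs))
    } else {
      new_rule_expr(as.character(r))
    }
  }
  inputs <- NULL
  if (!is.null(obj$inputs)) {
    inputs <- vapply(obj$inputs, as.character, character(1))
  }
  boolean_network(nodes, rules, inputs = inputs,
                  metadata = if (is.null(obj$metadata)) "" else
                    as.character(obj$metadata))
}

#' Serialize a Boolean network
#'
#' `"bnet"` writes BoolNet-style `targets, factors` text (truth-table rules
#' are lowered to an equivalent minterm DNF expression). `"json"` writes the
#' JSON dialect, preserving truth tables and input policies. Output is UTF-8
#' with LF newlines and is byte-stable for a given network.
#'
#' @param net a [boolean_network()].
#' @param dialect `"bnet"` or `"json"`.
#' @return a single string.
#' @export
format_network <- function(net, dialect = c("bnet", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "bnet") {
    lines <- character(0)
    if (nzchar(net$metadata)) lines <- paste0("# ", net$metadata)
    lines <- c(lines, "targets, factors",
               vapply(net$nodes, function(nm) {
                 paste0(nm, ", ", rule_text(net$rules[[nm]]))
               }, character(1)))
    return(paste0(paste(lines, collapse = "\n"), "\n"))
  }
  input_nodes <- attr(net, "input_nodes")
  if (is.null(input_nodes)) input_nodes <- character(0)
  pol0 <- attr(net, "input_policy")
  # an input node whose rule no longer matches its policy (e.g. it was
  # clamped) is serialized as an ordinary rule
  still_input <- vapply(input_nodes, function(nm) {
    want <- if (!is.null(pol0) && nm %in% names(pol0)) pol0[[nm]] else "hold"
    want <- if (want == "hold") nm else want
    identical(rule_text(net$rules[[nm]]), want)
  }, logical(1))
  input_nodes <- input_nodes[still_input]
  rules <- list()
  for (nm in setdiff(net$nodes, input_nodes)) {
    r <- net$rules[[nm]]
    rules[[nm]] <- if (r$kind == "table") {
      list(regulators = r$regulators, outputs = r$outputs)
    } else {
      r$text
    }
  }
  obj <- list(nodes = net$nodes, rules = rules)
  pol <- attr(net, "input_policy")
  if (length(input_nodes)) {
    all_pol <- stats::setNames(rep("hold", length(input_nodes)), input_nodes)
    if (!is.null(pol)) {
      keep <- intersect(names(pol), input_nodes)
      all_pol[keep] <- pol[keep]
    }
    obj$inputs <- as.list(all_pol)
  }
  if (nzchar(net$metadata)) obj$metadata <- net$metadata
  paste0(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA),
         "\n")
}

#' Read / write network files
#'
#' The dialect is taken from the file extension (`.bnet`/`.txt` vs `.json`)
#' unless given explicitly.
#'
#' @param path file path.
#' @param dialect `"auto"`, `"bnet"` or `"json"`.
#' @return `read_network` returns a [boolean_network()]; `write_network`
#'   returns `path` invisibly.
#' @export
read_network <- function(path, dialect = c("auto", "bnet", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "bnet"
  }
  parse_network(paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                      collapse = "\n"),
                dialect)
}

#' @rdname read_network
#' @param net a [boolean_network()].
#' @export
write_network <- function(net, path, dialect = c("auto", "bnet", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "bnet"
  }
  writeLines(sub("\n$", "", format_network(net, dialect)), path, useBytes = TRUE)
  invisible(path)
}

# ---- dynamics ----------------------------------------------------------

# Evaluate all rules on a set of states. `bits` is an m x n logical matrix
# (columns in node order); returns an m x n logical matrix of successors.
step_states <- function(net, bits) {
  m <- nrow(bits)
  env <- list2env(stats::setNames(
    lapply(seq_along(net$nodes), function(j) bits[, j]), net$nodes),
    parent = baseenv())
  out <- matrix(FALSE, m, length(net$nodes))
  for (j in seq_along(net$nodes)) {
    out[, j] <- eval_rule(net$rules[[j]], env, m)
  }
  out
}

#' Synchronous update step
#'
#' Applies every node's rule simultaneously to the current state: the value
#' of node *i* at time *t+1* is its rule evaluated on the full state at time
#' *t*. Deterministic by construction.
#'
#' @param net a [boolean_network()].
#' @param state 0/1 vector in node order.
#' @return 0/1 integer vector, the successor state.
#' @export
synchronous_step <- function(net, state) {
  state <- validate_state(net, state)
  bits <- matrix(state == 1L, nrow = 1L)
  as.integer(step_states(net, bits)[1L, ])
}

#' Integer encoding of network states
#'
#' States are encoded positionally: the node at position 1 of the network is
#' the least significant bit, so a state `s` maps to
#' `sum(s * 2^(0:(n-1)))`. Codes are returned as doubles (exact up to
#' n = 53 nodes; exhaustive analysis is limited far below that anyway).
#'
#' @param state 0/1 vector in node order.
#' @param net a [boolean_network()] (supplies the node count).
#' @return `state_to_code`: a non-negative number; `code_to_state`: a 0/1
#'   integer vector.
#' @examples
#' net <- boolean_network(c("A", "B", "C"), list(A = "A", B = "B", C = "C"))
#' state_to_code(c(1, 0, 0), net)  # 1
#' code_to_state(7, net)           # c(1, 1, 1)
#' @export
state_to_code <- function(state, net) {
  state <- validate_state(net, state)
  sum(as.numeric(state) * 2^(seq_along(state) - 1))
}

#' @rdname state_to_code
#' @param code integer code in `[0, 2^n)`.
#' @export
code_to_state <- function(code, net) {
  n <- length(net$nodes)
  code <- as.numeric(code)
  if (length(code) != 1L || is.na(code) || code < 0 || code >= 2^n ||
      code != floor(code)) {
    stop(sprintf("code must be a single integer in [0, 2^%d)", n))
  }
  out <- integer(n)
  for (j in seq_len(n)) {
    out[j] <- as.integer(code %% 2)
    code <- code %/% 2
  }
  out
}

# decode many codes at once into an m x n 0/1 integer matrix
codes_to_states <- function(codes, n) {
  m <- length(codes)
  out <- matrix(0L, m, n)
  codes <- as.numeric(codes)
  for (j in seq_len(n)) {
    out[, j] <- as.integer(codes %% 2)
    codes <- codes %/% 2
  }
  out
}

states_to_codes <- function(bits) {
  # bits: m x n logical or 0/1 matrix
  as.numeric(bits %*% 2^(seq_len(ncol(bits)) - 1))
}

# Full synchronous successor table: succ[code + 1] is the successor code of
# `code`, for all codes 0 .. 2^n - 1. Rules are evaluated vectorized over the
# whole state space, so the cost is O(n) vector operations of length 2^n.
successor_table <- function(net) {
  n <- length(net$nodes)
  if (n > 26L) stop("successor table limited to 26 nodes")
  N <- 2L^n
  codes <- 0:(N - 1L)
  cols <- lapply(seq_len(n), function(j) {
    bitwAnd(bitwShiftR(codes, j - 1L), 1L) == 1L
  })
  env <- list2env(stats::setNames(cols, net$nodes), parent = baseenv())
  succ <- numeric(N)
  for (j in seq_len(n)) {
    succ <- succ + as.numeric(eval_rule(net$rules[[j]], env, N)) * 2^(j - 1)
  }
  as.integer(succ)
}

#' Persistently clamp a node
#'
#' Returns a copy of the network in which the named node's rule is replaced
#' by the constant `value` — the in-silico analogue of a sustained knockout
#' (`value = 0`) or sustained over-activation (`value = 1`). The original
#' network is not modified; clamping an already clamped node to the same
#' value is a no-op (idempotent).
#'
#' @param net a [boolean_network()].
#' @param node node name.
#' @param value 0 or 1.
#' @return a new [boolean_network()] carrying a `clamps` attribute that
#'   accumulates the applied clamps (`"NODE=value"` strings).
#' @export
clamp_node <- function(net, node, value) {
  if (!node %in% net$nodes) stop("unknown node: ", node)
  value <- as.integer(value)
  if (!value %in% c(0L, 1L)) stop("clamp value must be 0 or 1")
  net$rules[[node]] <- new_rule_expr(as.character(value))
  cl <- attr(net, "clamps")
  tag <- sprintf("%s=%d", node, value)
  attr(net, "clamps") <- unique(c(cl, tag))
  net
}
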