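# Phenotype annotation of attractor states.
#
# A phenotype scheme is data, not code: an ordered list of labels, one marker
# condition (a Boolean expression over node names) per label except the
# fallback, and an outcome class per label. A state receives every label
# whose condition holds, or the fallback (the naive monocyte M0) when none
# does.

#' Construct a phenotype scheme
#'
#' @param labels ordered character vector of phenotype names; the order fixes
#'   how composite names are concatenated.
#' @param conditions named character vector of marker expressions, one per
#'   non-fallback label (same grammar as network rules).
#' @param fallback_label label assigned when no condition holds; must be in
#'   `labels` and carry no condition.
#' @param outcome_class named character vector mapping each label to one of
#'   `"tumor-eliminating"`, `"tumor-promoting"`, `"neutral"`.
#' @return an object of class `phenotype_scheme`.
#' @export
phenotype_scheme <- function(labels, conditions, fallback_label,
                             outcome_class) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate phenotype labels")
  if (!fallback_label %in% labels) stop("fallback label not among labels")
  if (fallback_label %in% names(conditions)) {
    stop("the fallback label must not carry a condition")
  }
  need <- setdiff(labels, fallback_label)
  if (!setequal(names(conditions), need)) {
    stop("conditions must cover exactly the non-fallback labels")
  }
  ok <- c("tumor-eliminating", "tumor-promoting", "neutral")
  if (!setequal(names(outcome_class), labels) ||
      !all(outcome_class %in% ok)) {
    stop("outcome_class must map every label to one of: ",
         paste(ok, collapse = ", "))
  }
  parsed <- lapply(conditions, new_rule_expr)
  structure(list(labels = labels, conditions = parsed[need],
                 fallback_label = fallback_label,
                 outcome_class = outcome_class[labels]),
            class = "phenotype_scheme")
}

#' @export
print.phenotype_scheme <- function(x, ...) {
  cat("Phenotype scheme:", paste(x$labels, collapse = ", "), "\n")
  for (lb in x$labels) {
    cond <- if (lb == x$fallback_label) "(fallback)" else
      x$conditions[[lb]]$text
    cat(sprintf("  %-5s %-22s [%s]\n", lb, cond, x$outcome_class[[lb]]))
  }
  invisible(x)
}

#' Default macrophage polarization scheme
#'
#' The marker associations statable for the M0/M1/M2 family: M1 is driven by
#' STAT1 or NFKB, M2a by STAT6, M2b by AP1, M2c by STAT3, M2d by HIF1A, and a
#' state with none of these markers is a naive monocyte M0. M1 is classed
#' tumor-eliminating, the M2 variants tumor-promoting, M0 neutral. (AP-1 has
#' conflicting phenotype associations in the literature; the M2b reading is
#' used here.)
#'
#' @return a [phenotype_scheme()].
#' @export
default_phenotype_scheme <- function() {
  phenotype_scheme(
    labels = c("M0", "M1", "M2a", "M2b", "M2c", "M2d"),
    conditions = c(M1 = "STAT1 | NFKB", M2a = "STAT6", M2b = "AP1",
                   M2c = "STAT3", M2d = "HIF1A"),
    fallback_label = "M0",
    outcome_class = c(M0 = "neutral", M1 = "tumor-eliminating",
                      M2a = "tumor-promoting", M2b = "tumor-promoting",
                      M2c = "tumor-promoting", M2d = "tumor-promoting")
  )
}

#' Read / write phenotype schemes as JSON
#'
#' @param path file path.
#' @return `read_phenotype_scheme` returns a [phenotype_scheme()];
#'   `write_phenotype_scheme` returns `path` invisibly.
#' @export
read_phenotype_scheme <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  phenotype_scheme(
    labels = vapply(obj$labels, as.character, character(1)),
    conditions = vapply(obj$conditions, as.character, character(1)),
    fallback_label = as.character(obj$fallback_label),
    outcome_class = vapply(obj$outcome_class, as.character, character(1))
  )
}

#' @rdname read_phenotype_scheme
#' @param scheme a [phenotype_scheme()].
#' @export
write_phenotype_scheme <- function(scheme, path) {
  obj <- list(
    labels = scheme$labels,
    conditions = lapply(scheme$conditions, function(r) r$text),
    fallback_label = scheme$fallback_label,
    outcome_class = as.list(scheme$outcome_class)
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE),
             path, useBytes = TRUE)
  invisible(path)
}

#' Check a scheme against a network
#'
#' Errors if any marker condition references a node the network does not
#' declare. Called by all annotation entry points, so bad schemes fail at
#' load time, not per state.
#'
#' @param scheme a [phenotype_scheme()].
#' @param net a [boolean_network()].
#' @return `scheme`, invisibly.
#' @export
validate_scheme <- function(scheme, net) {
  refs <- unique(unlist(lapply(scheme$conditions, `[[`, "refs")))
  miss <- setdiff(refs, net$nodes)
  if (length(miss)) {
    stop("scheme condition(s) reference unknown node(s): ",
         paste(miss, collapse = ", "))
  }
  invisible(scheme)
}

# Vectorized labeling: bits is m x n (0/1 or logical), columns in node order.
# Returns an m x L logical membership matrix, columns in scheme label order
# (fallback column = TRUE iff no other label applies).
label_matrix <- function(bits, scheme, net) {
  validate_scheme(scheme, net)
  m <- nrow(bits)
  env <- list2env(stats::setNames(
    lapply(seq_along(net$nodes), function(j) bits[, j] == 1L), net$nodes),
    parent = baseenv())
  memb <- matrix(FALSE, m, length(scheme$labels),
                 dimnames = list(NULL, scheme$labels))
  for (lb in names(scheme$conditions)) {
    memb[, lb] <- eval_rule(scheme$conditions[[lb]], env, m)
  }
  memb[, scheme$fallback_label] <- rowSums(memb) == 0L
  memb
}

composite_from_membership <- function(memb_row, scheme) {
  paste(scheme$labels[memb_row], collapse = "")
}

#' Label one network state
#'
#' Evaluates every marker condition on the state; the label set is all labels
#' whose condition holds, or the fallback when none does. The composite name
#' concatenates the labels in scheme order with no separator (e.g. `"M1M2c"`).
#'
#' @param state 0/1 vector in node order.
#' @param scheme a [phenotype_scheme()].
#' @param net a [boolean_network()].
#' @return `list(labels = character vector, name = string)`.
#' @examples
#' net <- macrophage_fixture()$network
#' s <- integer(length(net$nodes))
#' s[match("STAT1", net$nodes)] <- 1L
#' label_state(s, default_phenotype_scheme(), net)$name  # "M1"
#' @export
label_state <- function(state, scheme, net) {
  state <- validate_state(net, state)
  memb <- label_matrix(matrix(state, nrow = 1L), scheme, net)[1L, ]
  list(labels = scheme$labels[memb],
       name = composite_from_membership(memb, scheme))
}

#' Annotate and classify an attractor
#'
#' Names every state of the attractor, joins the per-state names with `"/"`
#' starting from the canonical rotation, and classifies the attractor:
#' `"cycle"` iff period > 1, `"pure fixed point"` iff period 1 with exactly
#' one label, `"hybrid fixed point"` iff period 1 with two or more labels.
#' The outcome summary is the union of the outcome classes of all labels
#' present in any state.
#'
#' @param a an `attractor`.
#' @param scheme a [phenotype_scheme()].
#' @param net a [boolean_network()].
#' @return an `attractor_annotation`: list with `state_labels` (list of
#'   character vectors), `state_names`, `name`, `class`, `outcomes`.
#' @export
classify_attractor <- function(a, scheme, net) {
  memb <- label_matrix(a$states, scheme, net)
  state_labels <- lapply(seq_len(nrow(memb)), function(i) {
    scheme$labels[memb[i, ]]
  })
  state_names <- vapply(seq_len(nrow(memb)), function(i) {
    composite_from_membership(memb[i, ], scheme)
  }, character(1))
  cls <- if (a$period > 1L) {
    "cycle"
  } else if (length(state_labels[[1L]]) == 1L) {
    "pure fixed point"
  } else {
    "hybrid fixed point"
  }
  all_labels <- unique(unlist(state_labels))
  outcomes <- sort(unique(unname(scheme$outcome_class[all_labels])))
  structure(list(state_labels = state_labels,
                 state_names = state_names,
                 name = paste(state_names, collapse = "/"),
                 class = cls,
                 outcomes = outcomes),
            class = "attractor_annotation")
}

#' @export
print.attractor_annotation <- function(x, ...) {
  cat(sprintf("<%s> %s  [%s]\n", x$class, x$name,
              paste(x$outcomes, collapse = ", ")))
  invisible(x)
}

outcome_category <- function(outcomes) {
  has_e <- "tumor-eliminating" %in% outcomes
  has_p <- "tumor-promoting" %in% outcomes
  if (has_e && has_p) "mixed"
  else if (has_p) "tumor-promoting only"
  else if (has_e) "tumor-eliminating only"
  else "neutral only"
}

#' Summarize an annotated attractor set
#'
#' @param aset an `attractor_set`.
#' @param scheme a [phenotype_scheme()].
#' @return list with `table` (one row per attractor: id, class, period, name,
#'   outcome category, basin), `class_counts`, `period_counts` and
#'   `outcome_by_class` (class x outcome-category contingency table).
#' @export
summarize_attractors <- function(aset, scheme) {
  anns <- lapply(aset$attractors, classify_attractor,
                 scheme = scheme, net = aset$network)
  n_att <- length(aset$attractors)
  tab <- data.frame(
    id = seq_len(n_att),
    class = vapply(anns, `[[`, character(1), "class"),
    period = vapply(aset$attractors, function(a) a$period, integer(1)),
    name = vapply(anns, `[[`, character(1), "name"),
    outcome = vapply(anns, function(x) outcome_category(x$outcomes),
                     character(1)),
    basin_size = vapply(aset$attractors, function(a) a$basin_size,
                        numeric(1)),
    basin_fraction = vapply(aset$attractors, function(a) a$basin_fraction,
                            numeric(1)),
    stringsAsFactors = FALSE
  )
  classes <- c("pure fixed point", "hybrid fixed point", "cycle")
  class_counts <- stats::setNames(
    vapply(classes, function(cl) sum(tab$class == cl), integer(1)), classes)
  period_counts <- if (n_att) table(tab$period) else table(integer(0))
  outcome_by_class <- if (n_att) {
    table(factor(tab$class, levels = classes), tab$outcome)
  } else {
    table(factor(character(0), levels = classes), character(0))
  }
  list(table = tab, class_counts = class_counts,
       period_counts = period_counts, outcome_by_class = outcome_by_class)
}

#' Write the annotated attractor table as TSV
#'
#' @param aset an `attractor_set`.
#' @param scheme a [phenotype_scheme()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotated_attractors <- function(aset, scheme, path) {
  tab <- summarize_attractors(aset, scheme)$table
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
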