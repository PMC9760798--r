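# Cell fate map: persistent bit-flip perturbations between attractors.
#
# For each attractor of the unperturbed network and each selected node, the
# node's rule is replaced by the opposite constant (a clamp) and the
# perturbed state is followed to the attractor of the *clamped* network.
# Sign convention: "+" = node was off and is turned (and held) on,
# "-" = node was on and is turned (and held) off. Nodes whose value varies
# across a cyclic source are perturbed with both clamps.

#' Resolve a single clamp perturbation
#'
#' Builds `clamp_node(net, node, clamp_value)`, then for each state of the
#' source attractor sets that node's bit to `clamp_value` and follows the
#' trajectory in the clamped network. Deterministic; for a fixed-point source
#' there is exactly one destination.
#'
#' @param net the unperturbed [boolean_network()].
#' @param source an `attractor` of `net`.
#' @param node node to clamp.
#' @param clamp_value 0 or 1.
#' @param mode `"clamp"` (persistent perturbation, the default) or
#'   `"transient"` (the bit is flipped once and the *original* network is
#'   run, for comparison with the one-step reading).
#' @return list of `list(attractor =, entry_state =, transient =)`, one per
#'   distinct destination; `entry_state` is the (first) index of the source
#'   state that led there.
#' @export
resolve_perturbation <- function(net, source, node, clamp_value,
                                 mode = c("clamp", "transient")) {
  mode <- match.arg(mode)
  if (!node %in% net$nodes) stop("unknown node: ", node)
  clamp_value <- as.integer(clamp_value)
  j <- match(node, net$nodes)
  run_net <- if (mode == "clamp") clamp_node(net, node, clamp_value) else net
  starts <- source$states
  starts[, j] <- clamp_value
  res <- trajectories_batch(run_net, starts,
                            max_steps = 2^min(length(net$nodes), 52))
  keys <- vapply(res$cycles, function(cyc) {
    attractor_key(canonical_rotation(cyc))
  }, character(1))
  first <- !duplicated(keys)
  lapply(which(first), function(i) {
    list(attractor = new_attractor(res$cycles[[i]], run_net),
         entry_state = i,
         n_entry_states = sum(keys == keys[i]),
         transient = res$transients[i])
  })
}

#' Build the cell fate map
#'
#' For every attractor in `aset` and every selected node: if the node is
#' constant across the attractor's states, the single opposite clamp is
#' applied; if it varies across cycle states, both clamps are applied (the
#' perturbation record carries `original_value = "varies"`). Destinations are
#' annotated with the phenotype scheme and tagged with their clamp context,
#' since they are attractors of the clamped, not the original, network.
#'
#' @param net a [boolean_network()].
#' @param aset `attractor_set` computed on `net`.
#' @param scheme a [phenotype_scheme()] used to name vertices.
#' @param nodes nodes to perturb (default all).
#' @param mode `"clamp"` or `"transient"`, see [resolve_perturbation()].
#' @return a `fate_map`: list with `vertices` (data frame: id, name, class,
#'   period, context, states) and `edges` (data frame: source, node, sign,
#'   original_value, destination, destination_class, n_entry_states).
#' @export
build_fate_map <- function(net, aset, scheme, nodes = NULL,
                           mode = c("clamp", "transient")) {
  mode <- match.arg(mode)
  validate_scheme(scheme, net)
  if (is.null(nodes)) nodes <- net$nodes
  miss <- setdiff(nodes, net$nodes)
  if (length(miss)) stop("unknown node(s): ", paste(miss, collapse = ", "))

  vkey <- character(0)    # attractor key + clamp context -> vertex id
  vertices <- list()
  add_vertex <- function(a, context, annotating_net) {
    key <- paste0(context, "|", attractor_key(a$codes))
    hit <- match(key, vkey)
    if (!is.na(hit)) return(hit)
    ann <- classify_attractor(a, scheme, annotating_net)
    id <- length(vertices) + 1L
    vertices[[id]] <<- data.frame(
      id = id, name = ann$name, class = ann$class, period = a$period,
      context = context,
      states = paste(apply(a$states, 1L, paste, collapse = ""),
                     collapse = "/"),
      stringsAsFactors = FALSE)
    vkey[id] <<- key
    id
  }

  src_ids <- vapply(aset$attractors, add_vertex, integer(1),
                    context = "", annotating_net = net)
  edges <- list()
  for (si in seq_along(aset$attractors)) {
    src <- aset$attractors[[si]]
    for (nd in nodes) {
      j <- match(nd, net$nodes)
      vals <- unique(src$states[, j])
      clamps <- if (length(vals) == 1L) {
        data.frame(value = 1L - vals, orig = as.character(vals))
      } else {
        data.frame(value = c(0L, 1L), orig = "varies")
      }
      for (ci in seq_len(nrow(clamps))) {
        cv <- clamps$value[ci]
        # transient destinations are attractors of the original network and
        # merge with the base vertices; clamped destinations are tagged
        context <- if (mode == "clamp") sprintf("%s=%d", nd, cv) else ""
        dest_net <- if (mode == "clamp") clamp_node(net, nd, cv) else net
        dests <- resolve_perturbation(net, src, nd, cv, mode = mode)
        for (d in dests) {
          di <- add_vertex(d$attractor, context, dest_net)
          edges[[length(edges) + 1L]] <- data.frame(
            source = src_ids[si], node = nd,
            sign = if (cv == 1L) "+" else "-",
            original_value = clamps$orig[ci],
            destination = di,
            n_entry_states = d$n_entry_states,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  vertices <- do.call(rbind, vertices)
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = integer(0), node = character(0), sign = character(0),
               original_value = character(0), destination = integer(0),
               n_entry_states = integer(0))
  structure(list(vertices = vertices, edges = edges, mode = mode,
                 network = net, scheme = scheme),
            class = "fate_map")
}

#' @export
print.fate_map <- function(x, ...) {
  cat(sprintf("Cell fate map (%s mode): %d vertices, %d edges\n",
              x$mode, nrow(x$vertices), nrow(x$edges)))
  invisible(x)
}

fate_map_edge_table <- function(map) {
  v <- map$vertices
  e <- map$edges
  data.frame(
    source_name = v$name[e$source],
    source_class = v$class[e$source],
    node = e$node,
    sign = e$sign,
    original_value = e$original_value,
    destination_name = v$name[e$destination],
    destination_class = v$class[e$destination],
    destination_context = v$context[e$destination],
    destination_states = v$states[e$destination],
    n_entry_states = e$n_entry_states,
    stringsAsFactors = FALSE
  )
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Export a cell fate map
#'
#' `"tsv"` writes the edge table (source name, node, sign, destination name
#' and class, plus context columns). `"graphml"` and `"dot"` write the same
#' graph with vertex attributes name/class/period/context and edge attributes
#' node/sign. All formats are byte-stable across runs.
#'
#' @param map a `fate_map`.
#' @param path output file.
#' @param format `"tsv"`, `"graphml"` or `"dot"` (default from extension).
#' @return `path`, invisibly.
#' @export
export_fate_map <- function(map, path, format = c("auto", "tsv", "graphml",
                                                  "dot")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext, tsv = "tsv", graphml = "graphml", dot = "dot",
                     gv = "dot",
                     stop("cannot infer format from extension: ", ext))
  }
  if (nrow(map$edges) == 0L) stop("fate map has no edges")
  if (format == "tsv") {
    utils::write.table(fate_map_edge_table(map), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  v <- map$vertices
  e <- map$edges
  if (format == "graphml") {
    lines <- c(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      paste0("<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\" ",
             "xmlns:xsi=\"http://www.w3.org/2001/XMLSchema-instance\" ",
             "xsi:schemaLocation=\"http://graphml.graphdrawing.org/xmlns ",
             "http://graphml.graphdrawing.org/xmlns/1.0/graphml.xsd\">"),
      "  <key id=\"name\" for=\"node\" attr.name=\"name\" attr.type=\"string\"/>",
      "  <key id=\"class\" for=\"node\" attr.name=\"class\" attr.type=\"string\"/>",
      "  <key id=\"period\" for=\"node\" attr.name=\"period\" attr.type=\"int\"/>",
      "  <key id=\"context\" for=\"node\" attr.name=\"context\" attr.type=\"string\"/>",
      "  <key id=\"node\" for=\"edge\" attr.name=\"node\" attr.type=\"string\"/>",
      "  <key id=\"sign\" for=\"edge\" attr.name=\"sign\" attr.type=\"string\"/>",
      "  <graph id=\"fatemap\" edgedefault=\"directed\">"
    )
    for (i in seq_len(nrow(v))) {
      lines <- c(lines,
        sprintf("    <node id=\"n%d\">", v$id[i]),
        sprintf("      <data key=\"name\">%s</data>", xml_escape(v$name[i])),
        sprintf("      <data key=\"class\">%s</data>", xml_escape(v$class[i])),
        sprintf("      <data key=\"period\">%d</data>", v$period[i]),
        sprintf("      <data key=\"context\">%s</data>",
                xml_escape(v$context[i])),
        "    </node>")
    }
    for (i in seq_len(nrow(e))) {
      lines <- c(lines,
        sprintf("    <edge source=\"n%d\" target=\"n%d\">",
                e$source[i], e$destination[i]),
        sprintf("      <data key=\"node\">%s</data>", xml_escape(e$node[i])),
        sprintf("      <data key=\"sign\">%s</data>",
                xml_escape(e$sign[i])),
        "    </edge>")
    }
    lines <- c(lines, "  </graph>", "</graphml>")
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(path))
  }
  # DOT
  q <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")
  lines <- c("digraph fatemap {")
  for (i in seq_len(nrow(v))) {
    lines <- c(lines, sprintf(
      "  n%d [label=%s, class=%s, period=%d, context=%s];",
      v$id[i], q(v$name[i]), q(v$class[i]), v$period[i], q(v$context[i])))
  }
  for (i in seq_len(nrow(e))) {
    lines <- c(lines, sprintf(
      "  n%d -> n%d [label=%s];",
      e$source[i], e$destination[i], q(paste0(e$sign[i], e$node[i]))))
  }
  lines <- c(lines, "}")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read back a fate-map TSV edge table
#'
#' @param path a TSV written by [export_fate_map()].
#' @return the edge table data frame.
#' @export
read_fate_map_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE)
}
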