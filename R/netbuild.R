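#' Node metadata table
#'
#' Wraps a data frame of individuals and their categorical attributes
#' (genetic sex, burial site, period, age class, burial orientation, item
#' flags, ...). The first argument must contain a character `id` column; every
#' other column is treated as a categorical attribute and stored as a factor
#' with a declared, finite level set.
#'
#' @param df data frame with an `id` column plus one column per attribute.
#' @param levels optional named list giving the level set of each attribute;
#'   attributes not listed get their observed unique values (sorted) as levels.
#' @return A `node_table`, a data frame with character `id` and factor
#'   attribute columns.
#' @examples
#' node_table(data.frame(id = c("a", "b"), sex = c("F", "M")))
#' @export
node_table <- function(df, levels = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) {
    stop("node table must contain an 'id' column", call. = FALSE)
  }
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    dup <- unique(df$id[duplicated(df$id)])
    stop("duplicated node id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  attrs <- setdiff(names(df), "id")
  if ("id" %in% attrs) stop("no attribute may be named 'id'", call. = FALSE)
  for (a in attrs) {
    lv <- if (!is.null(levels) && a %in% names(levels)) {
      as.character(levels[[a]])
    } else if (is.factor(df[[a]])) {
      base::levels(df[[a]])
    } else {
      sort(unique(as.character(df[[a]])))
    }
    x <- factor(as.character(df[[a]]), levels = lv)
    if (anyNA(x) && !anyNA(df[[a]])) {
      bad <- setdiff(unique(as.character(df[[a]])), lv)
      stop("attribute '", a, "' has values outside its declared levels: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    df[[a]] <- x
  }
  df <- df[, c("id", attrs), drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("node_table", "data.frame")
  df
}

#' @export
print.node_table <- function(x, ...) {
  cat("Node table:", nrow(x), "individuals,",
      ncol(x) - 1L, "attribute(s)\n")
  for (a in node_attributes(x)) {
    cat("  ", a, ": {", paste(base::levels(x[[a]]), collapse = ", "), "}\n",
        sep = "")
  }
  NextMethod()
}

#' Attribute names of a node table
#' @param nodes a [node_table()].
#' @return Character vector of attribute column names (excludes `id`).
#' @export
node_attributes <- function(nodes) setdiff(names(nodes), "id")

#' Combine categorical attributes into one composite attribute
#'
#' Several analyses treat a pair of node variables (for instance sex and age
#' class) as a single categorical attribute whose levels are the observed
#' combinations. This helper concatenates the levels explicitly; nothing in
#' the modelling code forms composites implicitly.
#'
#' @param nodes a [node_table()].
#' @param attrs character vector of two or more attribute names to combine.
#' @param name name of the new composite attribute.
#' @param sep separator between levels in the composite labels.
#' @return The node table with the composite column appended.
#' @examples
#' nt <- node_table(data.frame(id = c("a", "b"), sex = c("F", "M"),
#'                             age = c("Adult", "Subadult")))
#' combine_attributes(nt, c("sex", "age"), "sexage")
#' @export
combine_attributes <- function(nodes, attrs, name, sep = ".") {
  stopifnot(inherits(nodes, "node_table"), length(attrs) >= 2)
  missing <- setdiff(attrs, node_attributes(nodes))
  if (length(missing)) {
    stop("unknown attribute(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  combo <- do.call(paste, c(lapply(attrs, function(a) as.character(nodes[[a]])),
                            sep = sep))
  lv <- do.call(paste, c(do.call(expand.grid,
                                 lapply(rev(attrs),
                                        function(a) base::levels(nodes[[a]])))[,
                           length(attrs):1, drop = FALSE],
                         sep = sep))
  out <- nodes
  out[[name]] <- factor(combo, levels = sort(unique(c(lv, combo))))
  class(out) <- c("node_table", "data.frame")
  out
}

#' Thresholding rules for IBD sharing
#'
#' A kinship network is formed by declaring an edge between two individuals
#' when their pairwise IBD sharing exceeds a cutoff. Two rule types are
#' supported:
#'
#' * `scalar_rule(cutoff, field)`: edge iff the named scalar summary
#'   (by default total shared centimorgans) is `>= cutoff`. The boundary is
#'   inclusive.
#' * `two_block_rule(L1, k1, L2, k2)`: edge iff the pair shares at least `k1`
#'   IBD blocks of length `>= L1` cM *and* at least `k2` blocks of length
#'   `>= L2` cM. The default (12 cM x 2, 16 cM x 1) is the rule used for
#'   ancient-cemetery data, corresponding to roughly seventh-degree or closer
#'   relatedness.
#'
#' @param cutoff finite numeric cutoff `c`; the rule fires when the field is
#'   `>= c`.
#' @param field name of the scalar summary the cutoff applies to.
#' @param L1,L2 block-length thresholds in centimorgans, `0 < L1 <= L2`.
#' @param k1,k2 minimum block counts, `k1 >= k2 >= 1`.
#' @return A `threshold_rule` object.
#' @examples
#' scalar_rule(20)
#' two_block_rule()
#' @export
scalar_rule <- function(cutoff, field = "total_cM") {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, is.finite(cutoff))
  structure(list(type = "scalar", cutoff = cutoff, field = field),
            class = "threshold_rule")
}

#' @rdname scalar_rule
#' @export
two_block_rule <- function(L1 = 12, k1 = 2, L2 = 16, k2 = 1) {
  if (!(L1 > 0 && L2 >= L1)) stop("need L2 >= L1 > 0", call. = FALSE)
  if (!(k1 >= k2 && k2 >= 1)) stop("need k1 >= k2 >= 1", call. = FALSE)
  structure(list(type = "two_block", L1 = L1, k1 = k1, L2 = L2, k2 = k2),
            class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  if (x$type == "scalar") {
    cat("Threshold rule:", x$field, ">=", x$cutoff, "\n")
  } else {
    cat("Threshold rule: >=", x$k1, "block(s) >=", x$L1, "cM and >=",
        x$k2, "block(s) >=", x$L2, "cM\n")
  }
  invisible(x)
}

# Normalise a pairs data frame (segment or summary format) into one row per
# unordered pair with summary statistics. Duplicated unordered pairs in
# summary format, self pairs, and unknown ids are hard errors.
.normalise_pairs <- function(pairs, nodes) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("id1", "id2") %in% names(pairs))) {
    stop("pairs must have columns id1 and id2", call. = FALSE)
  }
  pairs$id1 <- as.character(pairs$id1)
  pairs$id2 <- as.character(pairs$id2)
  if (nrow(pairs)) {
    unknown <- setdiff(unique(c(pairs$id1, pairs$id2)), nodes$id)
    if (length(unknown)) {
      stop("pair id(s) not present in node table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (any(pairs$id1 == pairs$id2)) {
      stop("self pair (id1 == id2) for id: ",
           paste(unique(pairs$id1[pairs$id1 == pairs$id2]), collapse = ", "),
           call. = FALSE)
    }
  }
  # canonical unordered order by node-table position
  pos <- match(pairs$id1, nodes$id)
  pos2 <- match(pairs$id2, nodes$id)
  flip <- pos > pos2
  tmp <- pairs$id1[flip]; pairs$id1[flip] <- pairs$id2[flip]
  pairs$id2[flip] <- tmp

  segment <- "length_cM" %in% names(pairs)
  summary_cols <- c("n_ge12", "n_ge16", "total_cM")
  if (segment) {
    if (any(!is.finite(pairs$length_cM)) || any(pairs$length_cM < 0)) {
      stop("segment lengths must be finite and non-negative", call. = FALSE)
    }
    key <- paste(pairs$id1, pairs$id2, sep = "\r")
    out <- data.frame(
      id1 = pairs$id1[!duplicated(key)],
      id2 = pairs$id2[!duplicated(key)],
      stringsAsFactors = FALSE
    )
    okey <- unique(key)
    out$total_cM <- as.numeric(rowsum(pairs$length_cM, key)[okey, 1])
    out$n_ge12 <- as.integer(rowsum((pairs$length_cM >= 12) + 0, key)[okey, 1])
    out$n_ge16 <- as.integer(rowsum((pairs$length_cM >= 16) + 0, key)[okey, 1])
    segs <- split(pairs$length_cM, key)[okey]
    attr(out, "segments") <- segs
    attr(out, "format") <- "segment"
  } else {
    have <- intersect(summary_cols, names(pairs))
    if (!length(have)) {
      stop("pairs must carry either a length_cM column (segment format) ",
           "or summary columns (", paste(summary_cols, collapse = ", "), ")",
           call. = FALSE)
    }
    key <- paste(pairs$id1, pairs$id2, sep = "\r")
    if (anyDuplicated(key)) {
      d <- pairs[duplicated(key), c("id1", "id2"), drop = FALSE]
      stop("duplicated unordered pair(s): ",
           paste(unique(paste(d$id1, d$id2, sep = "--")), collapse = ", "),
           call. = FALSE)
    }
    out <- pairs
    attr(out, "format") <- "summary"
  }
  out
}

# Evaluate a threshold rule on normalised pair summaries -> logical vector.
.apply_rule <- function(norm, rule) {
  if (rule$type == "scalar") {
    if (!rule$field %in% names(norm)) {
      stop("scalar rule field '", rule$field,
           "' not available in the pair data", call. = FALSE)
    }
    norm[[rule$field]] >= rule$cutoff
  } else {
    segs <- attr(norm, "segments")
    if (!is.null(segs)) {
      n1 <- vapply(segs, function(s) sum(s >= rule$L1), integer(1))
      n2 <- vapply(segs, function(s) sum(s >= rule$L2), integer(1))
    } else if (rule$L1 == 12 && rule$L2 == 16 &&
               all(c("n_ge12", "n_ge16") %in% names(norm))) {
      n1 <- norm$n_ge12
      n2 <- norm$n_ge16
    } else {
      stop("two-block rule with L1=", rule$L1, ", L2=", rule$L2,
           " needs segment-level data (summaries only carry counts at 12 ",
           "and 16 cM)", call. = FALSE)
    }
    n1 >= rule$k1 & n2 >= rule$k2
  }
}

#' Build a kinship network by thresholding pairwise IBD sharing
#'
#' Applies a [scalar_rule()] or [two_block_rule()] to pairwise IBD summaries
#' and returns an undirected simple graph on the full node set. Pairs absent
#' from the input are treated as zero sharing (no edge), not as missing:
#' non-edges are observations in a dyad regression, and individuals with no
#' qualifying pair are retained as isolates.
#'
#' @param pairs data frame of pairwise IBD, either segment-level
#'   (`id1,id2,length_cM`, one row per segment) or pre-summarised
#'   (`id1,id2,n_ge12,n_ge16,total_cM`).
#' @param nodes a [node_table()]; every id in `pairs` must appear here.
#' @param rule a `threshold_rule`.
#' @return A `kin_network`: list with `nodes` (the node table), `edges`
#'   (data frame of node indices `i < j` in node-table order, plus `weight` =
#'   total shared cM where available).
#' @examples
#' nt <- node_table(data.frame(id = c("a", "b", "c"), sex = c("F", "M", "F")))
#' pr <- data.frame(id1 = c("a", "a"), id2 = c("b", "b"),
#'                  length_cM = c(13, 17.5))
#' threshold_network(pr, nt, two_block_rule())
#' @export
threshold_network <- function(pairs, nodes, rule) {
  stopifnot(inherits(nodes, "node_table"), inherits(rule, "threshold_rule"))
  norm <- .normalise_pairs(pairs, nodes)
  keep <- if (nrow(norm)) .apply_rule(norm, rule) else logical(0)
  i <- match(norm$id1, nodes$id)[keep]
  j <- match(norm$id2, nodes$id)[keep]
  w <- if ("total_cM" %in% names(norm)) norm$total_cM[keep] else rep(NA_real_, sum(keep))
  kin_network(nodes, edges = data.frame(i = i, j = j, weight = w))
}

#' Construct a kinship network from nodes and an edge list
#'
#' @param nodes a [node_table()].
#' @param edges data frame with integer columns `i`, `j` (node positions in
#'   `nodes`, any order) and optionally `weight` (total shared cM, `> 0`).
#' @return A `kin_network` object.
#' @export
kin_network <- function(nodes, edges = NULL) {
  stopifnot(inherits(nodes, "node_table"))
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(i = integer(0), j = integer(0), weight = numeric(0))
  } else {
    edges <- as.data.frame(edges)
    if (!"weight" %in% names(edges)) edges$weight <- NA_real_
    i <- pmin(edges$i, edges$j)
    j <- pmax(edges$i, edges$j)
    if (any(i == j)) stop("self-loop in edge list", call. = FALSE)
    if (any(i < 1L | j > nrow(nodes))) {
      stop("edge endpoint outside node table", call. = FALSE)
    }
    o <- order(i, j)
    edges <- data.frame(i = as.integer(i[o]), j = as.integer(j[o]),
                        weight = as.numeric(edges$weight[o]))
    if (anyDuplicated(edges[, c("i", "j")])) {
      stop("duplicated edge in edge list", call. = FALSE)
    }
    if (any(!is.na(edges$weight) & edges$weight <= 0)) {
      stop("edge weights must be > 0 where present", call. = FALSE)
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "kin_network")
}

#' @export
print.kin_network <- function(x, ...) {
  n <- nrow(x$nodes)
  m <- nrow(x$edges)
  dens <- if (n > 1) m / choose(n, 2) else NA_real_
  cat("Kinship network:", n, "nodes,", m, "edges",
      sprintf("(density %.4g)\n", dens))
  cat("Attributes:", paste(node_attributes(x$nodes), collapse = ", "), "\n")
  invisible(x)
}

#' Number of nodes / edges of a kinship network
#' @param net a `kin_network`.
#' @return Integer count.
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Convert a kinship network to an igraph graph
#'
#' Node attributes are attached as vertex attributes (as characters), ids as
#' the vertex `name`, and total shared cM as the edge `weight` where known.
#'
#' @param net a `kin_network`.
#' @return An undirected [igraph::make_graph()] object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "kin_network"))
  vdf <- data.frame(name = net$nodes$id, stringsAsFactors = FALSE)
  for (a in node_attributes(net$nodes)) vdf[[a]] <- as.character(net$nodes[[a]])
  edf <- data.frame(from = net$nodes$id[net$edges$i],
                    to = net$nodes$id[net$edges$j],
                    stringsAsFactors = FALSE)
  if (any(!is.na(net$edges$weight))) edf$weight <- net$edges$weight
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

#' Read node metadata from CSV
#'
#' Expects an `id` column plus one column per categorical attribute.
#'
#' @param path CSV file path.
#' @param levels optional named list of declared level sets (see
#'   [node_table()]).
#' @return A [node_table()].
#' @export
read_nodes <- function(path, levels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  node_table(df, levels = levels)
}

#' Read pairwise IBD records from CSV
#'
#' Accepts either segment-level rows (`id1,id2,length_cM`) or pre-summarised
#' rows (`id1,id2,n_ge12,n_ge16,total_cM`). Malformed rows are reported with
#' their line numbers.
#'
#' @param path CSV file path.
#' @return A data frame of pairwise records, suitable for
#'   [threshold_network()].
#' @export
read_ibd_pairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("id1", "id2") %in% names(df))) {
    stop("pairs CSV must have columns id1 and id2", call. = FALSE)
  }
  num_cols <- intersect(c("length_cM", "n_ge12", "n_ge16", "total_cM"),
                        names(df))
  if (!length(num_cols)) {
    stop("pairs CSV must carry length_cM or summary columns", call. = FALSE)
  }
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) | !is.finite(v) | v < 0)
    if (length(bad)) {
      stop("malformed values in column '", cc, "' at line(s) ",
           paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
    }
    df[[cc]] <- v
  }
  df
}

#' Write a kinship network to disk
#'
#' Two formats round-trip losslessly through [read_network()]:
#' `"edgelist"` writes a pair of CSVs — `<path>` with columns
#' `id1,id2,weight` and `<path base>_nodes.csv` with the node metadata —
#' while `"graphml"` writes a single GraphML file with node attributes
#' embedded.
#'
#' @param net a `kin_network`.
#' @param path output file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist")) {
  stopifnot(inherits(net, "kin_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    edf <- data.frame(id1 = net$nodes$id[net$edges$i],
                      id2 = net$nodes$id[net$edges$j],
                      weight = net$edges$weight)
    utils::write.csv(edf, path, row.names = FALSE)
    npath <- sub("\\.csv$", "", path)
    npath <- paste0(npath, "_nodes.csv")
    ndf <- net$nodes
    class(ndf) <- "data.frame"
    utils::write.csv(ndf, npath, row.names = FALSE)
  }
  invisible(path)
}

#' Read a kinship network from disk
#'
#' Inverse of [write_network()]. For `"edgelist"` the sibling
#' `<path base>_nodes.csv` file is read for node metadata.
#'
#' @param path file written by [write_network()].
#' @param format `"edgelist"` or `"graphml"`.
#' @return A `kin_network`.
#' @export
read_network <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    vat <- igraph::vertex_attr(g)
    ids <- if (!is.null(vat$name)) as.character(vat$name) else
      as.character(seq_len(igraph::vcount(g)))
    keep <- setdiff(names(vat), c("name", "id"))
    ndf <- data.frame(id = ids, stringsAsFactors = FALSE)
    for (a in keep) ndf[[a]] <- as.character(vat[[a]])
    nodes <- node_table(ndf)
    el <- igraph::as_edgelist(g, names = FALSE)
    w <- if ("weight" %in% igraph::edge_attr_names(g)) {
      igraph::E(g)$weight
    } else {
      rep(NA_real_, nrow(el))
    }
    kin_network(nodes, data.frame(i = el[, 1], j = el[, 2], weight = w))
  } else {
    edf <- utils::read.csv(path, stringsAsFactors = FALSE)
    npath <- paste0(sub("\\.csv$", "", path), "_nodes.csv")
    nodes <- read_nodes(npath)
    kin_network(nodes,
                data.frame(i = match(edf$id1, nodes$id),
                           j = match(edf$id2, nodes$id),
                           weight = if ("weight" %in% names(edf)) edf$weight
                                    else NA_real_))
  }
}
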