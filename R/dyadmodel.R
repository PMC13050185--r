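#' Model terms for dyad-independent network regression
#'
#' A model for the log-odds of a dyad being connected is an ordered list of
#' terms over node attributes (and optionally raw edge covariates). Available
#' terms:
#'
#' * `term_edges()`: the intercept (baseline log-odds); exactly one per model,
#'   always first.
#' * `term_nodematch(attribute)`: simple homophily — a single indicator that
#'   the two endpoints share the attribute level (one parameter).
#' * `term_nodematch_diff(attribute)`: differential homophily — one indicator
#'   per level, firing when both endpoints carry that level (one parameter
#'   per level).
#' * `term_nodemix(attribute, base_cell)`: attribute mixing — one indicator
#'   per unordered pair of levels, minus a reference cell (up to
#'   `choose(m, 2) + m - 1` parameters for `m` levels).
#' * `term_edgecov(name)`: a raw per-dyad numeric covariate.
#'
#' @param attribute attribute name in the node table.
#' @param base_cell for `term_nodemix`, a length-2 character vector giving the
#'   unordered level pair used as the reference cell. Default: the
#'   lexicographically smallest pair (deterministic); override to reproduce a
#'   substantively chosen baseline such as Adult F / Adult M.
#' @param name for `term_edgecov`, the name of the dyad covariate.
#' @return A `term_spec` object.
#' @examples
#' term_nodematch("sex")
#' term_nodemix("site", base_cell = c("A", "A"))
#' @export
term_edges <- function() {
  structure(list(kind = "edges", attribute = NULL), class = "term_spec")
}

#' @rdname term_edges
#' @export
term_nodematch <- function(attribute) {
  structure(list(kind = "nodematch", attribute = attribute),
            class = "term_spec")
}

#' @rdname term_edges
#' @export
term_nodematch_diff <- function(attribute) {
  structure(list(kind = "nodematch_diff", attribute = attribute),
            class = "term_spec")
}

#' @rdname term_edges
#' @export
term_nodemix <- function(attribute, base_cell = NULL) {
  if (!is.null(base_cell)) {
    stopifnot(length(base_cell) == 2)
    base_cell <- sort(as.character(base_cell))
  }
  structure(list(kind = "nodemix", attribute = attribute,
                 base_cell = base_cell),
            class = "term_spec")
}

#' @rdname term_edges
#' @export
term_edgecov <- function(name) {
  structure(list(kind = "edgecov", attribute = name), class = "term_spec")
}

#' @export
print.term_spec <- function(x, ...) {
  cat(x$kind, if (!is.null(x$attribute)) paste0("(", x$attribute, ")"), "\n")
  invisible(x)
}

#' Specify a dyad-independent network model
#'
#' Bundles an ordered list of terms (see [term_edges()]) into a model
#' specification. The intercept term is prepended automatically if absent;
#' duplicated (kind, attribute) pairs are rejected.
#'
#' @param ... `term_spec` objects, or a single list of them.
#' @param label optional human-readable model label.
#' @return A `model_spec` object.
#' @examples
#' model_spec(term_nodematch("sex"), label = "sexmatch")
#' @export
model_spec <- function(..., label = NULL) {
  terms <- list(...)
  if (length(terms) == 1 && is.list(terms[[1]]) &&
      !inherits(terms[[1]], "term_spec")) {
    terms <- terms[[1]]
  }
  ok <- vapply(terms, inherits, logical(1), what = "term_spec")
  if (!all(ok)) stop("all arguments must be term_spec objects", call. = FALSE)
  kinds <- vapply(terms, `[[`, character(1), "kind")
  if (sum(kinds == "edges") == 0) {
    terms <- c(list(term_edges()), terms)
    kinds <- c("edges", kinds)
  }
  if (sum(kinds == "edges") > 1) {
    stop("exactly one edges (intercept) term allowed", call. = FALSE)
  }
  if (which(kinds == "edges") != 1L) {
    terms <- c(terms[kinds == "edges"], terms[kinds != "edges"])
  }
  key <- vapply(terms, function(t)
    paste(t$kind, t$attribute %||% "", sep = ":"), character(1))
  if (anyDuplicated(key)) {
    stop("duplicated term: ", key[duplicated(key)][1], call. = FALSE)
  }
  structure(list(terms = terms, label = label), class = "model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.model_spec <- function(x, ...) {
  lab <- x$label %||% "(unlabelled)"
  cat("Model spec [", lab, "]: ", sep = "")
  cat(paste(vapply(x$terms, function(t)
    paste0(t$kind, if (!is.null(t$attribute)) paste0("(", t$attribute, ")")),
    character(1)), collapse = " + "), "\n")
  invisible(x)
}

#' Model label, defaulting to the term formula
#' @param spec a [model_spec()].
#' @return Character scalar.
#' @export
model_label <- function(spec) {
  spec$label %||% paste(vapply(spec$terms, function(t)
    paste0(t$kind, if (!is.null(t$attribute)) paste0(".", t$attribute)),
    character(1)), collapse = "+")
}

# All unordered level pairs of a level vector, in lexicographic order of
# (first, second) with first <= second. Returns a 2-column character matrix.
.unordered_cells <- function(lv) {
  m <- length(lv)
  out <- matrix(character(0), ncol = 2)
  for (a in seq_len(m)) for (b in a:m) out <- rbind(out, c(lv[a], lv[b]))
  out
}

# Column block for one term given endpoint attribute values (factors va, vb
# aligned to dyads). Returns a named numeric matrix (possibly 1 column).
.term_columns <- function(term, nodes, ai, bi, edge_covariates = NULL) {
  if (term$kind == "edges") {
    return(matrix(1, nrow = length(ai), ncol = 1,
                  dimnames = list(NULL, "edges")))
  }
  if (term$kind == "edgecov") {
    nm <- term$attribute
    if (is.null(edge_covariates) || !nm %in% names(edge_covariates)) {
      stop("edge covariate '", nm, "' not supplied for every dyad",
           call. = FALSE)
    }
    w <- edge_covariates[[nm]]
    if (length(w) != length(ai)) {
      stop("edge covariate '", nm, "' must have one value per dyad",
           call. = FALSE)
    }
    return(matrix(as.numeric(w), ncol = 1,
                  dimnames = list(NULL, paste0("edgecov.", nm))))
  }
  a <- term$attribute
  if (!a %in% node_attributes(nodes)) {
    stop("unknown attribute '", a, "' in ", term$kind, " term", call. = FALSE)
  }
  v <- nodes[[a]]
  if (anyNA(v)) {
    stop("attribute '", a, "' missing for node(s): ",
         paste(nodes$id[is.na(v)], collapse = ", "), call. = FALSE)
  }
  lv <- base::levels(v)
  if (length(base::levels(droplevels(v))) < 2) {
    stop("attribute '", a, "' has fewer than 2 observed levels", call. = FALSE)
  }
  va <- as.character(v)[ai]
  vb <- as.character(v)[bi]
  if (term$kind == "nodematch") {
    x <- matrix(as.numeric(va == vb), ncol = 1,
                dimnames = list(NULL, paste0("nodematch.", a)))
    return(x)
  }
  if (term$kind == "nodematch_diff") {
    obs <- lv[lv %in% unique(as.character(v))]
    x <- vapply(obs, function(l) as.numeric(va == l & vb == l),
                numeric(length(ai)))
    x <- matrix(x, ncol = length(obs),
                dimnames = list(NULL, paste0("nodematch_diff.", a, ".", obs)))
    return(x)
  }
  if (term$kind == "nodemix") {
    obs <- sort(lv[lv %in% unique(as.character(v))])
    cells <- .unordered_cells(obs)
    base_cell <- term$base_cell %||% cells[1, ]
    keep <- !(cells[, 1] == base_cell[1] & cells[, 2] == base_cell[2])
    if (all(keep)) {
      stop("nodemix base cell (", paste(base_cell, collapse = ","),
           ") is not a valid unordered level pair of '", a, "'",
           call. = FALSE)
    }
    cells <- cells[keep, , drop = FALSE]
    lo <- pmin(va, vb)
    hi <- pmax(va, vb)
    x <- vapply(seq_len(nrow(cells)), function(k)
      as.numeric(lo == cells[k, 1] & hi == cells[k, 2]),
      numeric(length(ai)))
    x <- matrix(x, ncol = nrow(cells),
                dimnames = list(NULL, paste0("nodemix.", a, ".",
                                             cells[, 1], ".", cells[, 2])))
    return(x)
  }
  stop("unknown term kind: ", term$kind, call. = FALSE)
}

# Dyad enumeration i<j in node-table order; returns list(i, j).
.dyads <- function(n) {
  if (n < 2) return(list(i = integer(0), j = integer(0)))
  j <- rep.int(2:n, 1:(n - 1))
  i <- sequence(1:(n - 1))
  list(i = i, j = j)
}

# Design matrix only (no response): the model applied to a node table.
.design_matrix <- function(nodes, spec, edge_covariates = NULL) {
  n <- nrow(nodes)
  d <- .dyads(n)
  blocks <- lapply(spec$terms, .term_columns, nodes = nodes,
                   ai = d$i, bi = d$j, edge_covariates = edge_covariates)
  X <- do.call(cbind, blocks)
  term_of <- rep(seq_along(spec$terms),
                 vapply(blocks, ncol, integer(1)))
  list(i = d$i, j = d$j, X = X, term_of = term_of)
}

#' Build the dyad-level design matrix of a model on a network
#'
#' Enumerates all `n(n-1)/2` unordered dyads `i < j` in node-table order,
#' evaluates each model term into indicator (or covariate) columns, and
#' attaches the observed adjacency as the 0/1 response. Column names follow
#' `<kind>.<attribute>.<level(s)>` so outputs are diffable.
#'
#' @param net a `kin_network` (see [threshold_network()]).
#' @param spec a [model_spec()].
#' @param edge_covariates optional named list of per-dyad numeric vectors
#'   (aligned with the dyad enumeration) for `term_edgecov` terms.
#' @param on_missing what to do when a node lacks an attribute value used by
#'   the model: `"error"` (default) or `"drop"` (remove every dyad touching an
#'   incomplete node; the dropped dyad count is recorded).
#' @return A `dyad_design`: list with `i`, `j` (dyad endpoints), `y` (0/1
#'   response), `X` (design matrix), `term_of` (term index per column) and
#'   `spec`.
#' @examples
#' nt <- node_table(data.frame(id = letters[1:3], sex = c("F", "F", "M")))
#' net <- kin_network(nt, data.frame(i = 1, j = 2))
#' build_design(net, model_spec(term_nodematch("sex")))
#' @export
build_design <- function(net, spec, edge_covariates = NULL,
                         on_missing = c("error", "drop")) {
  stopifnot(inherits(net, "kin_network"), inherits(spec, "model_spec"))
  on_missing <- match.arg(on_missing)
  nodes <- net$nodes
  dropped <- 0L
  if (on_missing == "drop") {
    used <- unlist(lapply(spec$terms, function(t)
      if (t$kind %in% c("nodematch", "nodematch_diff", "nodemix"))
        t$attribute))
    incomplete <- rep(FALSE, nrow(nodes))
    for (a in intersect(used, node_attributes(nodes))) {
      incomplete <- incomplete | is.na(nodes[[a]])
    }
    if (any(incomplete)) {
      keep_nodes <- which(!incomplete)
      dropped <- nrow(nodes) - length(keep_nodes)
      idx_map <- match(seq_len(nrow(nodes)), keep_nodes)
      sub_nodes <- nodes[keep_nodes, , drop = FALSE]
      class(sub_nodes) <- c("node_table", "data.frame")
      e <- net$edges
      ke <- !is.na(idx_map[e$i]) & !is.na(idx_map[e$j])
      net <- kin_network(sub_nodes,
                         data.frame(i = idx_map[e$i[ke]],
                                    j = idx_map[e$j[ke]],
                                    weight = e$weight[ke]))
      nodes <- net$nodes
    }
  }
  dm <- .design_matrix(nodes, spec, edge_covariates)
  n <- nrow(nodes)
  y <- numeric(length(dm$i))
  if (nrow(net$edges)) {
    # dyad (i,j), i<j, sits at position (j-1)(j-2)/2 + i in the enumeration
    pos <- (net$edges$j - 1) * (net$edges$j - 2) / 2 + net$edges$i
    y[pos] <- 1
  }
  structure(list(i = dm$i, j = dm$j, y = y, X = dm$X,
                 term_of = dm$term_of, spec = spec,
                 n_nodes = n, dropped_nodes = dropped),
            class = "dyad_design")
}

#' @export
print.dyad_design <- function(x, ...) {
  cat("Dyad design:", length(x$y), "dyads on", x$n_nodes, "nodes;",
      ncol(x$X), "parameter column(s)\n")
  cat("Columns:", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}

#' Parameter count of a model on a given node table
#'
#' Number of design-matrix columns (including the intercept) the model
#' produces for these nodes — e.g. over a 3-level attribute, nodematch
#' contributes 1 column, differential nodematch 3, and nodemix up to 5
#' (6 unordered cells minus the reference).
#'
#' @param spec a [model_spec()].
#' @param nodes a [node_table()].
#' @return Integer parameter count `k`.
#' @export
n_parameters <- function(spec, nodes) {
  # evaluate on a tiny slice: columns depend only on observed levels, so use
  # the full node set but only the first few dyads
  dm <- .design_matrix(nodes, spec)
  ncol(dm$X)
}
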