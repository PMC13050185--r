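# Simulation of networks from dyad-independent models, expected-edge
# calculations, and the synthetic Avar-like cemetery fixture.

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}

# Per-replicate seed: experiment seed plus replicate counter, kept inside
# 32-bit integer range so each replicate is reproducible in isolation.
.rep_seed <- function(seed, r) (as.numeric(seed) + r) %% 2147483647

#' Generate categorical node attributes with fixed group proportions
#'
#' Allocates levels by deterministic rounded quotas — `floor(n * p)` nodes
#' per level, with the remaining nodes assigned by a seeded draw weighted by
#' the fractional remainders — rather than a multinomial draw, so the group
#' sizes of a simulated design are exact (e.g. 150/150 or 75/225 at
#' `n = 300`). The assignment of levels to node positions is a seeded
#' permutation, so multiple attributes are unconfounded.
#'
#' @param n number of nodes.
#' @param attribute_specs named list; each element is a named numeric vector
#'   of level proportions (names are the levels, values sum to 1).
#' @param seed integer seed for the remainder draw and the permutation.
#' @return A [node_table()] with ids `n1 ... n<n>`.
#' @examples
#' generate_attributes(300, list(sex = c("1" = 0.25, "2" = 0.75)), seed = 1)
#' @export
generate_attributes <- function(n, attribute_specs, seed = 1) {
  stopifnot(n >= 1, length(attribute_specs) >= 1,
            !is.null(names(attribute_specs)))
  df <- data.frame(id = paste0("n", seq_len(n)), stringsAsFactors = FALSE)
  lvls <- list()
  .with_seed(seed, {
    for (a in names(attribute_specs)) {
      p <- attribute_specs[[a]]
      if (is.list(p)) p <- stats::setNames(p$proportions, p$levels)
      if (abs(sum(p) - 1) > 1e-8) {
        stop("proportions for '", a, "' must sum to 1", call. = FALSE)
      }
      nz <- sum(p > 0)
      if (n < nz) {
        stop("n = ", n, " smaller than the ", nz,
             " levels of '", a, "' with nonzero proportion", call. = FALSE)
      }
      quota <- floor(n * p)
      rem <- n - sum(quota)
      if (rem > 0) {
        frac <- n * p - quota
        extra <- sample(names(p), rem, replace = FALSE,
                        prob = frac + 1e-12)
        quota[extra] <- quota[extra] + 1
      }
      vals <- rep(names(p), times = quota)
      df[[a]] <- sample(vals, n, replace = FALSE)
      lvls[[a]] <- names(p)
    }
  })
  node_table(df, levels = lvls)
}

#' Simulate a network from a dyad-independent model
#'
#' Each unordered dyad `i < j` is connected independently with probability
#' `plogis(x_ij' theta)` where `x_ij` is the dyad's design row under `spec`.
#'
#' @param nodes a [node_table()].
#' @param spec a [model_spec()].
#' @param theta coefficient vector, one per design column (intercept first).
#' @param seed integer seed; the same seed reproduces the same edge set.
#' @return A `kin_network`.
#' @examples
#' nt <- generate_attributes(50, list(sex = c(F = 0.5, M = 0.5)), seed = 1)
#' simulate_network(nt, model_spec(term_nodematch("sex")), c(-3, 0.5), seed = 2)
#' @export
simulate_network <- function(nodes, spec, theta, seed = 1) {
  stopifnot(inherits(nodes, "node_table"), inherits(spec, "model_spec"))
  dm <- .design_matrix(nodes, spec)
  if (length(theta) != ncol(dm$X)) {
    stop("theta has length ", length(theta), " but the model has ",
         ncol(dm$X), " parameter column(s): ",
         paste(colnames(dm$X), collapse = ", "), call. = FALSE)
  }
  p <- stats::plogis(drop(dm$X %*% theta))
  y <- .with_seed(seed, stats::rbinom(length(p), 1L, p))
  on <- y == 1L
  kin_network(nodes, data.frame(i = dm$i[on], j = dm$j[on],
                                weight = rep(NA_real_, sum(on))))
}

#' Expected number of edges under a dyad-independent model
#'
#' Computes `sum_{i<j} plogis(x_ij' theta)` exactly, grouping dyads by the
#' covariate pattern of their endpoint attribute profiles rather than
#' enumerating all `n(n-1)/2` dyads, so it scales to large `n`.
#'
#' @inheritParams simulate_network
#' @return Expected edge count (non-negative real; 0 when `n < 2`).
#' @examples
#' nt <- generate_attributes(300, list(sex = c(F = 0.5, M = 0.5)), seed = 1)
#' expected_edges(nt, model_spec(term_edges()), -4) # ~806.7
#' @export
expected_edges <- function(nodes, spec, theta) {
  stopifnot(inherits(nodes, "node_table"), inherits(spec, "model_spec"))
  n <- nrow(nodes)
  if (n < 2) return(0)
  kinds <- vapply(spec$terms, `[[`, character(1), "kind")
  if (any(kinds == "edgecov")) {
    stop("expected_edges supports attribute-based terms only", call. = FALSE)
  }
  used <- unlist(lapply(spec$terms, function(t)
    if (t$kind %in% c("nodematch", "nodematch_diff", "nodemix")) t$attribute))
  if (!length(used)) {
    k <- 1L
    x <- matrix(1, 1, 1, dimnames = list(NULL, "edges"))
    return(choose(n, 2) * stats::plogis(drop(x %*% theta)))
  }
  prof <- do.call(paste, c(lapply(used, function(a)
    as.character(nodes[[a]])), sep = "\r"))
  first <- which(!duplicated(prof))
  counts <- as.integer(table(factor(prof, levels = prof[first])))
  m <- length(first)
  # representative endpoint pairs for every unordered class pair (a <= b)
  ai <- bi <- integer(0)
  na <- nb <- integer(0)
  for (a in seq_len(m)) {
    for (b in a:m) {
      ai <- c(ai, first[a]); bi <- c(bi, first[b])
      na <- c(na, counts[a]); nb <- c(nb, counts[b])
    }
  }
  blocks <- lapply(spec$terms, .term_columns, nodes = nodes, ai = ai, bi = bi)
  X <- do.call(cbind, blocks)
  if (length(theta) != ncol(X)) {
    stop("theta has length ", length(theta), " but the model has ",
         ncol(X), " parameter column(s)", call. = FALSE)
  }
  p <- stats::plogis(drop(X %*% theta))
  ndyads <- ifelse(ai == bi, choose(na, 2), na * nb)
  sum(ndyads * p)
}

#' Smallest node count reaching a target expected edge count
#'
#' Inverts [expected_edges()] by integer search: returns the smallest `n`
#' such that a node table generated by [generate_attributes()] with the given
#' proportions yields `expected_edges(n) >= target_edges`.
#'
#' @param target_edges target expected edge count (`>= 1`).
#' @param attribute_specs as in [generate_attributes()].
#' @param spec a [model_spec()] over those attributes.
#' @param theta coefficient vector for `spec`.
#' @param max_n search cap; exceeding it raises an "unreachable" error.
#' @return Integer node count.
#' @examples
#' nodes_for_expected_edges(806, list(sex = c(F = .5, M = .5)),
#'                          model_spec(term_edges()), -4) # 300
#' @export
nodes_for_expected_edges <- function(target_edges, attribute_specs, spec,
                                     theta, max_n = 1e6) {
  stopifnot(target_edges >= 1)
  min_n <- max(2L, max(vapply(attribute_specs, function(p)
    sum((if (is.list(p)) p$proportions else p) > 0), integer(1))))
  f <- function(n) expected_edges(
    generate_attributes(n, attribute_specs, seed = 1), spec, theta)
  hi <- min_n
  while (f(hi) < target_edges) {
    if (hi >= max_n) {
      stop("target of ", target_edges, " expected edges unreachable below n = ",
           max_n, call. = FALSE)
    }
    hi <- min(2L * hi, as.integer(max_n))
  }
  lo <- min_n
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (f(mid) >= target_edges) hi <- mid else lo <- mid
  }
  # quota rounding can make f locally flat; walk down over any flat run
  while (hi > min_n && f(hi - 1L) >= target_edges) hi <- hi - 1L
  as.integer(hi)
}

#' The default seven-model candidate family
#'
#' Candidate models over a binary attribute (`sex`, levels 1/2) and a
#' three-level attribute (`site`, levels A/B/C), spanning the three homophily
#' classes — simple match, differential match and mixing — and their
#' combinations with the sex match term:
#' edges-only; + nodematch(sex); + nodematch(site); + nodematch_diff(site);
#' + nodemix(site); + nodematch(sex) + nodematch_diff(site);
#' + nodematch(sex) + nodemix(site).
#'
#' @return Named list of seven [model_spec()] objects.
#' @export
default_model_family <- function() {
  list(
    edges = model_spec(term_edges(), label = "edges"),
    sexmatch = model_spec(term_nodematch("sex"), label = "sexmatch"),
    sitematch = model_spec(term_nodematch("site"), label = "sitematch"),
    sitediff = model_spec(term_nodematch_diff("site"), label = "sitediff"),
    sitemix = model_spec(term_nodemix("site"), label = "sitemix"),
    sexmatch_sitediff = model_spec(term_nodematch("sex"),
                                   term_nodematch_diff("site"),
                                   label = "sexmatch_sitediff"),
    sexmatch_sitemix = model_spec(term_nodematch("sex"),
                                  term_nodemix("site"),
                                  label = "sexmatch_sitemix")
  )
}

#' Attribute proportions used with the default family
#' @return Named list: equal sexes, equal thirds across three sites.
#' @export
default_family_attributes <- function() {
  list(sex = c("1" = 0.5, "2" = 0.5),
       site = c(A = 1 / 3, B = 1 / 3, C = 1 / 3))
}

# Truth coefficients for a design's columns. Level-specific terms get
# distinct values so that differential-match and mixing structures are
# identifiable against the simpler match model (equal coefficients across
# levels would collapse them onto it).
.truth_for_columns <- function(cols, theta0 = -4, match_effect = 0.75,
                               diff_effects = c(0.5, 1.0, 1.5),
                               mix_effects = c(0.3, 0.6, 0.75, 1.0, 1.5)) {
  th <- numeric(length(cols))
  names(th) <- cols
  di <- mi <- 0L
  for (i in seq_along(cols)) {
    nm <- cols[i]
    if (nm == "edges") th[i] <- theta0
    else if (startsWith(nm, "nodematch_diff.")) {
      di <- di + 1L
      th[i] <- diff_effects[((di - 1L) %% length(diff_effects)) + 1L]
    } else if (startsWith(nm, "nodemix.")) {
      mi <- mi + 1L
      th[i] <- mix_effects[((mi - 1L) %% length(mix_effects)) + 1L]
    } else if (startsWith(nm, "nodematch.")) th[i] <- match_effect
    else th[i] <- match_effect
  }
  th
}

#' Default truth coefficients for a candidate family
#'
#' For each candidate, a named coefficient vector aligned with the design
#' columns the model produces on `nodes`: intercept `theta0 = -4` (the
#' baseline used throughout the simulation studies), `0.75` for simple match
#' terms, and distinct per-level values for differential-match
#' (`0.5, 1.0, 1.5`) and mixing (`0.3, 0.6, 0.75, 1.0, 1.5`) terms so that
#' each model class is distinguishable from the simpler ones it nests.
#'
#' @param family named list of [model_spec()]s.
#' @param nodes a [node_table()] carrying the family's attributes.
#' @param theta0 baseline log-odds.
#' @return Named list of coefficient vectors, parallel to `family`.
#' @export
default_family_truth <- function(family = default_model_family(),
                                 nodes = generate_attributes(
                                   300, default_family_attributes(), seed = 1),
                                 theta0 = -4) {
  lapply(family, function(spec) {
    cols <- colnames(.design_matrix(nodes, spec)$X)
    .truth_for_columns(cols, theta0 = theta0)
  })
}

#' Synthetic Avar-like cemetery fixture
#'
#' Generates a reproducible stand-in for a 4-site, 2-period-era Carpathian
#' Basin cemetery cohort: 237 individuals across sites HNJ, KFJ, KUP and RK,
#' with genetic sex, age class (adult/subadult), their composite, and burial
#' orientation. The generating model has strong differential site homophily
#' (within-site folds in the hundreds, RK markedly less inter-related),
#' sex/age mixing shaped like a patrilocal system (adult-male pairs far more
#' likely to connect than adult-female pairs), and an orientation-match
#' effect. The generating coefficients are returned so parameter recovery can
#' be asserted. Pairwise IBD summaries consistent with the simulated edges
#' (plus low-level background sharing below any sensible cutoff) are included
#' so that thresholding and cutoff-sensitivity analyses can run end to end.
#'
#' This fixture is synthetic: it emulates the structure of an empirical
#' cohort, not its data.
#'
#' @param seed integer seed.
#' @param n number of individuals.
#' @return List with `nodes`, `spec`, `theta` (named generating
#'   coefficients), `network` (a simulated draw), `pairs` (summary-format IBD
#'   records) and `rule` (the default two-block threshold rule, under which
#'   `threshold_network(pairs, nodes, rule)` reproduces `network`).
#' @examples
#' fx <- make_avar_fixture(seed = 1)
#' fx$network
#' @export
make_avar_fixture <- function(seed = 1, n = 237) {
  specs <- list(
    site = c(HNJ = 0.25, KFJ = 0.21, KUP = 0.14, RK = 0.40),
    sex = c(F = 0.5, M = 0.5),
    age = c(Adult = 0.7, Subadult = 0.3),
    orientation = c("NW-SE" = 0.6, "W-E" = 0.4)
  )
  nodes <- generate_attributes(n, specs, seed = seed)
  nodes <- combine_attributes(nodes, c("age", "sex"), "sexage")
  spec <- model_spec(
    term_nodematch_diff("site"),
    term_nodemix("sexage", base_cell = c("Adult.F", "Adult.M")),
    term_nodematch("orientation"),
    label = "avar_fixture"
  )
  # log fold-changes in the spirit of a strongly site-structured, patrilocal
  # cohort: sparse between-site baseline, within-site folds in the hundreds,
  # adult-male homophily, adult-female exogamy signal
  theta <- c(
    edges = -7.5,
    nodematch_diff.site.HNJ = 6.65,
    nodematch_diff.site.KFJ = 7.35,
    nodematch_diff.site.KUP = 7.20,
    nodematch_diff.site.RK = 5.55,
    nodemix.sexage.Adult.F.Adult.F = log(0.256),
    nodemix.sexage.Adult.F.Subadult.F = log(0.89),
    nodemix.sexage.Adult.F.Subadult.M = log(1.18),
    nodemix.sexage.Adult.M.Adult.M = log(6.62),
    nodemix.sexage.Adult.M.Subadult.F = log(7.29),
    nodemix.sexage.Adult.M.Subadult.M = log(7.12),
    nodemix.sexage.Subadult.F.Subadult.F = log(4.40),
    nodemix.sexage.Subadult.F.Subadult.M = log(9.14),
    nodemix.sexage.Subadult.M.Subadult.M = log(12.8),
    nodematch.orientation = 1.051
  )
  dm <- .design_matrix(nodes, spec)
  if (!identical(colnames(dm$X), names(theta))) {
    # realign defensively (column construction is deterministic, but keep
    # the fixture robust to level-ordering changes)
    theta <- theta[colnames(dm$X)]
  }
  net <- simulate_network(nodes, spec, theta, seed = .rep_seed(seed, 1))
  # IBD summaries: qualifying totals/blocks on edges, sub-threshold
  # background sharing on a sprinkling of non-edges
  pairs <- .with_seed(.rep_seed(seed, 2), {
    m <- nrow(net$edges)
    edge_pairs <- data.frame(
      id1 = nodes$id[net$edges$i],
      id2 = nodes$id[net$edges$j],
      stringsAsFactors = FALSE
    )
    edge_pairs$n_ge16 <- 1L + stats::rpois(m, 0.8)
    edge_pairs$n_ge12 <- edge_pairs$n_ge16 + 1L + stats::rpois(m, 1.2)
    edge_pairs$total_cM <- 16 + stats::rgamma(m, shape = 2, scale = 30)
    d <- .dyads(n)
    on <- logical(length(d$i))
    if (m) on[(net$edges$j - 1) * (net$edges$j - 2) / 2 + net$edges$i] <- TRUE
    bg <- which(!on)
    bg <- bg[stats::runif(length(bg)) < 0.015]
    bg_pairs <- data.frame(
      id1 = nodes$id[d$i[bg]],
      id2 = nodes$id[d$j[bg]],
      n_ge16 = 0L,
      n_ge12 = 0L,
      total_cM = stats::runif(length(bg), 0, 11),
      stringsAsFactors = FALSE
    )
    rbind(edge_pairs[, c("id1", "id2", "n_ge12", "n_ge16", "total_cM")],
          bg_pairs)
  })
  list(nodes = nodes, spec = spec, theta = theta, network = net,
       pairs = pairs, rule = two_block_rule())
}
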