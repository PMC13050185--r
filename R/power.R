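# Empirical power of the Wald test for a homophily coefficient, and
# minimum-detectable-effect analysis against expected network size.

# Shared simulation/fit context for power runs: intercept + nodematch on a
# binary attribute. The design depends only on the node table, so it is
# built (and its covariate patterns grouped) once; each replicate draws a
# fresh response and refits.
.power_context <- function(n, proportions, seed) {
  nodes <- generate_attributes(n, list(sex = proportions), seed = seed)
  spec <- model_spec(term_nodematch("sex"), label = "sexmatch")
  dm <- .design_matrix(nodes, spec)
  agg <- .aggregate_design(dm$X)
  list(nodes = nodes, spec = spec, X = dm$X, agg = agg,
       N = nrow(dm$X), match_col = 2L)
}

# One power estimate: fraction of replicates whose Wald test on the match
# coefficient rejects at alpha. Degenerate replicates (empty or complete
# graphs) count as non-rejections; their count is returned.
.power_at <- function(ctx, theta0, theta1, reps, alpha, seed,
                      seed_offset = 0) {
  p <- stats::plogis(drop(ctx$X %*% c(theta0, theta1)))
  reject <- 0L
  degenerate <- 0L
  for (r in seq_len(reps)) {
    y <- .with_seed(.rep_seed(seed, seed_offset + r),
                    stats::rbinom(ctx$N, 1L, p))
    s <- drop(rowsum(y, ctx$agg$g))
    tot <- sum(s)
    if (tot == 0 || tot == ctx$N) {
      degenerate <- degenerate + 1L
      next
    }
    core <- .fit_core(ctx$agg$Xg, ctx$agg$m, s)
    if (core$separated[ctx$match_col]) next
    se <- sqrt(max(diag(core$vcov)[ctx$match_col], 0))
    if (se <= 0) next
    pv <- 2 * stats::pnorm(-abs(core$beta[ctx$match_col] / se))
    if (pv <= alpha) reject <- reject + 1L
  }
  list(power = reject / reps, degenerate = degenerate)
}

#' Empirical power curve for a homophily coefficient
#'
#' For each value on the effect grid, simulates `reps` networks from the
#' intercept + nodematch model on a binary attribute, fits the same model to
#' each, and records the fraction of replicates in which the two-sided Wald
#' test on the match coefficient rejects at level `alpha`. Degenerate
#' replicates (no edges, or all dyads connected) count as non-rejections and
#' are flagged.
#'
#' @param theta1_grid strictly increasing vector of true match coefficients
#'   (the canonical grid is 0 to 1 in steps of 0.05).
#' @param n nodes per network.
#' @param proportions named length-2 vector of group proportions (sums to 1).
#' @param theta0 baseline log-odds (default -4, the sparse-network regime).
#' @param reps replicates per grid value.
#' @param alpha significance level for the Wald test.
#' @param seed experiment seed.
#' @return A `power_curve` data frame: `theta1`, `fold` (probability
#'   fold-increase at the baseline), `power`, `reps`, `n_degenerate`.
#' @examples
#' empirical_power(c(0, 0.5), n = 100, reps = 20, seed = 1)
#' @export
empirical_power <- function(theta1_grid, n = 300,
                            proportions = c("1" = 0.5, "2" = 0.5),
                            theta0 = -4, reps = 100, alpha = 0.05,
                            seed = 1) {
  stopifnot(reps >= 1, alpha > 0, alpha < 1,
            !is.unsorted(theta1_grid, strictly = TRUE))
  ctx <- .power_context(n, proportions, seed)
  out <- data.frame(theta1 = theta1_grid,
                    fold = vapply(theta1_grid, function(t1)
                      fold_change(theta0, t1), numeric(1)),
                    power = NA_real_, reps = reps, n_degenerate = 0L)
  for (gi in seq_along(theta1_grid)) {
    res <- .power_at(ctx, theta0, theta1_grid[gi], reps, alpha, seed,
                     seed_offset = (gi - 1L) * reps)
    out$power[gi] <- res$power
    out$n_degenerate[gi] <- res$degenerate
  }
  attr(out, "design") <- list(n = n, proportions = proportions,
                              theta0 = theta0, alpha = alpha, seed = seed)
  class(out) <- c("power_curve", "data.frame")
  out
}

#' Minimum detectable effect versus expected network size
#'
#' For each target expected edge count, sizes the network via
#' [nodes_for_expected_edges()] (at the baseline, zero-effect model), then
#' bisects over the match coefficient — to a resolution of `resolution` —
#' for the smallest coefficient whose empirical power reaches
#' `target_power`, and converts it to a probability fold-increase at the
#' baseline. Power decreases with network size, so the minimal detectable
#' fold shrinks as the expected edge count grows.
#'
#' @param edge_grid vector of target expected edge counts.
#' @param target_power required power (conventionally 0.8).
#' @param theta0 baseline log-odds.
#' @param proportions binary group proportions.
#' @param reps replicates per power evaluation.
#' @param alpha significance level.
#' @param seed experiment seed.
#' @param theta_max search ceiling; a target unattainable for
#'   `theta1 <= theta_max` is recorded as not found.
#' @param resolution bisection resolution on the coefficient scale.
#' @return An `mde_result` data frame: `expected_edges`, `n`, `theta1`
#'   (minimal coefficient), `fold`, `found`.
#' @examples
#' min_detectable_effect(100, reps = 20, seed = 1)
#' @export
min_detectable_effect <- function(edge_grid, target_power = 0.8,
                                  theta0 = -4,
                                  proportions = c("1" = 0.5, "2" = 0.5),
                                  reps = 100, alpha = 0.05, seed = 1,
                                  theta_max = 3, resolution = 0.01) {
  stopifnot(target_power > 0, target_power < 1)
  base_spec <- model_spec(term_nodematch("sex"), label = "sexmatch")
  out <- data.frame(expected_edges = edge_grid, n = NA_integer_,
                    theta1 = NA_real_, fold = NA_real_, found = FALSE)
  eval_counter <- 0L
  for (gi in seq_along(edge_grid)) {
    n <- nodes_for_expected_edges(edge_grid[gi],
                                  list(sex = proportions),
                                  base_spec, c(theta0, 0))
    ctx <- .power_context(n, proportions, seed)
    pw <- function(t1) {
      eval_counter <<- eval_counter + 1L
      .power_at(ctx, theta0, t1, reps, alpha, seed,
                seed_offset = eval_counter * reps)$power
    }
    out$n[gi] <- n
    if (pw(theta_max) < target_power) next
    lo <- 0
    hi <- theta_max
    while (hi - lo > resolution) {
      mid <- (lo + hi) / 2
      if (pw(mid) >= target_power) hi <- mid else lo <- mid
    }
    out$theta1[gi] <- hi
    out$fold[gi] <- fold_change(theta0, hi)
    out$found[gi] <- TRUE
  }
  attr(out, "design") <- list(target_power = target_power, theta0 = theta0,
                              proportions = proportions, reps = reps,
                              alpha = alpha, seed = seed)
  class(out) <- c("mde_result", "data.frame")
  out
}
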