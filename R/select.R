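# Model selection among candidate dyad-independent models, the
# confusion-matrix experiment, and cutoff-sensitivity analysis.

# Argmin with ties broken toward smaller k, then candidate order.
.choose_min <- function(crit, k) {
  ord <- order(crit, k, seq_along(crit))
  ord[1]
}

#' Select among candidate models on one network
#'
#' Fits every candidate on the same dyad set and picks a winner. For
#' `criterion` in BIC / AIC / AICc the winner minimises the criterion, with
#' ties broken toward fewer parameters and then candidate order. For
#' `criterion = "pvalue"` a backward-elimination baseline is used instead:
#' starting from the largest candidate, the term whose coefficient block has
#' the largest Wald p-value is dropped while that p-value exceeds `alpha`,
#' refitting after each drop; the surviving term set is matched back to a
#' candidate when one has the same terms.
#'
#' @param net a `kin_network`.
#' @param candidates named list of [model_spec()] objects.
#' @param criterion `"BIC"` (default), `"AIC"`, `"AICc"` or `"pvalue"`.
#' @param alpha retention threshold for the p-value strategy.
#' @return A `model_selection`: comparison table (label, k, logLik, BIC,
#'   AIC, AICc), the chosen label, the chosen fit, and all fits. Candidates
#'   that fail to fit are recorded as failed and excluded from the argmin
#'   (with a warning).
#' @examples
#' fam <- default_model_family()
#' nt <- generate_attributes(80, default_family_attributes(), seed = 1)
#' net <- simulate_network(nt, fam$sexmatch, c(-2, 0.8), seed = 2)
#' select_model(net, fam[c("edges", "sexmatch")])
#' @export
select_model <- function(net, candidates,
                         criterion = c("BIC", "AIC", "AICc", "pvalue"),
                         alpha = 0.05) {
  stopifnot(inherits(net, "kin_network"), length(candidates) >= 1)
  criterion <- match.arg(criterion)
  if (is.null(names(candidates))) {
    names(candidates) <- vapply(candidates, model_label, character(1))
  }
  fits <- lapply(candidates, function(spec) {
    tryCatch(fit_dyad_ergm(build_design(net, spec)),
             error = function(e) structure(list(message = conditionMessage(e)),
                                           class = "kin_fit_failure"))
  })
  failed <- vapply(fits, inherits, logical(1), what = "kin_fit_failure")
  if (any(failed)) {
    warning("candidate(s) failed to fit: ",
            paste(names(candidates)[failed], collapse = ", "), call. = FALSE)
  }
  num <- function(f, what) if (inherits(f, "kin_fit_failure")) NA_real_
                           else f[[what]]
  tab <- data.frame(
    model = names(candidates),
    k = vapply(fits, num, numeric(1), "k"),
    logLik = vapply(fits, num, numeric(1), "loglik"),
    BIC = vapply(fits, num, numeric(1), "bic"),
    AIC = vapply(fits, num, numeric(1), "aic"),
    AICc = vapply(fits, num, numeric(1), "aicc"),
    failed = failed,
    stringsAsFactors = FALSE
  )
  ok <- which(!failed)
  if (!length(ok)) stop("no candidate could be fitted", call. = FALSE)
  if (criterion == "pvalue") {
    chosen_idx <- .backward_eliminate(net, candidates, fits, ok, alpha)
    chosen <- names(candidates)[chosen_idx$index]
    chosen_fit <- chosen_idx$fit
  } else {
    crit <- tab[[criterion]][ok]
    pick <- ok[.choose_min(crit, tab$k[ok])]
    chosen <- names(candidates)[pick]
    chosen_fit <- fits[[pick]]
  }
  structure(list(table = tab, criterion = criterion, chosen = chosen,
                 chosen_fit = chosen_fit, fits = fits, alpha = alpha),
            class = "model_selection")
}

# Backward elimination from the largest fitted candidate. A term block's
# p-value is the largest Wald p among its columns; the worst block is
# dropped while above alpha. Returns the index of the matching candidate
# (or the starting candidate if no exact term match) plus the final fit.
.backward_eliminate <- function(net, candidates, fits, ok, alpha) {
  ks <- vapply(fits[ok], function(f) f$k, numeric(1))
  start <- ok[which.max(ks)]
  spec <- candidates[[start]]
  fit <- fits[[start]]
  repeat {
    nt <- length(spec$terms)
    if (nt <= 1) break
    blockp <- vapply(2:nt, function(t)
      max(fit$p_value[fit$term_of == t], na.rm = TRUE), numeric(1))
    worst <- which.max(blockp)
    if (!is.finite(blockp[worst]) || blockp[worst] <= alpha) break
    spec <- model_spec(spec$terms[-(worst + 1)],
                       label = paste0(model_label(spec), "-reduced"))
    fit <- fit_dyad_ergm(build_design(net, spec))
  }
  sig <- function(s) paste(sort(vapply(s$terms, function(t)
    paste(t$kind, t$attribute %||% "", sep = ":"), character(1))),
    collapse = "|")
  match_idx <- which(vapply(candidates, function(c) sig(c) == sig(spec),
                            logical(1)))
  list(index = if (length(match_idx)) match_idx[1] else start, fit = fit)
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection by", x$criterion, "\n")
  tab <- x$table
  tab$logLik <- round(tab$logLik, 2)
  tab$BIC <- round(tab$BIC, 2)
  tab$AIC <- round(tab$AIC, 2)
  tab$AICc <- round(tab$AICc, 2)
  print(tab, row.names = FALSE)
  cat("Chosen:", x$chosen, "\n")
  invisible(x)
}

#' Confusion-matrix experiment for model selection
#'
#' For each model in the family, simulates `reps` networks from its truth
#' coefficients, runs selection over the whole family, and tallies which
#' model was selected. With the default family, n = 300 nodes and BIC, the
#' matrix is diagonal: every realisation is assigned to its generating model.
#'
#' @param family named list of [model_spec()]s.
#' @param truth named list of coefficient vectors, parallel to `family`
#'   (default: [default_family_truth()] on the generated nodes).
#' @param n_nodes nodes per simulated network.
#' @param reps replicates per true model.
#' @param seed experiment seed; replicate `r` of model `m` derives its own
#'   seed, so runs are reproducible.
#' @param criterion selection criterion passed through to the argmin.
#' @param attribute_specs proportions for [generate_attributes()].
#' @return A `confusion_matrix`: counts (rows = true model, columns =
#'   selected model plus a `failed` column), replicate count, accuracy
#'   (trace over total) and per-model specificity.
#' @examples
#' fam <- default_model_family()[c("edges", "sexmatch")]
#' confusion_experiment(fam, reps = 2, n_nodes = 100, seed = 1)
#' @export
confusion_experiment <- function(family = default_model_family(),
                                 truth = NULL,
                                 n_nodes = 300, reps = 100, seed = 1,
                                 criterion = c("BIC", "AIC", "AICc"),
                                 attribute_specs =
                                   default_family_attributes()) {
  stopifnot(reps >= 1, length(family) >= 1)
  criterion <- match.arg(criterion)
  if (is.null(names(family))) {
    names(family) <- vapply(family, model_label, character(1))
  }
  nodes <- generate_attributes(n_nodes, attribute_specs, seed = seed)
  if (is.null(truth)) truth <- default_family_truth(family, nodes)
  stopifnot(identical(names(truth), names(family)))
  ctx <- lapply(family, function(spec) {
    dm <- .design_matrix(nodes, spec)
    agg <- .aggregate_design(dm$X)
    c(agg, list(k = ncol(dm$X), X = dm$X))
  })
  N <- choose(n_nodes, 2)
  labels <- names(family)
  tally <- matrix(0L, nrow = length(family), ncol = length(family) + 1,
                  dimnames = list(true = labels,
                                  selected = c(labels, "failed")))
  counter <- 0L
  for (mi in seq_along(family)) {
    p_true <- stats::plogis(drop(ctx[[mi]]$X %*% truth[[mi]]))
    for (r in seq_len(reps)) {
      counter <- counter + 1L
      y <- .with_seed(.rep_seed(seed, counter),
                      stats::rbinom(N, 1L, p_true))
      crit <- k <- numeric(length(family))
      bad <- logical(length(family))
      for (ci in seq_along(family)) {
        cc <- ctx[[ci]]
        s <- drop(rowsum(y, cc$g))
        core <- tryCatch(.fit_core(cc$Xg, cc$m, s), error = function(e) NULL)
        if (is.null(core)) { bad[ci] <- TRUE; next }
        ic <- information_criteria(core$loglik, cc$k, N)
        crit[ci] <- ic[[criterion]]
        k[ci] <- cc$k
      }
      if (all(bad)) {
        tally[mi, "failed"] <- tally[mi, "failed"] + 1L
      } else {
        okc <- which(!bad)
        pick <- okc[.choose_min(crit[okc], k[okc])]
        tally[mi, pick] <- tally[mi, pick] + 1L
      }
    }
  }
  structure(list(counts = tally, reps = reps, criterion = criterion,
                 n_nodes = n_nodes, seed = seed,
                 accuracy = sum(diag(tally[, seq_along(family),
                                           drop = FALSE])) / sum(tally)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Model-selection confusion matrix (", x$criterion, ", ",
      x$reps, " reps, n = ", x$n_nodes, " nodes)\n", sep = "")
  print(x$counts)
  cat(sprintf("Accuracy: %.3f\n", x$accuracy))
  invisible(x)
}

#' Sensitivity of the selected model to the IBD threshold
#'
#' Re-thresholds the pairwise IBD data under each rule, reruns model
#' selection on each network, and reports which variables (term attributes)
#' are significant at `alpha` under each rule, together with their
#' intersection and union. Rules producing an empty edge set are flagged
#' degenerate and excluded from the stability summary.
#'
#' @param pairs pairwise IBD records (see [threshold_network()]).
#' @param nodes a [node_table()].
#' @param rules list of at least two `threshold_rule`s.
#' @param candidates named list of [model_spec()]s.
#' @param criterion,alpha passed to [select_model()]; `alpha` also defines
#'   significance in the stability report.
#' @return A `cutoff_sensitivity`: per-rule selection results, per-rule
#'   significant-variable sets, the stable (intersection) and ever-seen
#'   (union) sets, and degenerate flags.
#' @export
cutoff_sensitivity <- function(pairs, nodes, rules, candidates,
                               criterion = "BIC", alpha = 0.05) {
  stopifnot(length(rules) >= 2)
  per_rule <- lapply(rules, function(rule) {
    net <- threshold_network(pairs, nodes, rule)
    if (n_edges(net) == 0) {
      return(list(rule = rule, degenerate = TRUE, selection = NULL,
                  significant = character(0)))
    }
    sel <- select_model(net, candidates, criterion = criterion, alpha = alpha)
    fit <- sel$chosen_fit
    terms <- fit$spec$terms
    sig_attr <- character(0)
    for (t in seq_along(terms)[-1]) {
      pv <- fit$p_value[fit$term_of == t]
      if (any(pv <= alpha, na.rm = TRUE)) {
        sig_attr <- c(sig_attr, terms[[t]]$attribute %||% terms[[t]]$kind)
      }
    }
    list(rule = rule, degenerate = FALSE, selection = sel,
         significant = unique(sig_attr))
  })
  degen <- vapply(per_rule, `[[`, logical(1), "degenerate")
  sets <- lapply(per_rule[!degen], `[[`, "significant")
  structure(list(
    per_rule = per_rule,
    degenerate = degen,
    stable = if (length(sets)) Reduce(intersect, sets) else character(0),
    ever = if (length(sets)) Reduce(union, sets) else character(0)
  ), class = "cutoff_sensitivity")
}

#' @export
print.cutoff_sensitivity <- function(x, ...) {
  cat("Cutoff sensitivity over", length(x$per_rule), "rule(s);",
      sum(x$degenerate), "degenerate\n")
  for (i in seq_along(x$per_rule)) {
    pr <- x$per_rule[[i]]
    if (pr$degenerate) {
      cat(sprintf("  rule %d: DEGENERATE (empty edge set)\n", i))
    } else {
      cat(sprintf("  rule %d: chosen %s; significant: %s\n", i,
                  pr$selection$chosen,
                  paste(pr$significant, collapse = ", ")))
    }
  }
  cat("Stable (intersection):", paste(x$stable, collapse = ", "), "\n")
  cat("Union:", paste(x$ever, collapse = ", "), "\n")
  invisible(x)
}
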