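# Human-readable summary of a selected model: one row per non-intercept
# coefficient with its attribute, level(s), fold-change, p-value and term
# type (Match / Diff / Mix), in the style of a published ERGM results table.

#' Summary table of a fitted or selected model
#'
#' One row per non-intercept coefficient: the variable (attribute), the
#' level or level pair, the fold-increase in connection probability at the
#' fitted baseline, the raw two-sided Wald p-value (no multiple-testing
#' correction is applied), and the term type. Rows not significant at
#' `alpha` are flagged; separated coefficients carry an infinite fold.
#'
#' @param x a `kin_fit` or `model_selection`.
#' @param alpha significance flag threshold.
#' @return Data frame with columns `variable`, `level`, `fold`,
#'   `odds_ratio`, `p_value`, `type`, `significant`, `separated`.
#' @examples
#' fx <- make_avar_fixture(seed = 1)
#' fit <- fit_dyad_ergm(build_design(fx$network, fx$spec))
#' summary_table(fit)
#' @export
summary_table <- function(x, alpha = 0.05) {
  fit <- if (inherits(x, "model_selection")) x$chosen_fit else x
  stopifnot(inherits(fit, "kin_fit"))
  if (!fit$converged && !any(fit$separated)) {
    stop("summary_table requires a converged fit", call. = FALSE)
  }
  cols <- names(fit$coefficients)
  keep <- which(cols != "edges")
  type_map <- c(nodematch = "Match", nodematch_diff = "Diff",
                nodemix = "Mix", edgecov = "Edgecov")
  rows <- lapply(keep, function(j) {
    parts <- strsplit(cols[j], ".", fixed = TRUE)[[1]]
    kind <- parts[1]
    term <- fit$spec$terms[[fit$term_of[j]]]
    attribute <- term$attribute %||% ""
    rest <- if (length(parts) > 1) parts[-1] else character(0)
    rest <- rest[-1]  # drop the attribute name prefix; keep only levels
    level <- switch(kind,
      nodematch = "Match",
      nodematch_diff = paste(rest, collapse = "."),
      nodemix = {
        # levels may themselves contain the separator; split evenly
        h <- length(rest) %/% 2
        paste(paste(rest[seq_len(h)], collapse = "."),
              paste(rest[-seq_len(h)], collapse = "."), sep = "/")
      },
      edgecov = "",
      paste(rest, collapse = "."))
    data.frame(variable = attribute,
               level = level,
               fold = if (fit$separated[j]) Inf else fit$fold[j],
               odds_ratio = if (fit$separated[j]) Inf else fit$odds_ratio[j],
               p_value = fit$p_value[j],
               type = unname(type_map[kind]) %||% kind,
               significant = isTRUE(fit$p_value[j] <= alpha),
               separated = fit$separated[j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("kin_summary_table", "data.frame")
  out
}

#' Format a summary table for display or CSV export
#'
#' Renders folds to two decimals, p-values below `1e-4` as `"<1e-4"`, and
#' marks non-significant rows. `path` writes the formatted table as CSV.
#'
#' @param x a [summary_table()] result.
#' @param path optional CSV output path.
#' @return Character data frame (invisibly when writing to `path`).
#' @export
format_summary_table <- function(x, path = NULL) {
  stopifnot(inherits(x, "kin_summary_table"))
  fmt <- data.frame(
    Variable = x$variable,
    Level = x$level,
    Fold = ifelse(is.infinite(x$fold), "Inf",
                  formatC(x$fold, digits = 2, format = "f")),
    P = ifelse(is.na(x$p_value), "NA",
               ifelse(x$p_value < 1e-4, "<1e-4",
                      formatC(x$p_value, digits = 3, format = "g"))),
    Type = x$type,
    Significant = ifelse(x$significant, "", "ns"),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.csv(fmt, path, row.names = FALSE)
    return(invisible(fmt))
  }
  fmt
}

#' @export
print.kin_summary_table <- function(x, ...) {
  print(format_summary_table(x), row.names = FALSE)
  invisible(x)
}
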