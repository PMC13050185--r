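# Shared builders and oracles for the test suite.

# Small node table with given attribute vectors (characters).
make_nodes <- function(...) {
  vals <- list(...)
  n <- length(vals[[1]])
  df <- data.frame(id = paste0("v", seq_len(n)), stringsAsFactors = FALSE)
  for (a in names(vals)) df[[a]] <- vals[[a]]
  node_table(df)
}

# Network from an explicit i/j edge list on a node table.
make_net <- function(nodes, i = integer(0), j = integer(0), weight = NULL) {
  e <- data.frame(i = i, j = j)
  if (!is.null(weight)) e$weight <- weight
  kin_network(nodes, e)
}

# Independent MLE oracle: generic optimiser on the Bernoulli dyad
# log-likelihood, no IRLS involved.
optim_mle <- function(X, y) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  fit$par
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Dyad position of (i, j), i < j, in the package's enumeration order.
dyad_pos <- function(i, j) (j - 1) * (j - 2) / 2 + i

# All dyads i < j with a match indicator for one attribute.
all_dyads_match <- function(nodes, attr) {
  n <- nrow(nodes)
  j <- rep.int(2:n, 1:(n - 1))
  i <- sequence(1:(n - 1))
  v <- as.character(nodes[[attr]])
  list(i = i, j = j, match = as.numeric(v[i] == v[j]))
}
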