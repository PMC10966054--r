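# Independent oracles used by the test suite. Deliberately share no code with
# the package internals: a dense two-phase tableau simplex with Bland's rule
# for the transportation LP, plus small graph/distribution generators.

# min c'x s.t. Ax = b, x >= 0 (b >= 0). Returns list(value, x).
oracle_simplex_lp <- function(cc, A, b) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  # Phase I tableau with artificial variables
  Tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  obj <- c(rep(0, n), rep(1, m))
  pivot <- function(Tab, r, cl) {
    Tab[r, ] <- Tab[r, ] / Tab[r, cl]
    for (i in seq_len(nrow(Tab))) if (i != r && abs(Tab[i, cl]) > 1e-13)
      Tab[i, ] <- Tab[i, ] - Tab[i, cl] * Tab[r, ]
    Tab
  }
  run_simplex <- function(Tab, basis, obj, ncols) {
    repeat {
      # reduced costs (Bland: first negative)
      y <- obj[basis]
      red <- obj[seq_len(ncols)] - as.vector(y %*% Tab[, seq_len(ncols), drop = FALSE])
      ent <- which(red < -1e-10)[1L]
      if (is.na(ent)) return(list(Tab = Tab, basis = basis))
      col <- Tab[, ent]
      ratios <- ifelse(col > 1e-12, Tab[, ncol(Tab)] / col, Inf)
      if (all(!is.finite(ratios))) stop("unbounded LP")
      lv <- which(ratios == min(ratios))
      lv <- lv[which.min(basis[lv])] # Bland tie-break on leaving variable
      basis[lv] <- ent
      Tab <- pivot(Tab, lv, ent)
    }
  }
  ph1 <- run_simplex(Tab, basis, obj, n + m)
  y <- obj[ph1$basis]
  val1 <- sum(y * ph1$Tab[, ncol(ph1$Tab)])
  if (val1 > 1e-8) stop("infeasible LP")
  Tab <- ph1$Tab; basis <- ph1$basis
  # drive out any artificial variables still basic (degenerate rows)
  for (r in seq_len(m)) {
    if (basis[r] > n) {
      cl <- which(abs(Tab[r, seq_len(n)]) > 1e-10)[1L]
      if (!is.na(cl)) { basis[r] <- cl; Tab <- pivot(Tab, r, cl) }
    }
  }
  keep_rows <- basis <= n
  Tab2 <- Tab[keep_rows, c(seq_len(n), ncol(Tab)), drop = FALSE]
  basis2 <- basis[keep_rows]
  ph2 <- run_simplex(Tab2, basis2, c(cc, 0), n)
  x <- numeric(n)
  x[ph2$basis] <- ph2$Tab[, ncol(ph2$Tab)]
  list(value = sum(cc * x), x = x)
}

# exact 1-Wasserstein via the oracle simplex on the full transportation LP
oracle_ot <- function(D, p, q) {
  sp <- which(p > 0); sq <- which(q > 0)
  m <- length(sp); n <- length(sq)
  cc <- as.vector(D[sp, sq, drop = FALSE]) # column-major: x[(j-1)*m + i]
  A <- matrix(0, m + n, m * n)
  for (i in seq_len(m)) A[i, (seq_len(n) - 1L) * m + i] <- 1
  for (j in seq_len(n)) A[m + j, (j - 1L) * m + seq_len(m)] <- 1
  # drop one redundant constraint
  oracle_simplex_lp(cc, A[-(m + n), , drop = FALSE], c(p[sp], q[sq])[-(m + n)])$value
}

# random connected graph on n nodes (Erdos-Renyi conditioned on connectivity)
random_connected_graph <- function(n, p_edge = 0.4) {
  repeat {
    g <- igraph::sample_gnp(n, p_edge)
    if (igraph::is_connected(g)) return(g)
  }
}

# random rational distribution over n nodes with denominator <= den
random_rational_dist <- function(n, den = 8L) {
  repeat {
    k <- sample.int(den, 1L)
    cnt <- tabulate(sample.int(n, k, replace = TRUE), nbins = n)
    if (sum(cnt) > 0L) return(cnt / sum(cnt))
  }
}

# shape_graph fixture from an igraph + per-node label counts matrix
graph_fixture <- function(ig, label_counts = NULL, node_size = NULL) {
  n <- igraph::vcount(ig)
  e <- igraph::as_edgelist(ig, names = FALSE)
  e <- matrix(as.integer(e), ncol = 2L)
  members <- as.list(seq_len(n)) # one synthetic frame per node
  if (is.null(node_size)) node_size <- rep(1L, n)
  structure(list(members = members, edges = e,
                 node_size = as.integer(node_size),
                 label_counts = label_counts,
                 labels = NULL,
                 levels = if (!is.null(label_counts)) colnames(label_counts),
                 n_frames = n),
            class = "shape_graph")
}
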