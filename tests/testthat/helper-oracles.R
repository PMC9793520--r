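# Independent brute-force oracles used to pin expected values. These are
# deliberately naive (loops, direct definitions) and share no code with the
# package internals they check.

# Weighted KS enrichment score by walking the whole ranked list.
bf_enrichment_score <- function(ranked, gene_set, exponent = 0) {
  hits <- names(ranked) %in% gene_set
  k <- sum(hits)
  n <- length(ranked)
  w <- if (exponent == 0) as.numeric(hits) else abs(ranked)^exponent * hits
  w <- w / sum(w)
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- run + if (hits[i]) unname(w[i]) else -1 / (n - k)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Benjamini-Hochberg step-up by definition.
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    j <- o[i]
    q[j] <- min(p[o[i:n]] * n / (i:n))
  }
  pmin(q, 1)
}

# Right-tail hypergeometric P(X >= k) by direct summation.
bf_hyper_tail <- function(k, size_a, size_b, universe) {
  kk <- k:min(size_a, size_b)
  sum(choose(size_a, kk) * choose(universe - size_a, size_b - kk)) /
    choose(universe, size_b)
}

# Spearman correlation as rank-then-Pearson, by definition.
bf_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Two-gene-block expression data: one latent factor, one block follows it,
# the other opposes it, optional unrelated noise genes.
make_two_block_expr <- function(n_pos = 5, n_neg = 5, n_noise = 0,
                                n_samples = 20, noise_sd = 0.5,
                                seed = 1) {
  set.seed(seed)
  f <- rnorm(n_samples)
  pos <- t(vapply(seq_len(n_pos), function(i)
    f + rnorm(n_samples, sd = noise_sd), numeric(n_samples)))
  neg <- t(vapply(seq_len(n_neg), function(i)
    -f + rnorm(n_samples, sd = noise_sd), numeric(n_samples)))
  nz <- if (n_noise > 0)
    matrix(rnorm(n_noise * n_samples), n_noise, n_samples)
  expr <- rbind(pos, neg, nz)
  rownames(expr) <- c(paste0("p", seq_len(n_pos)),
                      paste0("m", seq_len(n_neg)),
                      if (n_noise > 0) paste0("z", seq_len(n_noise)))
  colnames(expr) <- paste0("s", seq_len(n_samples))
  list(expr = expr, latent = f,
       pos = paste0("p", seq_len(n_pos)),
       neg = paste0("m", seq_len(n_neg)))
}

# Fixed kinetic parameters for hand-analyzable circuits.
fixed_params <- function(topo, G, k, h, lam, X0, prot = NULL) {
  nodes <- sort(unique(c(topo$source, topo$target)))
  e <- as.data.frame(topo)
  e$h <- h; e$lam <- lam; e$X0 <- X0
  p <- list(G = setNames(G, nodes), k = setNames(k, nodes),
            prot = setNames(if (is.null(prot)) rep(1, length(nodes))
                            else prot, nodes),
            edges = e, nodes = nodes)
  class(p) <- "racipe_params"
  p
}

# naive residual evaluator, independent of the package's system builder:
# computes activities by direct per-node loops and the derivative from the
# model definition
naive_residual <- function(params, x) {
  nodes <- params$nodes
  e <- params$edges
  sig <- grepl("^signaling", e$type)
  a <- setNames(params$prot[nodes] * x[nodes], nodes)
  for (iter in 1:500) {
    a_new <- params$prot[nodes] * x[nodes]
    for (r in which(sig)) {
      a_new[e$target[r]] <- a_new[e$target[r]] *
        shifted_hill(a[e$source[r]], e$X0[r], e$h[r], e$lam[r])
    }
    if (max(abs(a_new - a)) < 1e-12) break
    a <- a_new
  }
  d <- setNames(params$G[nodes], nodes)
  for (r in which(!sig)) {
    d[e$target[r]] <- d[e$target[r]] *
      shifted_hill(a[e$source[r]], e$X0[r], e$h[r], e$lam[r])
  }
  max(abs(d - params$k[nodes] * x[nodes]))
}
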