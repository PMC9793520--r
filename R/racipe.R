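#' Network topologies for ensemble simulation
#'
#' A topology is a data.frame of directed edges with a regulation type.
#' Transcriptional edges (`excitatory`, `inhibitory`) change both the
#' expression and the activity of the target; signaling edges
#' (`signaling_excitatory`, `signaling_inhibitory`) change only the
#' target's activity. A non-regulator gene (no outgoing edges) with no
#' incoming signaling edges has activity equal to its expression; regulator
#' nodes additionally carry a random protein-level factor (see
#' [sample_model()]), so a TF's activity tracks but does not equal its
#' expression.
#'
#' @param edges data.frame with columns `source`, `target`, `type`; `type`
#'   is one of the four strings above or an integer code 1 = excitatory,
#'   2 = inhibitory, 3 = signaling excitatory, 4 = signaling inhibitory.
#' @return data.frame of class `grn_topology`.
#' @export
topology <- function(edges) {
  codes <- c("excitatory", "inhibitory", "signaling_excitatory",
             "signaling_inhibitory")
  if (is.numeric(edges$type)) edges$type <- codes[edges$type]
  if (!all(edges$type %in% codes))
    stop("edge types must be one of: ", paste(codes, collapse = ", "))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (anyDuplicated(edges[c("source", "target", "type")]))
    stop("duplicate (source, target, type) edge")
  structure(edges, class = c("grn_topology", "data.frame"))
}

#' @rdname topology
#' @param path TSV path with columns `source`, `target`, `type` (integer
#'   codes as above).
#' @export
read_topology <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  topology(d)
}

#' @rdname topology
#' @param topo a `grn_topology`.
#' @export
write_topology <- function(topo, path) {
  codes <- c(excitatory = 1L, inhibitory = 2L, signaling_excitatory = 3L,
             signaling_inhibitory = 4L)
  d <- data.frame(source = topo$source, target = topo$target,
                  type = codes[topo$type])
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

topology_nodes <- function(topo) sort(unique(c(topo$source, topo$target)))

.is_signaling <- function(type) grepl("^signaling", type)
.is_inhibitory <- function(type) type %in% c("inhibitory",
                                             "signaling_inhibitory")

#' Shifted Hill regulation function
#'
#' `H(X) = lam + (1 - lam) / (1 + (X / X0)^h)`: 1 at zero regulator, `lam`
#' at saturation, monotone in between. `lam > 1` encodes activation,
#' `lam` in (0, 1) inhibition, `lam = 1` no regulation.
#'
#' @param X regulator level (>= 0).
#' @param X0 half-response threshold (> 0).
#' @param h Hill coefficient.
#' @param lam fold change.
#' @return regulation factor, between `min(1, lam)` and `max(1, lam)`.
#' @export
shifted_hill <- function(X, X0, h, lam) {
  lam + (1 - lam) / (1 + (X / X0)^h)
}

# Median of G/k over the sampling ranges G ~ U[1,100], k ~ U[0.1,1]:
# P(G/k <= m) = (0.495 m - 0.9) / 89.1 = 1/2 gives m = 1010/11 exactly
# (valid because m*k stays inside [1, 100] for all k). Used by the
# half-functional rule for thresholds and for initial-condition ranges.
.M_GK <- 1010 / 11

#' Estimate contextual median activity levels per node
#'
#' The half-functional rule draws each edge's threshold around the median
#' level of its source, so that regulation has roughly even odds of being
#' engaged. A regulated node's level is shifted by its incoming fold
#' changes, so the isolated median `G/k` is a poor center for strongly
#' regulated regulators; this estimates each node's median activity by
#' Monte Carlo over the sampling ranges, multiplying the isolated level by
#' one random shifted-Hill factor per incoming edge (a depth-one
#' approximation: upstream regulators are taken at their isolated levels).
#' The computation runs on a private RNG stream, so results are
#' deterministic and the caller's random state is untouched.
#'
#' @param topo a [topology()].
#' @param n_draws Monte Carlo draws per node (default 2000).
#' @return named numeric vector of median levels per node.
#' @export
estimate_node_medians <- function(topo, n_draws = 2000L) {
  state <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(state)) assign(".Random.seed", state, globalenv()))
  set.seed(190748L)
  nodes <- topology_nodes(topo)
  M <- stats::setNames(rep(.M_GK, length(nodes)), nodes)
  for (nd in nodes) {
    inc <- topo[topo$target == nd, , drop = FALSE]
    base <- stats::runif(n_draws, 1, 100) / stats::runif(n_draws, 0.1, 1)
    for (r in seq_len(nrow(inc))) {
      lam <- if (.is_inhibitory(inc$type[r]))
        1 / stats::runif(n_draws, 1, 100) else stats::runif(n_draws, 1, 100)
      X <- stats::runif(n_draws, 1, 100) / stats::runif(n_draws, 0.1, 1)
      X0 <- stats::runif(n_draws, 0.02 * .M_GK, 1.98 * .M_GK)
      h <- sample(1:6, n_draws, replace = TRUE)
      base <- base * shifted_hill(X, X0, h, lam)
    }
    M[nd] <- stats::median(base)
  }
  M
}

#' Sample one random kinetic parameter set
#'
#' Per node: maximum production rate `G ~ U[1, 100]` and degradation rate
#' `k ~ U[0.1, 1]`. When `protein_noise > 0`, regulator nodes (nodes with
#' at least one outgoing edge) additionally get a random
#' translation/stability factor `c = 10^U[-protein_noise, protein_noise]`
#' (unit median) scaling their activity: the protein-level variability
#' that makes a TF's activity vary beyond its mRNA across models.
#' Non-regulator genes always have `c = 1`, so their activity equals
#' their expression. Per edge: integer
#' Hill coefficient `h ~ U{1..6}`, fold change `lam ~ U[1, 100]`
#' (excitatory-type) or `U[0.01, 1]` (inhibitory-type), and half-response
#' threshold `X0 ~ U[0.02 M_src, 1.98 M_src]` with `M_src` the source
#' node's contextual median level (the half-functional rule; see
#' [estimate_node_medians()]).
#'
#' @param topo a [topology()].
#' @param seed optional integer seed.
#' @param node_medians optional precomputed [estimate_node_medians()]
#'   vector (computed on the fly when `NULL`; precompute it when sampling
#'   many models of one topology).
#' @param protein_noise log10 half-spread of the regulator protein factor
#'   (default 0: activity is expression times the signaling factors, with
#'   no extra variability).
#' @return list of class `racipe_params` with `G`, `k`, `prot` (named
#'   vectors) and `edges` (the topology with `h`, `lam`, `X0` columns
#'   added).
#' @export
sample_model <- function(topo, seed = NULL, node_medians = NULL,
                         protein_noise = 0) {
  if (is.null(node_medians)) node_medians <- estimate_node_medians(topo)
  if (!is.null(seed)) set.seed(seed)
  nodes <- topology_nodes(topo)
  n <- length(nodes)
  ne <- nrow(topo)
  G <- stats::setNames(stats::runif(n, 1, 100), nodes)
  k <- stats::setNames(stats::runif(n, 0.1, 1), nodes)
  prot <- stats::setNames(rep(1, n), nodes)
  reg <- nodes %in% topo$source
  prot[reg] <- 10^stats::runif(sum(reg), -protein_noise, protein_noise)
  edges <- as.data.frame(topo)
  edges$h <- sample(1:6, ne, replace = TRUE)
  inh <- .is_inhibitory(edges$type)
  lam <- numeric(ne)
  lam[!inh] <- stats::runif(sum(!inh), 1, 100)
  # inhibitory fold change is the reciprocal of a U[1,100] draw: the range
  # is (0.01, 1] but mass sits at strong repression (median 1/50), mirroring
  # the excitatory distribution on the fold-change scale
  lam[inh] <- 1 / stats::runif(sum(inh), 1, 100)
  edges$lam <- lam
  m_src <- node_medians[edges$source]
  edges$X0 <- stats::runif(ne, 0.02 * m_src, 1.98 * m_src)
  structure(list(G = G, k = k, prot = prot, edges = edges, nodes = nodes),
            class = "racipe_params")
}

# Resolve activities a = c * x * prod_{signaling j -> i} H(a_j), with c the
# per-node protein factor. For an acyclic signaling graph fixed-point
# iteration from a = c * x reaches the exact result in at most depth steps;
# signaling cycles (which random TF-TF wiring does produce) are handled by
# continuing the iteration to a tolerance.
.resolve_activity <- function(x, prot, sig_src, sig_tgt, sig_X0, sig_h,
                              sig_lam, n, max_iter = 200L, tol = 1e-10) {
  base <- prot * x
  if (!length(sig_src)) return(base)
  a <- base
  for (it in seq_len(max_iter)) {
    H <- shifted_hill(a[sig_src], sig_X0, sig_h, sig_lam)
    fac <- rep(1, n)
    s <- rowsum(log(H), sig_tgt)
    fac[as.integer(rownames(s))] <- exp(s[, 1])
    a_new <- base * fac
    if (max(abs(a_new - a)) <= tol * (1 + max(abs(a)))) return(a_new)
    a <- a_new
  }
  stop("signaling activity fixed point did not converge")
}

# Build the ODE right-hand side and helpers for one parameterized model.
# clamp: optional list(gene=, level=) freezing one node's expression.
.model_system <- function(params, clamp = NULL) {
  nodes <- params$nodes
  n <- length(nodes)
  e <- params$edges
  sig <- .is_signaling(e$type)
  t_src <- match(e$source[!sig], nodes)
  t_tgt <- match(e$target[!sig], nodes)
  t_X0 <- e$X0[!sig]; t_h <- e$h[!sig]; t_lam <- e$lam[!sig]
  s_src <- match(e$source[sig], nodes)
  s_tgt <- match(e$target[sig], nodes)
  s_X0 <- e$X0[sig]; s_h <- e$h[sig]; s_lam <- e$lam[sig]
  G <- params$G[nodes]; k <- params$k[nodes]
  prot <- if (is.null(params$prot)) stats::setNames(rep(1, n), nodes) else
    params$prot[nodes]
  clamp_idx <- if (!is.null(clamp)) match(clamp$gene, nodes) else NA_integer_
  if (!is.null(clamp) && is.na(clamp_idx))
    stop("clamped gene not in topology: ", clamp$gene)
  activity <- function(x) .resolve_activity(x, prot, s_src, s_tgt, s_X0,
                                            s_h, s_lam, n)
  rhs <- function(x) {
    x <- pmax(x, 0)
    if (!is.na(clamp_idx)) x[clamp_idx] <- clamp$level
    a <- activity(x)
    prodH <- rep(1, n)
    if (length(t_src)) {
      H <- shifted_hill(a[t_src], t_X0, t_h, t_lam)
      s <- rowsum(log(H), t_tgt)
      prodH[as.integer(rownames(s))] <- exp(s[, 1])
    }
    d <- G * prodH - k * x
    if (!is.na(clamp_idx)) d[clamp_idx] <- 0
    d
  }
  list(n = n, nodes = nodes, rhs = rhs, activity = activity, G = G, k = k,
       clamp_idx = clamp_idx, clamp = clamp)
}

#' Stable steady states of one parameterized model
#'
#' Integrates the expression dynamics
#' `dx_i/dt = G_i prod_j H(a_j) - k_i x_i` (the product over transcriptional
#' regulators `j -> i`, read at the regulator's *activity*) from random
#' log-uniform initial conditions until the residual `max |dx/dt|` falls
#' below `tol`; converged endpoints are deduplicated at relative tolerance
#' 1e-2 in log space. Activities obey
#' `a_i = c_i x_i prod_j H(a_j)` over signaling regulators `j -> i`, with
#' `c_i` the node's protein factor (1 for non-regulator genes).
#'
#' @param topo a [topology()].
#' @param params a `racipe_params` from [sample_model()].
#' @param n_inits number of random initial conditions.
#' @param t_max integration horizon per attempt (one retry at 4x on
#'   non-convergence before the trajectory is discarded).
#' @param tol residual tolerance on `max |dx/dt|`.
#' @param seed optional integer seed for the initial conditions.
#' @param clamp optional `list(gene =, level =)` freezing one node.
#' @return list with `states` (each a list with expression `x`, activity
#'   `a`, `residual`) and `n_discarded`.
#' @export
steady_states <- function(topo, params, n_inits = 50L, t_max = 200,
                          tol = 1e-6, seed = NULL, clamp = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sys <- .model_system(params, clamp = clamp)
  lo <- 0.01 * sys$G / sys$k
  hi <- 100 * sys$G / sys$k
  states <- list()
  n_disc <- 0L
  for (i in seq_len(n_inits)) {
    x0 <- exp(stats::runif(sys$n, log(lo), log(hi)))
    if (!is.na(sys$clamp_idx)) x0[sys$clamp_idx] <- sys$clamp$level
    x <- .integrate_to_rest(sys, x0, t_max, tol)
    if (is.null(x)) {
      n_disc <- n_disc + 1L
      next
    }
    a <- sys$activity(x)
    names(x) <- names(a) <- sys$nodes
    dup <- FALSE
    lx <- log10(pmax(x, 1e-9))
    for (st in states) {
      if (max(abs(lx - log10(pmax(st$x, 1e-9)))) < 1e-2) {
        dup <- TRUE
        break
      }
    }
    if (!dup)
      states[[length(states) + 1L]] <-
        list(x = x, a = a, residual = max(abs(sys$rhs(x))))
  }
  list(states = states, n_discarded = n_disc)
}

# Integrate to t_max with a non-stiff multistep method (degradation rates
# bound all timescales to ~[1, 10] time units, so the system is not stiff),
# then polish the endpoint with damped per-node relaxation steps
# x <- x + a * (dx/dt) / k -- implicit-Euler-like toward the fixed point --
# until the residual drops below tol. One retry at 4x the horizon; anything
# still unconverged (e.g. a limit cycle) is discarded.
.integrate_to_rest <- function(sys, x0, t_max, tol) {
  f <- function(t, y, p) list(sys$rhs(y))
  x <- x0
  for (attempt in 1:2) {
    horizon <- t_max * c(1, 4)[attempt]
    # capture.output swallows the solver's step-limit console chatter;
    # unconverged endpoints are handled by the residual check below
    utils::capture.output(out <- tryCatch(
      suppressWarnings(
        deSolve::ode(x, times = c(0, horizon), func = f, parms = NULL,
                     method = "adams", rtol = 1e-6, atol = 1e-8)),
      error = function(e) NULL), type = "output")
    if (is.null(out) || nrow(out) < 2L || anyNA(out[nrow(out), ]))
      return(NULL)
    x <- pmax(as.numeric(out[nrow(out), -1L]), 0)
    if (!is.na(sys$clamp_idx)) x[sys$clamp_idx] <- sys$clamp$level
    for (i in seq_len(500L)) {
      d <- sys$rhs(x)
      if (max(abs(d)) < tol) return(x)
      x <- pmax(x + 0.3 * d / sys$k, 0)
      if (!is.na(sys$clamp_idx)) x[sys$clamp_idx] <- sys$clamp$level
    }
  }
  NULL
}

#' Simulate an ensemble of random-parameter models
#'
#' Draws `n_models` random kinetic parameter sets for a fixed topology and
#' collects the distinct stable steady states of each, carrying both the
#' expression and the activity vector per state. Per-model failures are
#' reported, never fatal. Fixed `seed` gives a byte-identical ensemble; a
#' knockdown run at the same seed is paired model-for-model with the
#' unperturbed run.
#'
#' @param topo a [topology()].
#' @param n_models number of random models (default 100).
#' @param n_inits random initial conditions per model (default 50).
#' @param seed optional integer seed.
#' @param t_max,tol see [steady_states()].
#' @param knockdown optional `list(gene =, factor =)`: the gene's maximum
#'   production rate `G` is multiplied by `factor` after sampling, leaving
#'   all other draws untouched.
#' @param clamp optional `list(gene =, level =)` passed to every model.
#' @param protein_noise see [sample_model()].
#' @return object of class `racipe_ensemble`.
#' @export
simulate_ensemble <- function(topo, n_models = 100L, n_inits = 50L,
                              seed = NULL, t_max = 200, tol = 1e-6,
                              knockdown = NULL, clamp = NULL,
                              protein_noise = 0) {
  stopifnot(n_models >= 1L)
  n_models <- as.integer(n_models)
  if (!is.null(seed)) set.seed(seed)
  node_medians <- estimate_node_medians(topo)
  model_seeds <- sample.int(.Machine$integer.max - 1L, n_models)
  models <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    set.seed(model_seeds[m])
    params <- sample_model(topo, node_medians = node_medians,
                           protein_noise = protein_noise)
    if (!is.null(knockdown)) {
      if (!knockdown$gene %in% params$nodes)
        stop("knockdown gene not in topology: ", knockdown$gene)
      stopifnot(knockdown$factor > 0, knockdown$factor <= 1)
      params$G[knockdown$gene] <- params$G[knockdown$gene] *
        knockdown$factor
    }
    ss <- tryCatch(
      steady_states(topo, params, n_inits = n_inits, t_max = t_max,
                    tol = tol, clamp = clamp),
      error = function(e) {
        warning(sprintf("model %d failed: %s", m, conditionMessage(e)))
        list(states = list(), n_discarded = n_inits)
      })
    models[[m]] <- list(params = params, states = ss$states,
                        n_discarded = ss$n_discarded)
  }
  structure(list(topology = topo, models = models, n_models = n_models,
                 n_inits = n_inits, seed = seed, tol = tol,
                 knockdown = knockdown, clamp = clamp),
            class = "racipe_ensemble")
}

#' @export
print.racipe_ensemble <- function(x, ...) {
  ns <- vapply(x$models, function(m) length(m$states), integer(1))
  cat(sprintf("racipe_ensemble: %d models, %d stable states (%d models with >= 2)\n",
              x$n_models, sum(ns), sum(ns >= 2L)))
  if (!is.null(x$knockdown))
    cat(sprintf("  knockdown: %s x %.3g\n", x$knockdown$gene,
                x$knockdown$factor))
  if (!is.null(x$clamp))
    cat(sprintf("  clamp: %s = %.3g\n", x$clamp$gene, x$clamp$level))
  invisible(x)
}

#' Knockdown ensemble
#'
#' Re-runs [simulate_ensemble()] with identical sampling (same seed gives
#' paired models) except that the knocked-down gene's production rate is
#' multiplied by `kd_factor`.
#'
#' @param topo a [topology()].
#' @param gene gene to knock down.
#' @param kd_factor production-rate multiplier in (0, 1); default 0.1.
#' @param ... passed to [simulate_ensemble()].
#' @return a `racipe_ensemble`.
#' @export
knockdown_ensemble <- function(topo, gene, kd_factor = 0.1, ...) {
  simulate_ensemble(topo, knockdown = list(gene = gene,
                                           factor = kd_factor), ...)
}

#' Pooled state matrix of an ensemble
#'
#' @param ens a `racipe_ensemble`.
#' @param what `"expression"` or `"activity"`.
#' @param log2 log2-transform (floor 1e-10) before standardizing.
#' @param standardize z-score each gene across states.
#' @return genes x states matrix; column names `model.state`; attributes
#'   `model` and `state` index the provenance of each column.
#' @export
state_matrix <- function(ens, what = c("expression", "activity"),
                         log2 = TRUE, standardize = TRUE) {
  what <- match.arg(what)
  field <- if (what == "expression") "x" else "a"
  cols <- list()
  model_id <- integer()
  state_id <- integer()
  for (m in seq_along(ens$models)) {
    sts <- ens$models[[m]]$states
    for (s in seq_along(sts)) {
      cols[[length(cols) + 1L]] <- sts[[s]][[field]]
      model_id <- c(model_id, m)
      state_id <- c(state_id, s)
    }
  }
  if (!length(cols)) stop("ensemble holds no stable states")
  mat <- do.call(cbind, cols)
  colnames(mat) <- paste(model_id, state_id, sep = ".")
  if (log2) mat <- base::log2(pmax(mat, 1e-10))
  if (standardize) mat <- standardize_expression(mat)
  structure(mat, model = model_id, state = state_id)
}

#' Global bifurcation sweep over a clamped control gene
#'
#' Clamps the control gene at each grid level (its equation removed) and
#' records the ensemble steady states per level, plus the first principal
#' component of pooled standardized activities as a one-dimensional state
#' coordinate. The same seed is used per level so models are paired across
#' the sweep.
#'
#' @param topo a [topology()].
#' @param control_gene gene to clamp.
#' @param levels numeric grid of clamp levels.
#' @param n_models,n_inits,seed,t_max,tol see [simulate_ensemble()].
#' @return object of class `bifurcation_sweep`: list with `levels`,
#'   `ensembles`, and `projection`, a data.frame (level, model, state, pc1).
#' @export
bifurcation_sweep <- function(topo, control_gene, levels, n_models = 50L,
                              n_inits = 10L, seed = NULL, t_max = 200,
                              tol = 1e-6) {
  if (!control_gene %in% topology_nodes(topo))
    stop("control gene not in topology: ", control_gene)
  ensembles <- lapply(levels, function(lv)
    simulate_ensemble(topo, n_models = n_models, n_inits = n_inits,
                      seed = seed, t_max = t_max, tol = tol,
                      clamp = list(gene = control_gene, level = lv)))
  mats <- lapply(ensembles, function(e)
    tryCatch(state_matrix(e, "activity", standardize = FALSE,
                          log2 = TRUE),
             error = function(err) NULL))
  keep <- !vapply(mats, is.null, logical(1))
  pooled <- standardize_expression(do.call(cbind, mats[keep]))
  pc <- stats::prcomp(t(pooled), center = FALSE)
  lvl_rep <- rep(levels[keep], vapply(mats[keep], ncol, integer(1)))
  proj <- data.frame(level = lvl_rep, pc1 = pc$x[, 1])
  structure(list(levels = levels, ensembles = ensembles,
                 projection = proj, control_gene = control_gene),
            class = "bifurcation_sweep")
}

#' Map simulated states to labeled reference profiles
#'
#' Assigns each state (column) the label of the reference profile with the
#' highest Pearson correlation on the shared gene space, computed on
#' per-gene standardized vectors. Ties take the first label in reference
#' order.
#'
#' @param states genes x states matrix (e.g. from [state_matrix()]).
#' @param reference genes x profiles matrix with profile labels as column
#'   names.
#' @return character vector of labels, one per state column.
#' @export
classify_states <- function(states, reference) {
  shared <- intersect(rownames(states), rownames(reference))
  if (length(shared) < 3L)
    stop("states and reference share fewer than 3 genes")
  s <- standardize_expression(states[shared, , drop = FALSE])
  r <- standardize_expression(reference[shared, , drop = FALSE])
  cc <- suppressWarnings(stats::cor(s, r))
  cc[is.na(cc)] <- -Inf
  colnames(reference)[apply(cc, 1L, which.max)]
}
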