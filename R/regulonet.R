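#' Fit a core TF regulatory network model from expression data
#'
#' The end-to-end estimator. Given a genes x samples expression matrix, a
#' per-sample condition label, and a TF-target regulon database, it
#' (1) computes differential-expression statistics for each condition
#' contrast, (2) identifies enriched TFs by gene-set enrichment with a
#' gene-label permutation null and takes the union across contrasts,
#' (3) infers per-sample TF activity from target expression (two-module
#' split, coherence filter, Hill-weighted signed average, sign assignment),
#' and (4) assembles signed TF-TF networks from the mutual information of
#' activity rows over a cutoff sweep. The fitted object can then be handed
#' to [simulate()][simulate.regulonet()] to validate a candidate network as
#' a dynamical system.
#'
#' @param expr numeric genes x samples matrix, log-scale values; rownames
#'   are gene symbols, colnames sample ids.
#' @param conditions character/factor of condition labels, one per sample.
#' @param db a [regulon_db()].
#' @param comparisons list of length-2 character vectors of condition
#'   labels to contrast; default all pairs in level order.
#' @param q_cutoff enrichment q-value cutoff(s), scalar or one per
#'   comparison (default 0.05).
#' @param n_perm gene-label permutations (default 10000).
#' @param weight_exponent see [enrichment_score()].
#' @param s0,hill_n Hill weighting parameters, see [hill_weight()].
#' @param min_targets minimum usable regulon size (default 5).
#' @param mi_cutoffs MI thresholds for the network sweep; default the
#'   50/75/90 percent quantiles of the observed pairwise MI plus 0.
#' @param n_bins see [mutual_information()].
#' @param sign_overrides optional named +1/-1 vector for non-DE TFs.
#' @param de_p_cut,de_fc_cut DE gene thresholds (defaults 0.05 and 2).
#' @param seed optional integer seed covering the permutation null.
#' @return object of class `regulonet` with components `de` (list of
#'   `de_result` per comparison), `enrichment` (list of
#'   `enrichment_result`), `tfs`, `activity` (TFs x samples),
#'   `groupings`, `network` (a `grn_sweep`), plus the inputs needed by the
#'   methods.
#' @seealso [print.regulonet()], [summary.regulonet()],
#'   [coef.regulonet()], [predict.regulonet()], [simulate.regulonet()],
#'   [plot.regulonet()]
#' @export
regulonet <- function(expr, conditions, db, comparisons = NULL,
                      q_cutoff = 0.05, n_perm = 10000L,
                      weight_exponent = 1, s0 = 0.05, hill_n = 1 / 5,
                      min_targets = 5L, mi_cutoffs = NULL, n_bins = NULL,
                      sign_overrides = NULL, de_p_cut = 0.05,
                      de_fc_cut = 2, seed = NULL) {
  cl <- match.call()
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expr needs gene rownames and sample colnames")
  conditions <- as.character(conditions)
  if (length(conditions) != ncol(expr))
    stop("one condition label per sample required")
  lvls <- unique(conditions)
  if (is.null(comparisons)) {
    if (length(lvls) < 2L) stop("need at least two conditions")
    comparisons <- utils::combn(lvls, 2L, simplify = FALSE)
  }
  db_r <- restrict_regulons(db, rownames(expr), min_size = min_targets)

  de_list <- lapply(comparisons, function(cmp) {
    diff_expression(expr,
                    colnames(expr)[conditions == cmp[1]],
                    colnames(expr)[conditions == cmp[2]])
  })
  names(de_list) <- vapply(comparisons, paste, character(1),
                           collapse = "_vs_")
  if (!is.null(seed)) set.seed(seed)
  enrich <- lapply(de_list, function(de)
    regulon_enrichment(rank_genes(de), db_r, n_perm = n_perm,
                       weight_exponent = weight_exponent))
  tfs <- select_tfs(enrich, q_cutoffs = q_cutoff)

  # combined DE table for activity weighting: per gene, the contrast in
  # which it is most significant
  s_mat <- do.call(cbind, lapply(de_list, function(d)
    d[rownames(expr), "s_adj"]))
  pick <- max.col(-s_mat, ties.method = "first")
  de_comb <- de_list[[1]][rownames(expr), ]
  for (j in seq_along(de_list)[-1]) {
    sel <- pick == j
    de_comb[sel, ] <- de_list[[j]][rownames(expr), ][sel, ]
  }
  class(de_comb) <- c("de_result", "data.frame")

  activity <- infer_activity(expr, db_r, tfs, de = de_comb, s0 = s0,
                             n = hill_n, min_targets = min_targets,
                             sign_overrides = sign_overrides,
                             de_p_cut = de_p_cut, de_fc_cut = de_fc_cut)
  groupings <- attr(activity, "groupings")

  network <- NULL
  if (nrow(activity) >= 2L) {
    mi <- mi_matrix(activity, n_bins = n_bins)
    vals <- mi[upper.tri(mi)]
    if (is.null(mi_cutoffs))
      mi_cutoffs <- unique(c(0, stats::quantile(vals, c(0.5, 0.75, 0.9),
                                                names = FALSE)))
    network <- network_sweep(activity, db_r, cutoffs = mi_cutoffs,
                             n_bins = n_bins)
  }

  structure(list(call = cl,
                 de = de_list, de_combined = de_comb,
                 enrichment = enrich, tfs = tfs,
                 activity = activity, groupings = groupings,
                 network = network,
                 db = db_r, conditions = conditions,
                 comparisons = comparisons,
                 gene_center = rowMeans(expr),
                 gene_scale = apply(expr, 1L, stats::sd),
                 params = list(q_cutoff = q_cutoff, n_perm = n_perm,
                               weight_exponent = weight_exponent,
                               s0 = s0, hill_n = hill_n,
                               min_targets = min_targets,
                               n_bins = n_bins,
                               de_p_cut = de_p_cut,
                               de_fc_cut = de_fc_cut),
                 seed = seed),
            class = "regulonet")
}

#' @export
print.regulonet <- function(x, ...) {
  cat("Core TF network fit\n")
  cat(sprintf("  %d comparisons, %d TFs selected (q < %s)\n",
              length(x$de), length(x$tfs),
              paste(x$params$q_cutoff, collapse = "/")))
  cat(sprintf("  activity: %d TFs x %d samples\n",
              nrow(x$activity), ncol(x$activity)))
  if (!is.null(x$network)) {
    s <- x$network$sizes
    cat(sprintf("  network sweep: %s edges at MI cutoffs %s\n",
                paste(s$n_edges, collapse = "/"),
                paste(signif(s$cutoff, 3), collapse = "/")))
  }
  invisible(x)
}

#' Summary of a fitted core-network model
#'
#' @param object a `regulonet` fit.
#' @param ... unused.
#' @return a `summary.regulonet` list: per-comparison DE and enrichment
#'   counts, target-retention statistics of the coherence filter, and the
#'   network size table.
#' @export
summary.regulonet <- function(object, ...) {
  de_counts <- vapply(object$de, function(d)
    length(de_genes(d, object$params$de_p_cut, object$params$de_fc_cut)),
    integer(1))
  enr_counts <- vapply(seq_along(object$enrichment), function(i) {
    q <- object$params$q_cutoff
    q <- if (length(q) == 1L) q else q[i]
    sum(object$enrichment[[i]]$q_value < q, na.rm = TRUE)
  }, integer(1))
  retention <- vapply(object$groupings, function(g) {
    kept <- length(g$group_pos) + length(g$group_neg)
    kept / (kept + length(g$filtered_out))
  }, numeric(1))
  structure(list(n_comparisons = length(object$de),
                 de_genes = de_counts,
                 enriched_tfs = enr_counts,
                 tfs = object$tfs,
                 skipped = attr(object$activity, "skipped"),
                 retention = retention,
                 network_sizes = if (!is.null(object$network))
                   object$network$sizes),
            class = "summary.regulonet")
}

#' @export
print.summary.regulonet <- function(x, ...) {
  cat(sprintf("comparisons: %d\n", x$n_comparisons))
  cat("DE genes per comparison: ", paste(x$de_genes, collapse = ", "), "\n")
  cat("enriched TFs per comparison: ",
      paste(x$enriched_tfs, collapse = ", "), "\n")
  cat(sprintf("selected TFs (union): %d\n", length(x$tfs)))
  if (length(x$skipped))
    cat("skipped (too few targets): ",
        paste(x$skipped, collapse = ", "), "\n")
  if (length(x$retention))
    cat(sprintf("target retention after filtering: median %.0f%%\n",
                100 * stats::median(x$retention)))
  if (!is.null(x$network_sizes)) {
    cat("network sweep:\n")
    print(x$network_sizes, row.names = FALSE)
  }
  invisible(x)
}

#' Extract the inferred activity matrix
#'
#' @param object a `regulonet` fit.
#' @param ... unused.
#' @return TFs x samples numeric matrix.
#' @export
coef.regulonet <- function(object, ...) {
  out <- object$activity
  attributes(out)[c("groupings", "skipped")] <- NULL
  out
}

#' Predict TF activity for new samples
#'
#' Applies the fitted target groupings and Hill weights to new expression
#' data: each gene is standardized with the training-set mean and standard
#' deviation, then the stored weighted signed average is evaluated.
#'
#' @param object a `regulonet` fit.
#' @param newdata genes x samples matrix containing all grouped target
#'   genes.
#' @param ... unused.
#' @return TFs x new-samples activity matrix.
#' @export
predict.regulonet <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  scale0 <- object$gene_scale
  scale0[scale0 == 0] <- 1
  rows <- lapply(names(object$groupings), function(tf) {
    g <- object$groupings[[tf]]
    genes <- c(g$group_pos, g$group_neg)
    if (!all(genes %in% rownames(newdata)))
      stop("newdata is missing grouped targets of ", tf)
    sgn <- c(rep(1, length(g$group_pos)), rep(-1, length(g$group_neg)))
    w <- hill_weight(object$de_combined[genes, "s_adj"],
                     s0 = object$params$s0, n = object$params$hill_n)
    z <- (newdata[genes, , drop = FALSE] - object$gene_center[genes]) /
      scale0[genes]
    drop(crossprod(z, w * sgn)[, 1] / sum(w))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(object$groupings)
  colnames(out) <- colnames(newdata)
  out
}

#' Convert a constructed network to a simulation topology
#'
#' @param grn a `grn` from [construct_network()].
#' @return a [topology()] with `excitatory`/`inhibitory` edge types.
#' @export
as_topology <- function(grn) {
  stopifnot(inherits(grn, "grn"))
  if (!nrow(grn$edges)) stop("network has no edges")
  topology(data.frame(source = grn$edges$source,
                      target = grn$edges$target,
                      type = ifelse(grn$edges$sign > 0, "excitatory",
                                    "inhibitory")))
}

#' Simulate the dynamics of a fitted core network
#'
#' Picks one network from the fitted MI cutoff sweep, converts its signed
#' edges to a transcriptional topology, and runs the random-parameter
#' ensemble simulator on it. The distribution of stable states over the
#' ensemble characterizes the expression patterns the network supports.
#'
#' @param object a `regulonet` fit with a non-empty network sweep.
#' @param nsim number of random-parameter models (default 100).
#' @param seed optional integer seed.
#' @param cutoff which MI cutoff's network to simulate; default the
#'   smallest cutoff whose network is non-empty.
#' @param n_inits initial conditions per model (default 10).
#' @param ... passed to [simulate_ensemble()].
#' @return a `racipe_ensemble`.
#' @export
simulate.regulonet <- function(object, nsim = 100L, seed = NULL,
                               cutoff = NULL, n_inits = 10L, ...) {
  if (is.null(object$network)) stop("fit has no network sweep")
  nets <- object$network$networks
  cutoffs <- object$network$cutoffs
  if (is.null(cutoff)) {
    nonempty <- which(vapply(nets, function(g) nrow(g$edges) > 0L,
                             logical(1)))
    if (!length(nonempty)) stop("all swept networks are empty")
    net <- nets[[nonempty[1]]]
  } else {
    i <- which.min(abs(cutoffs - cutoff))
    net <- nets[[i]]
  }
  simulate_ensemble(as_topology(net), n_models = nsim, n_inits = n_inits,
                    seed = seed, ...)
}

#' Plot a fitted core-network model
#'
#' `type = "activity"` draws a clustered heatmap of the inferred activity
#' matrix; `type = "network"` draws the selected network on a circular
#' layout with activation in blue and inhibition in red.
#'
#' @param x a `regulonet` fit.
#' @param type `"activity"` or `"network"`.
#' @param cutoff for `type = "network"`, see [simulate.regulonet()].
#' @param ... passed on to the underlying plotting function.
#' @return `x`, invisibly.
#' @export
plot.regulonet <- function(x, type = c("activity", "network"),
                           cutoff = NULL, ...) {
  type <- match.arg(type)
  if (type == "activity") {
    if (nrow(x$activity) < 2L) stop("need >= 2 TFs to draw a heatmap")
    stats::heatmap(x$activity, scale = "none",
                   col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                   ...)
  } else {
    nets <- x$network$networks
    i <- if (is.null(cutoff)) 1L else which.min(abs(x$network$cutoffs -
                                                      cutoff))
    net <- nets[[i]]
    if (!length(net$nodes)) stop("selected network is empty")
    nn <- length(net$nodes)
    th <- seq(0, 2 * pi, length.out = nn + 1L)[-(nn + 1L)]
    xs <- cos(th); ys <- sin(th)
    graphics::plot(xs, ys, asp = 1, axes = FALSE, xlab = "", ylab = "",
                   pch = 21, bg = "grey90", cex = 2.5,
                   xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25), ...)
    idx <- stats::setNames(seq_len(nn), net$nodes)
    for (r in seq_len(nrow(net$edges))) {
      e <- net$edges[r, ]
      graphics::arrows(xs[idx[e$source]], ys[idx[e$source]],
                       xs[idx[e$target]], ys[idx[e$target]],
                       length = 0.08,
                       col = if (e$sign > 0) "steelblue" else "firebrick")
    }
    graphics::text(1.15 * xs, 1.15 * ys, net$nodes, cex = 0.7)
  }
  invisible(x)
}
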