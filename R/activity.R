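#' Spearman correlation matrix of a TF's targets
#'
#' @param expr genes x samples numeric matrix (>= 3 samples).
#' @param targets gene symbols; at least 2 must be rows of `expr`.
#' @return symmetric rank-correlation matrix with unit diagonal. Rows with
#'   zero variance get zero correlations (with a warning): a constant gene
#'   carries no co-expression signal.
#' @export
target_correlation <- function(expr, targets) {
  targets <- intersect(targets, rownames(expr))
  if (length(targets) < 2L) stop("need at least 2 targets present in expr")
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  x <- t(expr[targets, , drop = FALSE])
  const <- apply(x, 2L, function(v) stats::sd(v) == 0)
  r <- suppressWarnings(stats::cor(x, method = "spearman"))
  if (any(const)) {
    warning("constant target gene(s): ",
            paste(targets[const], collapse = ", "))
    r[const, ] <- 0
    r[, const] <- 0
  }
  diag(r) <- 1
  r
}

#' Bipartition target genes by signed spectral modularity
#'
#' Splits a TF's targets into a putatively activated and a putatively
#' inhibited module using the leading eigenvector of the signed modularity
#' matrix of the correlation graph (weighted adjacency = correlation matrix
#' with zeroed diagonal; the null model subtracts the positive-weight
#' expectation and adds back the negative-weight expectation). When the
#' leading eigenvalue is non-positive the graph is indivisible -- all
#' correlations coherent -- and every gene goes into the first module.
#' Which module is "activated" is not decided here; signs are assigned
#' downstream (see [align_activity_sign()]).
#'
#' @param corr square correlation matrix from [target_correlation()].
#' @return object of class `target_grouping`: list with `group_pos`,
#'   `group_neg`, `filtered_out` (empty here), `scheme = "no_tf_expr"`,
#'   `flipped = FALSE`.
#' @export
split_two_groups <- function(corr) {
  p <- nrow(corr)
  if (is.null(p) || p < 2L) stop("need a correlation matrix of >= 2 genes")
  genes <- rownames(corr)
  a <- corr
  diag(a) <- 0
  apos <- pmax(a, 0); aneg <- pmax(-a, 0)
  kp <- rowSums(apos); kn <- rowSums(aneg)
  mp <- sum(kp); mn <- sum(kn)
  b <- a
  if (mp > 0) b <- b - outer(kp, kp) / mp
  if (mn > 0) b <- b + outer(kn, kn) / mn
  e <- eigen(b, symmetric = TRUE)
  if (e$values[1] <= 1e-10) {
    gp <- genes
    gn <- character()
  } else {
    v <- e$vectors[, 1]
    gp <- genes[v >= 0]
    gn <- genes[v < 0]
    if (!length(gp)) { gp <- gn; gn <- character() }
  }
  structure(list(group_pos = gp, group_neg = gn,
                 filtered_out = character(),
                 scheme = "no_tf_expr", flipped = FALSE),
            class = "target_grouping")
}

#' @export
print.target_grouping <- function(x, ...) {
  cat(sprintf("target_grouping (%s%s): +%d / -%d genes, %d filtered\n",
              x$scheme, if (x$flipped) ", flipped" else "",
              length(x$group_pos), length(x$group_neg),
              length(x$filtered_out)))
  invisible(x)
}

#' Filter incoherent targets within each module
#'
#' Each target's feature vector is its row of correlations with all targets.
#' Within each module, the k = 1 centroid is the member-wise mean vector and
#' a gene is filtered out when its squared Euclidean distance to the centroid
#' strictly exceeds the module's mean distance. Because the minimum distance
#' can never exceed the mean, a module is never emptied. Single-pass by
#' contract: distances are not recomputed on the survivor set.
#'
#' @param grouping a `target_grouping` from [split_two_groups()].
#' @param corr the correlation matrix the grouping was derived from.
#' @return the grouping with incoherent genes moved to `filtered_out`.
#' @export
filter_incoherent <- function(grouping, corr) {
  stopifnot(inherits(grouping, "target_grouping"))
  dropped <- character()
  for (side in c("group_pos", "group_neg")) {
    members <- grouping[[side]]
    if (length(members) < 2L) next
    feat <- corr[members, , drop = FALSE]
    center <- colMeans(feat)
    d <- rowSums((feat - rep(center, each = nrow(feat)))^2)
    out <- members[d > mean(d)]
    grouping[[side]] <- setdiff(members, out)
    dropped <- c(dropped, out)
  }
  grouping$filtered_out <- union(grouping$filtered_out, dropped)
  grouping
}

#' Hill weighting of a gene's differential-expression significance
#'
#' `w = 1 / (1 + (s / s0)^n)`: a decreasing Hill function of the adjusted
#' p-value, so strongly differential targets dominate the activity average.
#' At `s = s0` the weight is exactly 1/2.
#'
#' @param s adjusted p-value(s) in `[0, 1]`; values are clamped below at
#'   machine epsilon before exponentiation.
#' @param s0 half-weight threshold, default 0.05.
#' @param n Hill exponent, default 1/5 (a shallow curve, so even
#'   non-significant targets retain appreciable weight).
#' @return weight(s) in `(0, 1]`.
#' @examples
#' hill_weight(0.05)        # exactly 0.5
#' hill_weight(1)           # ~0.355
#' @export
hill_weight <- function(s, s0 = 0.05, n = 1 / 5) {
  stopifnot(s0 > 0, s0 < 1, n > 0)
  if (any(s < 0 | s > 1)) stop("adjusted p-values must lie in [0, 1]")
  s <- pmax(s, .Machine$double.eps)
  1 / (1 + (s / s0)^n)
}

#' TF activity as a Hill-weighted signed average of target z-scores
#'
#' Activity per sample is `sum(w_i g_i I_i) / sum(w_i)` over the grouped,
#' unfiltered targets: `g_i` the gene's standardized expression, `I_i` +1
#' for the first module and -1 for the second, and `w_i` the Hill weight of
#' the gene's adjusted p-value. With `de = NULL` all weights are equal
#' (the unweighted signed mean), the single-condition case where no
#' differential contrast exists.
#'
#' @param expr_z genes x samples matrix of per-gene z-scores (standardized
#'   across all samples; see [standardize_expression()]).
#' @param grouping a `target_grouping`.
#' @param de optional `de_result` supplying `s_adj` per gene.
#' @param s0,n Hill weight parameters, see [hill_weight()].
#' @return named numeric activity vector over samples.
#' @export
compute_activity <- function(expr_z, grouping, de = NULL, s0 = 0.05,
                             n = 1 / 5) {
  genes <- c(grouping$group_pos, grouping$group_neg)
  if (!length(genes)) stop("grouping has no retained genes")
  missing <- setdiff(genes, rownames(expr_z))
  if (length(missing))
    stop("grouped gene(s) absent from expression: ",
         paste(missing, collapse = ", "))
  sgn <- c(rep(1, length(grouping$group_pos)),
           rep(-1, length(grouping$group_neg)))
  if (is.null(de)) {
    w <- rep(1, length(genes))
  } else {
    idx <- match(genes, de$gene)
    if (anyNA(idx))
      stop("grouped gene(s) missing from DE result: ",
           paste(genes[is.na(idx)], collapse = ", "))
    w <- hill_weight(de$s_adj[idx], s0 = s0, n = n)
  }
  z <- expr_z[genes, , drop = FALSE]
  drop(crossprod(z, w * sgn)[, 1] / sum(w))
}

#' Standardize expression per gene
#'
#' z-scores each gene across all samples (mean 0, sd 1), the `g_i` input of
#' the activity average. Standardization spans conditions so activities are
#' comparable across them. Constant genes map to all-zero rows.
#'
#' @param expr genes x samples matrix.
#' @return matrix of the same shape.
#' @export
standardize_expression <- function(expr) {
  expr <- as.matrix(expr)
  if (anyNA(expr)) stop("expr contains missing values")
  m <- rowMeans(expr)
  s <- sqrt(rowSums((expr - m)^2) / (ncol(expr) - 1L))
  s[s == 0] <- 1
  (expr - m) / s
}

#' Align activity sign with TF expression
#'
#' The two-module split does not know which module the TF activates. For a
#' differentially expressed TF the convention comes from its own expression:
#' if Spearman correlation between activity and TF expression is negative,
#' the activity is negated and the module labels swap. Zero correlation (or
#' constant TF expression, with a warning) leaves the sign untouched.
#'
#' @param activity activity vector over samples.
#' @param tf_expr the TF's own expression over the same samples.
#' @param grouping the `target_grouping` that produced the activity.
#' @return list with elements `activity` and `grouping` (with `flipped`
#'   updated).
#' @export
align_activity_sign <- function(activity, tf_expr, grouping) {
  if (stats::sd(tf_expr) == 0) {
    warning("constant TF expression; activity sign left as computed")
    return(list(activity = activity, grouping = grouping))
  }
  rho <- suppressWarnings(
    stats::cor(activity, tf_expr, method = "spearman"))
  if (!is.na(rho) && rho < 0) {
    tmp <- grouping$group_pos
    grouping$group_pos <- grouping$group_neg
    grouping$group_neg <- tmp
    grouping$flipped <- !grouping$flipped
    activity <- -activity
  }
  list(activity = activity, grouping = grouping)
}

#' Group targets by the sign of their correlation with TF expression
#'
#' The alternative grouping scheme, used when target co-expression is too
#' noisy for the spectral split: targets with positive (or zero) Spearman
#' correlation to the TF's own expression form the first module, negative
#' the second, and targets whose absolute correlation falls strictly below
#' the mean absolute correlation of all targets are filtered out.
#'
#' @param expr genes x samples matrix containing the TF row.
#' @param tf TF symbol (must be a row of `expr`).
#' @param targets target gene symbols (>= 2 present in `expr`).
#' @return a `target_grouping` with `scheme = "with_tf_expr"`.
#' @export
split_by_tf_correlation <- function(expr, tf, targets) {
  if (!tf %in% rownames(expr)) stop("TF not in expression matrix: ", tf)
  targets <- intersect(setdiff(targets, tf), rownames(expr))
  if (length(targets) < 2L) stop("need at least 2 targets present in expr")
  rho <- suppressWarnings(apply(expr[targets, , drop = FALSE], 1L,
                                function(v) stats::cor(v, expr[tf, ],
                                                       method = "spearman")))
  rho[is.na(rho)] <- 0
  keep <- abs(rho) >= mean(abs(rho))  # strict <: equal-|rho| sets pass whole
  structure(list(group_pos = targets[keep & rho >= 0],
                 group_neg = targets[keep & rho < 0],
                 filtered_out = targets[!keep],
                 scheme = "with_tf_expr", flipped = FALSE),
            class = "target_grouping")
}

#' Choose between the two activity-inference schemes
#'
#' Computes activity both without TF expression (spectral split + coherence
#' filter) and with it (correlation-sign split), scores each scheme by the
#' mean absolute Spearman correlation between its activity and the
#' expression of its retained targets, and returns the higher-scoring
#' scheme. Ties, and failure of the TF-expression scheme, fall back to the
#' scheme without TF expression (the default scheme).
#'
#' @param expr genes x samples matrix (raw log scale, for correlations).
#' @param expr_z its standardized counterpart (for the activity average).
#' @param tf TF symbol.
#' @param targets the TF's usable targets.
#' @param de optional `de_result` for Hill weights.
#' @param s0,n Hill weight parameters.
#' @return list with `activity`, `grouping`, `score`.
#' @export
choose_scheme <- function(expr, expr_z, tf, targets, de = NULL, s0 = 0.05,
                          n = 1 / 5) {
  run <- function(grouping) {
    act <- compute_activity(expr_z, grouping, de = de, s0 = s0, n = n)
    kept <- c(grouping$group_pos, grouping$group_neg)
    sc <- mean(vapply(kept, function(g)
      abs(suppressWarnings(stats::cor(act, expr[g, ],
                                      method = "spearman"))),
      numeric(1)), na.rm = TRUE)
    list(activity = act, grouping = grouping, score = sc)
  }
  corr <- target_correlation(expr, targets)
  s1 <- run(filter_incoherent(split_two_groups(corr), corr))
  s2 <- tryCatch(run(split_by_tf_correlation(expr, tf, targets)),
                 error = function(e) NULL)
  if (is.null(s2) || is.na(s2$score) || s2$score <= s1$score) s1 else s2
}

#' Infer the TF activity matrix
#'
#' Orchestrates activity inference for a set of selected TFs. TFs flagged
#' differential (via [de_genes()] on `de`) are routed through scheme
#' selection and activity-sign alignment with their own expression; other
#' TFs use the scheme without TF expression and, lacking an expression
#' trend to set the sign, either take an explicit sign override or keep the
#' computed sign with a warning listing their top regulon-overlap partners
#' among the DE TFs as a curation aid.
#'
#' @param expr genes x samples matrix, log scale.
#' @param db a [regulon_db()].
#' @param tfs character vector of TFs to infer (subset of `names(db)`).
#' @param de optional `de_result`; `NULL` means uniform weights and no
#'   DE/non-DE routing (every TF treated as non-DE, silently).
#' @param s0,n Hill weight parameters.
#' @param min_targets minimum usable targets per TF (default 5); TFs below
#'   it are skipped with a warning.
#' @param sign_overrides optional named numeric vector (+1/-1 per TF symbol)
#'   forcing the activity sign of non-DE TFs.
#' @param de_p_cut,de_fc_cut thresholds passed to [de_genes()].
#' @return TFs x samples activity matrix with the per-TF `target_grouping`
#'   list attached as attribute `"groupings"` and skipped TFs as
#'   `"skipped"`.
#' @export
infer_activity <- function(expr, db, tfs, de = NULL, s0 = 0.05, n = 1 / 5,
                           min_targets = 5L, sign_overrides = NULL,
                           de_p_cut = 0.05, de_fc_cut = 2) {
  expr <- as.matrix(expr)
  tfs <- intersect(tfs, names(db))
  expr_z <- standardize_expression(expr)
  de_set <- if (is.null(de)) character() else
    de_genes(de, p_cut = de_p_cut, fc_cut = de_fc_cut)
  rows <- list()
  groupings <- list()
  skipped <- character()
  for (tf in tfs) {
    targets <- intersect(setdiff(db[[tf]], tf), rownames(expr))
    if (length(targets) < min_targets) {
      skipped <- c(skipped, tf)
      next
    }
    if (tf %in% de_set && tf %in% rownames(expr)) {
      fit <- choose_scheme(expr, expr_z, tf, targets, de = de, s0 = s0,
                           n = n)
      al <- align_activity_sign(fit$activity, expr[tf, ], fit$grouping)
      act <- al$activity
      grouping <- al$grouping
    } else {
      corr <- target_correlation(expr, targets)
      grouping <- filter_incoherent(split_two_groups(corr), corr)
      act <- compute_activity(expr_z, grouping, de = de, s0 = s0, n = n)
      ov <- sign_overrides[tf]
      if (!is.null(sign_overrides) && !is.na(ov)) {
        if (!ov %in% c(-1, 1)) stop("sign override must be +1 or -1: ", tf)
        if (ov == -1) {
          act <- -act
          tmp <- grouping$group_pos
          grouping$group_pos <- grouping$group_neg
          grouping$group_neg <- tmp
          grouping$flipped <- TRUE
        }
      } else if (!is.null(de)) {
        partners <- rank_overlap_partners(db, tf,
                                          intersect(de_set, names(db)),
                                          universe_size = nrow(expr))
        hint <- if (nrow(partners))
          paste(utils::head(partners$partner, 3L), collapse = ", ")
        else "none found"
        warning(sprintf(
          "non-DE TF %s: activity sign left as computed; top overlap partners: %s",
          tf, hint))
      }
    }
    grouping$tf <- tf
    rows[[tf]] <- act
    groupings[[tf]] <- grouping
  }
  if (length(skipped))
    warning("TFs skipped (< ", min_targets, " usable targets): ",
            paste(skipped, collapse = ", "))
  act <- if (length(rows))
    do.call(rbind, rows)
  else
    matrix(numeric(), 0L, ncol(expr), dimnames = list(NULL, colnames(expr)))
  colnames(act) <- colnames(expr)
  structure(act, groupings = groupings, skipped = skipped)
}
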