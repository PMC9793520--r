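#' Generate a ground-truth synthetic TF-target network
#'
#' Builds a hierarchical random GRN: `n_tf` TFs, each regulating
#' `targets_per_tf` distinct genes drawn from a shared pool of `n_pool`
#' genes (a pool gene may serve several TFs, so target sharing arises
#' naturally) plus `tf_out_degree` distinct other TFs. TF-to-TF edges are
#' excitatory, inhibitory, or signaling with probabilities `p_types_tf`
#' (signaling edges then carry an excitatory or inhibitory sign with equal
#' chance); TF-to-target edges are excitatory or inhibitory with
#' probabilities `p_types_target`. The pool is disjoint from the TF set;
#' pool genes never referenced are omitted from the node list. With the
#' defaults the network has exactly `30*20 + 30*2 = 660` directed links.
#'
#' @param n_tf number of TFs (default 30).
#' @param targets_per_tf targets per TF (default 20).
#' @param n_pool target-pool size (default 1000).
#' @param tf_out_degree TF-TF edges per TF (default 2).
#' @param p_types_tf probabilities of (excitatory, inhibitory, signaling)
#'   for TF-TF edges; default `c(0.25, 0.25, 0.50)`.
#' @param p_types_target probabilities of (excitatory, inhibitory) for
#'   TF-target edges; default `c(0.5, 0.5)`.
#' @param seed optional integer seed.
#' @return object of class `synthetic_grn`: list with `topology` (a
#'   [topology()]), `regulons` (a [regulon_db()] of each TF's pool
#'   targets), `tf_edges` (the TF-TF triples), `tfs`, `targets` (the
#'   referenced pool genes), `pool` (all pool gene names).
#' @export
synthetic_grn <- function(n_tf = 30L, targets_per_tf = 20L, n_pool = 1000L,
                          tf_out_degree = 2L,
                          p_types_tf = c(0.25, 0.25, 0.50),
                          p_types_target = c(0.5, 0.5), seed = NULL) {
  stopifnot(n_tf >= 2L, targets_per_tf >= 1L, tf_out_degree >= 1L,
            tf_out_degree < n_tf,
            abs(sum(p_types_tf) - 1) < 1e-12,
            abs(sum(p_types_target) - 1) < 1e-12)
  if (targets_per_tf > n_pool)
    stop("targets_per_tf exceeds the target pool size")
  if (!is.null(seed)) set.seed(seed)
  tfs <- paste0("TF", seq_len(n_tf))
  pool <- paste0("G", seq_len(n_pool))
  edges <- vector("list", 2L * n_tf)
  regulons <- vector("list", n_tf)
  for (i in seq_len(n_tf)) {
    tg <- sample(pool, targets_per_tf)
    tg_type <- ifelse(
      sample(c(TRUE, FALSE), targets_per_tf, replace = TRUE,
             prob = p_types_target),
      "excitatory", "inhibitory")
    partners <- sample(setdiff(tfs, tfs[i]), tf_out_degree)
    cls <- sample(c("excitatory", "inhibitory", "signaling"),
                  tf_out_degree, replace = TRUE, prob = p_types_tf)
    sig_sign <- sample(c("signaling_excitatory", "signaling_inhibitory"),
                       tf_out_degree, replace = TRUE)
    tf_type <- ifelse(cls == "signaling", sig_sign, cls)
    edges[[2L * i - 1L]] <- data.frame(source = tfs[i], target = tg,
                                       type = tg_type)
    edges[[2L * i]] <- data.frame(source = tfs[i], target = partners,
                                  type = tf_type)
    regulons[[i]] <- tg
  }
  all_edges <- do.call(rbind, edges)
  tf_edges <- all_edges[all_edges$target %in% tfs, , drop = FALSE]
  structure(list(topology = topology(all_edges),
                 regulons = regulon_db(stats::setNames(regulons, tfs),
                                       species = "synthetic"),
                 tf_edges = tf_edges,
                 tfs = tfs,
                 targets = sort(unique(unlist(regulons))),
                 pool = pool,
                 params = list(n_tf = n_tf,
                               targets_per_tf = targets_per_tf,
                               n_pool = n_pool,
                               tf_out_degree = tf_out_degree)),
            class = "synthetic_grn")
}

#' @export
print.synthetic_grn <- function(x, ...) {
  cat(sprintf("synthetic_grn: %d TFs, %d distinct targets, %d directed links\n",
              length(x$tfs), length(x$targets), nrow(x$topology)))
  invisible(x)
}

#' Simulate benchmark expression and activity profiles
#'
#' Runs the random-parameter ensemble simulator on the synthetic network
#' and pools the distinct stable states as samples, returning matched
#' expression and activity matrices over all network genes. TF activity
#' in the benchmark data carries random protein-level variability
#' (`protein_noise`, default one decade of half-spread) on top of the
#' signaling factors, emulating the fact that a TF's regulatory output is
#' set by its protein state, which transcriptomics does not measure; this
#' is what makes TF expression an imperfect surrogate of TF activity in
#' the benchmark. An optional knockdown reduces the named TF's production
#' rate, giving a perturbed condition paired with the unperturbed run at
#' the same seed.
#'
#' @param grn a [synthetic_grn()].
#' @param n_models ensemble size (default 100).
#' @param n_inits initial conditions per model (default 1: one state drawn
#'   per model, non-converged models dropped).
#' @param seed optional integer seed.
#' @param knockdown optional `list(gene =, factor =)`.
#' @param protein_noise log10 half-spread of the per-model TF protein
#'   factor, see [sample_model()].
#' @param ... passed to [simulate_ensemble()].
#' @return list of class `grn_sim` with `expression` and `activity`
#'   (genes x states, raw levels), `ensemble`, `condition` (a label,
#'   `"wt"` or `"kd:<gene>"`).
#' @export
simulate_grn_data <- function(grn, n_models = 100L, n_inits = 1L,
                              seed = NULL, knockdown = NULL,
                              protein_noise = 1, ...) {
  stopifnot(inherits(grn, "synthetic_grn"))
  ens <- simulate_ensemble(grn$topology, n_models = n_models,
                           n_inits = n_inits, seed = seed,
                           knockdown = knockdown,
                           protein_noise = protein_noise, ...)
  expr <- state_matrix(ens, "expression", log2 = FALSE,
                       standardize = FALSE)
  act <- state_matrix(ens, "activity", log2 = FALSE, standardize = FALSE)
  cond <- if (is.null(knockdown)) "wt" else paste0("kd:", knockdown$gene)
  colnames(expr) <- colnames(act) <- paste0(cond, ".", colnames(expr))
  structure(list(expression = expr, activity = act, ensemble = ens,
                 condition = cond),
            class = "grn_sim")
}

#' Perturb regulons by random target replacement
#'
#' Mimics an imperfect literature database: per repeat and per TF,
#' `n_replace` of the true targets are swapped for genes drawn (without
#' replacement) from the pool excluding that TF's true targets, preserving
#' regulon size. `n_replace` of 0/5/10/15 out of 20 corresponds to
#' 0/25/50/75 percent perturbation.
#'
#' @param grn a [synthetic_grn()].
#' @param n_replace targets to replace per TF.
#' @param n_repeats number of independently perturbed databases.
#' @param seed optional integer seed.
#' @return list of `n_repeats` [regulon_db()] objects.
#' @export
perturb_regulons <- function(grn, n_replace, n_repeats = 1L, seed = NULL) {
  stopifnot(inherits(grn, "synthetic_grn"),
            n_replace <= grn$params$targets_per_tf, n_replace >= 0L)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_repeats), function(r) {
    sets <- lapply(names(grn$regulons), function(tf) {
      true <- grn$regulons[[tf]]
      if (n_replace == 0L) return(true)
      out <- sample(true, length(true) - n_replace)
      decoys_from <- setdiff(grn$pool, true)
      if (length(decoys_from) < n_replace)
        stop("target pool exhausted for decoy sampling")
      c(out, sample(decoys_from, n_replace))
    })
    regulon_db(stats::setNames(sets, names(grn$regulons)),
               species = "synthetic")
  })
}

#' Jaccard index of two sets
#'
#' @param a,b vectors treated as sets; their union must be non-empty.
#' @return `|a n b| / |a u b|` in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) stop("both sets are empty")
  length(intersect(a, b)) / u
}

#' Score activity recovery against simulated ground truth
#'
#' For each TF shared between the inferred and the true activity matrices,
#' computes the absolute Spearman correlation of the two rows, then
#' averages over TFs (inference leaves a global sign per TF unidentified
#' in a single-condition design, so the absolute value is the right
#' scale).
#'
#' @param inferred TFs x samples matrix.
#' @param truth TFs x samples matrix over the same samples.
#' @return mean over shared TFs of `|Spearman|`; TFs missing from either
#'   matrix are excluded with a warning.
#' @export
activity_recovery <- function(inferred, truth) {
  shared <- intersect(rownames(inferred), rownames(truth))
  if (!length(shared)) stop("no shared TFs")
  if (length(shared) < nrow(truth))
    warning("TFs missing from inferred activity: ",
            paste(setdiff(rownames(truth), shared), collapse = ", "))
  mean(vapply(shared, function(tf)
    abs(suppressWarnings(stats::cor(inferred[tf, ], truth[tf, ],
                                    method = "spearman"))),
    numeric(1)), na.rm = TRUE)
}

#' Activity-recovery benchmark across regulon perturbation levels
#'
#' The in-silico headline experiment: infer TF activity from simulated
#' expression using increasingly corrupted regulon databases and score the
#' recovery of the simulated (ground-truth) activities. Reported per level
#' is the median over repeats of the TF-averaged absolute Spearman
#' correlation, plus the same score computed from the TFs' own expression
#' rows as the baseline activity estimate.
#'
#' @param grn a [synthetic_grn()].
#' @param sim a `grn_sim` from [simulate_grn_data()] (or a combined one
#'   from [combine_grn_sims()]).
#' @param levels numbers of replaced targets per TF (default
#'   `c(0, 5, 10, 15)`).
#' @param n_repeats perturbed databases per level (default 20).
#' @param seed optional integer seed.
#' @param de optional `de_result` for Hill weighting (two-condition
#'   designs); `NULL` gives uniform weights.
#' @param min_targets passed to [infer_activity()].
#' @return data.frame of class `activity_benchmark` with columns `level`
#'   (fraction replaced), `n_replace`, `median_recovery`; attribute
#'   `expression_baseline` holds the TF-expression score.
#' @export
run_activity_benchmark <- function(grn, sim, levels = c(0L, 5L, 10L, 15L),
                                   n_repeats = 20L, seed = NULL,
                                   de = NULL, min_targets = 2L) {
  if (!is.null(seed)) set.seed(seed)
  truth <- sim$activity[grn$tfs, , drop = FALSE]
  rows <- lapply(levels, function(nr) {
    dbs <- perturb_regulons(grn, n_replace = nr,
                            n_repeats = if (nr == 0L) 1L else n_repeats)
    scores <- vapply(dbs, function(db) {
      inferred <- suppressWarnings(
        infer_activity(sim$expression, db, tfs = names(db), de = de,
                       min_targets = min_targets))
      suppressWarnings(activity_recovery(inferred, truth))
    }, numeric(1))
    data.frame(n_replace = nr,
               level = nr / grn$params$targets_per_tf,
               median_recovery = stats::median(scores))
  })
  out <- do.call(rbind, rows)
  baseline <- suppressWarnings(
    activity_recovery(sim$expression[grn$tfs, , drop = FALSE], truth))
  structure(out, expression_baseline = baseline,
            class = c("activity_benchmark", "data.frame"))
}

#' Combine simulated conditions into one dataset
#'
#' Column-binds the expression and activity matrices of several simulated
#' conditions (e.g. unperturbed plus a TF knockdown) and records the
#' per-sample condition labels.
#'
#' @param ... `grn_sim` objects over the same genes.
#' @return a `grn_sim` with an added `conditions` vector.
#' @export
combine_grn_sims <- function(...) {
  sims <- list(...)
  stopifnot(length(sims) >= 2L)
  expr <- do.call(cbind, lapply(sims, `[[`, "expression"))
  act <- do.call(cbind, lapply(sims, `[[`, "activity"))
  conds <- unlist(lapply(sims, function(s)
    rep(s$condition, ncol(s$expression))))
  structure(list(expression = expr, activity = act,
                 condition = paste(unique(conds), collapse = "+"),
                 conditions = conds),
            class = "grn_sim")
}

#' Precision-recall of a ranked undirected edge prediction
#'
#' Sweeps prefixes of the MI-ranked pair list: at each threshold,
#' precision is the fraction of predicted pairs that are true and recall
#' the fraction of true pairs predicted. Pairs are undirected because
#' mutual information is symmetric. For the novel-interaction variant,
#' pairs in `exclude` (e.g. TF pairs already implied by the regulon
#' database used for inference) are removed from both prediction and
#' truth.
#'
#' @param ranked_pairs data.frame with columns `a`, `b`, `score`, ranked
#'   or rankable by decreasing score.
#' @param truth_pairs data.frame with columns `a`, `b` of true undirected
#'   pairs.
#' @param exclude optional data.frame (`a`, `b`) of pairs to drop.
#' @return data.frame with `threshold` (prefix size), `precision`,
#'   `recall`; attribute `aupr` holds the trapezoidal area under the
#'   precision-recall curve.
#' @export
network_pr <- function(ranked_pairs, truth_pairs, exclude = NULL) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  truth <- unique(key(truth_pairs$a, truth_pairs$b))
  if (!length(truth)) stop("empty truth set")
  pred <- ranked_pairs[order(-ranked_pairs$score), , drop = FALSE]
  pk <- key(pred$a, pred$b)
  dup <- duplicated(pk)
  pk <- pk[!dup]
  if (!is.null(exclude) && nrow(exclude)) {
    ex <- unique(key(exclude$a, exclude$b))
    truth <- setdiff(truth, ex)
    pk <- setdiff(pk, ex)
    if (!length(truth)) stop("truth set empty after exclusion")
  }
  hit <- pk %in% truth
  tp <- cumsum(hit)
  kgrid <- seq_along(pk)
  prec <- tp / kgrid
  rec <- tp / length(truth)
  aupr <- sum(diff(c(0, rec)) * prec)
  structure(data.frame(threshold = kgrid, precision = prec, recall = rec),
            aupr = aupr, n_truth = length(truth),
            class = c("network_pr", "data.frame"))
}

#' MI-ranked TF pairs from an activity (or expression) matrix
#'
#' @param mat TFs x samples matrix.
#' @param n_bins see [mutual_information()].
#' @return data.frame (`a`, `b`, `score`) of all unordered row pairs
#'   ranked by decreasing mutual information.
#' @export
rank_tf_pairs <- function(mat, n_bins = NULL) {
  mi <- suppressWarnings(mi_matrix(mat, n_bins = n_bins))
  idx <- which(upper.tri(mi), arr.ind = TRUE)
  out <- data.frame(a = rownames(mi)[idx[, 1]],
                    b = rownames(mi)[idx[, 2]],
                    score = mi[idx])
  out[order(-out$score), , drop = FALSE]
}

#' Regulon recovery by MI ranking: activity versus expression profiles
#'
#' For each TF, ranks every simulated pool gene by the mutual information
#' between the TF's profile (its simulated activity row, or its expression
#' row) and the gene's expression, takes the top `targets_per_tf` genes as
#' the recovered regulon, and scores it against the true regulon by the
#' Jaccard index.
#'
#' @param grn a [synthetic_grn()].
#' @param sim a `grn_sim`.
#' @param n_bins see [mutual_information()].
#' @return data.frame with columns `tf`, `jaccard_activity`,
#'   `jaccard_expression`.
#' @export
regulon_recovery_mi <- function(grn, sim, n_bins = NULL) {
  genes <- intersect(grn$targets, rownames(sim$expression))
  expr_g <- sim$expression[genes, , drop = FALSE]
  k <- grn$params$targets_per_tf
  rows <- lapply(grn$tfs, function(tf) {
    score_against <- function(profile) {
      mi <- vapply(genes, function(g)
        suppressWarnings(mutual_information(profile, expr_g[g, ],
                                            n_bins = n_bins)),
        numeric(1))
      top <- genes[order(-mi)][seq_len(min(k, length(genes)))]
      jaccard(top, grn$regulons[[tf]])
    }
    data.frame(tf = tf,
               jaccard_activity = score_against(sim$activity[tf, ]),
               jaccard_expression = score_against(sim$expression[tf, ]))
  })
  do.call(rbind, rows)
}
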