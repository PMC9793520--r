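#' Mutual information on equal-frequency bins
#'
#' Plug-in mutual information (natural-log units) after discretizing each
#' vector into `n_bins` equal-frequency bins by rank (ties broken by input
#' order, so the estimate is invariant under strictly monotone transforms
#' of either argument). A constant vector carries no information and
#' returns 0 with a warning.
#'
#' @param x,y numeric vectors of equal length >= 6.
#' @param n_bins number of bins (>= 2); default
#'   `max(2, floor(sqrt(length(x) / 5)))`, a conservative rate for the
#'   small sample sizes typical of activity matrices.
#' @return non-negative mutual information in nats; equals `log(n_bins)`
#'   for `y` a monotone function of `x` when the length is divisible by
#'   `n_bins`.
#' @export
mutual_information <- function(x, y, n_bins = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 6L)
  if (is.null(n_bins)) n_bins <- max(2L, floor(sqrt(n / 5)))
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector; mutual information set to 0")
    return(0)
  }
  bx <- .ef_bins(x, n_bins)
  by <- .ef_bins(y, n_bins)
  joint <- table(bx, by) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
}

# equal-frequency bin index by rank; ties.method "first" keeps the map
# deterministic and injective
.ef_bins <- function(x, n_bins) {
  r <- rank(x, ties.method = "first")
  ceiling(r * n_bins / length(x))
}

#' Pairwise mutual information of activity rows
#'
#' @param act TFs x samples activity matrix.
#' @param n_bins see [mutual_information()].
#' @return symmetric matrix of pairwise MI (diagonal `NA`).
#' @export
mi_matrix <- function(act, n_bins = NULL) {
  k <- nrow(act)
  m <- matrix(NA_real_, k, k, dimnames = list(rownames(act), rownames(act)))
  if (k < 2L) return(m)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      m[i, j] <- m[j, i] <- mutual_information(act[i, ], act[j, ],
                                               n_bins = n_bins)
    }
  }
  m
}

#' Construct the signed core TF-TF network
#'
#' Candidate directed edges are the TF-TF pairs supported by the regulon
#' database (`a -> b` iff `b` is in `a`'s regulon and both have activity
#' rows). An edge is kept when the mutual information of the two activity
#' rows strictly exceeds `mi_cutoff`; its sign is the sign of the Spearman
#' correlation of the two rows (exactly zero correlation cannot be signed
#' and drops the edge). TFs left without edges are removed from the node
#' list.
#'
#' @param act TFs x samples activity matrix (>= 2 TFs).
#' @param db a [regulon_db()] providing the directed TF-TF support.
#' @param mi_cutoff mutual-information threshold (default 0).
#' @param n_bins see [mutual_information()].
#' @return object of class `grn`: list with `nodes` and an `edges`
#'   data.frame (`source`, `target`, `sign`, `mi`).
#' @export
construct_network <- function(act, db, mi_cutoff = 0, n_bins = NULL) {
  stopifnot(nrow(act) >= 2L, inherits(db, "regulon_db"))
  tfs <- rownames(act)
  mi <- mi_matrix(act, n_bins = n_bins)
  rho <- suppressWarnings(stats::cor(t(act), method = "spearman"))
  edges <- list()
  for (a in intersect(tfs, names(db))) {
    for (b in intersect(db[[a]], setdiff(tfs, a))) {
      if (is.na(mi[a, b]) || mi[a, b] <= mi_cutoff) next
      s <- sign(rho[a, b])
      if (is.na(s) || s == 0) next  # unsignable
      edges[[length(edges) + 1L]] <-
        data.frame(source = a, target = b, sign = s, mi = mi[a, b])
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
  else data.frame(source = character(), target = character(),
                  sign = numeric(), mi = numeric())
  nodes <- sort(unique(c(edges$source, edges$target)))
  structure(list(nodes = nodes, edges = edges, mi_cutoff = mi_cutoff),
            class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("grn: %d TFs, %d signed edges (MI > %.3g)\n",
              length(x$nodes), nrow(x$edges), x$mi_cutoff))
  invisible(x)
}

#' Sweep MI cutoffs to produce nested candidate networks
#'
#' Higher cutoffs keep subsets of the edges kept at lower cutoffs, yielding
#' candidate networks of decreasing size for downstream model selection by
#' ensemble simulation.
#'
#' @param act TFs x samples activity matrix.
#' @param db a [regulon_db()].
#' @param cutoffs ascending MI thresholds.
#' @param n_bins see [mutual_information()].
#' @return object of class `grn_sweep`: list with `cutoffs`, `networks`
#'   (one `grn` per cutoff) and a `sizes` data.frame.
#' @export
network_sweep <- function(act, db, cutoffs, n_bins = NULL) {
  stopifnot(length(cutoffs) >= 1L)
  cutoffs <- sort(cutoffs)
  nets <- lapply(cutoffs, function(cf)
    construct_network(act, db, mi_cutoff = cf, n_bins = n_bins))
  sizes <- data.frame(cutoff = cutoffs,
                      n_nodes = vapply(nets, function(g) length(g$nodes),
                                       integer(1)),
                      n_edges = vapply(nets, function(g) nrow(g$edges),
                                       integer(1)))
  structure(list(cutoffs = cutoffs, networks = nets, sizes = sizes),
            class = "grn_sweep")
}

#' @export
print.grn_sweep <- function(x, ...) {
  cat("MI cutoff sweep:\n")
  print(x$sizes, row.names = FALSE)
  invisible(x)
}

#' Write a network as an edge-list TSV or SIF file
#'
#' @param grn a `grn`.
#' @param path output path.
#' @param format `"tsv"` (source, target, sign, mi) or `"sif"`
#'   (source, activates|inhibits, target).
#' @return `path`, invisibly.
#' @export
write_network <- function(grn, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(grn$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    rel <- ifelse(grn$edges$sign > 0, "activates", "inhibits")
    writeLines(paste(grn$edges$source, rel, grn$edges$target, sep = "\t"),
               path)
  }
  invisible(path)
}
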