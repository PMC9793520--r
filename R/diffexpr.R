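#' Two-group differential expression statistics
#'
#' Per-gene Welch two-sample t statistics on log-scale expression, two-sided
#' p-values, Benjamini-Hochberg adjusted p-values and log2 fold changes.
#' The downstream machinery consumes only the rank of `|statistic|` (for
#' enrichment) and the adjusted p-value (as the weighting input of the
#' activity average), so any reasonable two-group statistic preserves the
#' semantics; tables from external fitters (limma moderated t, negative
#' binomial Wald) can be supplied instead through [read_de_table()].
#'
#' @param expr numeric matrix, genes x samples, log-scale values (microarray
#'   log-intensities or RNA-seq log-CPM), with gene symbols as rownames and
#'   sample ids as colnames.
#' @param group_a,group_b disjoint character vectors of sample ids (or column
#'   indices), at least 2 samples each.
#' @return data.frame of class `de_result` with one row per gene and columns
#'   `gene`, `statistic`, `p_value`, `s_adj`, `log2fc`, `flat` (logical: zero
#'   variance in both groups). `log2fc` is `mean(group_b) - mean(group_a)`.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(60), 6, 10,
#'             dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
#' m["g1", 6:10] <- m["g1", 6:10] + 3
#' de <- diff_expression(m, paste0("s", 1:5), paste0("s", 6:10))
#' head(de)
#' @export
diff_expression <- function(expr, group_a, group_b) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expr must have gene symbols as rownames")
  if (anyNA(expr)) stop("expr contains missing values")
  a <- expr[, group_a, drop = FALSE]
  b <- expr[, group_b, drop = FALSE]
  if (length(intersect(colnames(a), colnames(b))))
    stop("groups must be disjoint")
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 samples")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1L)
  vb <- rowSums((b - mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  flat <- se2 == 0
  stat <- ifelse(flat, 0, (mb - ma) / sqrt(ifelse(flat, 1, se2)))
  # Welch-Satterthwaite degrees of freedom
  df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  df[flat] <- na + nb - 2L
  p <- ifelse(flat, 1, 2 * stats::pt(-abs(stat), df))
  out <- data.frame(gene = rownames(expr),
                    statistic = as.numeric(stat),
                    p_value = as.numeric(p),
                    s_adj = stats::p.adjust(p, method = "BH"),
                    log2fc = as.numeric(mb - ma),
                    flat = flat,
                    row.names = rownames(expr))
  class(out) <- c("de_result", "data.frame")
  out
}

#' Import a differential-expression table computed elsewhere
#'
#' @param path TSV/CSV with columns `gene`, `statistic`, `p`, `adj_p`,
#'   `log2fc` (header required; separator sniffed from the first line).
#' @return A `de_result` data.frame as from [diff_expression()].
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("gene", "statistic", "p", "adj_p", "log2fc")
  if (!all(need %in% names(d)))
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(d$gene)) stop("duplicate gene symbols in DE table")
  out <- data.frame(gene = as.character(d$gene),
                    statistic = as.numeric(d$statistic),
                    p_value = as.numeric(d$p),
                    s_adj = as.numeric(d$adj_p),
                    log2fc = as.numeric(d$log2fc),
                    flat = FALSE,
                    row.names = d$gene)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Flag differentially expressed genes
#'
#' A gene is differential when its adjusted p-value is below `p_cut` and its
#' absolute log2 fold change at least `fc_cut` (defaults 0.05 and 2).
#'
#' @param de a `de_result`.
#' @param p_cut adjusted p-value cutoff (strict `<`).
#' @param fc_cut absolute log2 fold-change cutoff (`>=`).
#' @return character vector of DE gene symbols.
#' @export
de_genes <- function(de, p_cut = 0.05, fc_cut = 2) {
  stopifnot(p_cut > 0, fc_cut > 0)
  de$gene[de$s_adj < p_cut & abs(de$log2fc) >= fc_cut]
}

#' Rank genes by absolute test statistic
#'
#' @param de a `de_result`.
#' @return named numeric vector of ranking scores `|statistic|`, sorted
#'   decreasing; ties broken by ascending gene symbol so the order is
#'   deterministic regardless of input row order.
#' @export
rank_genes <- function(de) {
  if (!nrow(de)) stop("empty DE result")
  s <- stats::setNames(abs(de$statistic), de$gene)
  s[order(-s, names(s), method = "radix")]
}
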