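#' Regulon (gene-set) databases
#'
#' A regulon database maps each transcription factor (TF) to the set of genes
#' it is known to regulate (its regulon). The on-disk exchange format is GMT:
#' one tab-separated line per TF with fields name, description, and one field
#' per member gene.
#'
#' @param sets named list of character vectors; names are TF symbols, elements
#'   are target gene symbols.
#' @param species tag recording the symbol convention, one of `"human"`,
#'   `"mouse"`, `"synthetic"`.
#' @return An object of class `regulon_db`: a named list of unique, non-empty
#'   character vectors with a `species` attribute.
#' @examples
#' db <- regulon_db(list(TFA = c("g1", "g2"), TFB = c("g2", "g3")))
#' names(db)
#' @export
regulon_db <- function(sets, species = c("synthetic", "human", "mouse")) {
  species <- match.arg(species)
  if (is.null(names(sets)) || any(names(sets) == "") || anyNA(names(sets)))
    stop("every regulon must be named by its TF symbol")
  if (anyDuplicated(names(sets)))
    stop("duplicate TF symbols: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(x) {
    x <- as.character(x)
    x <- unique(x[!is.na(x) & nzchar(x)])
    x
  })
  if (any(lengths(sets) == 0L) && length(sets))
    stop("empty regulon(s): ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  structure(sets, species = species, class = "regulon_db")
}

#' @export
print.regulon_db <- function(x, ...) {
  cat(sprintf("regulon_db: %d TFs (%s symbols)\n", length(x),
              attr(x, "species")))
  if (length(x))
    cat(sprintf("  targets per TF: median %d, range %d-%d\n",
                as.integer(stats::median(lengths(x))),
                min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' @export
`[.regulon_db` <- function(x, i) {
  structure(NextMethod(), species = attr(x, "species"), class = "regulon_db")
}

#' Read a regulon database from a GMT file
#'
#' Each line must carry at least three tab-separated fields: the TF symbol,
#' a free-text description (ignored), and one or more target symbols.
#' Duplicate targets within a line are dropped; a duplicated TF name across
#' lines is an error.
#'
#' @param path path to a GMT file.
#' @param species symbol convention tag, see [regulon_db()].
#' @param casefold if `TRUE`, upper-case all symbols on ingest. Off by
#'   default: symbol matching everywhere in the package is case-sensitive
#'   (human symbols are upper-case, mouse title-case).
#' @return A [regulon_db()].
#' @examples
#' gmt <- system.file("extdata", "synthetic_regulons.gmt",
#'                    package = "regulonet")
#' read_gmt(gmt)
#' @export
read_gmt <- function(path, species = c("synthetic", "human", "mouse"),
                     casefold = FALSE) {
  species <- match.arg(species)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(regulon_db(stats::setNames(list(), character()),
                                        species = species))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], ": fewer than 3 tab-separated fields")
  tfs <- vapply(fields, `[[`, character(1), 1L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  if (casefold) {
    tfs <- toupper(tfs)
    sets <- lapply(sets, toupper)
  }
  if (anyDuplicated(tfs))
    stop("duplicate TF line(s) in GMT: ",
         paste(unique(tfs[duplicated(tfs)]), collapse = ", "))
  regulon_db(stats::setNames(sets, tfs), species = species)
}

#' Write a regulon database to a GMT file
#'
#' @param db a [regulon_db()].
#' @param path output path.
#' @param description description field written for every line.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path, description = "na") {
  stopifnot(inherits(db, "regulon_db"))
  lines <- vapply(seq_along(db), function(i) {
    paste(c(names(db)[i], description, db[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict regulons to a gene universe
#'
#' Targets absent from the expression matrix cannot contribute to activity
#' inference; this intersects every regulon with the measured universe and
#' drops TFs left with too few targets.
#'
#' @param db a [regulon_db()].
#' @param universe character vector of measured gene symbols.
#' @param min_size minimum surviving regulon size (default 5; below this the
#'   two-module split and the weighted average are not meaningful).
#' @return A [regulon_db()] with the original TF order preserved.
#' @export
restrict_regulons <- function(db, universe, min_size = 5L) {
  stopifnot(inherits(db, "regulon_db"), min_size >= 1L)
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty gene universe")
  sets <- lapply(db, intersect, y = universe)
  keep <- lengths(sets) >= min_size
  regulon_db(sets[keep], species = attr(db, "species"))
}

#' Regulon overlap by Fisher's exact test
#'
#' One-sided (over-representation) Fisher test of the 2x2 table formed by
#' membership of a gene universe in each of two regulons. Used to rank
#' putative interaction partners of a TF whose activity sign cannot be set
#' from its own (non-differential) expression.
#'
#' @param db a [regulon_db()].
#' @param tf_a,tf_b TF symbols present in `db`.
#' @param universe_size number of genes in the universe; must be at least
#'   the size of the union of the two regulons.
#' @return list with elements `tf_a`, `tf_b`, `overlap`, `p_value`,
#'   `universe`.
#' @export
regulon_overlap_fisher <- function(db, tf_a, tf_b, universe_size) {
  stopifnot(inherits(db, "regulon_db"))
  for (tf in c(tf_a, tf_b))
    if (!tf %in% names(db)) stop("TF not in database: ", tf)
  a <- db[[tf_a]]
  b <- db[[tf_b]]
  n_union <- length(union(a, b))
  if (universe_size < n_union)
    stop("universe_size smaller than the union of the two regulons")
  k <- length(intersect(a, b))
  tab <- matrix(c(k,
                  length(a) - k,
                  length(b) - k,
                  universe_size - n_union), 2L, 2L)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(tf_a = tf_a, tf_b = tf_b, overlap = k,
       p_value = min(1, p), universe = as.integer(universe_size))
}

#' Rank DE partners of a TF by regulon overlap
#'
#' @param db a [regulon_db()].
#' @param tf TF symbol to find partners for.
#' @param partners candidate partner TF symbols (typically the DE TFs).
#' @param universe_size gene-universe size for the Fisher test.
#' @return data.frame sorted by increasing p-value with columns
#'   `partner`, `overlap`, `p_value`.
#' @export
rank_overlap_partners <- function(db, tf, partners, universe_size) {
  partners <- setdiff(intersect(partners, names(db)), tf)
  if (!length(partners))
    return(data.frame(partner = character(), overlap = integer(),
                      p_value = numeric()))
  res <- lapply(partners, function(p)
    regulon_overlap_fisher(db, tf, p, universe_size))
  out <- data.frame(partner = partners,
                    overlap = vapply(res, `[[`, integer(1), "overlap"),
                    p_value = vapply(res, `[[`, numeric(1), "p_value"))
  out[order(out$p_value, out$partner), , drop = FALSE]
}
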