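#' Hypergeometric over-representation probability
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the
#' chance of drawing at least `k` members of a size-`K` set when sampling
#' `n` genes without replacement from a universe of `N`. Computed through
#' the log-space hypergeometric tail ([stats::phyper()]), which is
#' numerically stable at genome-scale arguments; `k = 0` returns exactly 1.
#'
#' @param k observed overlap.
#' @param K gene-set size within the universe.
#' @param n query size within the universe.
#' @param N universe size.
#' @return the tail probability, a number in `(0, 1]`.
#' @examples
#' hypergeom_overrep(4, 5, 4, 10)  # 5/210
#' @export
hypergeom_overrep <- function(k, K, n, N) {
  for (v in list(k, K, n, N))
    if (!is_count(v)) stopf("hypergeometric arguments must be non-negative integers")
  if (K > N || n > N || k > min(K, n))
    stopf("invalid hypergeometric arguments: need k <= min(K, n), K <= N, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate members within a set are dropped (set semantics).
#'
#' @param path GMT file path.
#' @return named list of character vectors (set members), with set
#'   descriptions in attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stopf("GMT parse error at line %d: need name, description and >= 1 member", i)
    sets[[f[1L]]] <- unique(f[-(1:2)])
    descs[f[1L]] <- f[2L]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write gene sets as GMT
#'
#' @param sets named list of character vectors.
#' @param path output file path.
#' @param descriptions optional named character vector of set descriptions
#'   (default `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[nm] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Cross-reference a query gene list with gene-set collections
#'
#' Intersects each gene set and the query with the universe, counts the
#' overlap and computes the hypergeometric over-representation probability
#' per set. Sets are flagged significant at `p < alpha` (no multiple-testing
#' correction across sets by default; set `adjust = TRUE` for
#' Benjamini-Hochberg across the collection).
#'
#' @param query character vector of query gene ids (e.g. DE genes).
#' @param sets named list of gene sets (see [read_gmt()]).
#' @param universe character vector: the background gene population.
#' @param alpha per-set significance level (default 0.05).
#' @param adjust apply BH correction across sets before flagging?
#' @param ignore_case case-insensitive identifier matching (default TRUE).
#' @param synonym_map optional named character vector old id -> canonical id,
#'   applied to query, sets and universe before matching.
#' @return data frame with one row per set: `set_name`, `N`, `K`, `n`, `k`,
#'   `p_value`, `significant`, `degenerate` (TRUE when the set has no member
#'   in the universe), `overlapping_genes` (comma-joined).
#' @export
cross_reference <- function(query, sets, universe, alpha = 0.05,
                            adjust = FALSE, ignore_case = TRUE,
                            synonym_map = NULL) {
  if (length(universe) == 0L) stopf("universe must be non-empty")
  harmonize <- function(x) {
    if (!is.null(synonym_map)) {
      hit <- x %in% names(synonym_map)
      x[hit] <- unname(synonym_map[x[hit]])
    }
    if (ignore_case) tolower(x) else x
  }
  universe <- unique(harmonize(universe))
  query_raw <- unique(harmonize(query))
  query <- intersect(query_raw, universe)
  unmapped <- setdiff(query_raw, universe)
  if (length(unmapped) > 0.05 * length(query_raw))
    warnf("%d of %d query genes (%.1f%%) are not in the universe, e.g. %s",
          length(unmapped), length(query_raw),
          100 * length(unmapped) / length(query_raw),
          paste(utils::head(unmapped, 5L), collapse = ", "))
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(harmonize(sets[[nm]])), universe)
    K <- length(members)
    hits <- intersect(members, query)
    k <- length(hits)
    p <- hypergeom_overrep(k, K, n, N)
    data.frame(set_name = nm, N = N, K = K, n = n, k = k, p_value = p,
               degenerate = K == 0L,
               overlapping_genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  p_flag <- if (adjust) stats::p.adjust(out$p_value, "BH") else out$p_value
  out$significant <- p_flag < alpha & !out$degenerate
  out[c("set_name", "N", "K", "n", "k", "p_value", "significant",
        "degenerate", "overlapping_genes")]
}
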