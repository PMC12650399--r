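#' Gene-set collections for over-representation analysis
#'
#' `readGmt()` parses a GMT-like tab-separated file (term, description,
#' gene, gene, ...). `geneSetCollection()` builds a collection from a named
#' list of gene vectors; the universe defaults to the union of all sets.
#' Empty sets are dropped; sets are truncated to the universe.
#'
#' @param path GMT file path.
#' @param sets Named list of character vectors of gene identifiers.
#' @param name Collection name.
#' @param universe Character vector of gene identifiers; default the union of
#'   all sets.
#' @return A list with elements `name`, `sets` (named list) and `universe`.
#' @export
readGmt <- function(path, name = basename(path), universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  geneSetCollection(sets, name = name, universe = universe)
}

#' @rdname readGmt
#' @export
geneSetCollection <- function(sets, name = "collection", universe = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("gene sets must be named")
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  sets <- sets[lengths(sets) > 0L]
  if (length(sets) == 0L) stop("no non-empty gene sets")
  list(name = name, sets = sets, universe = universe)
}

#' Exact upper-tail hypergeometric test
#'
#' The over-representation p-value: drawing `n` genes from a universe of `N`
#' of which `K` carry an annotation, the probability of seeing `k` or more
#' annotated genes, `P(X >= k)`.
#'
#' @param k Observed overlap.
#' @param K Annotated genes in the universe.
#' @param n Selected genes.
#' @param N Universe size.
#' @return The exact p-value in (0, 1].
#' @examples
#' hypergeomTest(5, 5, 5, 20)  # 1/choose(20,5)
#' @export
hypergeomTest <- function(k, K, n, N) {
  if (any(K > N) || any(n > N) || any(k > pmin(K, n)) || any(k < 0))
    stop("inconsistent counts: need 0 <= k <= min(K, n) and K, n <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene selection
#'
#' Tests every annotation term with at least one overlapping gene by the
#' exact hypergeometric upper tail, then adjusts across all tested terms by
#' Benjamini–Hochberg. Selected genes outside the universe are dropped with
#' a message. Results are sorted by q-value, then p-value, then term.
#'
#' @param selected Character vector of selected gene identifiers.
#' @param collection A collection from [geneSetCollection()]/[readGmt()].
#' @param alpha Significance level echoed in the output attributes
#'   (results are not truncated), default 0.05.
#' @return A `data.frame` with columns `term`, `k_overlap`, `K_annotated`,
#'   `n_selected`, `N_universe`, `p_value`, `q_value`.
#' @export
enrich <- function(selected, collection, alpha = 0.05) {
  selected <- unique(selected)
  if (length(selected) == 0L) stop("empty selection")
  outside <- setdiff(selected, collection$universe)
  if (length(outside)) {
    message("enrich: dropping ", length(outside),
            " selected gene(s) outside the universe")
    selected <- intersect(selected, collection$universe)
    if (length(selected) == 0L) stop("no selected genes inside the universe")
  }
  N <- length(collection$universe)
  n <- length(selected)
  k <- vapply(collection$sets, function(s) length(intersect(s, selected)),
              integer(1))
  K <- lengths(collection$sets)
  keep <- k >= 1L
  if (!any(keep))
    return(data.frame(term = character(0), k_overlap = integer(0),
                      K_annotated = integer(0), n_selected = integer(0),
                      N_universe = integer(0), p_value = numeric(0),
                      q_value = numeric(0)))
  p <- hypergeomTest(k[keep], K[keep], n, N)
  out <- data.frame(term = names(collection$sets)[keep],
                    k_overlap = unname(k[keep]),
                    K_annotated = unname(K[keep]),
                    n_selected = n, N_universe = N,
                    p_value = unname(p),
                    q_value = unname(p.adjust(p, method = "BH")),
                    stringsAsFactors = FALSE)
  out <- out[order(out$q_value, out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "adjustment") <- "BH"
  out
}
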