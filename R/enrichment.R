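# Gene-set overrepresentation by the hypergeometric upper tail -- a generic,
# reproducible stand-in for proprietary ontology tools.

#' Hypergeometric gene-set overrepresentation test
#'
#' Tests whether `hits` overlaps `gene_set` more than expected under
#' sampling without replacement from `universe`:
#' p = P[X >= n_overlap] for X ~ Hypergeometric(n_universe, n_set, n_hits),
#' computed by exact summation of the hypergeometric mass. Gene names are
#' case-normalized before matching.
#'
#' @param hits character vector of query genes (must all be in `universe`).
#' @param gene_set character vector, the annotated set.
#' @param universe character vector, the background.
#' @param set_name label carried into the result.
#' @return list of class `enrichment_result`: `set_name`, `n_universe`,
#'   `n_set`, `n_hits`, `n_overlap`, `p_value`.
#' @export
hypergeometric_enrichment <- function(hits, gene_set, universe,
                                      set_name = "gene_set") {
  norm <- function(x) unique(toupper(x))
  universe <- norm(universe)
  hits <- norm(hits)
  gene_set <- intersect(norm(gene_set), universe)
  missing <- setdiff(hits, universe)
  if (length(missing)) {
    stop("hit gene(s) absent from universe: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  N <- length(universe); K <- length(gene_set); n <- length(hits)
  k <- length(intersect(hits, gene_set))
  p <- if (k == 0L) 1 else sum(dhyper(k:min(K, n), K, N - K, n))
  p <- min(1, p)
  structure(list(set_name = set_name, n_universe = N, n_set = K,
                 n_hits = n, n_overlap = k, p_value = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s: overlap %d/%d hits (set %d, universe %d), p = %.3g\n",
              x$set_name, x$n_overlap, x$n_hits, x$n_set, x$n_universe,
              x$p_value))
  invisible(x)
}

#' Test a gene list against every set of a GMT collection
#'
#' @param hits character vector of query genes.
#' @param gmt named list of gene sets (e.g. from [read_gmt()]).
#' @param universe background gene vector.
#' @param adjust apply Benjamini-Hochberg correction across sets (off by
#'   default; single-set ontology reports are conventionally uncorrected).
#' @return data.frame, one row per set, ordered by p-value; with `p_adjust`
#'   when `adjust = TRUE`.
#' @export
enrichment_table <- function(hits, gmt, universe, adjust = FALSE) {
  rows <- lapply(names(gmt), function(nm) {
    r <- hypergeometric_enrichment(hits, gmt[[nm]], universe, set_name = nm)
    data.frame(set_name = r$set_name, n_universe = r$n_universe,
               n_set = r$n_set, n_hits = r$n_hits, n_overlap = r$n_overlap,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adjust <- p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), , drop = FALSE]
}

#' Read gene sets in GMT format
#'
#' Thin wrapper over `fgsea::gmtPathways()`.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description per-set description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
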