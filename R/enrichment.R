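#' Read a GMT gene-set collection
#'
#' Tab-separated lines: set name, description, then member genes. Duplicate
#' genes within a set are collapsed; an empty file yields an empty
#' collection with a warning; a line with fewer than three fields is an
#' error reported with its line number.
#'
#' @param path GMT file path.
#' @return named list of character vectors with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(list(), description = character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 0L) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 tab-separated fields")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  structure(sets, description = setNames(vapply(parts, `[[`, "", 2L),
                                         names(sets)))
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional per-set description (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(length(names(sets)) == length(sets))
  if (is.null(descriptions)) descriptions <- attr(sets, "description")
  if (is.null(descriptions)) descriptions <- rep("NA", length(sets))
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation of gene sets in a target list
#'
#' For each set, intersected with the background universe first, computes
#' the upper-tail hypergeometric probability of observing at least the
#' realized overlap between the target and the set
#' (`P(X >= k)`, `X ~ Hypergeometric(N, K, n)` with universe size `N`,
#' set size `K`, target size `n`), then BH-adjusts across sets. One-sided by
#' design: only over-representation is tested.
#'
#' @param target character vector of genes of interest; must be a subset of
#'   `background`.
#' @param background character vector; the universe of genes with
#'   detectable expression.
#' @param sets named list of gene sets (see [read_gmt()]).
#' @param min_set_size smallest in-universe set size tested.
#' @return data.frame(set, k, n, K, N, p_raw, p_adj, overlap) sorted by
#'   p_adj then p_raw; `overlap` is the comma-separated overlapping genes.
#' @export
hypergeom_enrich <- function(target, background, sets, min_set_size = 2L) {
  target <- unique(target)
  background <- unique(background)
  bad <- setdiff(target, background)
  if (length(bad))
    stop("target genes missing from background: ",
         paste(head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L))
  N <- length(background)
  n <- length(target)
  rows <- list()
  for (nm in names(sets)) {
    s <- intersect(unique(sets[[nm]]), background)
    K <- length(s)
    if (K < min_set_size) next
    ov <- intersect(s, target)
    k <- length(ov)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[nm]] <- data.frame(set = nm, k = k, n = n, K = K, N = N,
                             p_raw = p,
                             overlap = paste(sort(ov), collapse = ","),
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    warning("no gene set meets min_set_size within the background")
    return(data.frame(set = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p_raw = numeric(0),
                      p_adj = numeric(0), overlap = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p_raw)
  res <- res[order(res$p_adj, res$p_raw), c("set", "k", "n", "K", "N",
                                            "p_raw", "p_adj", "overlap")]
  rownames(res) <- NULL
  res
}

#' Enrichment of recovery categories against gene-set collections
#'
#' Runs [hypergeom_enrich()] with each recovery category's genes as the
#' target, pooled across clusters and optionally per cluster. Adds the
#' per-set fraction of the category's genes that fall in the set
#' (`gene_fraction = k / n`). Categories with fewer than two genes are
#' skipped with a warning. Target genes not present in the background are
#' dropped (with a warning) before testing.
#'
#' @param rtab recovery table from [build_recovery_table()].
#' @param background universe of detectable genes.
#' @param sets named list of gene sets.
#' @param by_cluster also run each cluster separately.
#' @param min_set_size passed to [hypergeom_enrich()].
#' @return data.frame with columns category, cluster (`"pooled"` or a
#'   cluster name) and the [hypergeom_enrich()] columns plus
#'   `gene_fraction`.
#' @export
enrich_by_category <- function(rtab, background, sets, by_cluster = FALSE,
                               min_set_size = 2L) {
  if (!nrow(rtab)) stop("empty recovery table")
  scopes <- list(pooled = rtab)
  if (by_cluster)
    for (cl in sort(unique(rtab$cluster)))
      scopes[[cl]] <- rtab[rtab$cluster == cl, , drop = FALSE]
  out <- list()
  for (scope in names(scopes)) {
    sub <- scopes[[scope]]
    for (cat in c("Recovered", "NotRecovered", "Different")) {
      genes <- unique(sub$gene[sub$category == cat])
      drop <- setdiff(genes, background)
      if (length(drop)) {
        warning(length(drop), " ", cat, " gene(s) not in background; dropped")
        genes <- setdiff(genes, drop)
      }
      if (length(genes) < 2L) {
        warning("category ", cat, " (", scope, ") has fewer than 2 genes; skipped")
        next
      }
      r <- hypergeom_enrich(genes, background, sets, min_set_size)
      if (!nrow(r)) next
      r <- cbind(category = cat, cluster = scope, r,
                 stringsAsFactors = FALSE)
      r$gene_fraction <- r$k / r$n
      out[[length(out) + 1L]] <- r
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
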