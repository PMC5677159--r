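## Hypergeometric term enrichment of DMGs against the genome background and
## hierarchical clustering of methylation-ratio profiles.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for X ~ Hypergeometric(N, K, n): the probability of seeing at
#' least `k` annotated genes in a draw of `n` genes from a universe of `N`
#' genes of which `K` carry the term.
#'
#' @param k observed annotated genes in the draw.
#' @param K annotated genes in the universe.
#' @param n draw size (number of DMGs tested).
#' @param N universe size.
#' @return the upper-tail p-value.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0) || any(k > pmin(n, K)) ||
      any(pmax(n, K) > N))
    stop("validation error: need 0 <= k <= min(n, K) <= N", call. = FALSE)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term enrichment of a DMG set
#'
#' One hypergeometric upper-tail test per term with at least one annotated
#' gene in both the universe and the DMG set, BH-corrected across tested
#' terms. Hyper- and hypo-methylated DMGs can be tested as separate sets by
#' passing the corresponding subset as `dmgs`.
#'
#' @param dmgs character vector of DMG ids (must be a subset of
#'   `background`).
#' @param background character vector: the gene universe.
#' @param term_map `data.table` with `gene_id`, `term_id`.
#' @param q_max significance threshold on the BH q-value (default 0.05).
#' @return `data.table` with `term_id`, `k`, `n`, `K`, `N`, `p`, `q`,
#'   `significant`, sorted by `q`.
#' @export
enrich_terms <- function(dmgs, background, term_map, q_max = 0.05) {
  if (!all(dmgs %in% background))
    stop("validation error: dmgs must be a subset of background",
         call. = FALSE)
  tm <- unique(as.data.table(term_map)[gene_id %in% background,
                                       .(gene_id, term_id)])
  if (length(dmgs) == 0) {
    warning("empty DMG set")
    return(data.table(term_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      q = numeric(), significant = logical()))
  }
  N <- length(unique(background))
  n <- length(unique(dmgs))
  tab <- tm[, .(K = uniqueN(gene_id), k = uniqueN(gene_id[gene_id %in% dmgs])),
            by = term_id]
  tab <- tab[K >= 1 & k >= 1]
  tab[, `:=`(n = n, N = N)]
  tab[, p := hypergeom_upper_tail(k, K, n, N)]
  tab[, q := bh_fdr(p)]
  tab[, significant := q <= q_max]
  setorder(tab, q, p)
  tab[, .(term_id, k, n, K, N, p, q, significant)]
}

#' Average-linkage clustering of methylation profiles
#'
#' Profiles are transformed as `log2(ratio + eps)`; the distance between
#' genes is `1 - r` with r the Pearson correlation of the transformed
#' profiles; agglomeration is average linkage. Constant (zero-variance)
#' profiles get distance 1 to everything and are flagged rather than
#' raising an error. Output includes the ordered matrix, the `hclust` tree,
#' a Newick string and Cluster-3.0-compatible CDT/GTR text.
#'
#' @param mat numeric matrix, genes in rows, samples in columns (at least 2
#'   genes).
#' @param eps offset inside the log transform (default 0.01).
#' @return list: `hclust`, `order` (row labels in dendrogram order),
#'   `ordered` (reordered transformed matrix), `newick`, `flagged_constant`
#'   (labels of zero-variance profiles).
#' @export
cluster_profiles <- function(mat, eps = 0.01) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  lm <- log2(mat + eps)
  sds <- apply(lm, 1, stats::sd)
  flagged <- rownames(lm)[sds == 0]
  cc <- suppressWarnings(cor(t(lm)))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  d <- as.dist(1 - cc)
  hc <- hclust(d, method = "average")
  list(hclust = hc,
       order = rownames(lm)[hc$order],
       ordered = lm[hc$order, , drop = FALSE],
       newick = ape::write.tree(ape::as.phylo(hc)),
       flagged_constant = flagged)
}

#' Write CDT/GTR files for a clustering
#'
#' Minimal Cluster-3.0-compatible output: the GTR file lists the merge
#' heights (as similarities `1 - height`), the CDT file the reordered
#' matrix.
#'
#' @param cl result of [cluster_profiles()].
#' @param basename output path prefix (writes `<basename>.cdt` and
#'   `<basename>.gtr`).
#' @return character vector of the two paths, invisibly.
#' @export
write_cdt <- function(cl, basename) {
  hc <- cl$hclust
  n <- length(hc$labels)
  gtr <- sprintf("NODE%dX\t%s\t%s\t%f", seq_len(nrow(hc$merge)),
                 merge_ref(hc$merge[, 1]), merge_ref(hc$merge[, 2]),
                 1 - hc$height)
  gtr_path <- paste0(basename, ".gtr")
  writeLines(gtr, gtr_path)
  m <- cl$ordered
  idx <- match(rownames(m), hc$labels)
  cdt_path <- paste0(basename, ".cdt")
  con <- file(cdt_path, "w")
  on.exit(close(con))
  writeLines(paste(c("GID", "UNIQID", "NAME", colnames(m)), collapse = "\t"),
             con)
  writeLines(sprintf("GENE%dX\t%s\t%s\t%s", idx, rownames(m), rownames(m),
                     apply(m, 1, function(r) paste(sprintf("%f", r),
                                                   collapse = "\t"))), con)
  invisible(c(cdt_path, gtr_path))
}

## internal: Cluster-3.0 node references for an hclust merge matrix
merge_ref <- function(col) {
  ifelse(col < 0, sprintf("GENE%dX", -col), sprintf("NODE%dX", col))
}

#' Summarise DMGs per functional bin
#'
#' Counts hyper- and hypo-methylated DMGs per bin of a flat functional map
#' (MapMan-style bins); genes absent from the map are counted as unbinned.
#'
#' @param dmgs DMG table from [map_dmgs()] (`gene_id`, `direction`).
#' @param bin_map `data.table` with `gene_id`, `bin`.
#' @return `data.table` with `bin`, `n_hyper`, `n_hypo`, `net` (one row per
#'   bin, plus an `unbinned` row when applicable).
#' @export
mapman_bins <- function(dmgs, bin_map) {
  d <- as.data.table(dmgs)
  bm <- as.data.table(bin_map)
  merged <- bm[d, on = "gene_id"]
  merged[is.na(bin), bin := "unbinned"]
  out <- merged[, .(n_hyper = sum(direction == "hyper"),
                    n_hypo = sum(direction == "hypo")), by = bin]
  out[, net := fifelse(n_hyper > n_hypo, "hyper",
               fifelse(n_hypo > n_hyper, "hypo", "balanced"))]
  setorder(out, bin)
  out[]
}
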