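#' Cross-dataset intersection of DNAm-linked genes with direction concordance
#'
#' Maps gene-level cis-linkage summaries from two datasets (e.g. a human
#' in vitro and a mouse in vivo model) through a 1:1 ortholog map, keeps
#' the ortholog pairs where both genes carry at least one significant
#' cis pair, and compares the sign of each gene's representative
#' correlation: a pair is concordant when the signs match.
#'
#' @param labels_a,labels_b Outputs of [summarize_gene_labels()] for the
#'   two datasets.
#' @param ortholog_map Tibble with columns `gene_a`, `gene_b`; must be
#'   1:1 (no gene repeated in either column).
#' @return A tibble of class `"methlink_concordance"` with one row per
#'   shared gene pair (`gene_a`, `gene_b`, `rho_a`, `rho_b`,
#'   `concordant`); attributes `n_shared` and `n_same_direction` hold the
#'   headline counts (also via [glance()]).
#' @export
intersect_linked_genes <- function(labels_a, labels_b, ortholog_map) {
  dup_a <- unique(ortholog_map$gene_a[duplicated(ortholog_map$gene_a)])
  dup_b <- unique(ortholog_map$gene_b[duplicated(ortholog_map$gene_b)])
  if (length(dup_a) || length(dup_b)) {
    abort(paste0("ortholog map is not 1:1; duplicated: ",
                 paste(c(dup_a, dup_b), collapse = ", ")))
  }
  sig_a <- labels_a %>% filter(.data$n_sig_pairs > 0) %>%
    select(gene_a = "gene_id", rho_a = "rep_rho")
  sig_b <- labels_b %>% filter(.data$n_sig_pairs > 0) %>%
    select(gene_b = "gene_id", rho_b = "rep_rho")
  shared <- ortholog_map %>%
    inner_join(sig_a, by = "gene_a") %>%
    inner_join(sig_b, by = "gene_b") %>%
    mutate(concordant = sign(.data$rho_a) == sign(.data$rho_b)) %>%
    arrange(.data$gene_a)
  attr(shared, "n_shared") <- nrow(shared)
  attr(shared, "n_same_direction") <- sum(shared$concordant)
  class(shared) <- c("methlink_concordance", class(shared))
  shared
}
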