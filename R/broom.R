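# tidy()/glance() methods for the package's result tables. tidy() returns
# the per-feature tibble stripped of the result class; glance() returns a
# one-row summary.

strip_class <- function(x) {
  class(x) <- setdiff(class(x), c("methlink_de", "methlink_dmp",
                                  "methlink_dmr", "methlink_rescue",
                                  "methlink_pairs", "methlink_concordance"))
  as_tibble(x)
}

#' @method tidy methlink_de
#' @export
tidy.methlink_de <- function(x, ...) strip_class(x)

#' @method glance methlink_de
#' @export
glance.methlink_de <- function(x, ...) {
  tibble(
    n_tested = nrow(x),
    n_excluded = length(attr(x, "excluded")),
    n_deg = sum(x$is_deg),
    n_up = sum(x$is_deg & x$log2fc > 0),
    n_down = sum(x$is_deg & x$log2fc < 0),
    fdr = attr(x, "fdr"),
    contrast = x$contrast[1]
  )
}

#' @method tidy methlink_dmp
#' @export
tidy.methlink_dmp <- function(x, ...) strip_class(x)

#' @method glance methlink_dmp
#' @export
glance.methlink_dmp <- function(x, ...) {
  prior <- attr(x, "prior")
  tibble(
    n_tested = nrow(x),
    n_dmp = sum(x$is_dmp),
    n_hypo = sum(x$is_dmp & x$delta_beta < 0),
    n_hyper = sum(x$is_dmp & x$delta_beta > 0),
    prior_df = prior$d0,
    prior_var = prior$s0sq,
    fdr = attr(x, "fdr"),
    contrast = x$contrast[1]
  )
}

#' @method tidy methlink_dmr
#' @export
tidy.methlink_dmr <- function(x, ...) strip_class(x)

#' @method glance methlink_dmr
#' @export
glance.methlink_dmr <- function(x, ...) {
  x %>%
    group_by(.data$region_kind) %>%
    summarise(n_regions = dplyr::n(), n_dmr = sum(.data$is_dmr),
              n_hypo = sum(.data$is_dmr & .data$direction == "hypo"),
              n_hyper = sum(.data$is_dmr & .data$direction == "hyper"))
}

#' @method tidy methlink_rescue
#' @export
tidy.methlink_rescue <- function(x, ...) strip_class(x)

#' @method glance methlink_rescue
#' @export
glance.methlink_rescue <- function(x, ...) {
  affected <- sum(x$status != "not_applicable")
  tibble(
    n_features = nrow(x),
    n_affected = affected,
    n_both = sum(x$status == "both"),
    n_R1_only = sum(x$status == "R1_only"),
    n_R2_only = sum(x$status == "R2_only"),
    n_none = sum(x$status == "none"),
    fraction_rescued = if (affected > 0) {
      sum(x$status %in% c("both", "R1_only", "R2_only")) / affected
    } else NA_real_
  )
}

#' @method tidy methlink_pairs
#' @export
tidy.methlink_pairs <- function(x, ...) strip_class(x)

#' @method glance methlink_pairs
#' @export
glance.methlink_pairs <- function(x, ...) {
  labels <- summarize_gene_labels(x)
  tibble(
    n_pairs = nrow(x),
    n_sig_pairs = sum(x$pair_class != "ns"),
    n_genes_linked = nrow(labels),
    n_genes_canonical = sum(labels$canonical),
    n_genes_non_canonical = sum(labels$non_canonical),
    fdr = attr(x, "fdr")
  )
}

#' @method tidy methlink_concordance
#' @export
tidy.methlink_concordance <- function(x, ...) strip_class(x)

#' @method glance methlink_concordance
#' @export
glance.methlink_concordance <- function(x, ...) {
  tibble(
    n_shared = attr(x, "n_shared"),
    n_same_direction = attr(x, "n_same_direction"),
    fraction_concordant = if (attr(x, "n_shared") > 0) {
      attr(x, "n_same_direction") / attr(x, "n_shared")
    } else NA_real_
  )
}
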