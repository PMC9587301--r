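#' Classify knockout-dysregulated features as rescued by isoform re-expression
#'
#' A feature (gene or probe) is knockout-affected when its KO-vs-WT
#' q-value falls below the threshold. It counts as rescued by isoform X
#' when it is no longer significant in the X-vs-WT contrast and — with the
#' default `require_reversal = TRUE` — additionally shows a significant
#' X-vs-KO change in the direction opposite to the knockout effect (a
#' guard against declaring low-power features rescued). The two per-isoform
#' booleans compose into the status `both`, `R1_only`, `R2_only` or
#' `none`; features that are not knockout-affected are `not_applicable`.
#'
#' All five inputs must be results on the same feature universe:
#' [test_de()] tables (genes, effect column `log2fc`) or [test_dmp()]
#' tables (probes, effect column `delta_beta`).
#'
#' @param ko_vs_wt KO vs WT result.
#' @param r1_vs_wt,r2_vs_wt Rescue line vs WT results.
#' @param r1_vs_ko,r2_vs_ko Rescue line vs KO results (used only when
#'   `require_reversal` is `TRUE`).
#' @param fdr Significance threshold applied to all contrasts.
#' @param require_reversal Require a significant sign-reversing X-vs-KO
#'   change for rescue (default `TRUE`); `FALSE` gives the permissive
#'   loss-of-significance definition.
#' @return A tibble of class `"methlink_rescue"`: `feature_id`,
#'   `feature_kind`, `ko_call`, `rescued_R1`, `rescued_R2`, `status`.
#' @export
classify_rescue <- function(ko_vs_wt, r1_vs_wt, r2_vs_wt,
                            r1_vs_ko = NULL, r2_vs_ko = NULL,
                            fdr = 0.05, require_reversal = TRUE) {
  eff <- function(x) {
    if ("log2fc" %in% names(x)) x$log2fc else x$delta_beta
  }
  idcol <- if ("gene_id" %in% names(ko_vs_wt)) "gene_id" else "probe_id"
  kind <- if (idcol == "gene_id") "gene" else "probe"
  ids <- ko_vs_wt[[idcol]]
  align <- function(x, label) {
    if (is.null(x)) {
      if (require_reversal) {
        abort(paste0(label, " is required when require_reversal = TRUE"))
      }
      return(NULL)
    }
    if (!setequal(x[[idcol]], ids)) {
      abort(paste0("feature universe of ", label,
                   " differs from the KO-vs-WT contrast"))
    }
    x[match(ids, x[[idcol]]), ]
  }
  r1w <- align(r1_vs_wt, "r1_vs_wt")
  r2w <- align(r2_vs_wt, "r2_vs_wt")
  r1k <- align(r1_vs_ko, "r1_vs_ko")
  r2k <- align(r2_vs_ko, "r2_vs_ko")

  ko_sig <- ko_vs_wt$q < fdr
  ko_eff <- eff(ko_vs_wt)
  rescued_by <- function(rw, rk) {
    ok <- rw$q >= fdr
    if (require_reversal) {
      ok <- ok & rk$q < fdr & sign(eff(rk)) == -sign(ko_eff)
    }
    ok
  }
  r1 <- rescued_by(r1w, r1k)
  r2 <- rescued_by(r2w, r2k)
  status <- dplyr::case_when(
    !ko_sig ~ "not_applicable",
    r1 & r2 ~ "both",
    r1 & !r2 ~ "R1_only",
    !r1 & r2 ~ "R2_only",
    TRUE ~ "none"
  )
  res <- tibble(
    feature_id = ids,
    feature_kind = kind,
    ko_call = ifelse(!ko_sig, "null", ifelse(ko_eff > 0, "up", "down")),
    rescued_R1 = ifelse(ko_sig, r1, NA),
    rescued_R2 = ifelse(ko_sig, r2, NA),
    status = status
  )
  attr(res, "fdr") <- fdr
  attr(res, "require_reversal") <- require_reversal
  class(res) <- c("methlink_rescue", class(res))
  res
}

#' @rdname classify_rescue
#' @param ... Passed to [classify_rescue()]; inputs are [test_dmp()]
#'   results on the probe universe.
#' @export
classify_methylation_rescue <- function(...) classify_rescue(...)

#' Summarise a rescue classification
#'
#' @param rescue A [classify_rescue()] result.
#' @return A tibble of counts per status plus the rescued fraction among
#'   knockout-affected features (`both` and single-isoform statuses over
#'   all non-`not_applicable` features).
#' @export
rescue_summary <- function(rescue) {
  counts <- rescue %>% count(.data$feature_kind, .data$status)
  affected <- sum(rescue$status != "not_applicable")
  rescued <- sum(rescue$status %in% c("both", "R1_only", "R2_only"))
  attr(counts, "fraction_rescued") <-
    if (affected > 0) rescued / affected else NA_real_
  counts
}
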