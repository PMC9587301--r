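# Readers/writers for the pipeline's plain-text formats. All tabular
# outputs are TSV with optional "# key: value" metadata header lines;
# annotation additionally round-trips through GTF (1-based inclusive) and
# BED6 (0-based half-open) via rtracklayer.

#' Write a tibble as TSV with metadata header lines
#'
#' @param df Tibble to write. List columns are serialized as
#'   comma-separated strings.
#' @param path Output path.
#' @param meta Named character vector written as leading `# key: value`
#'   lines.
#' @return `path`, invisibly.
#' @export
write_methlink_tsv <- function(df, path, meta = character()) {
  df <- df %>% mutate(across(where(is.list),
                             ~ map_chr(.x, paste, collapse = ",")))
  header <- if (length(meta)) paste0("# ", names(meta), ": ", meta) else character()
  readr::write_lines(header, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_methlink_tsv()]
#' @param path Input path.
#' @return A tibble (metadata lines are skipped).
#' @export
read_methlink_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Write / read a probe manifest as CSV
#' @param manifest Manifest tibble.
#' @param path File path.
#' @return `path` (writer) or a tibble (reader).
#' @export
write_manifest_csv <- function(manifest, path) {
  readr::write_csv(manifest, path)
  invisible(path)
}

#' @rdname write_manifest_csv
#' @export
read_manifest_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

annotation_to_granges <- function(annotation) {
  GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end),
    strand = annotation$strand,
    gene_id = annotation$gene_id
  )
}

#' Write gene annotation as GTF (1-based inclusive)
#' @param annotation Annotation tibble (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param path File path.
#' @export
write_annotation_gtf <- function(annotation, path) {
  gr <- annotation_to_granges(annotation)
  gr$type <- "gene"
  gr$source <- "methlink"
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read gene annotation from GTF, deriving the TSS
#'
#' The TSS is the start coordinate for plus-strand genes and the end
#' coordinate for minus-strand genes.
#'
#' @param path GTF file; `gene`-type rows (or all rows if untyped) are
#'   used.
#' @return Annotation tibble with a derived `tss` column.
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(gr$type == "gene")) {
    gr <- gr[gr$type == "gene"]
  }
  tibble(
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ) %>%
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end))
}

#' Write gene annotation (or regions) as BED6 (0-based half-open)
#' @inheritParams write_annotation_gtf
#' @export
write_annotation_bed <- function(annotation, path) {
  gr <- annotation_to_granges(annotation)
  gr$name <- annotation$gene_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_annotation_bed
#' @export
read_annotation_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble(
    gene_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ) %>%
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end))
}
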