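# Internal helpers shared across modules.

# Condition sets for the two supported designs.
.designs <- list(
  ko_rescue = c("WT", "KO", "R1", "R2"),
  two_group = c("FLFL", "DIEC")
)

abort_config <- function(msg) {
  abort(msg, class = "methlink_config_error")
}

# Seed sub-streams: fixed offsets off one master seed so that independent
# stages draw from independent, reproducible streams. Offsets are small so
# the derived seed stays a valid 32-bit integer for small master seeds.
with_substream <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
  force(code)
}

# Strip/normalize "chr" prefixes so probe and gene coordinates compare.
norm_chrom <- function(x) sub("^[Cc]hr", "", as.character(x))

# All permutations of seq_len(n), one per row. Only used when n! is small
# (exhaustive permutation mode); recursion depth is n.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

# Newton inversion of trigamma(), used by the moderated-t prior fit.
# trigamma is convex decreasing on (0, Inf); iteration on 1/x is stable.
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

# Convert a tibble with an id column + numeric sample columns to a matrix.
df_to_matrix <- function(df, id_col) {
  stopifnot(id_col %in% names(df))
  m <- as.matrix(df[setdiff(names(df), id_col)])
  storage.mode(m) <- "double"
  rownames(m) <- df[[id_col]]
  m
}

matrix_to_df <- function(m, id_col) {
  as_tibble(m, rownames = id_col)
}

# Validate a sample design table (shared by several modules).
check_design <- function(design) {
  req <- c("sample_id", "condition", "replicate")
  if (!all(req %in% names(design))) {
    abort(paste0("design must have columns: ", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(design$sample_id)) abort("sample_ids must be unique")
  tab <- table(design$condition)
  if (any(tab < 2)) {
    abort(paste0("every condition needs >= 2 replicates; offending: ",
                 paste(names(tab)[tab < 2], collapse = ", ")))
  }
  invisible(design)
}

contrast_samples <- function(design, contrast) {
  if (length(contrast) != 2L) abort("contrast must be length 2: c(reference, alternative)")
  missing <- setdiff(contrast, unique(design$condition))
  if (length(missing)) {
    abort(paste0("contrast condition(s) absent from design: ",
                 paste(missing, collapse = ", ")))
  }
  list(
    a = design$sample_id[design$condition == contrast[[1]]],
    b = design$sample_id[design$condition == contrast[[2]]]
  )
}
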