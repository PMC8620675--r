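# The repeats-by-samples abundance matrix and its state machine
# (raw -> log -> quantile_normalized).

#' Construct an abundance matrix
#'
#' An `abundance_matrix` is a tibble with a `repeat_id` column followed by
#' one numeric column per sample, carrying two attributes: `state` (one of
#' `"raw"`, `"log"`, `"quantile_normalized"`) and `sample_meta` (a tibble
#' `sample_id`, `species`, `replicate`). State transitions are enforced:
#' raw matrices may be log-transformed, log matrices quantile-normalized.
#'
#' @param values Numeric matrix (repeats x samples) with rownames and
#'   colnames, or a tibble with `repeat_id` first.
#' @param sample_meta Tibble with `sample_id`, `species`, `replicate`
#'   covering every sample column.
#' @param state Matrix state; new matrices are `"raw"`.
#' @return An `abundance_matrix`.
#' @export
abundance_matrix <- function(values, sample_meta,
                             state = c("raw", "log", "quantile_normalized")) {
  state <- match.arg(state)
  if (is.matrix(values)) {
    df <- tibble(repeat_id = rownames(values) %||% as.character(seq_len(nrow(values))))
    df <- dplyr::bind_cols(df, as_tibble(values, .name_repair = "minimal"))
  } else {
    df <- as_tibble(values)
    stopifnot(names(df)[1L] == "repeat_id")
  }
  if (anyDuplicated(df$repeat_id)) abort("duplicated repeat ids")
  samples <- names(df)[-1L]
  if (!all(samples %in% sample_meta$sample_id)) {
    abort("sample_meta does not cover every sample column")
  }
  sample_meta <- sample_meta[match(samples, sample_meta$sample_id), , drop = FALSE]
  if (state == "raw" && nrow(df) && any(as.matrix(df[-1L]) < 0)) {
    abort("raw abundances must be non-negative")
  }
  structure(
    df,
    state = state,
    sample_meta = as_tibble(sample_meta),
    class = c("abundance_matrix", class(tibble()))
  )
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("# abundance_matrix [", nrow(x), " repeats x ", ncol(x) - 1L,
    " samples], state: ", attr(x, "state"), "\n",
    sep = ""
  )
  NextMethod()
}

#' Matrix state and sample metadata accessors
#' @param x An `abundance_matrix`.
#' @return `matrix_state()`: the state string; `sample_meta()`: the sample
#'   metadata tibble.
#' @export
matrix_state <- function(x) attr(x, "state")

#' @rdname matrix_state
#' @export
sample_meta <- function(x) attr(x, "sample_meta")

# numeric matrix view (repeats x samples)
am_values <- function(x) {
  m <- as.matrix(as.data.frame(x[, -1L, drop = FALSE]))
  rownames(m) <- x$repeat_id
  m
}

am_replace <- function(x, values, state) {
  abundance_matrix(values, sample_meta(x), state = state)
}

assert_state <- function(x, allowed, op) {
  if (!matrix_state(x) %in% allowed) {
    abort(paste0(
      op, " expects matrix state ", paste(allowed, collapse = " or "),
      ", got ", matrix_state(x)
    ))
  }
}

#' Natural-log transform of a raw abundance matrix
#'
#' Applies `ln(value + pseudo)` elementwise. The pseudo-count (default 1)
#' keeps zero abundances at zero and preserves ordering.
#'
#' @param x A raw `abundance_matrix`.
#' @param pseudo Positive pseudo-count.
#' @return An `abundance_matrix` in state `"log"`.
#' @export
log_transform <- function(x, pseudo = 1) {
  assert_state(x, "raw", "log_transform()")
  stopifnot(pseudo > 0)
  am_replace(x, log(am_values(x) + pseudo), "log")
}

#' Quantile normalization
#'
#' Classic quantile normalization of the sample columns: each value is
#' replaced by the mean over samples of the values at its rank, ties
#' receiving the mean of their tied-rank targets. Afterwards every column
#' has the identical sorted value vector. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param x An `abundance_matrix` in state `"log"`.
#' @return An `abundance_matrix` in state `"quantile_normalized"`.
#' @export
quantile_normalize <- function(x) {
  assert_state(x, "log", "quantile_normalize()")
  if (ncol(x) - 1L < 2L) abort("quantile normalization needs >= 2 samples")
  v <- am_values(x)
  if (nrow(v) <= 1L) {
    # degenerate matrices: a single row's rank-1 target is its own mean
    if (nrow(v) == 1L) v[1L, ] <- mean(v[1L, ])
    return(am_replace(x, v, "quantile_normalized"))
  }
  v <- limma::normalizeQuantiles(v, ties = TRUE)
  am_replace(x, v, "quantile_normalized")
}

#' Filter repeats by maximum abundance across samples
#'
#' Keeps exactly the rows whose maximum over samples is strictly greater
#' than `threshold`. The abundance thresholds used in practice (e.g. 150 or
#' 665 reads per base pair) are on the raw coverage scale, so this is
#' normally applied to the raw matrix before transformation.
#'
#' @param x An `abundance_matrix` (any state).
#' @param threshold Numeric threshold; rows with `max > threshold` are kept.
#' @return The filtered `abundance_matrix`, same state.
#' @export
filter_by_max <- function(x, threshold) {
  v <- am_values(x)
  keep <- if (nrow(v)) apply(v, 1L, max) > threshold else logical(0)
  am_replace(x, v[keep, , drop = FALSE], matrix_state(x))
}

#' Write / read an abundance matrix as TSV
#'
#' Values are written at full precision with `repeat_id` in column 1 and
#' sample ids in the header; the state and sample metadata travel in a JSON
#' sidecar at `<path>.json` so the round trip is lossless.
#'
#' @param x An `abundance_matrix`.
#' @param path Output TSV path.
#' @return `path` invisibly; `read_abundance_tsv()` returns the matrix.
#' @export
write_abundance_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  jsonlite::write_json(
    list(state = matrix_state(x), sample_meta = sample_meta(x)),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  abundance_matrix(df, as_tibble(side$sample_meta), state = side$state)
}

#' @export
tidy.abundance_matrix <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"repeat_id",
    names_to = "sample_id", values_to = "abundance"
  ) |>
    left_join(sample_meta(x), by = "sample_id")
}

#' @export
autoplot.abundance_matrix <- function(object, ...) {
  dat <- tidy.abundance_matrix(object)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$sample_id, y = .data$repeat_id,
    fill = .data$abundance
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = attr(object, "state")) +
    ggplot2::labs(x = "sample", y = "repeat") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
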