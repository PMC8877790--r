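#' Filter per-gene differential-expression results
#'
#' Applies the study's significance filter to a tidy table of per-gene
#' results: a gene is significant in a condition when
#' |log2 fold change| >= `lfc_cut` (inclusive) AND adjusted p < `padj_cut`
#' (strict). Records with a missing adjusted p (e.g. removed by
#' independent filtering upstream) are never significant; their count is
#' attached as the `n_untested` attribute.
#'
#' @param records Tibble with at least `gene_id`, `log2fc`, `padj`;
#'   condition columns (`chemical`, `concentration_nM`, `duration`) are
#'   carried through.
#' @param lfc_cut Absolute log2 fold-change threshold (default 0.75).
#' @param padj_cut Adjusted-p threshold (default 0.1).
#' @return The significant rows with an added `direction`
#'   (`"up"`/`"down"`) column; attribute `n_untested` counts rows with
#'   missing `padj`.
#' @export
#' @examples
#' tbl <- tibble::tibble(gene_id = c("a", "b"), log2fc = c(0.75, 0.74),
#'                       padj = c(0.099, 1e-10))
#' filter_degs(tbl)$gene_id # "a"
filter_degs <- function(records, lfc_cut = 0.75, padj_cut = 0.1) {
  stopifnot(lfc_cut > 0, padj_cut > 0)
  stopifnot(all(c("gene_id", "log2fc", "padj") %in% names(records)))
  ok <- is.na(records$padj) | (records$padj >= 0 & records$padj <= 1)
  if (!all(ok)) stop("adjusted p-values must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(records$log2fc))) {
    stop("log2 fold changes must be finite", call. = FALSE)
  }
  keep <- !is.na(records$padj) &
    abs(records$log2fc) >= lfc_cut &
    records$padj < padj_cut
  out <- records[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  attr(out, "n_untested") <- sum(is.na(records$padj))
  out
}

#' Count significant genes by condition
#'
#' Tallies filtered results per concentration and per chemical x
#' duration. Two deduplication policies are supported because count
#' tables and prose summaries in this literature use both:
#' \describe{
#'   \item{`"sum"`}{duration totals add the per-concentration counts; a
#'     gene significant at two concentrations counts twice. This is the
#'     arithmetic behind per-chemical count tables.}
#'   \item{`"unique"`}{each distinct gene counts once per chemical x
#'     duration; genes significant in opposite directions at different
#'     concentrations are reported as variably regulated.}
#' }
#'
#' @param sig Output of [filter_degs()] (needs `gene_id`, `chemical`,
#'   `concentration_nM`, `duration`, `direction`).
#' @param dedup_policy `"sum"` or `"unique"`.
#' @return A list of class `deg_counts`: `per_concentration` (tibble
#'   with n_up, n_down, n_total) and `per_duration` (tibble with
#'   total_up, total_down, n_total, and for `"unique"` also
#'   `n_variably_regulated`), plus `policy`.
#' @export
count_by_condition <- function(sig, dedup_policy = c("sum", "unique")) {
  dedup_policy <- match.arg(dedup_policy)
  per_conc <- sig |>
    dplyr::group_by(.data$chemical, .data$duration, .data$concentration_nM) |>
    dplyr::summarise(
      n_up = sum(.data$direction == "up"),
      n_down = sum(.data$direction == "down"),
      n_total = dplyr::n(),
      .groups = "drop"
    )
  if (dedup_policy == "sum") {
    per_dur <- per_conc |>
      dplyr::group_by(.data$chemical, .data$duration) |>
      dplyr::summarise(
        total_up = sum(.data$n_up),
        total_down = sum(.data$n_down),
        n_total = sum(.data$n_total),
        .groups = "drop"
      )
  } else {
    per_dur <- sig |>
      dplyr::group_by(.data$chemical, .data$duration, .data$gene_id) |>
      dplyr::summarise(
        dirs = list(unique(.data$direction)),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        variably = purrr::map_lgl(.data$dirs, ~ length(.x) > 1L),
        dir1 = purrr::map_chr(.data$dirs, 1)
      ) |>
      dplyr::group_by(.data$chemical, .data$duration) |>
      dplyr::summarise(
        total_up = sum(!.data$variably & .data$dir1 == "up"),
        total_down = sum(!.data$variably & .data$dir1 == "down"),
        n_variably_regulated = sum(.data$variably),
        n_total = dplyr::n(),
        .groups = "drop"
      )
  }
  structure(
    list(per_concentration = per_conc, per_duration = per_dur, policy = dedup_policy),
    class = "deg_counts"
  )
}

#' @export
print.deg_counts <- function(x, ...) {
  cat(sprintf("DEG counts (policy '%s'):\n", x$policy))
  print(x$per_duration)
  invisible(x)
}

#' Exact Venn decomposition of named gene sets
#'
#' Decomposes up to five named gene sets into their disjoint Venn
#' regions with member lists. Region counts are non-negative, disjoint
#' and sum to the size of the union.
#'
#' @param sets Named list of character vectors (>= 2 sets, unique
#'   names).
#' @return A tibble of class `overlap_result` with one row per
#'   non-empty-membership region: `region` (member set names joined by
#'   `&`), `sets` (list of member names), `degree`, `n`, `genes`
#'   (list-column).
#' @export
#' @examples
#' overlap_sets(list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = "c"))
overlap_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L) {
    stop("need at least two named sets", call. = FALSE)
  }
  nm <- names(sets)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("sets must have unique, non-empty names", call. = FALSE)
  }
  if (length(sets) > 5L) {
    stop("region decomposition supported for up to 5 sets", call. = FALSE)
  }
  sets <- purrr::map(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L, dimnames = list(NULL, nm))
  key <- apply(membership, 1L, function(row) paste(nm[row], collapse = "&"))
  out <- purrr::map_dfr(unique(key), function(k) {
    members <- strsplit(k, "&", fixed = TRUE)[[1]]
    genes <- universe[key == k]
    tibble::tibble(
      region = k, sets = list(members), degree = length(members),
      n = length(genes), genes = list(sort(genes))
    )
  })
  out <- dplyr::arrange(out, .data$degree, .data$region)
  class(out) <- c("overlap_result", class(out))
  out
}

#' Combine a chemical's significant genes across conditions
#'
#' Builds one gene set per chemical by unioning its significant genes
#' over all concentrations and durations — the construction used for
#' cross-chemical Venn comparisons.
#'
#' @param sig Output of [filter_degs()].
#' @return Named list of character vectors, one per chemical.
#' @export
combine_condition_sets <- function(sig) {
  split(sig$gene_id, sig$chemical) |> purrr::map(unique)
}

#' Annotate significant genes with functional categories
#'
#' Left-joins a user-supplied gene-to-category map (a stand-in for
#' proprietary pathway annotation); unmapped genes are labeled
#' `"unassigned"`.
#'
#' @param sig Output of [filter_degs()].
#' @param category_map Tibble with columns `gene_id`, `category` (one
#'   row per gene), or a path to a two-column TSV.
#' @param dedup_policy `"sum"` counts each significant record, `"unique"`
#'   each distinct gene once per category.
#' @return A list: `records` (annotated rows) and `counts` (per-category
#'   tallies).
#' @export
annotate_categories <- function(sig, category_map,
                                dedup_policy = c("sum", "unique")) {
  dedup_policy <- match.arg(dedup_policy)
  if (is.character(category_map) && length(category_map) == 1L) {
    category_map <- readr::read_tsv(category_map, show_col_types = FALSE)
  }
  if (!all(c("gene_id", "category") %in% names(category_map))) {
    stop("malformed category map: need columns gene_id, category", call. = FALSE)
  }
  if (anyDuplicated(category_map$gene_id)) {
    stop("malformed category map: duplicate gene_id entries", call. = FALSE)
  }
  records <- dplyr::left_join(sig, category_map, by = "gene_id") |>
    dplyr::mutate(category = dplyr::coalesce(.data$category, "unassigned"))
  counts <- if (dedup_policy == "sum") {
    dplyr::count(records, .data$category, name = "n")
  } else {
    records |>
      dplyr::distinct(.data$category, .data$gene_id) |>
      dplyr::count(.data$category, name = "n")
  }
  list(records = records, counts = counts)
}
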