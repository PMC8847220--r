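#' Collapse haplotype vectors into personal vectors
#'
#' A diploid individual contributes two haplotype vectors per chromosome; the
#' two copies carry equal weight, so the individual is represented by their
#' coordinate-wise mean — the personal vector. Haploid input (one vector per
#' sample, e.g. Y chromosome) passes through unchanged.
#'
#' @param vectors A tibble of haplotype vectors: a `sample` column, optional
#'   grouping columns (e.g. `chromosome`), and the numeric vector components.
#'   An `id` or `hap` column, if present, is dropped.
#' @return A tibble with one row per sample (per grouping column combination)
#'   whose numeric columns are the means of that sample's 1 or 2 haplotype
#'   rows. More than two rows per sample is an error.
#' @export
personal_vectors <- function(vectors) {
  stopifnot(is.data.frame(vectors), "sample" %in% names(vectors))
  drop <- intersect(c("id", "hap"), names(vectors))
  vectors <- dplyr::select(vectors, -dplyr::all_of(drop))
  keys <- names(vectors)[!vapply(vectors, is.numeric, logical(1))]
  out <- vectors |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys)))
  sizes <- dplyr::group_size(out)
  if (any(sizes > 2)) {
    abort("a sample has more than 2 haplotype vectors for one chromosome")
  }
  out |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean),
                     .groups = "drop")
}

#' Population centroids of personal vectors
#'
#' Each population is represented by one point per chromosome: the unweighted
#' mean of the personal vectors of its members. Distances between populations
#' are then distances between these centers.
#'
#' @param personal A tibble of personal vectors with a `sample` column,
#'   optional grouping columns (e.g. `chromosome`), and numeric components.
#' @param panel A two-column data frame mapping `sample` to `population`
#'   (extra columns are ignored), or `NULL` if `personal` already has a
#'   `population` column.
#' @return A tibble with `population`, any grouping columns, `member_count`,
#'   and the mean vector components.
#' @export
population_centroids <- function(personal, panel = NULL) {
  stopifnot(is.data.frame(personal), "sample" %in% names(personal))
  if (!is.null(panel)) {
    stopifnot(all(c("sample", "population") %in% names(panel)))
    unmapped <- setdiff(personal$sample, panel$sample)
    if (length(unmapped) > 0) {
      warn(paste0("dropping ", length(unmapped),
                  " sample(s) absent from the panel: ",
                  paste(head(unmapped, 5), collapse = ", ")))
    }
    personal <- dplyr::inner_join(
      personal,
      dplyr::select(panel, "sample", "population"),
      by = "sample")
  }
  if (!"population" %in% names(personal)) {
    abort("no `population` column and no panel supplied")
  }
  if (nrow(personal) == 0) {
    abort("no samples left to aggregate into centroids")
  }
  keys <- setdiff(
    names(personal)[!vapply(personal, is.numeric, logical(1))],
    "sample")
  personal |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(member_count = dplyr::n(),
                     dplyr::across(dplyr::where(is.numeric), mean),
                     .groups = "drop") |>
    dplyr::relocate("population")
}

#' Euclidean distance matrix between labeled vectors
#'
#' @param vectors A tibble with one label column (default `population`) and
#'   numeric vector components (a `member_count` column is ignored).
#' @param label Name of the label column.
#' @return A symmetric, zero-diagonal labeled matrix of pairwise Euclidean
#'   distances, of class `dnv_dist`.
#' @export
distance_matrix <- function(vectors, label = "population") {
  stopifnot(is.data.frame(vectors), label %in% names(vectors))
  labels <- as.character(vectors[[label]])
  if (anyDuplicated(labels)) {
    abort(paste0("duplicate label: ", labels[duplicated(labels)][1]))
  }
  if (nrow(vectors) < 2) {
    abort("need at least 2 labeled vectors")
  }
  num <- dplyr::select(vectors, dplyr::where(is.numeric),
                       -dplyr::any_of("member_count"))
  m <- as.matrix(dist(as.matrix(num)))
  dimnames(m) <- list(labels, labels)
  diag(m) <- 0
  new_dnv_dist(m)
}

#' Sum distance matrices across chromosomes
#'
#' Per-chromosome distance matrices over the same populations are combined by
#' entrywise summation; the tree built from the sum is the total-autosome
#' tree. Summing and averaging differ only by a positive constant, which
#' distance-based tree topologies are invariant to, so the sum is the
#' default and the mean is available via `average = TRUE`.
#'
#' @param matrices A list of labeled matrices sharing one label set (order
#'   may differ; alignment is by label).
#' @param average Divide the sum by the number of matrices.
#' @return The entrywise sum (or mean) as a `dnv_dist` labeled matrix.
#' @export
sum_matrices <- function(matrices, average = FALSE) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  matrices <- lapply(matrices, validate_labeled_matrix)
  ref_labels <- sort(rownames(matrices[[1]]))
  for (i in seq_along(matrices)) {
    labs <- sort(rownames(matrices[[i]]))
    if (!identical(labs, ref_labels)) {
      only_first <- setdiff(ref_labels, labs)
      only_this <- setdiff(labs, ref_labels)
      abort(paste0("label sets differ between matrices 1 and ", i, ": ",
                   paste(c(only_first, only_this), collapse = ", ")))
    }
  }
  acc <- Reduce(`+`, lapply(matrices, function(m) {
    unclass(m)[ref_labels, ref_labels]
  }))
  if (average) acc <- acc / length(matrices)
  new_dnv_dist(acc)
}

#' Mean pairwise distance within a set of vectors
#'
#' The mean of all pairwise Euclidean distances among the personal vectors of
#' one population — a summary of within-population diversity (larger genetic
#' distances reflect higher diversity).
#'
#' @param vectors A tibble of at least two vectors; numeric columns are the
#'   components (a `member_count` column is ignored).
#' @return A non-negative scalar.
#' @export
within_population_mean_distance <- function(vectors) {
  num <- dplyr::select(as_tibble(vectors), dplyr::where(is.numeric),
                       -dplyr::any_of("member_count"))
  if (nrow(num) < 2) {
    abort("need at least 2 member vectors")
  }
  mean(dist(as.matrix(num)))
}

#' Within-population mean distances for every population
#'
#' @param personal A tibble of personal vectors with a `sample` column.
#' @param panel Sample-to-population map as in [population_centroids()], or
#'   `NULL` if `personal` has a `population` column.
#' @return A tibble with `population`, `n_members`, `mean_distance`.
#' @export
within_population_distances <- function(personal, panel = NULL) {
  if (!is.null(panel)) {
    personal <- dplyr::inner_join(
      personal, dplyr::select(panel, "sample", "population"), by = "sample")
  }
  stopifnot("population" %in% names(personal))
  personal |>
    dplyr::group_by(.data$population) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      mean_distance = within_population_mean_distance(dplyr::pick(dplyr::everything())),
      .groups = "drop")
}

# ---- labeled matrix helpers -------------------------------------------------

#' Validate a labeled distance matrix
#'
#' Checks the invariants every distance matrix in the pipeline must satisfy:
#' square with row = column labels, symmetric within 1e-9, exactly zero
#' diagonal, non-negative entries.
#'
#' @param m A numeric matrix with dimnames.
#' @return The matrix (diagonal zeroed, symmetrized to machine precision),
#'   invisibly classed as before.
#' @export
validate_labeled_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) abort("not a numeric matrix")
  if (nrow(m) != ncol(m)) abort("matrix is not square")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("matrix must carry row and column labels")
  }
  if (!identical(rownames(m), colnames(m))) {
    abort("row and column labels differ")
  }
  if (anyDuplicated(rownames(m))) abort("duplicate labels")
  if (any(m < 0)) abort("negative distances")
  if (max(abs(m - t(m))) > 1e-9) abort("matrix is not symmetric within 1e-9")
  if (any(diag(m) != 0)) abort("nonzero diagonal")
  m
}

new_dnv_dist <- function(m) {
  class(m) <- c("dnv_dist", class(unclass(m)))
  m
}

#' @export
print.dnv_dist <- function(x, ...) {
  cat("Labeled distance matrix over", nrow(x), "units\n")
  print(round(unclass(x), 6), ...)
  invisible(x)
}

#' Tidy a labeled distance matrix into long form
#'
#' @param x A `dnv_dist` matrix.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `distance`, one row per
#'   unordered pair (upper triangle).
#' @export
tidy.dnv_dist <- function(x, ...) {
  m <- unclass(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble(from = rownames(m)[idx[, 1]],
         to = colnames(m)[idx[, 2]],
         distance = m[idx])
}

#' Heatmap of a labeled distance matrix
#'
#' @param object A `dnv_dist` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dnv_dist <- function(object, ...) {
  m <- unclass(object)
  idx <- which(row(m) > 0, arr.ind = TRUE)
  df <- tibble(from = factor(rownames(m)[idx[, 1]], levels = rownames(m)),
               to = factor(colnames(m)[idx[, 2]], levels = colnames(m)),
               distance = m[idx])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
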