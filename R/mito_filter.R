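#' Mitogenome quality-filter configuration
#'
#' Defaults implement the quality window around the human reference
#' mitogenome (16,569 bp): sequences shorter than 16,564 bp or longer than
#' 16,574 bp are removed (boundaries inclusive on the kept side), sequences
#' with more than one literal `N` are removed, and groups (countries) that
#' retain fewer than two sequences are dropped entirely.
#'
#' @param min_length Minimum kept length (inclusive).
#' @param max_length Maximum kept length (inclusive).
#' @param max_n Maximum number of `N` symbols (case-insensitive; other IUPAC
#'   ambiguity codes are not counted).
#' @param min_group_size Minimum surviving sequences per group.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_length = 16564, max_length = 16574,
                          max_n = 1, min_group_size = 2) {
  stopifnot(min_length <= max_length, max_n >= 0, min_group_size >= 1)
  structure(list(min_length = min_length, max_length = max_length,
                 max_n = max_n, min_group_size = min_group_size),
            class = "filter_config")
}

#' Sequence-level mitogenome quality filter
#'
#' Annotates each sequence with its length, `N` count, and pass/fail status.
#' Rejections carry a machine-readable reason code: `TOO_SHORT`, `TOO_LONG`,
#' or `TOO_MANY_N` (length violations take precedence over the `N` count).
#'
#' @param seqs A tibble with columns `id` and `seq` (extra columns are kept).
#' @param cfg A [filter_config()].
#' @return The input tibble with added columns `length`, `n_count`, `kept`
#'   (logical), and `reason` (`NA` when kept).
#' @export
filter_sequences <- function(seqs, cfg = filter_config()) {
  seqs <- as_tibble(seqs)
  stopifnot(all(c("id", "seq") %in% names(seqs)), inherits(cfg, "filter_config"))
  len <- nchar(seqs$seq)
  n_count <- stringr::str_count(toupper(seqs$seq), stringr::fixed("N"))
  reason <- dplyr::case_when(
    len < cfg$min_length ~ "TOO_SHORT",
    len > cfg$max_length ~ "TOO_LONG",
    n_count > cfg$max_n ~ "TOO_MANY_N",
    TRUE ~ NA_character_
  )
  dplyr::mutate(seqs, length = len, n_count = n_count,
                kept = is.na(reason), reason = reason)
}

#' Group-level mitogenome filter
#'
#' After the sequence-level filter, groups (countries) whose surviving
#' sequence count falls below the minimum are dropped entirely; their
#' survivors are re-marked as rejected with reason `GROUP_TOO_SMALL`.
#'
#' @param filtered Output of [filter_sequences()] with an added `group`
#'   column labeling every sequence.
#' @param cfg A [filter_config()].
#' @return The tibble with `kept`/`reason` updated; dropped group names are
#'   attached as attribute `dropped_groups`.
#' @export
filter_groups <- function(filtered, cfg = filter_config()) {
  stopifnot(is.data.frame(filtered),
            all(c("id", "kept", "reason") %in% names(filtered)))
  if (!"group" %in% names(filtered) || anyNA(filtered$group)) {
    abort("every sequence must carry a non-missing `group` label")
  }
  survivors <- dplyr::count(dplyr::filter(filtered, .data$kept), .data$group)
  small <- survivors$group[survivors$n < cfg$min_group_size]
  # groups whose sequences all failed the sequence filter are dropped too
  all_groups <- unique(filtered$group)
  small <- union(small, setdiff(all_groups, survivors$group))
  out <- dplyr::mutate(
    filtered,
    reason = dplyr::if_else(.data$kept & .data$group %in% small,
                            "GROUP_TOO_SMALL", .data$reason),
    kept = .data$kept & !(.data$group %in% small))
  attr(out, "dropped_groups") <- sort(small)
  out
}

#' Run both mitogenome filter stages
#'
#' @param seqs A tibble with `id`, `seq`, and `group` columns.
#' @param cfg A [filter_config()].
#' @return As [filter_groups()].
#' @export
filter_mitogenomes <- function(seqs, cfg = filter_config()) {
  filter_groups(filter_sequences(seqs, cfg), cfg)
}
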