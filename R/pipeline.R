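#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs. Inputs come in one of two
#' modes: VCF mode (`reference` + `vcf`, per chromosome) reconstructs
#' haplotypes first; FASTA mode (`fasta`, per chromosome) starts from ready
#' sequences whose record identifiers are sample names.
#'
#' @param out_dir Output directory; created if missing.
#' @param panel Path to a two-column TSV mapping `sample` to `population`.
#' @param fasta Named character vector of per-chromosome cohort FASTA paths
#'   (names = chromosome labels), or `NULL` in VCF mode.
#' @param reference,vcf Named character vectors of per-chromosome reference
#'   FASTA and VCF paths (same names), or `NULL` in FASTA mode.
#' @param k Segment count for the divided natural vector (default 4).
#' @param tree_method `"bionj"` (default), `"nj"`, or `"upgma"`.
#' @param outgroup Optional population label to root the tree at.
#' @param excluded_populations Populations dropped before centroid
#'   distances (e.g. admixed populations that blur the signal).
#' @param haploid Reconstruct one haplotype per sample in VCF mode.
#' @param graph_layers Layers for the natural graph.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, panel, fasta = NULL, reference = NULL,
                       vcf = NULL, k = 4, tree_method = "bionj",
                       outgroup = NULL, excluded_populations = character(),
                       haploid = FALSE, graph_layers = 2) {
  stopifnot(k >= 1, tree_method %in% c("bionj", "nj", "upgma"))
  if (is.null(fasta) && (is.null(reference) || is.null(vcf))) {
    abort("supply either `fasta`, or both `reference` and `vcf`")
  }
  if (!is.null(vcf) && !identical(sort(names(reference)), sort(names(vcf)))) {
    abort("`reference` and `vcf` must be named by the same chromosomes")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline
#'
#' Stage order: reconstruct (VCF mode) -> divided natural vectors per
#' haplotype -> personal vectors -> population centroids -> per-chromosome
#' distance matrices -> summed matrix -> tree (with optional outgroup
#' rooting) -> natural graph. Every intermediate is written under
#' `config$out_dir` (floats at 12 significant digits) and listed, with MD5
#' checksums, in `manifest.json`; identical config and inputs give identical
#' checksums.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `manifest` (tibble: `file`, `md5`), the
#'   summed matrix `total`, the `tree`, and the natural `graph`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- stage("read-panel", {
    p <- readr::read_tsv(config$panel, show_col_types = FALSE)
    stopifnot(all(c("sample", "population") %in% names(p)))
    p
  })

  chroms <- names(config$fasta %||% config$vcf)
  if (is.null(chroms)) {
    abort("per-chromosome inputs must be a *named* vector of paths")
  }
  outputs <- character()

  matrices <- lapply(chroms, function(chr) {
    seqs <- if (!is.null(config$fasta)) {
      stage(paste0("read-fasta:", chr), {
        s <- read_fasta(config$fasta[[chr]])
        dplyr::mutate(s, sample = .data$id, hap = "a")
      })
    } else {
      stage(paste0("reconstruct:", chr), {
        ref <- read_fasta(config$reference[[chr]])
        recs <- read_vcf(config$vcf[[chr]])
        reconstruct_cohort(ref[1, ], recs, haploid = config$haploid)
      })
    }
    vecs <- stage(paste0("dnv:", chr), {
      v <- divided_natural_vector(seqs, k = config$k)
      dplyr::bind_cols(dplyr::select(seqs, "sample", "hap"),
                       dplyr::select(v, -"id"))
    })
    f_vec <- file.path(config$out_dir, paste0("vectors_", chr, ".tsv"))
    write_numeric_tsv(vecs, f_vec)
    personal <- stage(paste0("personal:", chr), personal_vectors(vecs))
    centroids <- stage(paste0("centroids:", chr), {
      cen <- population_centroids(personal, panel)
      dplyr::filter(cen, !.data$population %in% config$excluded_populations)
    })
    f_cen <- file.path(config$out_dir, paste0("centroids_", chr, ".tsv"))
    write_numeric_tsv(centroids, f_cen)
    m <- stage(paste0("distmat:", chr), distance_matrix(centroids))
    f_m <- file.path(config$out_dir, paste0("dist_", chr, ".tsv"))
    write_distance_matrix(m, f_m)
    outputs <<- c(outputs, f_vec, f_cen, f_m)
    m
  })

  total <- stage("sum-matrices", sum_matrices(matrices))
  f_total <- file.path(config$out_dir, "total_distance.tsv")
  write_distance_matrix(total, f_total)

  tree <- stage("tree", build_tree(total, method = config$tree_method,
                                   outgroup = config$outgroup))
  f_tree <- file.path(config$out_dir, "tree.nwk")
  write_newick(tree, f_tree)

  graph <- stage("natural-graph",
                 build_natural_graph(total, layers = config$graph_layers))
  f_graph <- file.path(config$out_dir, "graph_edges.tsv")
  f_dot <- file.path(config$out_dir, "graph.dot")
  write_natural_graph(graph, dot_path = f_dot, tsv_path = f_graph)

  outputs <- c(outputs, f_total, f_tree, f_graph, f_dot)
  manifest <- tibble(file = basename(outputs),
                     md5 = unname(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(list(manifest = manifest, total = total, tree = tree,
                 graph = graph))
}

stage <- function(name, code) {
  t0 <- Sys.time()
  out <- tryCatch(force(code), error = function(e) {
    abort(paste0("pipeline stage [", name, "] failed: ",
                 conditionMessage(e)))
  })
  inform(sprintf("[%s] done in %.2fs", name,
                 as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

# 12 significant digits keeps golden files stable across platforms.
write_numeric_tsv <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                        ~ signif(.x, 12)))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a key-value pipeline configuration file
#'
#' Plain `key = value` lines (one per key, `#` comments allowed). List-valued
#' keys (`fasta`, `reference`, `vcf`, `excluded_populations`) take
#' comma-separated entries, with optional `name=path` pairs for
#' per-chromosome files.
#'
#' @param path Config file path.
#' @param ... Overrides applied on top of the file values.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, ...) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- stringr::str_match(lines, "^\\s*([a-z_]+)\\s*=\\s*(.*?)\\s*$")
  if (anyNA(kv[, 1])) {
    abort(paste0("malformed config line: ", lines[is.na(kv[, 1])][1]))
  }
  vals <- setNames(as.list(kv[, 3]), kv[, 2])
  parse_files <- function(x) {
    if (is.null(x)) return(NULL)
    parts <- strsplit(x, ",", fixed = TRUE)[[1]]
    named <- stringr::str_match(parts, "^([^=]+)=(.*)$")
    if (all(!is.na(named[, 1]))) {
      setNames(trimws(named[, 3]), trimws(named[, 2]))
    } else {
      p <- trimws(parts)
      setNames(p, paste0("chr", seq_along(p)))
    }
  }
  args <- list(
    out_dir = vals$out_dir, panel = vals$panel,
    fasta = parse_files(vals$fasta),
    reference = parse_files(vals$reference),
    vcf = parse_files(vals$vcf))
  if (!is.null(vals$k)) args$k <- as.integer(vals$k)
  if (!is.null(vals$tree_method)) args$tree_method <- vals$tree_method
  if (!is.null(vals$outgroup)) args$outgroup <- vals$outgroup
  if (!is.null(vals$excluded_populations)) {
    args$excluded_populations <-
      trimws(strsplit(vals$excluded_populations, ",")[[1]])
  }
  if (!is.null(vals$haploid)) args$haploid <- as.logical(vals$haploid)
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(run_config, args[!vapply(args, is.null, logical(1))])
}

#' Structure-recovery simulation
#'
#' Repeatedly simulates a population-structured cohort, runs the vector ->
#' centroid -> summed-matrix -> tree pipeline in memory, and scores whether
#' the inferred tree matches the generating population topology
#' (Robinson-Foulds distance 0). This is the package's main end-to-end
#' calibration: with the default generator settings the topology should be
#' recovered in nearly every replicate.
#'
#' @param n_replicates Number of seeded replicates.
#' @param seed Base seed; replicate `i` uses `seed + i`.
#' @param k Segment count for the divided natural vector.
#' @param tree_method Tree builder, `"bionj"` by default.
#' @param ... Passed to [simulate_population_sequences()].
#' @return A tibble with columns `replicate`, `rf` (Robinson-Foulds distance
#'   of the inferred to the generating tree) and attribute-free summary via
#'   `mean(rf == 0)`.
#' @export
structure_recovery <- function(n_replicates = 100, seed = 1, k = 4,
                               tree_method = "bionj", ...) {
  rf <- vapply(seq_len(n_replicates), function(i) {
    sim <- simulate_population_sequences(seed = seed + i, ...)
    mats <- lapply(split(sim$sequences, sim$sequences$chromosome),
                   function(chr_seqs) {
      vecs <- divided_natural_vector(chr_seqs[, c("id", "seq")], k = k)
      vecs$population <- chr_seqs$population
      cen <- vecs |>
        dplyr::group_by(.data$population) |>
        dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean),
                         .groups = "drop")
      distance_matrix(cen)
    })
    tree <- build_tree(sum_matrices(mats), method = tree_method)
    robinson_foulds(tree, sim$tree)
  }, numeric(1))
  tibble(replicate = seq_len(n_replicates), rf = rf)
}
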