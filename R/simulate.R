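#' Simulate a random reference sequence
#'
#' Uniform-random A/C/G/T string, byte-reproducible from the seed. Stands in
#' for a reference chromosome when exercising the pipeline without real data.
#'
#' @param length Sequence length (>= 1).
#' @param seed Integer seed.
#' @return A one-row tibble with columns `id` (`"ref"`) and `seq`.
#' @export
simulate_reference <- function(length, seed) {
  if (length < 1) abort("reference length must be >= 1")
  with_local_seed(seed, {
    tibble(id = "ref",
           seq = paste0(sample(DNA_BASES, length, replace = TRUE),
                        collapse = ""))
  })
}

#' Specification of a synthetic diploid VCF cohort
#'
#' Describes a population-structured cohort of phased diploid genotypes:
#' SNPs shared across all populations segregate at frequency ~0.5 everywhere,
#' while population-private SNPs segregate at high frequency (0.9) in the
#' owning population and are absent elsewhere, so population structure is
#' recoverable from the reconstructed sequences. A fraction of records are
#' small indels, and a fraction are symbolic structural records (e.g.
#' `<CN0>`) that the reconstruction step must exclude.
#'
#' @param n_populations Number of populations.
#' @param samples_per_population Diploid samples per population.
#' @param sequence_length Reference length used when no reference is passed
#'   to [simulate_vcf_cohort()].
#' @param shared_snps Count of cohort-wide SNPs.
#' @param population_private_snps Count of private SNPs per population.
#' @param indel_fraction Fraction of non-structural records that are small
#'   indels instead of SNPs.
#' @param sv_fraction Fraction of additional symbolic structural records,
#'   relative to the non-structural count.
#' @param private_freq Within-population allele frequency of private SNPs.
#' @param shared_freq Cohort-wide allele frequency of shared SNPs.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_populations = 4, samples_per_population = 20,
                        sequence_length = 10000, shared_snps = 40,
                        population_private_snps = 30, indel_fraction = 0.1,
                        sv_fraction = 0.05, private_freq = 0.9,
                        shared_freq = 0.5, seed = 1) {
  stopifnot(n_populations >= 1, samples_per_population >= 1,
            sequence_length >= 1, shared_snps >= 0,
            population_private_snps >= 0,
            indel_fraction >= 0, indel_fraction <= 1,
            sv_fraction >= 0, sv_fraction <= 1)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Simulate a phased diploid VCF cohort
#'
#' Generates VCF text (and a sample-to-population panel) over a reference
#' according to a [cohort_spec()]. Variant positions are placed on a spaced
#' grid so reference spans never overlap; REF alleles are taken verbatim from
#' the reference, so reconstruction passes its REF-verification check.
#'
#' @param reference A reference tibble (as from [simulate_reference()] or
#'   [read_fasta()]) or a single sequence string. `NULL` simulates one of
#'   `spec$sequence_length` from `spec$seed`.
#' @param spec A [cohort_spec()].
#' @param vcf_path,panel_path Optional output paths; when given, the VCF text
#'   and the two-column panel TSV are written there.
#' @return A list with `vcf_lines` (character vector of VCF text),
#'   `panel` (tibble: `sample`, `population`), `reference` (tibble), and
#'   `truth` (tibble of planted records: `pos`, `ref`, `alt`, `type`,
#'   `population` owner or `NA`, plus the planted allele-index matrix in
#'   list-column `gt`).
#' @export
simulate_vcf_cohort <- function(reference = NULL, spec = cohort_spec(),
                                vcf_path = NULL, panel_path = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(reference)) {
    reference <- simulate_reference(spec$sequence_length, spec$seed)
  }
  ref_seq <- as_seq_string(reference)
  L <- nchar(ref_seq)

  n_small <- spec$shared_snps + spec$n_populations * spec$population_private_snps
  n_sv <- floor(spec$sv_fraction * n_small)
  n_total <- n_small + n_sv
  grid <- seq(5L, L - 10L, by = 10L)  # spacing > max REF span, no overlaps
  if (n_total > length(grid)) {
    abort(paste0("requested ", n_total, " variants but only ", length(grid),
                 " non-overlapping positions are available"))
  }

  pops <- sprintf("POP%d", seq_len(spec$n_populations))
  samples <- as.vector(vapply(pops, function(p) {
    sprintf("%s_S%02d", p, seq_len(spec$samples_per_population))
  }, character(spec$samples_per_population)))
  panel <- tibble(sample = samples,
                  population = rep(pops, each = spec$samples_per_population))

  with_local_seed(spec$seed, {
    pos <- sort(sample(grid, n_total))
    type <- rep("snp", n_total)
    if (n_sv > 0) type[sample(n_total, n_sv)] <- "sv"
    small_idx <- which(type == "snp")
    n_indel <- floor(spec$indel_fraction * length(small_idx))
    if (n_indel > 0) type[sample(small_idx, n_indel)] <- "indel"
    small_idx <- which(type != "sv")
    owner <- rep(NA_character_, n_total)
    if (length(small_idx) > 0) {
      private_n <- spec$n_populations * spec$population_private_snps
      private_sites <- sample(small_idx, min(private_n, length(small_idx)))
      owner[private_sites] <- rep(pops, length.out = length(private_sites))
    }

    rows <- lapply(seq_len(n_total), function(i) {
      p <- pos[i]
      base <- substring(ref_seq, p, p)
      if (type[i] == "sv") {
        list(ref = base, alt = "<CN0>", info = "SVTYPE=CNV")
      } else if (type[i] == "indel") {
        if (stats::runif(1) < 0.5) {  # deletion
          dl <- sample(1:4, 1)
          list(ref = substring(ref_seq, p, p + dl), alt = base, info = ".")
        } else {                      # insertion
          ins <- paste0(sample(DNA_BASES, sample(1:5, 1), replace = TRUE),
                        collapse = "")
          list(ref = base, alt = paste0(base, ins), info = ".")
        }
      } else {
        list(ref = base, alt = sample(setdiff(DNA_BASES, base), 1), info = ".")
      }
    })

    n_s <- length(samples)
    gt <- lapply(seq_len(n_total), function(i) {
      freq <- if (type[i] == "sv") {
        rep(0.3, n_s)
      } else if (is.na(owner[i])) {
        rep(spec$shared_freq, n_s)
      } else {
        ifelse(panel$population == owner[i], spec$private_freq, 0)
      }
      matrix(stats::rbinom(2 * n_s, 1, rep(freq, each = 2)), nrow = 2)
    })

    body <- vapply(seq_len(n_total), function(i) {
      g <- gt[[i]]
      paste(c("chrS", pos[i], sprintf("var%04d", i),
              rows[[i]]$ref, rows[[i]]$alt, ".", "PASS", rows[[i]]$info, "GT",
              paste0(g[1, ], "|", g[2, ])),
            collapse = "\t")
    }, character(1))

    header <- c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", samples), collapse = "\t"))
    vcf_lines <- c(header, body)

    truth <- tibble(
      pos = pos, type = type, population = owner,
      ref = vapply(rows, `[[`, character(1), "ref"),
      alt = vapply(rows, `[[`, character(1), "alt"),
      gt = gt)

    if (!is.null(vcf_path)) writeLines(vcf_lines, vcf_path)
    if (!is.null(panel_path)) readr::write_tsv(panel, panel_path)
    list(vcf_lines = vcf_lines, panel = panel,
         reference = tibble(id = "ref", seq = ref_seq), truth = truth)
  })
}

#' Simulate population-structured sequence cohorts
#'
#' Generates sequences by mutating a common ancestor along a known two-level
#' tree (superpopulation -> population -> individual), with substitution
#' counts proportional to branch lengths. Within-population divergence is
#' therefore smaller than between-population divergence, and the generating
#' population topology is returned for recovery tests. Multiple independent
#' "chromosomes" (fresh ancestors, same tree) can be generated to exercise
#' matrix summation.
#'
#' Default mutation counts (per 10 kb: 150 to each superpopulation, 60 to
#' each population, 25 to each individual) put the population-level signal
#' well above the individual-level noise at 20 samples per population, the
#' regime in which centroid averaging is expected to work.
#'
#' @param n_superpops Number of superpopulations.
#' @param pops_per_superpop Populations per superpopulation.
#' @param samples_per_population Sequences per population.
#' @param length Sequence length.
#' @param n_chromosomes Independent replicate sequence sets.
#' @param mut_superpop,mut_population,mut_individual Substitution counts on
#'   the ancestor->superpopulation, superpopulation->population and
#'   population->individual branches.
#' @param seed Integer seed.
#' @return A list with `sequences` (tibble: `chromosome`, `superpopulation`,
#'   `population`, `sample`, `id`, `seq`) and `tree` (the generating
#'   [ape::phylo] topology over population labels, branch lengths in
#'   expected substitutions).
#' @export
simulate_population_sequences <- function(n_superpops = 2,
                                          pops_per_superpop = 2,
                                          samples_per_population = 20,
                                          length = 10000,
                                          n_chromosomes = 2,
                                          mut_superpop = 150,
                                          mut_population = 60,
                                          mut_individual = 25,
                                          seed = 1) {
  stopifnot(n_superpops >= 1, pops_per_superpop >= 1,
            samples_per_population >= 1, length >= 1, n_chromosomes >= 1)
  sp_names <- sprintf("SP%d", seq_len(n_superpops))
  pop_names <- as.vector(vapply(seq_len(n_superpops), function(i) {
    sprintf("SP%d_P%d", i, seq_len(pops_per_superpop))
  }, character(pops_per_superpop)))

  with_local_seed(seed, {
    seqs <- lapply(seq_len(n_chromosomes), function(chr) {
      ancestor <- sample(DNA_BASES, length, replace = TRUE)
      rows <- list()
      for (i in seq_len(n_superpops)) {
        sp_seq <- mutate_chars(ancestor, mut_superpop)
        for (j in seq_len(pops_per_superpop)) {
          pop <- sprintf("SP%d_P%d", i, j)
          pop_seq <- mutate_chars(sp_seq, mut_population)
          for (s in seq_len(samples_per_population)) {
            ind <- mutate_chars(pop_seq, mut_individual)
            rows[[length(rows) + 1]] <- tibble(
              chromosome = sprintf("chr%d", chr),
              superpopulation = sp_names[i],
              population = pop,
              sample = sprintf("%s_S%02d", pop, s),
              seq = paste0(ind, collapse = ""))
          }
        }
      }
      dplyr::bind_rows(rows)
    })
    sequences <- dplyr::bind_rows(seqs)
    sequences$id <- paste0(sequences$sample, "_", sequences$chromosome)
    list(sequences = sequences,
         tree = generating_tree(n_superpops, pops_per_superpop,
                                mut_superpop, mut_population))
  })
}

# Substitute `m` random positions, each to a different base.
mutate_chars <- function(s, m) {
  if (m == 0) return(s)
  m <- min(m, length(s))
  idx <- sample(length(s), m)
  s[idx] <- vapply(s[idx], function(b) sample(setdiff(DNA_BASES, b), 1),
                   character(1))
  s
}

generating_tree <- function(n_superpops, pops_per_superpop,
                            mut_superpop, mut_population) {
  clades <- vapply(seq_len(n_superpops), function(i) {
    tips <- sprintf("SP%d_P%d:%d", i, seq_len(pops_per_superpop),
                    mut_population)
    if (pops_per_superpop == 1) {
      sprintf("SP%d_P1:%d", i, mut_superpop + mut_population)
    } else {
      paste0("(", paste(tips, collapse = ","), "):", mut_superpop)
    }
  }, character(1))
  ape::read.tree(text = paste0("(", paste(clades, collapse = ","), ");"))
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
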