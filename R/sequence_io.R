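#' Read nucleotide sequences from a FASTA file
#'
#' Parses a FASTA file (wrapped or unwrapped lines, any case) into a tibble of
#' sequences. Residues are uppercased and validated against the IUPAC
#' nucleotide alphabet; anything else is an error naming the offending
#' character and record.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (record identifier, the first
#'   whitespace-delimited token of the header) and `seq` (uppercase residues).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ac", "gt", ">s2", "TTTT"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file does not exist: ", path))
  }
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                       forceDNAtolower = FALSE),
    error = function(e) abort(paste0("cannot parse FASTA file ", path, ": ",
                                     conditionMessage(e)))
  )
  if (length(recs) == 0) {
    abort(paste0("FASTA file contains no records: ", path))
  }
  ids <- vapply(recs, function(r) attr(r, "name"), character(1))
  seqs <- toupper(vapply(recs, as.character, character(1)))
  seqs <- gsub("[[:space:]]", "", seqs)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence identifier in ", path, ": ",
                 ids[duplicated(ids)][1]))
  }
  out <- tibble(id = unname(ids), seq = unname(seqs))
  validate_sequences(out, context = path)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs A tibble with columns `id` and `seq`.
#' @param path Output file path.
#' @param linewidth Residues per line; 60 by default.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, linewidth = 60) {
  seqs <- as_seq_tbl(seqs)
  if (anyDuplicated(seqs$id)) {
    abort("duplicate sequence identifiers; FASTA records must be unique")
  }
  seqinr::write.fasta(as.list(seqs$seq), names = seqs$id,
                      file.out = path, nbchar = linewidth)
  invisible(path)
}

#' Read variant records from a VCF file
#'
#' Reads the minimal VCFv4 subset the reconstruction pipeline needs: CHROM,
#' POS, ID, REF, ALT, the SVTYPE INFO key, and per-sample GT fields. Phased
#' (`|`) and unphased (`/`) genotype separators are both accepted; missing
#' alleles (`.`) are recorded as `NA`. Plain-text and gzipped VCFs are
#' supported.
#'
#' @param path Path to a VCF file.
#' @return A tibble with one row per data line: `chrom`, `pos` (1-based
#'   integer), `id`, `ref`, `alt` (list column of character vectors), `svtype`
#'   (`NA` unless the INFO field carries SVTYPE), and `gt`, a list column in
#'   which each element is a tibble with columns `sample`, `a1`, `a2`
#'   (integer allele indices, 0 = REF, j = j-th ALT, `NA` = missing; `a2` is
#'   `NA` for haploid calls).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("VCF file does not exist: ", path))
  }
  check_vcf_columns(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  fix <- as_tibble(as.data.frame(fix, stringsAsFactors = FALSE))
  if (nrow(fix) == 0) {
    return(tibble(chrom = character(), pos = integer(), id = character(),
                  ref = character(), alt = list(), svtype = character(),
                  gt = list()))
  }
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) {
    abort(paste0("non-integer POS field in ", path, ": ",
                 fix$POS[which(is.na(pos))[1]]))
  }
  gt_raw <- v@gt
  samples <- colnames(gt_raw)[-1]
  gt_fields <- sub(":.*$", "", gt_raw[, -1, drop = FALSE])
  gt <- lapply(seq_len(nrow(fix)), function(i) {
    alleles <- strsplit(gt_fields[i, ], "[|/]")
    a1 <- unname(vapply(alleles, function(a) parse_allele(a[1]), integer(1)))
    a2 <- unname(vapply(alleles, function(a) {
      if (length(a) >= 2) parse_allele(a[2]) else NA_integer_
    }, integer(1)))
    tibble(sample = samples, a1 = a1, a2 = a2)
  })
  svtype <- stringr::str_match(fix$INFO, "(?:^|;)SVTYPE=([^;]+)")[, 2]
  tibble(
    chrom = fix$CHROM,
    pos = pos,
    id = fix$ID,
    ref = fix$REF,
    alt = strsplit(fix$ALT, ",", fixed = TRUE),
    svtype = svtype,
    gt = gt
  )
}

parse_allele <- function(x) {
  if (is.na(x) || x == ".") return(NA_integer_)
  i <- suppressWarnings(as.integer(x))
  if (is.na(i) || i < 0) abort(paste0("malformed GT allele index: ", x))
  i
}

# A data line with fewer columns than the declared samples silently loses
# genotypes in permissive parsers, so the column count is checked up front.
check_vcf_columns <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  n_expected <- NA_integer_
  line_no <- 0L
  repeat {
    batch <- readLines(con, n = 1000L)
    if (length(batch) == 0) break
    for (line in batch) {
      line_no <- line_no + 1L
      if (startsWith(line, "##") || !nzchar(line)) next
      n <- length(strsplit(line, "\t", fixed = TRUE)[[1]])
      if (startsWith(line, "#CHROM")) {
        n_expected <- n
        next
      }
      if (is.na(n_expected)) {
        abort(paste0("VCF ", path, " has data before the #CHROM header line"))
      }
      if (n < n_expected) {
        abort(paste0("VCF data line ", line_no, " has ", n,
                     " columns but the header declares ", n_expected))
      }
    }
  }
  if (is.na(n_expected)) {
    abort(paste0("VCF ", path, " has no #CHROM header line"))
  }
  invisible(TRUE)
}

#' Read a phylogenetic tree from a Newick file
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort(paste0("cannot parse Newick file: ", path))
  tree
}

#' Write a phylogenetic tree to a Newick file
#'
#' @param tree An [ape::phylo] tree with at least two uniquely labeled leaves.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2) {
    abort("tree must have at least 2 leaves")
  }
  if (anyDuplicated(tree$tip.label)) {
    abort(paste0("duplicate leaf label: ",
                 tree$tip.label[duplicated(tree$tip.label)][1]))
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a labeled distance matrix from a TSV file
#'
#' The expected layout is the one [write_distance_matrix()] produces: first
#' row and first column carry unit labels, the body is the square matrix.
#'
#' @param path Path to a tab-separated matrix file.
#' @return A labeled, validated distance matrix (see [distance_matrix()]).
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- rownames(df)
  new_dnv_dist(validate_labeled_matrix(m))
}

#' Write a labeled distance matrix to a TSV file
#'
#' @param m A labeled square matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path) {
  m <- validate_labeled_matrix(m)
  df <- data.frame(unit = rownames(m),
                   signif(unclass(m), 12),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Coerce input to a (id, seq) tibble and check residues.
as_seq_tbl <- function(seqs) {
  if (is.character(seqs)) {
    ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
    seqs <- tibble(id = ids, seq = unname(seqs))
  }
  if (!is.data.frame(seqs) || !all(c("id", "seq") %in% names(seqs))) {
    abort("sequences must be a data frame with columns `id` and `seq`")
  }
  as_tibble(seqs)
}

validate_sequences <- function(seqs, context = "input") {
  bad_len <- !nzchar(seqs$seq)
  if (any(bad_len)) {
    abort(paste0("empty sequence for record ", seqs$id[bad_len][1],
                 " in ", context))
  }
  pattern <- paste0("[^", paste(IUPAC_CODES, collapse = ""), "]")
  hit <- stringr::str_extract(seqs$seq, pattern)
  if (any(!is.na(hit))) {
    i <- which(!is.na(hit))[1]
    abort(paste0("invalid character '", hit[i], "' in record ",
                 seqs$id[i], " in ", context,
                 "; allowed: ", paste(IUPAC_CODES, collapse = "")))
  }
  invisible(seqs)
}
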