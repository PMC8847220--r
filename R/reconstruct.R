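#' Identify structural variant records
#'
#' Copy-number and other structural variants are excluded from consensus
#' reconstruction: their leftmost-position coordinates are ambiguous in
#' duplicated regions, so splicing them into the reference is unreliable. A
#' record is structural when any ALT allele is symbolic (angle-bracketed, e.g.
#' `<CN0>`) or when the INFO field carries SVTYPE. Multi-base explicit
#' alleles are small indels, not structural variants.
#'
#' @param records A variant tibble as returned by [read_vcf()].
#' @return A logical vector, one element per record.
#' @export
is_structural <- function(records) {
  symbolic <- vapply(records$alt, function(a) any(grepl("^<.*>$", a)),
                     logical(1))
  symbolic | !is.na(records$svtype)
}

#' Allele carried by one haplotype at one variant record
#'
#' @param rec A one-row variant tibble (one element of [read_vcf()] output).
#' @param sample Sample name.
#' @param hap_index Which haplotype: 0 (first GT field) or 1 (second).
#' @return The ALT allele string the haplotype carries, or `"reference"` when
#'   the allele index is 0 or the call is missing.
#' @export
haplotype_allele <- function(rec, sample, hap_index) {
  stopifnot(nrow(rec) == 1, hap_index %in% c(0, 1))
  gt <- rec$gt[[1]]
  row <- match(sample, gt$sample)
  if (is.na(row)) {
    abort(paste0("sample not present in record: ", sample))
  }
  idx <- if (hap_index == 0) gt$a1[row] else gt$a2[row]
  if (is.na(idx) || idx == 0) {
    return("reference")
  }
  alts <- rec$alt[[1]]
  if (idx > length(alts)) {
    abort(paste0("allele index ", idx, " out of range at pos ", rec$pos))
  }
  alts[idx]
}

#' Apply variant calls to a reference to reconstruct one haplotype
#'
#' Splices the alleles one haplotype carries into the reference sequence: for
#' every non-reference call, the reference substring
#' `[pos, pos + nchar(ref) - 1]` is replaced by the allele string.
#' Substitutions are applied in descending position order on a copy, so
#' earlier VCF coordinates stay valid in the presence of indels. Structural
#' records are skipped; missing allele calls are treated as reference.
#'
#' @param reference Reference sequence: a single string or a one-row tibble
#'   with columns `id` and `seq`.
#' @param records Variant tibble from [read_vcf()].
#' @param sample Sample name.
#' @param hap_index 0 or 1, selecting the first or second GT field.
#' @param verify_ref Check that each applied record's REF matches the
#'   reference at its position: `"error"` (default) aborts on mismatch,
#'   `"warn"` downgrades to a warning (useful when the reference build is
#'   known to differ), `"none"` skips the check.
#' @return The reconstructed haplotype as a single string.
#' @export
apply_variants <- function(reference, records, sample, hap_index,
                           verify_ref = c("error", "warn", "none")) {
  verify_ref <- match.arg(verify_ref)
  ref_seq <- as_seq_string(reference)
  if (nrow(records) == 0) {
    return(ref_seq)
  }
  records <- records[!is_structural(records), , drop = FALSE]
  if (nrow(records) == 0) {
    return(ref_seq)
  }
  alleles <- vapply(seq_len(nrow(records)), function(i) {
    haplotype_allele(records[i, ], sample, hap_index)
  }, character(1))
  apply_idx <- which(alleles != "reference")
  if (length(apply_idx) == 0) {
    return(ref_seq)
  }
  pos <- records$pos[apply_idx]
  ref_allele <- records$ref[apply_idx]
  alt_allele <- alleles[apply_idx]

  span_end <- pos + nchar(ref_allele) - 1L
  ord <- order(pos)
  if (any(pos[ord][-1] <= span_end[ord][-length(ord)])) {
    j <- which(pos[ord][-1] <= span_end[ord][-length(ord)])[1]
    abort(paste0("overlapping variant records at positions ",
                 pos[ord][j], " and ", pos[ord][j + 1],
                 " for sample ", sample))
  }
  if (any(span_end > nchar(ref_seq))) {
    abort(paste0("variant at pos ", pos[which(span_end > nchar(ref_seq))[1]],
                 " extends past the reference end"))
  }
  if (verify_ref != "none") {
    found <- substring(ref_seq, pos, span_end)
    bad <- found != ref_allele
    if (any(bad)) {
      msg <- paste0("REF allele mismatch at pos ", pos[bad][1],
                    ": VCF says ", ref_allele[bad][1],
                    ", reference has ", found[bad][1])
      if (verify_ref == "error") abort(msg) else warn(msg)
    }
  }
  # Descending-position splice keeps upstream coordinates valid.
  out <- ref_seq
  for (i in order(pos, decreasing = TRUE)) {
    out <- paste0(substring(out, 1, pos[i] - 1L),
                  alt_allele[i],
                  substring(out, span_end[i] + 1L))
  }
  out
}

#' Reconstruct haplotype sequences for a cohort of samples
#'
#' Runs [apply_variants()] over both haplotypes of every sample, yielding the
#' "a"/"b" chromosome copies of each individual. Which copy is maternal or
#' paternal is unknowable from phased VCF data, so the labels are arbitrary;
#' downstream averaging makes them exchangeable. In haploid mode (e.g. a Y
#' chromosome, where one sequence represents a male individual) only the
#' first GT field is used and a single sequence per sample is returned.
#'
#' @inheritParams apply_variants
#' @param samples Character vector of sample names; default all samples
#'   present in the records (or in `panel_samples` when records are empty).
#' @param haploid Reconstruct one sequence per sample from the first GT field.
#' @return A tibble with columns `sample`, `hap` (`"a"`/`"b"`, or `"a"` only
#'   in haploid mode), `id` (`<sample>_<hap>`), and `seq`.
#' @export
reconstruct_cohort <- function(reference, records, samples = NULL,
                               haploid = FALSE,
                               verify_ref = c("error", "warn", "none")) {
  verify_ref <- match.arg(verify_ref)
  if (is.null(samples)) {
    if (nrow(records) == 0) {
      abort("no records and no `samples` given; cannot infer the cohort")
    }
    samples <- records$gt[[1]]$sample
  }
  haps <- if (haploid) "a" else c("a", "b")
  grid <- tidyr::expand_grid(sample = samples, hap = haps)
  seqs <- purrr::map2_chr(grid$sample, grid$hap, function(s, h) {
    apply_variants(reference, records, s, hap_index = match(h, c("a", "b")) - 1L,
                   verify_ref = verify_ref)
  })
  dplyr::mutate(grid, id = paste0(.data$sample, "_", .data$hap), seq = seqs)
}

as_seq_string <- function(reference) {
  if (is.data.frame(reference)) {
    if (nrow(reference) != 1 || !"seq" %in% names(reference)) {
      abort("`reference` data frame must have exactly one row and a `seq` column")
    }
    reference <- reference$seq
  }
  if (!is.character(reference) || length(reference) != 1 || !nzchar(reference)) {
    abort("`reference` must be a single nonempty sequence string")
  }
  toupper(reference)
}
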