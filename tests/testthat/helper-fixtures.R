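# Shared fixture builders. Everything is generated in code; no binary files.

# Random uppercase A/C/G/T string.
random_seq <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random unrooted binary tree with positive branch lengths and sorted labels.
random_tree <- function(n_tips, min_edge = 0.5, max_edge = 3) {
  tr <- ape::rtree(n_tips, rooted = FALSE,
                   tip.label = sprintf("T%02d", seq_len(n_tips)))
  tr$edge.length <- runif(length(tr$edge.length), min_edge, max_edge)
  tr
}

# Additive distance matrix induced by a tree (the independent oracle for NJ).
additive_matrix <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  labs <- sort(rownames(m))
  m <- m[labs, labs]
  diag(m) <- 0
  m
}

# Ultrametric matrix from a random coalescent tree (oracle for UPGMA).
ultrametric_matrix <- function(n_tips) {
  tr <- ape::rcoal(n_tips, tip.label = sprintf("U%02d", seq_len(n_tips)))
  additive_matrix(tr)
}

# The spec'd 4-taxon additive matrix from tree ((A:1,B:2):1,(C:3,D:4)).
four_taxon_additive <- function() {
  m <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  m["A", "B"] <- 3; m["A", "C"] <- 5; m["A", "D"] <- 6
  m["B", "C"] <- 6; m["B", "D"] <- 7; m["C", "D"] <- 7
  m + t(m)
}

# Ultrametric toy: d(A,B)=2, d(.,C)=4, d(.,D)=6.
four_taxon_ultrametric <- function() {
  m <- matrix(6, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  m["A", "B"] <- 2; m["B", "A"] <- 2
  m["A", "C"] <- 4; m["C", "A"] <- 4
  m["B", "C"] <- 4; m["C", "B"] <- 4
  diag(m) <- 0
  m
}

# Labeled distance matrix from a set of labeled Euclidean points: the metric
# oracle used for triangle-inequality and matrix-property checks.
points_matrix <- function(points) {
  m <- as.matrix(dist(points))
  dimnames(m) <- list(rownames(points), rownames(points))
  m
}

# Independent left-to-right splicing oracle for variant application: walks
# the reference once, copying unchanged stretches and substituting alleles.
oracle_splice <- function(ref, pos, ref_allele, alt_allele) {
  ord <- order(pos)
  pos <- pos[ord]; ref_allele <- ref_allele[ord]; alt_allele <- alt_allele[ord]
  out <- character(0)
  cursor <- 1L
  for (i in seq_along(pos)) {
    out <- c(out, substring(ref, cursor, pos[i] - 1L), alt_allele[i])
    cursor <- pos[i] + nchar(ref_allele[i])
  }
  paste0(c(out, substring(ref, cursor, nchar(ref))), collapse = "")
}

# Write a minimal VCF with given body lines and sample names.
write_mini_vcf <- function(body, samples, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body), path)
  path
}

worked_example_ref <- function() {
  read_fasta(system.file("extdata", "worked_example_ref.fa", package = "dnv"))
}

worked_example_vcf <- function() {
  read_vcf(system.file("extdata", "worked_example.vcf", package = "dnv"))
}
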