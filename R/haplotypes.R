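#' Aligned mtDNA haplotype sequences
#'
#' Equal-length aligned sequences (control-region haplotypes) with sample
#' identifiers. Sites where any sequence carries a symbol outside A/C/G/T
#' (ambiguity codes, gaps, N) are recorded in `excluded_sites` and dropped
#' listwise from every sequence statistic and distance computation.
#'
#' @param individual_ids Character vector of unique sequence labels.
#' @param sequences Character vector of aligned sequences (one string per
#'   individual); case-insensitive on input, stored uppercase.
#' @return An object of class `haplotype_alignment` with elements `ids`,
#'   `seq` (uppercase strings), `length` (alignment length) and
#'   `excluded_sites` (1-based positions excluded from statistics).
#' @export
haplotype_alignment <- function(individual_ids, sequences) {
  individual_ids <- as.character(individual_ids)
  sequences <- toupper(as.character(sequences))
  if (length(individual_ids) != length(sequences))
    stop("one id per sequence required")
  if (anyDuplicated(individual_ids))
    stop("duplicate sequence ids")
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1)
    stop("alignment error: sequences have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")")
  L <- lens[1]
  m <- .seq_matrix(sequences)
  bad <- which(apply(m, 2, function(col) any(!col %in% c("A", "C", "G", "T"))))
  structure(list(ids = individual_ids, seq = sequences, length = L,
                 excluded_sites = bad),
            class = "haplotype_alignment")
}

.seq_matrix <- function(sequences) {
  do.call(rbind, strsplit(sequences, ""))
}

#' Sites usable for sequence statistics
#' @param mt A [haplotype_alignment()].
#' @return Integer vector of 1-based site positions with A/C/G/T in every
#'   sequence.
#' @export
usable_sites <- function(mt) {
  setdiff(seq_len(mt$length), mt$excluded_sites)
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat("haplotype_alignment:", length(x$ids), "sequences of length",
      x$length, "\n")
  if (length(x$excluded_sites))
    cat(length(x$excluded_sites), "sites excluded (non-ACGT symbols)\n")
  invisible(x)
}

#' Subset an alignment by individuals
#' @param x A [haplotype_alignment()].
#' @param i Index vector (ids, positions or logical).
#' @param ... Unused.
#' @export
`[.haplotype_alignment` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  haplotype_alignment(x$ids[i], x$seq[i])
}

#' Read an aligned FASTA file
#'
#' Thin wrapper around [ape::read.FASTA()]; records must have identical
#' lengths (it is an alignment, not a sequence set).
#'
#' @param path Path to a FASTA file.
#' @return A [haplotype_alignment()].
#' @export
read_haplotypes <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), function(s)
    paste(toupper(s), collapse = ""), character(1))
  haplotype_alignment(names(dna), unname(seqs))
}

#' Write an alignment to FASTA
#' @param mt A [haplotype_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(mt, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0(">", mt$ids, "\n", mt$seq), con)
  invisible(path)
}

#' Read a population-partition table
#'
#' A CSV with columns `id` and `population` assigning individuals to the
#' (externally inferred) genetic clusters. The partition is an input, never
#' inferred here; cluster inference itself is out of scope.
#'
#' @param path Path to the CSV file.
#' @param geno,mt Optional [genotype_table()] / [haplotype_alignment()]
#'   against which ids are validated: every labelled individual must exist
#'   in at least one of them.
#' @return A data frame with columns `id` and `population` (factor with
#'   levels in order of first appearance).
#' @export
read_partition <- function(path, geno = NULL, mt = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "population") %in% names(df)))
    stop("partition file needs 'id' and 'population' columns")
  partition(df$id, df$population, geno = geno, mt = mt)
}

#' Build a population partition
#' @param ids Character vector of individual ids (no duplicates).
#' @param populations Population label per id.
#' @param geno,mt Optional containers used to validate that every id exists.
#' @return Data frame `id`, `population` (factor, levels in order of first
#'   appearance).
#' @export
partition <- function(ids, populations, geno = NULL, mt = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("partition assigns some individuals twice: populations must be ",
         "disjoint")
  if (!is.null(geno) || !is.null(mt)) {
    known <- c(if (!is.null(geno)) geno$ids, if (!is.null(mt)) mt$ids)
    missing <- setdiff(ids, known)
    if (length(missing))
      stop("partition labels unknown individuals: ",
           paste(head(missing, 5), collapse = ", "))
  }
  data.frame(id = ids,
             population = factor(populations, levels = unique(populations)),
             stringsAsFactors = FALSE)
}

#' Write a partition table to CSV
#' @param part Data frame from [partition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(part, path) {
  write.csv(data.frame(id = part$id,
                       population = as.character(part$population)),
            path, row.names = FALSE)
  invisible(path)
}

.pop_of <- function(ids, part) {
  part$population[match(ids, part$id)]
}

#' Individual-inclusion filter
#'
#' Keeps an individual when at least half of its marker information is
#' available: at least 6 typed microsatellite loci, or at least 5 typed loci
#' together with an mtDNA sequence. Individuals present only in the mtDNA
#' alignment are untouched (they participate only in sequence statistics).
#' The filter is idempotent.
#'
#' @param geno A [genotype_table()].
#' @param mt Optional [haplotype_alignment()] used to check mtDNA
#'   availability.
#' @param min_loci_with_mt,min_loci_without Inclusion thresholds (defaults
#'   5 and 6).
#' @return A list with `genotypes` (the filtered table) and `report` (data
#'   frame of all individuals with `typed_loci`, `has_mt`, `kept`,
#'   `reason`).
#' @export
filter_individuals <- function(geno, mt = NULL, min_loci_with_mt = 5,
                               min_loci_without = 6) {
  typed <- typed_loci(geno)
  has_mt <- if (is.null(mt)) rep(FALSE, length(geno$ids)) else
    geno$ids %in% mt$ids
  kept <- typed >= min_loci_without |
    (typed >= min_loci_with_mt & has_mt)
  reason <- ifelse(kept, "",
                   sprintf("only %d typed loci and %s mtDNA sequence",
                           typed, ifelse(has_mt, "an", "no")))
  report <- data.frame(id = geno$ids, typed_loci = typed, has_mt = has_mt,
                       kept = kept, reason = reason,
                       stringsAsFactors = FALSE)
  list(genotypes = geno[which(kept)], report = report)
}
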