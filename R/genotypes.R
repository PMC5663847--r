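#' Diploid microsatellite genotype table
#'
#' The central container for nuclear genotypes: an individuals-by-loci table
#' of unordered diploid allele pairs, stored as integer allele sizes in
#' repeat units. A genotype is either fully typed (both alleles present) or
#' missing (both `NA`); a sentinel size of 0 is never used in computations.
#'
#' @param individual_ids Character vector of unique individual labels.
#' @param locus_names Character vector of locus names (at least one locus).
#' @param allele1,allele2 Integer matrices (individuals x loci) of allele
#'   sizes in repeat units; `NA` marks a missing genotype and must occur in
#'   both matrices at the same cells.
#' @param locality Optional character vector of sampling-locality labels,
#'   one per individual.
#' @param motif_lengths Optional integer vector (one per locus) giving the
#'   repeat-motif length in base pairs, used when converting base-pair
#'   allele calls to repeat units.
#'
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(individual_ids, locus_names, allele1, allele2,
                           locality = NULL, motif_lengths = NULL) {
  individual_ids <- as.character(individual_ids)
  locus_names <- as.character(locus_names)
  allele1 <- as.matrix(allele1)
  allele2 <- as.matrix(allele2)
  storage.mode(allele1) <- "integer"
  storage.mode(allele2) <- "integer"
  n <- length(individual_ids)
  L <- length(locus_names)
  if (L < 1) stop("at least one locus is required")
  if (anyDuplicated(individual_ids))
    stop("duplicate individual ids: ",
         paste(unique(individual_ids[duplicated(individual_ids)]),
               collapse = ", "))
  if (!all(dim(allele1) == c(n, L)) || !all(dim(allele2) == c(n, L)))
    stop("allele matrices must be individuals x loci")
  if (!identical(unname(is.na(allele1)), unname(is.na(allele2))))
    stop("a genotype must have both alleles present or both missing")
  if (any(allele1 <= 0, na.rm = TRUE) || any(allele2 <= 0, na.rm = TRUE))
    stop("allele sizes must be positive integers")
  if (!is.null(locality) && length(locality) != n)
    stop("locality must have one entry per individual")
  if (!is.null(motif_lengths) && length(motif_lengths) != L)
    stop("motif_lengths must have one entry per locus")
  dimnames(allele1) <- dimnames(allele2) <- list(individual_ids, locus_names)
  structure(list(ids = individual_ids, loci = locus_names,
                 a1 = allele1, a2 = allele2,
                 locality = if (is.null(locality)) NULL else
                   as.character(locality),
                 motif_lengths = motif_lengths),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$ids), "individuals,",
      length(x$loci), "loci\n")
  cat("missing fraction per locus:",
      paste(sprintf("%.2f", missing_fraction(x)), collapse = " "), "\n")
  invisible(x)
}

#' Number of typed loci per individual
#' @param geno A [genotype_table()].
#' @return Integer vector, one entry per individual.
#' @export
typed_loci <- function(geno) {
  rowSums(!is.na(geno$a1))
}

#' Missing-data fraction per locus
#' @param geno A [genotype_table()].
#' @return Numeric vector in `[0, 1]`, one entry per locus.
#' @export
missing_fraction <- function(geno) {
  colMeans(is.na(geno$a1))
}

#' Subset a genotype table by individuals
#' @param x A [genotype_table()].
#' @param i Index vector (ids, positions or logical) of individuals to keep.
#' @param ... Unused.
#' @return A [genotype_table()] restricted to the selected individuals.
#' @export
`[.genotype_table` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  genotype_table(x$ids[i], x$loci, x$a1[i, , drop = FALSE],
                 x$a2[i, , drop = FALSE],
                 locality = if (is.null(x$locality)) NULL else x$locality[i],
                 motif_lengths = x$motif_lengths)
}

.bp_to_repeats <- function(mat, motif_lengths) {
  res <- sweep(mat, 2, motif_lengths, "/")
  if (any(abs(res - round(res)) > 1e-9, na.rm = TRUE))
    stop("base-pair allele sizes are not integral multiples of the motif ",
         "length; check motif_lengths")
  round(res)
}

#' Read a genotype table from GenePop or CSV
#'
#' The GenePop dialects with 2-digit (4 per genotype) and 3-digit (6 per
#' genotype) allele codes are supported; `00`/`000` encodes a missing
#' genotype and population blocks become locality labels. The CSV layout has
#' columns `id`, `locality`, then `<locus>_a`, `<locus>_b` pairs, with 0 or
#' empty cells marking missing genotypes.
#'
#' @param path Path to the input file.
#' @param format One of `"auto"`, `"genepop"`, `"csv"`. With `"auto"` the
#'   file extension decides (`.csv` vs anything else).
#' @param units `"repeats"` if allele codes already count repeat units
#'   (default), `"bp"` if they are fragment/motif sizes in base pairs to be
#'   divided by `motif_lengths`.
#' @param motif_lengths Integer vector of per-locus motif lengths in bp;
#'   required when `units = "bp"`.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, format = c("auto", "genepop", "csv"),
                           units = c("repeats", "bp"), motif_lengths = NULL) {
  format <- match.arg(format)
  units <- match.arg(units)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
      else "genepop"
  gt <- if (format == "genepop") .read_genepop(path) else .read_geno_csv(path)
  if (units == "bp") {
    if (is.null(motif_lengths))
      stop("motif_lengths is required when units = 'bp'")
    gt$a1 <- .bp_to_repeats(gt$a1, motif_lengths)
    gt$a2 <- .bp_to_repeats(gt$a2, motif_lengths)
    gt$motif_lengths <- motif_lengths
  } else if (!is.null(motif_lengths)) {
    gt$motif_lengths <- motif_lengths
  }
  genotype_table(gt$ids, gt$loci, gt$a1, gt$a2, gt$locality,
                 gt$motif_lengths)
}

.read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("malformed GenePop file: too few lines")
  body <- lines[-1]  # drop title
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_idx) == 0)
    stop("malformed GenePop file: no 'POP' line found")
  locus_lines <- body[seq_len(pop_idx[1] - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  ids <- character(); locality <- character()
  rows <- list()
  pop_no <- 0
  for (k in seq_along(body)) {
    if (k < pop_idx[1]) next
    line <- body[k]
    if (grepl("^\\s*pop\\s*$", line, ignore.case = TRUE)) {
      pop_no <- pop_no + 1
      next
    }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2)
      stop("malformed GenePop file at line ", k + 1,
           ": expected 'id , genotypes'")
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = " ")),
                      "\\s+")[[1]]
    if (length(codes) != length(loci))
      stop("malformed GenePop file at line ", k + 1, ": ", length(codes),
           " genotypes for ", length(loci), " loci")
    w <- unique(nchar(codes))
    if (length(w) != 1 || !(w %in% c(4, 6)))
      stop("malformed GenePop file at line ", k + 1,
           ": genotype codes must be uniformly 4 or 6 digits")
    half <- w / 2
    a1 <- as.integer(substr(codes, 1, half))
    a2 <- as.integer(substr(codes, half + 1, w))
    if (any(is.na(a1)) || any(is.na(a2)))
      stop("malformed GenePop file at line ", k + 1,
           ": non-numeric allele code")
    a1[a1 == 0] <- NA; a2[a2 == 0] <- NA
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA; a2[miss] <- NA
    ids <- c(ids, id)
    locality <- c(locality, paste0("pop", pop_no))
    rows[[length(rows) + 1]] <- rbind(a1, a2)
  }
  a1 <- do.call(rbind, lapply(rows, function(r) r[1, ]))
  a2 <- do.call(rbind, lapply(rows, function(r) r[2, ]))
  list(ids = ids, loci = loci, a1 = a1, a2 = a2, locality = locality,
       motif_lengths = NULL)
}

.read_geno_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("id", "locality") %in% names(df)))
    stop("malformed genotype CSV: need 'id' and 'locality' columns")
  acols <- setdiff(names(df), c("id", "locality"))
  if (length(acols) %% 2 != 0)
    stop("malformed genotype CSV: odd number of allele columns")
  la <- acols[seq(1, length(acols), by = 2)]
  lb <- acols[seq(2, length(acols), by = 2)]
  if (!all(sub("_a$", "", la) == sub("_b$", "", lb)))
    stop("malformed genotype CSV: allele columns must come in ",
         "<locus>_a, <locus>_b pairs")
  loci <- sub("_a$", "", la)
  a1 <- as.matrix(df[, la, drop = FALSE]); storage.mode(a1) <- "integer"
  a2 <- as.matrix(df[, lb, drop = FALSE]); storage.mode(a2) <- "integer"
  a1[a1 == 0] <- NA; a2[a2 == 0] <- NA
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA; a2[miss] <- NA
  list(ids = df$id, loci = loci, a1 = a1, a2 = a2, locality = df$locality,
       motif_lengths = NULL)
}

#' Write a genotype table to GenePop or CSV
#'
#' @param geno A [genotype_table()].
#' @param path Output path.
#' @param format `"genepop"` or `"csv"`.
#' @param digits Allele-code width for GenePop (2 or 3 digits per allele).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("genepop", "csv"),
                            digits = 3) {
  format <- match.arg(format)
  if (format == "csv") {
    a1 <- geno$a1; a2 <- geno$a2
    a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
    out <- data.frame(id = geno$ids,
                      locality = geno$locality %||%
                        rep("pop1", length(geno$ids)),
                      stringsAsFactors = FALSE, check.names = FALSE)
    for (l in seq_along(geno$loci)) {
      out[[paste0(geno$loci[l], "_a")]] <- a1[, l]
      out[[paste0(geno$loci[l], "_b")]] <- a2[, l]
    }
    write.csv(out, path, row.names = FALSE)
    return(invisible(path))
  }
  if (!(digits %in% c(2, 3))) stop("digits must be 2 or 3")
  fmt <- paste0("%0", digits, "d%0", digits, "d")
  loc <- geno$locality %||% rep("pop1", length(geno$ids))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("finpop genotype export", con)
  writeLines(geno$loci, con)
  for (p in unique(loc)) {
    writeLines("POP", con)
    for (i in which(loc == p)) {
      a1 <- geno$a1[i, ]; a2 <- geno$a2[i, ]
      a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
      if (any(a1 >= 10^digits) || any(a2 >= 10^digits))
        stop("allele size too large for ", digits, "-digit GenePop codes")
      writeLines(paste0(geno$ids[i], " , ",
                        paste(sprintf(fmt, a1, a2), collapse = " ")), con)
    }
  }
  invisible(path)
}
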