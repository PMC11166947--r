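#' Genotype matrix container
#'
#' Holds per-individual allele counts over biallelic SNPs. Values count the
#' alternative allele: 0, 1, 2 or `NA` (missing). Pseudohaploid individuals
#' carry a single sampled allele doubled, so they never hold the value 1.
#'
#' @param values integer matrix, individuals in rows, SNPs in columns;
#'   `NA` marks missing calls.
#' @param ploidy character vector, one of `"diploid"` or `"pseudohaploid"`
#'   per individual (recycled if length 1).
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(values, ploidy = "diploid") {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  ploidy <- rep_len(match.arg(ploidy, c("diploid", "pseudohaploid"),
                              several.ok = TRUE), nrow(values))
  bad <- !is.na(values) & !(values %in% 0:2)
  if (any(bad)) stop("genotype values must be 0, 1, 2 or NA")
  ph <- ploidy == "pseudohaploid"
  if (any(ph) && any(values[ph, , drop = FALSE] == 1L, na.rm = TRUE))
    stop("pseudohaploid individuals cannot carry heterozygous calls")
  structure(list(values = values, ploidy = ploidy), class = "geno_matrix")
}

#' @export
dim.geno_matrix <- function(x) dim(x$values)

#' @export
print.geno_matrix <- function(x, ...) {
  miss <- mean(is.na(x$values))
  cat(sprintf("<geno_matrix> %d individuals x %d SNPs (%.1f%% missing; %d pseudohaploid)\n",
              nrow(x$values), ncol(x$values), 100 * miss,
              sum(x$ploidy == "pseudohaploid")))
  invisible(x)
}

#' SNP metadata table
#'
#' @param snp_id,chromosome,genetic_pos,physical_pos,ref,alt column vectors;
#'   `genetic_pos` is in Morgans, `physical_pos` 1-based base pairs.
#' @return A `data.frame` with class `snp_table`.
#' @export
snp_table <- function(snp_id, chromosome, genetic_pos, physical_pos, ref, alt) {
  df <- data.frame(snp_id = as.character(snp_id),
                   chromosome = as.integer(chromosome),
                   genetic_pos = as.numeric(genetic_pos),
                   physical_pos = as.integer(physical_pos),
                   ref = as.character(ref), alt = as.character(alt),
                   stringsAsFactors = FALSE)
  if (any(df$genetic_pos < 0)) stop("genetic positions must be non-negative")
  if (any(df$physical_pos < 1)) stop("physical positions must be >= 1")
  if (any(df$ref == df$alt)) stop("ref and alt alleles must differ")
  for (ch in unique(df$chromosome)) {
    sel <- df$chromosome == ch
    if (is.unsorted(df$genetic_pos[sel]))
      stop("genetic positions must be non-decreasing within chromosome ", ch)
    if (is.unsorted(df$physical_pos[sel], strictly = TRUE))
      stop("physical positions must be strictly increasing within chromosome ", ch)
  }
  class(df) <- c("snp_table", "data.frame")
  df
}

#' Individual metadata table
#'
#' @param individual_id unique identifiers.
#' @param sex one of `"M"`, `"F"`, `"U"` per individual.
#' @param population population label per individual.
#' @return A `data.frame` with class `ind_table`.
#' @export
ind_table <- function(individual_id, sex = "U", population) {
  individual_id <- as.character(individual_id)
  if (anyDuplicated(individual_id))
    stop("individual ids must be unique")
  sex <- rep_len(as.character(sex), length(individual_id))
  if (!all(sex %in% c("M", "F", "U"))) stop("sex must be M, F or U")
  df <- data.frame(individual_id = individual_id, sex = sex,
                   population = as.character(population),
                   stringsAsFactors = FALSE)
  class(df) <- c("ind_table", "data.frame")
  df
}

#' Read an EIGENSTRAT genotype triplet
#'
#' Reads `<prefix>.geno` (ASCII, one row per SNP, one digit per individual,
#' `9` = missing), `<prefix>.snp` (six whitespace-separated columns: id,
#' chromosome, genetic position, physical position, ref, alt) and
#' `<prefix>.ind` (id, sex, population label).
#'
#' @param prefix file path prefix of the triplet.
#' @param gpos_unit unit of the `.snp` genetic-position column; the
#'   EIGENSTRAT convention is Morgans, but centimorgan files exist.
#' @param ploidy ploidy mode assigned to every individual (the format does
#'   not record it).
#' @return A list with elements `geno` ([geno_matrix()]), `snp`
#'   ([snp_table()]) and `ind` ([ind_table()]).
#' @export
read_eigenstrat <- function(prefix, gpos_unit = c("morgans", "cm"),
                            ploidy = "diploid") {
  gpos_unit <- match.arg(gpos_unit)
  paths <- paste0(prefix, c(".geno", ".snp", ".ind"))
  for (p in paths) if (!file.exists(p)) stop("missing file: ", p)

  ind_raw <- utils::read.table(paths[3], header = FALSE,
                               col.names = c("id", "sex", "pop"),
                               stringsAsFactors = FALSE)
  snp_raw <- utils::read.table(paths[2], header = FALSE,
                               col.names = c("id", "chrom", "gpos", "ppos",
                                             "ref", "alt"),
                               colClasses = c("character", "integer",
                                              "numeric", "integer",
                                              "character", "character"))
  glines <- readLines(paths[1])
  if (length(glines) != nrow(snp_raw))
    stop(sprintf("dimension mismatch: %s has %d rows but %s has %d lines",
                 paths[1], length(glines), paths[2], nrow(snp_raw)))
  widths <- nchar(glines)
  if (any(widths != nrow(ind_raw)))
    stop(sprintf("dimension mismatch: %s line %d has %d genotypes but %s has %d individuals",
                 paths[1], which(widths != nrow(ind_raw))[1],
                 widths[widths != nrow(ind_raw)][1], paths[3], nrow(ind_raw)))
  bad <- grep("[^0-9]", glines)
  if (length(bad))
    stop(sprintf("non-digit genotype character in %s line %d", paths[1], bad[1]))
  vals <- matrix(as.integer(unlist(strsplit(glines, "", fixed = TRUE),
                                   use.names = FALSE)),
                 nrow = nrow(ind_raw), ncol = length(glines))
  vals[vals == 9L] <- NA_integer_

  gpos <- snp_raw$gpos
  if (gpos_unit == "cm") gpos <- gpos / 100
  if (all(gpos == 0)) {
    message("all genetic positions are zero; falling back to 1 cM ~ 1 Mb from physical positions")
    gpos <- snp_raw$ppos * 1e-8
  }
  snp <- snp_table(snp_raw$id, snp_raw$chrom, gpos, snp_raw$ppos,
                   snp_raw$ref, snp_raw$alt)
  ind <- ind_table(ind_raw$id, ind_raw$sex, ind_raw$pop)
  g <- geno_matrix(vals, ploidy)
  rownames(g$values) <- ind$individual_id
  colnames(g$values) <- snp$snp_id
  message(sprintf("read %d individuals x %d SNPs from %s*", nrow(vals),
                  ncol(vals), prefix))
  list(geno = g, snp = snp, ind = ind)
}

#' Write an EIGENSTRAT genotype triplet
#'
#' Inverse of [read_eigenstrat()]; genetic positions are written in Morgans.
#'
#' @param geno a [geno_matrix()].
#' @param snp a [snp_table()].
#' @param ind an [ind_table()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_eigenstrat <- function(geno, snp, ind, prefix) {
  stopifnot(nrow(geno$values) == nrow(ind), ncol(geno$values) == nrow(snp))
  v <- geno$values
  v[is.na(v)] <- 9L
  lines <- apply(v, 2, paste0, collapse = "")
  writeLines(lines, paste0(prefix, ".geno"))
  utils::write.table(
    data.frame(snp$snp_id, snp$chromosome,
               sprintf("%.10g", snp$genetic_pos), snp$physical_pos,
               snp$ref, snp$alt),
    paste0(prefix, ".snp"), quote = FALSE, row.names = FALSE,
    col.names = FALSE, sep = "\t")
  utils::write.table(
    data.frame(ind$individual_id, ind$sex, ind$population),
    paste0(prefix, ".ind"), quote = FALSE, row.names = FALSE,
    col.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' Population allele frequencies
#'
#' Tallies alternative-allele counts per population. A non-missing diploid
#' call contributes two observed alleles; a pseudohaploid call contributes
#' two copies of its single sampled allele; missing calls contribute none.
#'
#' @param geno a [geno_matrix()].
#' @param ind matching [ind_table()].
#' @param populations populations to tabulate (default: all labels in `ind`).
#' @return An object of class `pop_freq`: matrices `alt`, `obs` and `freq`
#'   (populations x SNPs); `freq` is `NaN` where no alleles were observed.
#' @export
allele_frequencies <- function(geno, ind, populations = NULL) {
  stopifnot(nrow(geno$values) == nrow(ind))
  populations <- populations %||% unique(ind$population)
  missing_pops <- setdiff(populations, ind$population)
  if (length(missing_pops))
    stop("empty population(s): ", paste(missing_pops, collapse = ", "))
  nsnp <- ncol(geno$values)
  alt <- obs <- matrix(0, length(populations), nsnp,
                       dimnames = list(populations, colnames(geno$values)))
  for (i in seq_along(populations)) {
    rows <- geno$values[ind$population == populations[i], , drop = FALSE]
    alt[i, ] <- colSums(rows, na.rm = TRUE)
    obs[i, ] <- 2 * colSums(!is.na(rows))
  }
  structure(list(alt = alt, obs = obs, freq = alt / obs,
                 populations = populations),
            class = "pop_freq")
}

# pop_freq built from known truth frequencies (simulation sources).
pop_freq_from_truth <- function(freq) {
  structure(list(alt = NULL, obs = matrix(Inf, nrow(freq), ncol(freq),
                                          dimnames = dimnames(freq)),
                 freq = freq, populations = rownames(freq)),
            class = "pop_freq")
}

#' @export
print.pop_freq <- function(x, ...) {
  cat(sprintf("<pop_freq> %d populations x %d SNPs\n",
              nrow(x$freq), ncol(x$freq)))
  invisible(x)
}

#' Partition SNPs into contiguous jackknife blocks
#'
#' Greedy left-to-right blocking: a new block starts whenever the
#' accumulated genetic span exceeds `span_cm` or the chromosome changes.
#' Blocks are the resampling unit for all block-jackknife standard errors.
#'
#' @param snp a [snp_table()] sorted by (chromosome, physical position).
#' @param span_cm nominal block span in centimorgans.
#' @return A `data.frame` of class `block_partition` with 0-based half-open
#'   column ranges `start`, `end` and the `chromosome` of each block.
#' @export
make_blocks <- function(snp, span_cm = 5) {
  if (span_cm <= 0) stop("span_cm must be positive")
  n <- nrow(snp)
  gpos_cm <- snp$genetic_pos * 100
  starts <- integer(0)
  block_start <- 1L
  anchor <- gpos_cm[1]
  for (i in seq_len(n)) {
    new_chrom <- i > 1 && snp$chromosome[i] != snp$chromosome[i - 1]
    if (new_chrom || gpos_cm[i] - anchor >= span_cm - 1e-9) {
      starts <- c(starts, block_start)
      block_start <- i
      anchor <- gpos_cm[i]
    }
  }
  starts <- c(starts, block_start)
  ends <- c(starts[-1] - 1L, n)
  df <- data.frame(chromosome = snp$chromosome[starts],
                   start = starts - 1L, end = ends)
  attr(df, "span_cm") <- span_cm
  class(df) <- c("block_partition", "data.frame")
  df
}

# Per-SNP block index (1-based) from a block partition.
block_index <- function(blocks, nsnp) {
  idx <- integer(nsnp)
  for (b in seq_len(nrow(blocks)))
    idx[(blocks$start[b] + 1):blocks$end[b]] <- b
  idx
}
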