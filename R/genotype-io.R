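#' Genotype matrix constructor
#'
#' Haploid-coded biallelic genotypes for inbred accessions: calls are 0
#' (allele 1), 1 (allele 2) or `NA` (missing), stored as an accession x locus
#' integer matrix with unique dimnames.
#'
#' @param calls matrix of 0/1/NA, accessions in rows, loci in columns.
#' @return the validated matrix with class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls) {
  m <- as.matrix(calls)
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L, NA_integer_))) stop("calls must be 0, 1 or NA")
  if (nrow(m) > 0 && (is.null(rownames(m)) || anyDuplicated(rownames(m)))) {
    stop("accession ids must be present and unique")
  }
  if (ncol(m) > 0 && (is.null(colnames(m)) || anyDuplicated(colnames(m)))) {
    stop("locus ids must be present and unique")
  }
  class(m) <- unique(c("genotype_matrix", oldClass(m)))
  m
}

#' Read a two-line allele-counts snpsfile
#'
#' Each SNP occupies two consecutive tab-separated lines: counts of allele 1
#' per accession column on the first line, counts of allele 2 on the second.
#' With one haploid individual per column, counts are 0 or 1 and a 0/0 column
#' means missing.
#'
#' @param path file path.
#' @param accession_ids optional accession names (columns).
#' @param locus_ids optional locus names (line pairs).
#' @return a [genotype_matrix()] (accessions x loci).
#' @export
read_snpsfile <- function(path, accession_ids = NULL, locus_ids = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 2 != 0) stop("snpsfile has an odd number of lines")
  n_loci <- length(lines) %/% 2
  parse_line <- function(x) as.integer(strsplit(x, "\t", fixed = TRUE)[[1]])
  calls <- matrix(NA_integer_, nrow = 0, ncol = n_loci)
  first <- parse_line(lines[1])
  n_acc <- length(first)
  calls <- matrix(NA_integer_, nrow = n_acc, ncol = n_loci)
  for (l in seq_len(n_loci)) {
    a1 <- parse_line(lines[2 * l - 1])
    a2 <- parse_line(lines[2 * l])
    if (length(a1) != n_acc || length(a2) != n_acc) {
      stop("column count mismatch at SNP ", l)
    }
    tot <- a1 + a2
    if (any(tot > 1, na.rm = TRUE)) stop("counts exceed haploid sample size at SNP ", l)
    call <- ifelse(tot == 0, NA_integer_, ifelse(a2 == 1L, 1L, 0L))
    calls[, l] <- call
  }
  rownames(calls) <- accession_ids %||% sprintf("acc%03d", seq_len(n_acc))
  colnames(calls) <- locus_ids %||% sprintf("snp%05d", seq_len(n_loci))
  genotype_matrix(calls)
}

#' Write a genotype matrix as a two-line allele-counts snpsfile
#'
#' Inverse of [read_snpsfile()]: allele-1 counts on the first line of each
#' SNP pair, allele-2 counts on the second, tab-separated; missing calls
#' written as 0/0. `write_snpsfile(read_snpsfile(f), f2)` reproduces
#' canonical files byte for byte.
#'
#' @param G a [genotype_matrix()].
#' @param path output path.
#' @export
write_snpsfile <- function(G, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (l in seq_len(ncol(G))) {
    call <- G[, l]
    a2 <- ifelse(is.na(call), 0L, call)
    a1 <- ifelse(is.na(call), 0L, 1L - call)
    writeLines(c(paste(a1, collapse = "\t"), paste(a2, collapse = "\t")),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read/write genotype calls as TSV
#'
#' Plain accession x locus table of `{0, 1, NA}` calls with accession ids in
#' the first column and locus ids as header.
#'
#' @param path file path.
#' @return a [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  genotype_matrix(as.matrix(df))
}

#' @rdname read_genotype_tsv
#' @param G a [genotype_matrix()].
#' @export
write_genotype_tsv <- function(G, path) {
  df <- data.frame(accession = rownames(G), as.data.frame(unclass(G)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Marker map constructor and I/O
#'
#' A marker map records, per locus: chromosome, genetic position (cM),
#' physical position (bp) and the cumulative genetic position `ccM` across
#' the concatenated genome (chromosomes laid end to end in sorted order).
#'
#' @param id,chrom,cM,bp parallel vectors describing the loci.
#' @return data frame sorted by chromosome and cM, with a strictly handled
#'   `ccM` column.
#' @export
marker_map <- function(id, chrom, cM, bp) {
  chrom <- rep_len(chrom, length(id))
  stopifnot(length(id) == length(cM), length(id) == length(bp),
            all(cM >= 0))
  df <- data.frame(id = as.character(id), chrom = as.character(chrom),
                   cM = as.numeric(cM), bp = as.numeric(bp))
  if (anyDuplicated(df$id)) stop("locus ids must be unique")
  df <- df[order(df$chrom, df$cM, df$bp), ]
  chrom_levels <- sort(unique(df$chrom))
  off <- c(0, head(cumsum(vapply(chrom_levels, function(ch)
    max(df$cM[df$chrom == ch]), numeric(1))), -1))
  names(off) <- chrom_levels
  df$ccM <- df$cM + off[df$chrom]
  rownames(df) <- NULL
  df
}

#' @rdname marker_map
#' @param path file path.
#' @export
read_marker_map <- function(path) {
  df <- utils::read.delim(path)
  marker_map(df$id, df$chrom, df$cM, df$bp)
}

#' @rdname marker_map
#' @param map a marker map data frame.
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(map[, c("id", "chrom", "cM", "bp")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Q matrix (group membership probabilities) constructor and I/O
#'
#' @param q accession x cluster matrix of membership probabilities; rows must
#'   sum to 1 within 1e-6.
#' @return validated numeric matrix.
#' @export
q_matrix <- function(q) {
  m <- as.matrix(q)
  storage.mode(m) <- "double"
  if (any(m < 0) || any(m > 1)) stop("memberships must lie in [0, 1]")
  if (any(abs(rowSums(m) - 1) > 1e-6)) stop("Q rows must sum to 1")
  m
}

#' @rdname q_matrix
#' @param path file path.
#' @export
read_q_tsv <- function(path) {
  df <- utils::read.delim(path, row.names = 1)
  q_matrix(as.matrix(df))
}

#' @rdname q_matrix
#' @export
write_q_tsv <- function(q, path) {
  df <- data.frame(accession = rownames(q), as.data.frame(q),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
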