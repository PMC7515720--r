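#' A-site offset table for yeast ribosome footprints
#'
#' Offsets (nt from the fragment 5' end to the first nt of the A-site
#' codon) by fragment length (27..33 nt) and reading frame (the 5'-end
#' position modulo 3 in 0-based CDS coordinates).  Cells where the A-site
#' cannot be assigned unambiguously are `NA` and such reads are discarded.
#'
#' @return A data.frame with columns `length`, `frame`, `offset`.
#' @export
asite_offset_table <- function() {
  data.frame(
    length = rep(27:33, each = 3L),
    frame  = rep(0:2, times = 7L),
    offset = c(15, 15, 18,   # 27
               15, 15, 18,   # 28
               15, NA, 18,   # 29
               15, 18, 18,   # 30
               15, 18, 18,   # 31
               NA, 18, 18,   # 32
               18, 18, 18))  # 33
}

#' Map footprint records to A-site codon positions
#'
#' Pure lookup of the offset by `(length, frame)` followed by
#' `codon = floor((pos5 + offset)/3) + 1`, with `pos5` the 0-based
#' nucleotide position of the fragment 5' end in CDS coordinates.  When
#' `frame` is missing it is computed as `pos5 %% 3`.
#'
#' @param pos5 integer vector of 0-based 5'-end positions.
#' @param length integer vector of fragment lengths in nt.
#' @param frame optional integer vector of frames (0/1/2).
#' @return Integer vector of A-site codons, `NA` for discarded reads, with
#'   attribute `discard_reason` (`"length"`, `"ambiguous"`, or `NA` for
#'   mapped reads).
#' @export
map_asite <- function(pos5, length, frame = NULL) {
  if (is.null(frame)) frame <- pos5 %% 3L
  stopifnot(all(frame %in% 0:2), all(length > 0))
  tab <- asite_offset_table()
  key <- match(paste(length, frame), paste(tab$length, tab$frame))
  offset <- tab$offset[key]
  reason <- rep(NA_character_, length(pos5))
  reason[is.na(key)] <- "length"
  reason[!is.na(key) & is.na(offset)] <- "ambiguous"
  codon <- ifelse(is.na(reason), (pos5 + offset) %/% 3L + 1L, NA_integer_)
  structure(as.integer(codon), discard_reason = reason)
}

#' Raw per-codon A-site count profile
#'
#' @param gene_id character scalar.
#' @param counts non-negative integer counts for codons `2..L`.
#' @return An object of class `raw_profile` with fields `counts`, `total`
#'   and `L`.
#' @export
raw_profile <- function(gene_id, counts) {
  counts <- as.numeric(counts)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(list(gene_id = gene_id, counts = counts,
                 total = sum(counts), L = length(counts) + 1L),
            class = "raw_profile")
}

#' Aggregate footprint records into per-gene count profiles
#'
#' Maps each record to its A-site codon via [map_asite()] and histograms the
#' codons per gene.  Reads that cannot be mapped (unsupported length,
#' ambiguous cell, A-site outside codons `2..L`) are discarded and counted
#' by reason.
#'
#' @param records data.frame with columns `gene_id`, `pos5`, `length` (and
#'   optionally `frame`).
#' @param gene_lengths named integer vector: codon count `L` per gene.
#' @return A list with `profiles` (list of [raw_profile()] per gene) and
#'   `discards` (named counts by reason).
#' @export
aggregate_counts <- function(records, gene_lengths) {
  stopifnot(all(c("gene_id", "pos5", "length") %in% names(records)))
  frame <- if ("frame" %in% names(records)) records$frame else NULL
  codon <- map_asite(records$pos5, records$length, frame)
  reason <- attr(codon, "discard_reason")
  discards <- c(length = sum(reason == "length", na.rm = TRUE),
                ambiguous = sum(reason == "ambiguous", na.rm = TRUE),
                out_of_range = 0L, start_codon = 0L)
  profiles <- list()
  for (g in names(gene_lengths)) {
    L <- gene_lengths[[g]]
    sel <- records$gene_id == g & !is.na(codon)
    cg <- codon[sel]
    discards[["start_codon"]] <- discards[["start_codon"]] + sum(cg == 1L)
    discards[["out_of_range"]] <-
      discards[["out_of_range"]] + sum(cg < 1L | cg > L)
    cg <- cg[cg >= 2L & cg <= L]
    profiles[[g]] <- raw_profile(g, tabulate(cg - 1L, nbins = L - 1L))
  }
  list(profiles = profiles, discards = discards)
}

#' Normalized experimental density profile
#'
#' @param gene_id character scalar.
#' @param r densities (ribosomes/codon) for codons `2..L`, each in `[0, 1]`.
#' @return An object of class `normalized_profile` with `r_mean` and the
#'   ribosome count `N = r_mean * (L - 1)`.
#' @export
normalized_profile <- function(gene_id, r) {
  r <- as.numeric(r)
  stopifnot(all(r >= 0))
  if (any(r > 1)) .gene_rejected(gene_id, "density>1")
  structure(list(gene_id = gene_id, r = r, L = length(r) + 1L,
                 r_mean = mean(r), N = sum(r)),
            class = "normalized_profile")
}

.gene_rejected <- function(gene_id, reason) {
  stop(structure(class = c("gene_rejected", "error", "condition"),
                 list(message = sprintf("gene %s rejected: %s",
                                        gene_id, reason),
                      call = sys.call(-1), gene_id = gene_id,
                      reason = reason)))
}

#' Normalize a raw count profile to absolute densities
#'
#' Read fractions are put on the absolute ribosome/codon scale set by the
#' gene's mean ribosome density (e.g. from polysome profiling):
#' `r[i] = counts[i]/total * N` with `N = mean_density * (L - 1)`, so the
#' mean of the resulting profile equals the supplied density.  A gene whose
#' profile would exceed one ribosome per codon anywhere is rejected, as is
#' a gene without reads (condition class `gene_rejected`).
#'
#' @param raw a [raw_profile()].
#' @param mean_density absolute mean ribosome density for the gene
#'   (ribosomes/codon), positive.
#' @return A [normalized_profile()].
#' @export
normalize_profile <- function(raw, mean_density) {
  stopifnot(inherits(raw, "raw_profile"), mean_density > 0)
  if (raw$total == 0) .gene_rejected(raw$gene_id, "no reads")
  N <- mean_density * (raw$L - 1L)
  r <- raw$counts / raw$total * N
  if (any(r > 1)) .gene_rejected(raw$gene_id, "density>1")
  normalized_profile(raw$gene_id, r)
}

#' Coverage filter for count profiles
#'
#' A gene passes when its mean reads per codon, `total/(L-1)`, reaches the
#' threshold (boundary inclusive).  Codons with zero counts are reported:
#' inside passing genes they imply unbounded apparent elongation speed and
#' are handled specially by the inference step.
#'
#' @param raw a [raw_profile()].
#' @param min_mean_reads threshold on mean reads per codon (default 10).
#' @return A list with `pass` (logical), `reason` (`NA` when passing),
#'   `mean_reads`, and `zero_codons` (codon indices with zero counts).
#' @export
filter_gene <- function(raw, min_mean_reads = 10) {
  stopifnot(inherits(raw, "raw_profile"))
  mean_reads <- raw$total / (raw$L - 1L)
  zero_codons <- which(raw$counts == 0) + 1L
  if (raw$total == 0)
    list(pass = FALSE, reason = "no reads", mean_reads = 0,
         zero_codons = zero_codons)
  else if (mean_reads < min_mean_reads)
    list(pass = FALSE, reason = "low coverage", mean_reads = mean_reads,
         zero_codons = zero_codons)
  else
    list(pass = TRUE, reason = NA_character_, mean_reads = mean_reads,
         zero_codons = zero_codons)
}

#' Read per-codon count profiles from TSV
#'
#' Expects columns `gene_id`, `codon`, `count`, codons `2..L` per gene.
#'
#' @param path TSV file path.
#' @return Named list of [raw_profile()] objects.
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "codon", "count") %in% names(df)))
  out <- lapply(split(df, df$gene_id), function(d) {
    d <- d[order(d$codon), ]
    if (!identical(as.integer(d$codon), seq(2L, max(d$codon))))
      stop("counts for gene ", d$gene_id[1],
           " must cover codons 2..L contiguously")
    raw_profile(d$gene_id[1], d$count)
  })
  out[unique(df$gene_id)]
}

#' Read a per-gene mean ribosome density table from TSV
#'
#' Expects columns `gene_id` and `density` (ribosomes/codon).
#'
#' @param path TSV file path.
#' @return Named numeric vector of densities.
#' @export
read_density_table_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "density") %in% names(df)))
  setNames(df$density, df$gene_id)
}

#' Write normalized profiles to TSV
#'
#' @param profiles list of [normalized_profile()] objects.
#' @param path output file path.
#' @export
write_normalized_tsv <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(gene_id = p$gene_id, codon = seq(2L, p$L), r = p$r)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read normalized profiles from TSV
#'
#' @param path TSV with columns `gene_id`, `codon`, `r`.
#' @return Named list of [normalized_profile()] objects.
#' @export
read_normalized_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "codon", "r") %in% names(df)))
  out <- lapply(split(df, df$gene_id), function(d) {
    d <- d[order(d$codon), ]
    normalized_profile(d$gene_id[1], d$r)
  })
  out[unique(df$gene_id)]
}
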