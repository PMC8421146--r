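#' Define a Cas9 guide target
#'
#' A guide is a 20-nt protospacer anchored to a genome coordinate, together
#' with the PAM pattern its nuclease recognises (NGG for SpCas9, NGN for
#' Cas9-NG/SpG, NNN for the near PAM-less SpRY). The blunt cut falls between
#' protospacer positions 17 and 18, i.e. 3 bp 5' of the PAM.
#'
#' @param protospacer 20-nt ACGT string in guide orientation.
#' @param pam_pattern 3-character IUPAC pattern over A/C/G/T/N/R/Y.
#' @param chrom chromosome name the on-target site lives on.
#' @param protospacer_start 0-based genome coordinate of the 23-nt site's
#'   leftmost base (protospacer end for "+" sites, PAM end for "-" sites).
#' @param strand "+" or "-".
#' @return object of class \code{guide_target} with a derived
#'   \code{cut_position} (0-based coordinate of the base immediately 3' of
#'   the blunt cut on the reference strand).
#' @export
guide_target <- function(protospacer, pam_pattern = "NGG", chrom = "chr1",
                         protospacer_start = 0L, strand = "+") {
  protospacer <- .check_dna(protospacer, "protospacer")
  if (nchar(protospacer) != 20L)
    stop("protospacer must be exactly 20 nt", call. = FALSE)
  if (nchar(pam_pattern) != 3L)
    stop("pam_pattern must have length 3", call. = FALSE)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  start <- as.integer(protospacer_start)
  # blunt cut 3 bp from the PAM: boundary after protospacer position 17
  cut <- if (strand == "+") start + 17L else start + 6L
  structure(list(protospacer = protospacer, pam_pattern = toupper(pam_pattern),
                 chrom = chrom, protospacer_start = start, strand = strand,
                 cut_position = cut),
            class = "guide_target")
}

#' @export
print.guide_target <- function(x, ...) {
  cat("guide_target:", x$protospacer, "| PAM", x$pam_pattern, "|",
      x$chrom, x$protospacer_start, x$strand, "| cut", x$cut_position, "\n")
  invisible(x)
}

#' Count protospacer mismatches (Hamming distance)
#'
#' Pure positionwise mismatch count between two equal-length ACGT strings.
#' Bulges/gaps are deliberately not modelled: candidate off-target sites are
#' defined by Hamming distance over the 20-nt protospacer only.
#'
#' @param a,b equal-length ACGT strings.
#' @return integer number of differing positions.
#' @export
count_mismatches <- function(a, b) {
  a <- .check_dna(a); b <- .check_dna(b)
  if (nchar(a) != nchar(b)) stop("sequences must have equal length", call. = FALSE)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# cut position of a candidate 23-nt window [start, start+23), 0-based
candidate_cut_position <- function(start, strand) {
  ifelse(strand == "+", start + 17L, start + 6L)
}

#' Enumerate guide-homologous candidate sites genome-wide
#'
#' Scans every 23-nt window on both strands of a genome and returns those
#' whose 20-nt protospacer portion is within \code{max_mismatches} Hamming
#' distance of the guide and whose 3-nt PAM matches \code{pam_pattern}
#' (NNN matches everything). This is the candidate universe used both for
#' junction-based hotspot calling and for CNN ranking.
#'
#' @param genome a \code{Biostrings::DNAStringSet} or path to a FASTA file.
#' @param guide a \code{\link{guide_target}}.
#' @param max_mismatches maximum protospacer mismatches (default 7: sites
#'   with "less than eight" mismatches).
#' @param pam_pattern IUPAC PAM filter; defaults to the guide's own pattern.
#' @return \code{data.table} with columns chrom, start, end (0-based
#'   half-open, width 23), strand, sequence_23 (guide orientation),
#'   mismatch_count, pam; sorted by (chrom, start, strand).
#' @export
enumerate_candidates <- function(genome, guide, max_mismatches = 7L,
                                 pam_pattern = guide$pam_pattern) {
  stopifnot(inherits(guide, "guide_target"), max_mismatches >= 0)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  proto <- Biostrings::DNAString(guide$protospacer)
  proto_rc <- Biostrings::reverseComplement(proto)
  out <- vector("list", 2L * length(genome))
  k <- 0L
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci]
    seqc <- genome[[ci]]
    len <- length(seqc)
    if (len < 23L) {
      warning("contig '", chrom, "' shorter than 23 nt; skipped", call. = FALSE)
      next
    }
    # plus strand: protospacer at p (1-based), PAM at [p+20, p+22]
    mp <- Biostrings::matchPattern(proto, seqc, max.mismatch = max_mismatches)
    p <- BiocGenerics::start(mp)
    p <- p[p + 22L <= len]
    if (length(p)) {
      win <- as.character(Biostrings::extractAt(
        seqc, IRanges::IRanges(start = p, width = 23L)))
      pam <- substr(win, 21L, 23L)
      keep <- pam_matches(pam, pam_pattern)
      if (any(keep)) {
        mm <- Biostrings::neditStartingAt(proto, seqc, starting.at = p[keep])
        k <- k + 1L
        out[[k]] <- data.table(chrom = chrom, start = p[keep] - 1L,
                               strand = "+", sequence_23 = win[keep],
                               mismatch_count = as.integer(mm),
                               pam = pam[keep])
      }
    }
    # minus strand: revcomp(protospacer) at q; window starts at q-3
    mm2 <- Biostrings::matchPattern(proto_rc, seqc, max.mismatch = max_mismatches)
    q <- BiocGenerics::start(mm2)
    q <- q[q >= 4L & q + 19L <= len]
    if (length(q)) {
      win <- as.character(Biostrings::extractAt(
        seqc, IRanges::IRanges(start = q - 3L, width = 23L)))
      win <- revcomp(win)
      pam <- substr(win, 21L, 23L)
      keep <- pam_matches(pam, pam_pattern)
      if (any(keep)) {
        nm <- Biostrings::neditStartingAt(proto_rc, seqc, starting.at = q[keep])
        k <- k + 1L
        out[[k]] <- data.table(chrom = chrom, start = q[keep] - 4L,
                               strand = "-", sequence_23 = win[keep],
                               mismatch_count = as.integer(nm),
                               pam = pam[keep])
      }
    }
  }
  res <- if (k == 0L) {
    data.table(chrom = character(), start = integer(), strand = character(),
               sequence_23 = character(), mismatch_count = integer(),
               pam = character())
  } else rbindlist(out[seq_len(k)])
  res[, end := start + 23L]
  res[, cut_position := candidate_cut_position(start, strand)]
  setcolorder(res, c("chrom", "start", "end", "strand", "sequence_23",
                     "mismatch_count", "pam", "cut_position"))
  setorder(res, chrom, start, strand)
  res[]
}

#' Classify a PAM by its second and third nucleotides
#'
#' The NRN/NYN split follows the purine/pyrimidine identity of the PAM's
#' second nucleotide (R = A/G, Y = C/T), the axis along which the near
#' PAM-less SpRY retains a moderate preference.
#'
#' @param pam character vector of 3-nt ACGT strings.
#' @return \code{data.table} with columns pam, second_nt, third_nt,
#'   category ("NRN" or "NYN").
#' @export
classify_pam <- function(pam) {
  pam <- .check_dna(pam, "pam")
  if (any(nchar(pam) != 3L)) stop("pam must be 3 nt", call. = FALSE)
  second <- substr(pam, 2, 2)
  data.table(pam = pam, second_nt = second, third_nt = substr(pam, 3, 3),
             category = ifelse(second %in% c("A", "G"), "NRN", "NYN"))
}

#' Write candidates as BED6+ TSV
#'
#' Columns: chrom, start, end, name = sequence_23, score = mismatch_count,
#' strand, pam (0-based half-open coordinates).
#' @param candidates table from \code{\link{enumerate_candidates}}.
#' @param path output file.
#' @export
write_candidates <- function(candidates, path) {
  bed <- candidates[, .(chrom, start, end, name = sequence_23,
                        score = mismatch_count, strand, pam)]
  fwrite(bed, path, sep = "\t")
  invisible(path)
}

#' Read a candidates/off-target BED6+ TSV back into a candidate table
#' @param path file written by \code{\link{write_candidates}} or
#'   \code{\link{write_offtargets}}.
#' @export
read_candidates <- function(path) {
  x <- fread(path, sep = "\t")
  setnames(x, old = c("name", "score"),
           new = c("sequence_23", "mismatch_count"), skip_absent = TRUE)
  if (!"cut_position" %in% names(x))
    x[, cut_position := candidate_cut_position(start, strand)]
  x[]
}
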