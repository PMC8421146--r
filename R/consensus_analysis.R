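#' Position frequency matrix over 23-nt sites
#'
#' Columnwise base frequencies over the 20 protospacer + 3 PAM positions of
#' a set of sites in guide orientation -- the numeric object behind a
#' consensus sequence logo.
#'
#' @param sites candidate/off-target table with a \code{sequence_23} column,
#'   or a character vector of 23-nt strings.
#' @return matrix 23 x 4 (columns A, C, G, T), rows summing to 1, with
#'   attribute \code{site_count}.
#' @export
build_pfm <- function(sites) {
  seqs <- if (is.character(sites)) sites else sites$sequence_23
  if (length(seqs) == 0L) stop("no sites given", call. = FALSE)
  seqs <- .check_dna(seqs)
  if (any(nchar(seqs) != 23L)) stop("sites must be 23 nt", call. = FALSE)
  cons <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs),
                                      baseOnly = TRUE)
  counts <- t(cons[c("A", "C", "G", "T"), , drop = FALSE])
  pfm <- counts / length(seqs)
  rownames(pfm) <- c(paste0("proto", 1:20), paste0("pam", 1:3))
  attr(pfm, "site_count") <- length(seqs)
  pfm
}

#' PAM position statistics and the NRN/NYN split
#'
#' Tallies the second and third PAM nucleotides of a site set and counts
#' sites whose PAM is NRN (second nt purine) versus NYN (pyrimidine).
#'
#' @param sites table with a \code{pam} column, or character vector of PAMs.
#' @return list(second_nt, third_nt: named counts over A/C/G/T;
#'   nrn, nyn, site_count).
#' @export
pam_position_stats <- function(sites) {
  pams <- if (is.character(sites)) sites else sites$pam
  cls <- classify_pam(pams)
  tally <- function(x) {
    t <- table(factor(x, levels = c("A", "C", "G", "T")))
    setNames(as.integer(t), names(t))
  }
  list(second_nt = tally(cls$second_nt), third_nt = tally(cls$third_nt),
       nrn = sum(cls$category == "NRN"), nyn = sum(cls$category == "NYN"),
       site_count = nrow(cls))
}

#' Mismatch-number distribution of an off-target set
#'
#' @param sites table with a \code{mismatch_count} column.
#' @param max_mm histogram upper bound (default 7; sites are defined with
#'   fewer than eight protospacer mismatches).
#' @return named integer vector of counts over 0..max_mm.
#' @export
mismatch_distribution <- function(sites, max_mm = 7L) {
  mm <- if (is.numeric(sites)) sites else sites$mismatch_count
  t <- table(factor(mm, levels = 0:max_mm))
  setNames(as.integer(t), names(t))
}

#' Cross-variant off-target overlap (Venn cells)
#'
#' Two sites from different variants are the same locus iff they lie on the
#' same chromosome and strand with cut positions within \code{match_radius}
#' bp. Site equivalence classes are the connected components of that match
#' relation; each class is assigned the set of variants contributing to it,
#' giving exclusive Venn cell counts that sum to the union size.
#'
#' @param site_lists named list (variant -> site table with chrom, strand,
#'   cut_position or start columns).
#' @param match_radius matching half-width in bp.
#' @return list(cells = named counts keyed by "+"-joined variant subsets,
#'   union_size).
#' @export
overlap_sets <- function(site_lists, match_radius = 100L) {
  if (length(site_lists) < 2L) stop("need at least two variants", call. = FALSE)
  all <- rbindlist(lapply(names(site_lists), function(v) {
    s <- as.data.table(site_lists[[v]])
    if (!"cut_position" %in% names(s))
      s[, cut_position := candidate_cut_position(start, strand)]
    s[, .(variant = v, chrom, strand, cut_position)]
  }))
  n <- nrow(all)
  if (n == 0L) return(list(cells = integer(), union_size = 0L))
  # union-find over the pairwise match relation
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  setorder(all, chrom, strand, cut_position)
  for (i in seq_len(n - 1L)) {
    j <- i + 1L
    while (j <= n && all$chrom[j] == all$chrom[i] &&
           all$strand[j] == all$strand[i] &&
           all$cut_position[j] - all$cut_position[i] <= match_radius) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
      j <- j + 1L
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  members <- split(all$variant, comp)
  keys <- vapply(members, function(v)
    paste(sort(unique(v)), collapse = "+"), character(1))
  cells <- table(keys)
  list(cells = setNames(as.integer(cells), names(cells)),
       union_size = length(members))
}

#' Paired Wilcoxon signed-rank comparison of two variant metrics
#'
#' Two-sided Wilcoxon matched-pairs signed-rank test on per-locus paired
#' values; zero differences are dropped; the exact null distribution is used
#' for n <= 25 informative pairs (normal approximation with continuity
#' correction beyond). P < 0.05 is reported as significant. When every
#' difference is zero the test is undefined and reported non-significant
#' with \code{degenerate = TRUE}.
#'
#' @param metric_a,metric_b equal-length paired numeric vectors
#'   (one value per locus).
#' @return list(statistic, p_value, significant, n_pairs, degenerate).
#' @export
paired_compare <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b))
    stop("paired vectors must have equal length", call. = FALSE)
  if (length(metric_a) < 5L)
    stop("need at least 5 pairs", call. = FALSE)
  d <- metric_a - metric_b
  nz <- d[d != 0]
  if (length(nz) == 0L)
    return(list(statistic = NA_real_, p_value = NA_real_,
                significant = FALSE, n_pairs = 0L, degenerate = TRUE))
  exact <- length(nz) <= 25L && !anyDuplicated(abs(nz))
  wt <- suppressWarnings(
    stats::wilcox.test(metric_a, metric_b, paired = TRUE,
                       alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       significant = wt$p.value < 0.05, n_pairs = length(nz),
       degenerate = FALSE)
}

#' Write a PFM as TSV (23 rows x A/C/G/T columns)
#' @param pfm matrix from \code{\link{build_pfm}}.
#' @param path output file.
#' @export
write_pfm <- function(pfm, path) {
  dt <- data.table(position = rownames(pfm), as.data.table(pfm))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
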