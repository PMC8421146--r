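#' Remove junctions proximal to the on-target break site
#'
#' Junctions within +/- \code{radius} (default 20 kb) of the cut on the
#' bait chromosome are dominated by indels and resection-driven deletions
#' and are excluded before enrichment-based hotspot discovery. Records
#' without a junction (uncut alleles) are dropped as well.
#'
#' @param junctions junction table (see \code{\link{read_junctions}}).
#' @param guide a \code{\link{guide_target}}.
#' @param radius exclusion half-width in bp.
#' @return filtered junction table (possibly empty).
#' @export
exclude_proximal <- function(junctions, guide, radius = 20000L) {
  stopifnot(inherits(guide, "guide_target"))
  j <- as.data.table(junctions)
  j <- j[junction_present == 1L & !is.na(prey_pos)]
  j[prey_ref != guide$chrom |
      abs(prey_pos - guide$cut_position) > radius]
}

#' Find junction-enriched regions by gap clustering
#'
#' Deterministic stand-in for a peak caller: prey positions on each
#' reference are single-linkage clustered at gap <= \code{window}; clusters
#' with at least \code{min_junctions} members become regions. The summit is
#' the modal prey position (leftmost on ties).
#'
#' @param junctions table already filtered by \code{\link{exclude_proximal}}.
#' @param window maximum gap between neighbouring junctions in one
#'   region (bp).
#' @param min_junctions minimum junctions per emitted region.
#' @return \code{data.table} with columns chrom, start, end (0-based
#'   half-open), junction_count, summit, and a list column
#'   \code{positions} holding the member prey positions.
#' @export
find_enriched_regions <- function(junctions, window = 100L,
                                  min_junctions = 2L) {
  j <- as.data.table(junctions)
  if (nrow(j) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), junction_count = integer(),
                      summit = integer(), positions = list()))
  j <- j[junction_present == 1L & !is.na(prey_pos)]
  setorder(j, prey_ref, prey_pos)
  j[, cluster := cumsum(c(1L, diff(prey_pos) > window)), by = prey_ref]
  regions <- j[, {
    tab <- table(prey_pos)
    modal <- as.integer(names(tab)[which.max(tab)])  # which.max: leftmost tie
    .(start = min(prey_pos), end = max(prey_pos) + 1L,
      junction_count = .N, summit = modal, positions = list(prey_pos))
  }, by = .(chrom = prey_ref, cluster)]
  regions <- regions[junction_count >= min_junctions]
  regions[, cluster := NULL]
  setorder(regions, chrom, start)
  regions[]
}

#' Call off-target hotspots
#'
#' A candidate site becomes an off-target call iff (a) more than
#' \code{min_junctions - 1} junctions (default rule: > 3, i.e. >= 4) fall
#' within +/- \code{cut_window} of its presumable cut position, (b) its
#' protospacer has fewer than \code{max_mismatches + 1} mismatches
#' (default rule: < 8), and (c) it is not the on-target site itself; calls
#' within +/-20 kb of the on-target cut on its chromosome are rejected by
#' construction (the input regions are built from proximal-excluded
#' junctions) and re-asserted here. Candidates sharing a region's junctions
#' are all reported and flagged \code{ambiguous}.
#'
#' @param regions output of \code{\link{find_enriched_regions}}.
#' @param candidates output of \code{\link{enumerate_candidates}} (run with
#'   \code{max_mismatches >= 7}).
#' @param guide a \code{\link{guide_target}}.
#' @param cut_window half-width (bp) of the "presumable cutting site"
#'   window around a candidate's cut position (default 25).
#' @param min_junctions minimum junction support (default 4, the "> 3" rule).
#' @param max_mismatches maximum allowed protospacer mismatches
#'   (default 7, the "< 8" rule).
#' @param proximal_radius on-target exclusion radius re-asserted on calls.
#' @return \code{data.table} of calls: candidate columns + junction_count,
#'   region_index, ambiguous; sorted by descending junction_count
#'   (ties by chrom, start).
#' @export
call_hotspots <- function(regions, candidates, guide, cut_window = 25L,
                          min_junctions = 4L, max_mismatches = 7L,
                          proximal_radius = 20000L) {
  stopifnot(inherits(guide, "guide_target"))
  cand <- as.data.table(candidates)
  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      strand = character(), sequence_23 = character(),
                      mismatch_count = integer(), pam = character(),
                      cut_position = integer(), junction_count = integer(),
                      region_index = integer(), ambiguous = logical())
  if (nrow(cand) == 0L || nrow(regions) == 0L) return(empty)
  if (!"cut_position" %in% names(cand))
    cand[, cut_position := candidate_cut_position(start, strand)]
  # drop the on-target site and over-mismatched candidates up front
  cand <- cand[mismatch_count <= max_mismatches]
  is_on <- cand$chrom == guide$chrom &
    cand$cut_position == guide$cut_position
  cand <- cand[!is_on]
  if (nrow(cand) == 0L) return(empty)
  calls <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ri <- which(regions$chrom == cand$chrom[i] &
                  regions$start <= cand$cut_position[i] + cut_window &
                  regions$end > cand$cut_position[i] - cut_window)
    if (!length(ri)) next
    pos <- unlist(regions$positions[ri])
    jc <- sum(abs(pos - cand$cut_position[i]) <= cut_window)
    if (jc >= min_junctions) {
      calls[[i]] <- cbind(cand[i], junction_count = jc,
                          region_index = ri[1])
    }
  }
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (!length(calls)) return(empty)
  out <- rbindlist(calls)
  # re-assert the proximal exclusion (type invariant)
  out <- out[chrom != guide$chrom |
               abs(cut_position - guide$cut_position) > proximal_radius]
  out[, ambiguous := .N > 1L, by = region_index]
  setorder(out, -junction_count, chrom, start)
  out[]
}

#' Write off-target calls as BED6+ TSV
#'
#' Columns: chrom, start, end, name = sequence_23, score = junction_count,
#' strand, mismatch_count, pam.
#' @param calls table from \code{\link{call_hotspots}}.
#' @param path output file.
#' @export
write_offtargets <- function(calls, path) {
  bed <- calls[, .(chrom, start, end, name = sequence_23,
                   score = junction_count, strand, mismatch_count, pam)]
  fwrite(bed, path, sep = "\t")
  invisible(path)
}

#' Read off-target calls written by \code{\link{write_offtargets}}
#' @param path BED6+ TSV path.
#' @export
read_offtargets <- function(path) {
  x <- fread(path, sep = "\t")
  setnames(x, old = c("name", "score"),
           new = c("sequence_23", "junction_count"), skip_absent = TRUE)
  x[, cut_position := candidate_cut_position(start, strand)]
  x[]
}
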