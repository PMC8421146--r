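OUTCOME_CLASSES <- c("uncut", "indel", "large_deletion",
                     "offtarget_translocation", "general_translocation",
                     "plasmid_insertion")

#' Classify junctions into editing-outcome classes
#'
#' Distance-based taxonomy of deduplicated editing events: no junction ->
#' uncut; prey on the plasmid -> plasmid_insertion; same chromosome within
#' \code{ld_threshold} (100 bp) of the cut -> indel; same chromosome between
#' \code{ld_threshold} and \code{proximal_radius} (20 kb) -> large_deletion
#' (resection-driven); within \code{ot_radius} (100 bp) of a called
#' off-target cut on any chromosome -> offtarget_translocation; everything
#' else -> general_translocation (fusion to a Cas9-independent break).
#' Classes are mutually exclusive and exhaustive.
#'
#' @param junctions junction table.
#' @param guide a \code{\link{guide_target}}.
#' @param offtargets off-target calls (\code{\link{call_hotspots}} output or
#'   \code{\link{read_offtargets}}); may be empty.
#' @param ld_threshold indel / large-deletion boundary in bp.
#' @param proximal_radius on-target proximal radius in bp.
#' @param ot_radius off-target cut-site radius in bp.
#' @param genome_names character vector of valid genome contig names; when
#'   provided, unknown prey references raise an error naming the contig.
#' @return input table with an appended \code{outcome} factor column.
#' @export
classify_junctions <- function(junctions, guide, offtargets = NULL,
                               ld_threshold = 100L, proximal_radius = 20000L,
                               ot_radius = 100L, genome_names = NULL) {
  stopifnot(inherits(guide, "guide_target"))
  j <- copy(as.data.table(junctions))
  if (!is.null(genome_names)) {
    bad <- setdiff(unique(j$prey_ref[j$junction_present == 1L]),
                   c(genome_names, "plasmid"))
    if (length(bad))
      stop("unknown prey reference(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  cut <- guide$cut_position
  near_ot <- rep(FALSE, nrow(j))
  if (!is.null(offtargets) && nrow(offtargets)) {
    ot <- as.data.table(offtargets)
    if (!"cut_position" %in% names(ot))
      ot[, cut_position := candidate_cut_position(start, strand)]
    for (i in seq_len(nrow(ot))) {
      near_ot <- near_ot | (j$prey_ref == ot$chrom[i] &
                              !is.na(j$prey_pos) &
                              abs(j$prey_pos - ot$cut_position[i]) <= ot_radius)
    }
  }
  same <- j$prey_ref == guide$chrom & !is.na(j$prey_pos)
  dist <- ifelse(same, abs(j$prey_pos - cut), NA_integer_)
  outcome <- rep("general_translocation", nrow(j))
  outcome[near_ot] <- "offtarget_translocation"
  outcome[same & dist <= proximal_radius] <- "large_deletion"
  outcome[same & dist <= ld_threshold] <- "indel"
  outcome[j$prey_ref == "plasmid"] <- "plasmid_insertion"
  outcome[j$junction_present == 0L] <- "uncut"
  j[, outcome := factor(outcome, levels = OUTCOME_CLASSES)]
  j[]
}

#' Summarise a classified junction table
#'
#' Editing efficiency is the total percentage of edited alleles (indels,
#' large deletions, translocations of both kinds and plasmid insertions)
#' among all captured events, uncut germline alleles included in the
#' denominator.
#'
#' @param classified output of \code{\link{classify_junctions}}.
#' @return object of class \code{editing_summary}: per-class counts,
#'   total_events, editing_efficiency and per-class rates (percent).
#' @export
summarize_outcomes <- function(classified) {
  cl <- as.data.table(classified)
  total <- nrow(cl)
  if (total == 0L) stop("cannot summarise an empty library", call. = FALSE)
  counts <- table(factor(cl$outcome, levels = OUTCOME_CLASSES))
  counts <- setNames(as.integer(counts), OUTCOME_CLASSES)
  stopifnot(sum(counts) == total)
  edited <- total - counts[["uncut"]]
  rates <- 100 * counts / total
  structure(list(
    counts = counts, total_events = total,
    editing_efficiency = 100 * edited / total,
    indel_rate = rates[["indel"]],
    large_deletion_rate = rates[["large_deletion"]],
    offtarget_translocation_rate = rates[["offtarget_translocation"]],
    general_translocation_rate = rates[["general_translocation"]],
    plasmid_insertion_rate = rates[["plasmid_insertion"]]),
    class = "editing_summary")
}

#' @export
print.editing_summary <- function(x, ...) {
  cat("editing summary:", x$total_events, "events, efficiency",
      sprintf("%.2f%%", x$editing_efficiency), "\n")
  for (cls in OUTCOME_CLASSES)
    cat(sprintf("  %-24s %8d (%6.2f%%)\n", cls, x$counts[[cls]],
                100 * x$counts[[cls]] / x$total_events))
  invisible(x)
}

#' Fold change of a metric between two libraries
#'
#' Used to express variant-vs-SpCas9 relative ratios of, e.g., translocation
#' or large-deletion rates.
#'
#' @param summary,reference \code{editing_summary} objects.
#' @param metric name of a numeric field (e.g.
#'   "general_translocation_rate", "large_deletion_rate").
#' @return ratio metric(summary) / metric(reference).
#' @export
fold_change <- function(summary, reference, metric) {
  if (!metric %in% names(summary) || !is.numeric(summary[[metric]]))
    stop("unknown metric: ", metric, call. = FALSE)
  ref <- reference[[metric]]
  if (!is.numeric(ref) || ref == 0)
    stop("reference metric '", metric, "' is zero", call. = FALSE)
  summary[[metric]] / ref
}

#' Plasmid-integration profile and per-100k rate
#'
#' Normalises plasmid junction counts to a per-100,000 rate -- denominator
#' either all editing events (edited alleles) or on-target indels, both
#' phrasings in use for this metric -- and bins plasmid junction positions
#' at \code{binsize} (default 100 bp) across the backbone.
#'
#' @param classified output of \code{\link{classify_junctions}}.
#' @param plasmid_length backbone length in bp.
#' @param denominator "editing_events" or "on_target_indels".
#' @param binsize bin width in bp.
#' @return list(per_100k, denominator_count, plasmid_junctions,
#'   profile = data.table(bin_start, bin_end, count)).
#' @export
plasmid_profile <- function(classified, plasmid_length,
                            denominator = c("editing_events", "on_target_indels"),
                            binsize = 100L) {
  denominator <- match.arg(denominator)
  cl <- as.data.table(classified)
  n_plasmid <- sum(cl$outcome == "plasmid_insertion")
  denom <- if (denominator == "editing_events") {
    sum(cl$outcome != "uncut")
  } else sum(cl$outcome == "indel")
  if (denom == 0L)
    stop("denominator count (", denominator, ") is zero", call. = FALSE)
  breaks <- seq(0L, plasmid_length + binsize - 1L, by = binsize)
  profile <- data.table(bin_start = head(breaks, -1L),
                        bin_end = pmin(breaks[-1L], plasmid_length))
  pos <- cl[outcome == "plasmid_insertion", prey_pos]
  profile[, count := 0L]
  if (length(pos)) {
    bi <- pos %/% binsize + 1L
    tab <- table(bi)
    profile[as.integer(names(tab)), count := as.integer(tab)]
  }
  list(per_100k = n_plasmid / denom * 1e5,
       denominator_count = denom, plasmid_junctions = n_plasmid,
       profile = profile[])
}
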