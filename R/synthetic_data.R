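#' Configuration for the synthetic PEM-seq-like world
#'
#' Describes a toy genome with planted guide-homologous sites and a junction
#' library drawn from known outcome proportions, so off-target calling,
#' outcome classification and the CNN ranker can all be tested against
#' ground truth without any deposited sequencing libraries.
#'
#' @param genome_length total genome size in bp, split equally across
#'   \code{chrom_count} contigs.
#' @param chrom_count number of contigs (named chr1..chrN).
#' @param protospacer the guide's 20-nt protospacer.
#' @param guide_pam literal 3-nt PAM planted at the on-target site.
#' @param pam_pattern the nuclease's PAM pattern (NGG, NGN, NNN, ...).
#' @param guide_chrom,guide_position 0-based placement of the on-target
#'   23-nt site (defaults to the middle of chr1).
#' @param planted_sites \code{data.frame} with columns mismatch_count
#'   (0-12), pam (3-nt literal), chrom, position (0-based site start) and
#'   optionally strand (default "+").
#' @param outcome_proportions named numeric over \{uncut, indel,
#'   large_deletion, offtarget_translocation, general_translocation,
#'   plasmid_insertion\}; must be non-negative and sum to 1.
#' @param n_events number of deduplicated editing events to simulate.
#' @param resection_length_distribution \code{c(min, max)} bp for
#'   large-deletion prey distances; min must exceed 100 bp (the indel /
#'   large-deletion boundary).
#' @param offtarget_jitter max |prey - planted cut| scatter in bp for
#'   off-target translocations (resection jitter stand-in; default 10).
#' @param plasmid_length plasmid backbone size in bp.
#' @param plasmid_u6_frac fraction of plasmid-insertion prey concentrated in
#'   the U6-sgRNA region (emulates PAM-flexible self-cleavage); remainder
#'   uniform over the backbone. Default 0 (even distribution).
#' @param seed integer RNG seed; the whole world is a pure function of it.
#' @return object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(genome_length = 300000L,
                             chrom_count = 3L,
                             protospacer = "GACCTGAGTCCGGGTCAGGA",
                             guide_pam = "AGG",
                             pam_pattern = "NGG",
                             guide_chrom = "chr1",
                             guide_position = NULL,
                             planted_sites = NULL,
                             outcome_proportions = c(
                               uncut = 0.70, indel = 0.15,
                               large_deletion = 0.04,
                               offtarget_translocation = 0.05,
                               general_translocation = 0.04,
                               plasmid_insertion = 0.02),
                             n_events = 10000L,
                             resection_length_distribution = c(150L, 15000L),
                             offtarget_jitter = 10L,
                             plasmid_length = 8000L,
                             plasmid_u6_frac = 0,
                             seed = 1L) {
  classes <- c("uncut", "indel", "large_deletion", "offtarget_translocation",
               "general_translocation", "plasmid_insertion")
  p <- outcome_proportions[classes]
  names(p) <- classes
  p[is.na(p)] <- 0
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("outcome_proportions must be non-negative and sum to 1", call. = FALSE)
  chrom_len <- as.integer(genome_length %/% chrom_count)
  if (is.null(guide_position)) guide_position <- as.integer(chrom_len %/% 2)
  if (is.null(planted_sites)) {
    planted_sites <- data.frame(mismatch_count = integer(), pam = character(),
                                chrom = character(), position = integer(),
                                strand = character())
  }
  planted_sites <- as.data.frame(planted_sites)
  if (nrow(planted_sites) && is.null(planted_sites$strand))
    planted_sites$strand <- "+"
  chroms <- paste0("chr", seq_len(chrom_count))
  if (nrow(planted_sites)) {
    bad <- planted_sites$position < 0 |
      planted_sites$position + 23L > chrom_len |
      !planted_sites$chrom %in% chroms
    if (any(bad))
      stop("planted sites must fit inside the genome with a 23-nt margin",
           call. = FALSE)
    if (any(planted_sites$mismatch_count < 0 | planted_sites$mismatch_count > 12))
      stop("planted mismatch_count must be between 0 and 12", call. = FALSE)
  }
  if (resection_length_distribution[1] <= 100L)
    stop("resection_length_distribution minimum must exceed 100 bp", call. = FALSE)
  structure(list(
    genome_length = as.integer(genome_length), chrom_count = as.integer(chrom_count),
    chrom_len = chrom_len, chroms = chroms,
    protospacer = .check_dna(protospacer), guide_pam = toupper(guide_pam),
    pam_pattern = toupper(pam_pattern), guide_chrom = guide_chrom,
    guide_position = as.integer(guide_position),
    planted_sites = planted_sites, outcome_proportions = p,
    n_events = as.integer(n_events),
    resection_length_distribution = as.integer(resection_length_distribution),
    offtarget_jitter = as.integer(offtarget_jitter),
    plasmid_length = as.integer(plasmid_length),
    plasmid_u6_frac = plasmid_u6_frac,
    seed = as.integer(seed)), class = "synthetic_config")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate `mm` protospacer positions of the on-target 20-mer, chosen uniformly
# without replacement; each chosen position is forced to a different base
.mutate_protospacer <- function(proto, mm) {
  s <- strsplit(proto, "")[[1]]
  if (mm > 0) {
    pos <- sample(20L, mm)
    for (i in pos) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1L)
  }
  paste(s, collapse = "")
}

#' Generate the synthetic reference world
#'
#' Builds an i.i.d. uniform-ACGT genome, plants the on-target site (0
#' mismatches, canonical PAM) and every requested homologous off-target site
#' (exact mismatch count, requested PAM), and builds a plasmid whose
#' U6-sgRNA cassette carries the protospacer (so PAM-flexible self-cleavage
#' of the delivery plasmid is simulatable).
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list with elements \code{genome} (DNAStringSet), \code{plasmid}
#'   (DNAStringSet, one contig named "plasmid"), \code{guide}
#'   (\code{\link{guide_target}}) and \code{truth} (planted-site table with
#'   sequences and cut positions, plus the plasmid U6 region).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  # collision check: all planted 23-nt intervals plus the on-target site
  sites <- rbind(
    data.frame(chrom = config$guide_chrom, position = config$guide_position,
               label = "on_target"),
    if (nrow(config$planted_sites))
      data.frame(chrom = config$planted_sites$chrom,
                 position = config$planted_sites$position,
                 label = paste0("planted_", seq_len(nrow(config$planted_sites))))
  )
  for (ch in unique(sites$chrom)) {
    s <- sites[sites$chrom == ch, ]
    s <- s[order(s$position), ]
    if (nrow(s) > 1) {
      ov <- which(diff(s$position) < 23L)
      if (length(ov))
        stop("planted sites overlap: ", s$label[ov[1]], " and ",
             s$label[ov[1] + 1L], " on ", ch, call. = FALSE)
    }
  }
  with_seed(config$seed, {
    chromseqs <- vapply(seq_len(config$chrom_count),
                        function(i) .random_dna(config$chrom_len), character(1))
    names(chromseqs) <- config$chroms
    plant <- function(seqs, chrom, pos0, site23, strand) {
      if (strand == "-") site23 <- revcomp(site23)
      substr(seqs[[chrom]], pos0 + 1L, pos0 + 23L) <- site23
      seqs
    }
    # on-target: exact protospacer + canonical PAM, plus strand
    on_site <- paste0(config$protospacer, config$guide_pam)
    chromseqs <- plant(chromseqs, config$guide_chrom, config$guide_position,
                       on_site, "+")
    ps <- config$planted_sites
    planted <- data.table(
      site_id = if (nrow(ps)) paste0("OT", seq_len(nrow(ps))) else character(),
      chrom = as.character(ps$chrom), position = as.integer(ps$position),
      strand = as.character(ps$strand),
      mismatch_count = as.integer(ps$mismatch_count),
      pam = as.character(ps$pam), sequence_23 = character(nrow(ps)))
    if (nrow(planted)) {
      for (i in seq_len(nrow(planted))) {
        proto_i <- .mutate_protospacer(config$protospacer,
                                       planted$mismatch_count[i])
        site23 <- paste0(proto_i, .check_dna(planted$pam[i], "planted pam"))
        planted[i, sequence_23 := site23]
        chromseqs <- plant(chromseqs, planted$chrom[i], planted$position[i],
                           site23, planted$strand[i])
      }
      planted[, cut_position := candidate_cut_position(position, strand)]
    } else planted[, cut_position := integer()]
    # plasmid: random backbone with a U6-sgRNA cassette CACC<N20>GTTT
    u6_start <- 400L
    cassette <- paste0("CACC", config$protospacer, "GTTT")
    plasmid_seq <- .random_dna(config$plasmid_length)
    substr(plasmid_seq, u6_start + 1L, u6_start + nchar(cassette)) <- cassette
    guide <- guide_target(config$protospacer, config$pam_pattern,
                          config$guide_chrom, config$guide_position, "+")
    list(genome = Biostrings::DNAStringSet(chromseqs),
         plasmid = Biostrings::DNAStringSet(c(plasmid = plasmid_seq)),
         guide = guide,
         truth = list(planted = planted,
                      u6_region = c(start = u6_start,
                                    end = u6_start + nchar(cassette)),
                      config = config))
  })
}

#' Simulate a deduplicated junction table with known outcome composition
#'
#' Draws \code{n_events} events i.i.d. from the configured outcome
#' proportions. Bait is fixed at the on-target cut; prey placement per class:
#' indel within 100 bp of the cut, large deletion at a resection distance
#' (>100 bp) on the same chromosome, off-target translocation at a planted
#' site's cut +/- jitter, general translocation uniform outside +/-20 kb of
#' the target and +/-100 bp of planted sites, plasmid insertion on the
#' plasmid backbone; uncut alleles are full-length no-junction records.
#'
#' @param truth the \code{truth} element of \code{\link{generate_reference}}.
#' @param config the same \code{\link{synthetic_config}}.
#' @return list with \code{junctions} (data.table: read_id, bait_chrom,
#'   bait_pos, bait_strand, prey_ref, prey_pos, prey_strand,
#'   junction_present) and \code{truth_events} (read_id, true_class,
#'   true_site_id) plus \code{class_counts} and per-planted-site
#'   \code{site_junction_counts}.
#' @export
simulate_junctions <- function(truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  p <- config$outcome_proportions
  if (abs(sum(p) - 1) > 1e-9)
    stop("outcome_proportions must sum to 1", call. = FALSE)
  planted <- truth$planted
  if (any(p[c("offtarget_translocation")] > 0) && nrow(planted) == 0L)
    stop("offtarget_translocation proportion > 0 but no planted sites", call. = FALSE)
  guide_cut <- candidate_cut_position(config$guide_position, "+")
  chrom_len <- config$chrom_len
  with_seed(config$seed + 1L, {
    n <- config$n_events
    cls <- sample(names(p), n, replace = TRUE, prob = p)
    prey_ref <- rep(config$guide_chrom, n)
    prey_pos <- rep(NA_integer_, n)
    prey_strand <- sample(c("+", "-"), n, replace = TRUE)
    site_id <- rep(NA_character_, n)
    junction_present <- as.integer(cls != "uncut")

    idx <- which(cls == "indel")
    if (length(idx)) {
      d <- sample(-100:100, length(idx), replace = TRUE)
      prey_pos[idx] <- pmin(pmax(guide_cut + d, 0L), chrom_len - 1L)
    }
    idx <- which(cls == "large_deletion")
    if (length(idx)) {
      r <- config$resection_length_distribution
      d <- sample(r[1]:r[2], length(idx), replace = TRUE) *
        sample(c(-1L, 1L), length(idx), replace = TRUE)
      pos <- guide_cut + d
      # reflect the rare out-of-genome draw back inside, keeping |d| > 100
      pos[pos < 0L] <- guide_cut + abs(d[pos < 0L])
      pos[pos > chrom_len - 1L] <- guide_cut - abs(d[pos > chrom_len - 1L])
      prey_pos[idx] <- as.integer(pos)
    }
    idx <- which(cls == "offtarget_translocation")
    if (length(idx)) {
      si <- sample(nrow(planted), length(idx), replace = TRUE)
      jit <- sample(-config$offtarget_jitter:config$offtarget_jitter,
                    length(idx), replace = TRUE)
      prey_ref[idx] <- planted$chrom[si]
      prey_pos[idx] <- planted$cut_position[si] + jit
      site_id[idx] <- planted$site_id[si]
    }
    idx <- which(cls == "general_translocation")
    if (length(idx)) {
      # rejection-sample uniform genome positions away from target and
      # planted sites
      need <- length(idx)
      acc_ref <- character(0); acc_pos <- integer(0)
      while (length(acc_pos) < need) {
        m <- 2L * (need - length(acc_pos)) + 10L
        ch <- sample(config$chroms, m, replace = TRUE)
        po <- sample.int(chrom_len, m, replace = TRUE) - 1L
        ok <- !(ch == config$guide_chrom & abs(po - guide_cut) <= 20000L)
        if (nrow(planted)) {
          for (i in seq_len(nrow(planted)))
            ok <- ok & !(ch == planted$chrom[i] &
                           abs(po - planted$cut_position[i]) <= 100L)
        }
        acc_ref <- c(acc_ref, ch[ok]); acc_pos <- c(acc_pos, po[ok])
      }
      prey_ref[idx] <- acc_ref[seq_along(idx)]
      prey_pos[idx] <- acc_pos[seq_along(idx)]
    }
    idx <- which(cls == "plasmid_insertion")
    if (length(idx)) {
      prey_ref[idx] <- "plasmid"
      in_u6 <- runif(length(idx)) < config$plasmid_u6_frac
      u6 <- truth$u6_region
      prey_pos[idx] <- ifelse(
        in_u6, sample(u6["start"]:(u6["end"] - 1L), length(idx), replace = TRUE),
        sample.int(config$plasmid_length, length(idx), replace = TRUE) - 1L)
    }
    prey_strand[cls == "uncut"] <- "+"
    junctions <- data.table(
      read_id = sprintf("ev%06d", seq_len(n)),
      bait_chrom = config$guide_chrom, bait_pos = guide_cut,
      bait_strand = "+", prey_ref = prey_ref,
      prey_pos = as.integer(prey_pos), prey_strand = prey_strand,
      junction_present = junction_present)
    truth_events <- data.table(read_id = junctions$read_id, true_class = cls,
                               true_site_id = site_id)
    sj <- truth_events[!is.na(true_site_id), .N, by = true_site_id]
    list(junctions = junctions, truth_events = truth_events,
         class_counts = table(factor(cls, levels = names(p))),
         site_junction_counts = setNames(
           as.integer(sj$N), sj$true_site_id))
  })
}

#' Write a synthetic bundle to disk
#'
#' Emits genome.fa, plasmid.fa, junctions.tsv (tab-separated, 0-based
#' coordinates), guide.json and truth.json under \code{outdir}.
#' @param ref result of \code{\link{generate_reference}}.
#' @param sim result of \code{\link{simulate_junctions}}.
#' @param outdir output directory (created if needed).
#' @return named character vector of paths.
#' @export
write_synthetic_bundle <- function(ref, sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(outdir, "genome.fa"),
             plasmid = file.path(outdir, "plasmid.fa"),
             junctions = file.path(outdir, "junctions.tsv"),
             guide = file.path(outdir, "guide.json"),
             truth = file.path(outdir, "truth.json"))
  Biostrings::writeXStringSet(ref$genome, paths["genome"])
  Biostrings::writeXStringSet(ref$plasmid, paths["plasmid"])
  fwrite(sim$junctions, paths["junctions"], sep = "\t")
  write_json_file(unclass(ref$guide), paths["guide"])
  write_json_file(list(
    planted = ref$truth$planted, u6_region = as.list(ref$truth$u6_region),
    class_counts = as.list(sim$class_counts),
    site_junction_counts = as.list(sim$site_junction_counts)),
    paths["truth"])
  paths
}

#' Read a junction TSV written by \code{\link{write_synthetic_bundle}}
#' @param path junctions.tsv path.
#' @export
read_junctions <- function(path) {
  j <- fread(path, sep = "\t",
             colClasses = list(character = c("prey_ref", "bait_chrom")))
  req <- c("read_id", "bait_chrom", "bait_pos", "bait_strand", "prey_ref",
           "prey_pos", "prey_strand", "junction_present")
  miss <- setdiff(req, names(j))
  if (length(miss))
    stop("junction table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  j[]
}

#' Read a guide.json written by \code{\link{write_synthetic_bundle}}
#' @param path guide.json path.
#' @export
read_guide <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  guide_target(g$protospacer, g$pam_pattern, g$chrom, g$protospacer_start,
               g$strand)
}
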