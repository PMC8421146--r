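eo_guide <- function() guide_target("GACCTGAGTCCGGGTCAGGA", "NGG",
                                    "chr1", 50000L, "+")  # cut 50017

eo_junction <- function(prey_ref, prey_pos, present = 1L) {
  data.table::data.table(
    read_id = sprintf("r%03d", seq_along(prey_ref)),
    bait_chrom = "chr1", bait_pos = 50017L, bait_strand = "+",
    prey_ref = prey_ref, prey_pos = as.integer(prey_pos),
    prey_strand = "+", junction_present = present)
}

eo_offtargets <- function() data.table::data.table(
  chrom = "chr7", start = 1000L, end = 1023L, strand = "+",
  sequence_23 = strrep("A", 23), mismatch_count = 4L, pam = "AGG",
  junction_count = 10L, cut_position = 1017L)

test_that("classification follows the distance taxonomy", {
  g <- eo_guide()
  ot <- eo_offtargets()
  cases <- list(
    list(ref = "chr1", pos = 50017 + 30, want = "indel"),
    list(ref = "chr1", pos = 50017 - 100, want = "indel"),
    list(ref = "chr1", pos = 50017 + 150, want = "large_deletion"),
    list(ref = "chr1", pos = 50017 + 101, want = "large_deletion"),
    list(ref = "chr1", pos = 50017 + 20000, want = "large_deletion"),
    list(ref = "chr1", pos = 50017 + 20001, want = "general_translocation"),
    list(ref = "chr7", pos = 1017 + 40, want = "offtarget_translocation"),
    list(ref = "chr7", pos = 1017 + 100, want = "offtarget_translocation"),
    list(ref = "chr7", pos = 1017 + 101, want = "general_translocation"),
    list(ref = "chr9", pos = 5, want = "general_translocation"),
    list(ref = "plasmid", pos = 10, want = "plasmid_insertion"))
  for (cs in cases) {
    cl <- classify_junctions(eo_junction(cs$ref, cs$pos), g, ot)
    expect_identical(as.character(cl$outcome), cs$want)
  }
  # no junction -> uncut
  cl <- classify_junctions(eo_junction("chr1", NA, present = 0L), g, ot)
  expect_identical(as.character(cl$outcome), "uncut")
})

test_that("empty off-target list never yields offtarget_translocation", {
  g <- eo_guide()
  j <- eo_junction(c("chr7", "chr9", "chr1"), c(1057L, 5L, 50017L + 500L))
  cl <- classify_junctions(j, g, NULL)
  expect_false(any(cl$outcome == "offtarget_translocation"))
})

test_that("unknown prey reference raises a named error", {
  g <- eo_guide()
  expect_error(
    classify_junctions(eo_junction("chrUn", 5L), g, NULL,
                       genome_names = c("chr1", "chr7")),
    "chrUn")
})

test_that("summarize computes efficiency from the printed definition", {
  g <- eo_guide()
  j <- eo_junction(
    c(rep("chr1", 12), rep("chr9", 3), rep("chr1", 85)),
    c(rep(50017L + 10L, 10), rep(50017L + 500L, 2), rep(7L, 3), rep(NA, 85)),
    present = c(rep(1L, 15), rep(0L, 85)))
  s <- summarize_outcomes(classify_junctions(j, g, NULL))
  expect_identical(s$total_events, 100L)
  expect_identical(s$counts[["indel"]], 10L)
  expect_identical(s$counts[["large_deletion"]], 2L)
  expect_identical(s$counts[["general_translocation"]], 3L)
  expect_equal(s$editing_efficiency, 15)
  expect_identical(sum(s$counts), s$total_events)
  # all-uncut library
  j0 <- eo_junction(rep("chr1", 5), rep(NA, 5), present = 0L)
  s0 <- summarize_outcomes(classify_junctions(j0, g, NULL))
  expect_equal(s0$editing_efficiency, 0)
  expect_error(summarize_outcomes(j0[0]), "empty")
})

test_that("class proportions land in exact binomial 99% bands (n = 10k)", {
  cfg <- synthetic_config(planted_sites = default_planted(4),
                          n_events = 10000L, seed = 23L)
  ref <- generate_reference(cfg)
  sim <- simulate_junctions(ref$truth, cfg)
  cand <- enumerate_candidates(ref$genome, ref$guide, 7L, "NNN")
  ot <- call_hotspots(
    find_enriched_regions(exclude_proximal(sim$junctions, ref$guide)),
    cand, ref$guide)
  cl <- classify_junctions(sim$junctions, ref$guide, ot,
                           genome_names = names(ref$genome))
  s <- summarize_outcomes(cl)
  expect_identical(sum(s$counts), 10000L)
  for (cls in names(cfg$outcome_proportions)) {
    band <- binom99(10000L, cfg$outcome_proportions[[cls]])
    expect_gte(s$counts[[cls]], band[["lo"]])
    expect_lte(s$counts[[cls]], band[["hi"]])
  }
})

test_that("fold_change recovers planted ratios and validates input", {
  g <- eo_guide()
  mk <- function(p_gt, seed) {
    cfg <- synthetic_config(
      outcome_proportions = c(uncut = 0.8 - p_gt, indel = 0.15,
                              large_deletion = 0.05,
                              offtarget_translocation = 0,
                              general_translocation = p_gt,
                              plasmid_insertion = 0),
      n_events = 10000L, seed = seed)
    ref <- generate_reference(cfg)
    sim <- simulate_junctions(ref$truth, cfg)
    summarize_outcomes(classify_junctions(sim$junctions, ref$guide, NULL))
  }
  base <- mk(0.04, 101L)
  expect_equal(fold_change(base, base, "general_translocation_rate"), 1.0)
  for (ratio in c(1.5, 2.0)) {
    var <- mk(0.04 * ratio, 102L + as.integer(10 * ratio))
    got <- fold_change(var, base, "general_translocation_rate")
    lo <- qbinom(0.005, 10000L, 0.04 * ratio) / qbinom(0.995, 10000L, 0.04)
    hi <- qbinom(0.995, 10000L, 0.04 * ratio) / qbinom(0.005, 10000L, 0.04)
    expect_gte(got, lo)
    expect_lte(got, hi)
  }
  expect_error(fold_change(base, mk(0, 55L), "general_translocation_rate"),
               "zero")
  expect_error(fold_change(base, base, "nope"), "unknown metric")
})

test_that("plasmid profile: rate arithmetic, binning, linearity", {
  g <- eo_guide()
  # 5 plasmid junctions, 10,000 editing events in total
  j <- eo_junction(
    c(rep("plasmid", 5), rep("chr1", 9995)),
    c(c(250L, 255L, 260L, 270L, 299L), rep(50017L + 10L, 9995)))
  cl <- classify_junctions(j, g, NULL)
  pp <- plasmid_profile(cl, plasmid_length = 1000L)
  expect_equal(pp$per_100k, 50)
  expect_identical(pp$denominator_count, 10000L)
  expect_identical(nrow(pp$profile), 10L)
  # all five junctions fall in the [200, 300) bin
  expect_identical(pp$profile$count[3], 5L)
  expect_identical(sum(pp$profile$count), 5L)
  # indel denominator
  pp2 <- plasmid_profile(cl, 1000L, denominator = "on_target_indels")
  expect_equal(pp2$per_100k, 5 / 9995 * 1e5)
  # doubling plasmid junctions doubles the rate (same denominator class mix)
  j2 <- eo_junction(
    c(rep("plasmid", 10), rep("chr1", 9990)),
    c(rep(250L, 10), rep(50017L + 10L, 9990)))
  pp3 <- plasmid_profile(classify_junctions(j2, g, NULL), 1000L)
  expect_equal(pp3$per_100k, 2 * pp$per_100k)
  # zero plasmid junctions: rate 0, all bins 0
  j0 <- eo_junction("chr1", 50017L + 10L)
  pp0 <- plasmid_profile(classify_junctions(j0, g, NULL), 1000L)
  expect_equal(pp0$per_100k, 0)
  expect_true(all(pp0$profile$count == 0L))
  # zero denominator errors
  ju <- eo_junction("chr1", NA, present = 0L)
  expect_error(plasmid_profile(classify_junctions(ju, g, NULL), 1000L),
               "denominator")
})

test_that("planted one-bin plasmid hotspot is maximal in exactly that bin", {
  cfg <- synthetic_config(plasmid_u6_frac = 1, n_events = 3000L, seed = 5L,
                          outcome_proportions = c(
                            uncut = 0.7, indel = 0.2, large_deletion = 0,
                            offtarget_translocation = 0,
                            general_translocation = 0,
                            plasmid_insertion = 0.1))
  ref <- generate_reference(cfg)
  sim <- simulate_junctions(ref$truth, cfg)
  cl <- classify_junctions(sim$junctions, ref$guide, NULL)
  pp <- plasmid_profile(cl, cfg$plasmid_length)
  u6 <- ref$truth$u6_region
  u6_bins <- which(pp$profile$bin_start < u6["end"] &
                     pp$profile$bin_end > u6["start"])
  expect_identical(sum(pp$profile$count[-u6_bins]), 0L)
  expect_identical(sum(pp$profile$count), sum(cl$outcome == "plasmid_insertion"))
})
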