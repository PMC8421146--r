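#' junctionscan: junction-level analysis of CRISPR genome editing
#'
#' Off-target hotspot calling, editing-outcome classification, consensus /
#' PAM statistics and CNN-based off-target ranking from translocation
#' junction libraries, with a synthetic-data generator for end-to-end
#' testing.
#'
#' @import data.table
#' @importFrom jsonlite write_json read_json toJSON
#' @importFrom stats rbinom runif rnorm setNames wilcox.test
#' @importFrom utils head tail
#' @keywords internal
"_PACKAGE"

# IUPAC subset used for PAM patterns: N, R (A/G), Y (C/T) plus literals.
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  N = c("A", "C", "G", "T")
)

.check_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  if (any(grepl("[^ACGT]", x)))
    stop(what, " contains non-ACGT characters", call. = FALSE)
  x
}

#' Reverse complement of a DNA string
#'
#' @param x character vector of ACGT strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  x <- .check_dna(x)
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Match 3-nt PAMs against an IUPAC pattern
#'
#' Supports the alphabet used for Cas9 PAM classes: literals A/C/G/T plus
#' N (any), R (purine) and Y (pyrimidine) -- enough for NGG, NGN, NGA/NGT/NGC,
#' NNN, NRN and NYN.
#'
#' @param pam character vector of 3-nt ACGT strings.
#' @param pattern single 3-character IUPAC pattern.
#' @return logical vector.
#' @export
pam_matches <- function(pam, pattern) {
  pattern <- toupper(pattern)
  if (nchar(pattern) != 3L)
    stop("pam pattern must have length 3", call. = FALSE)
  pat <- strsplit(pattern, "")[[1]]
  if (!all(pat %in% names(.IUPAC_SETS)))
    stop("pam pattern may only use A/C/G/T/N/R/Y", call. = FALSE)
  pam <- .check_dna(pam, "pam")
  if (any(nchar(pam) != 3L)) stop("pam strings must have length 3", call. = FALSE)
  res <- rep(TRUE, length(pam))
  for (i in 1:3) {
    res <- res & substr(pam, i, i) %in% .IUPAC_SETS[[pat[i]]]
  }
  res
}

# Run code under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards so library code never clobbers user seeds.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic JSON writer used for all report/manifest output.
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}
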