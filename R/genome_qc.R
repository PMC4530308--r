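# Single-cell genome quality metrics: contig filtering, assembly size,
# N50, GC-distribution unimodality screening, marker-gene completeness and
# genome-size extrapolation.

#' Filter contigs by minimum length
#'
#' Drops contigs shorter than `min_len_bp`, the standard post-assembly
#' cleanup for single-cell drafts ("less than" semantics: a contig exactly
#' at the threshold is kept). Input order is preserved.
#'
#' @param contigs A data.frame with at least a `length_bp` column (see
#'   [read_contigs()]), or a numeric vector of lengths.
#' @param min_len_bp Minimum retained length, bp (default 500).
#' @return The filtered data.frame (or vector).
#' @export
filter_contigs <- function(contigs, min_len_bp = 500) {
  if (!is.numeric(min_len_bp) || min_len_bp < 1)
    stop("min_len_bp must be >= 1")
  lens <- contig_lengths(contigs)
  keep <- lens >= min_len_bp
  if (is.data.frame(contigs)) contigs[keep, , drop = FALSE] else contigs[keep]
}

contig_lengths <- function(contigs) {
  lens <- if (is.data.frame(contigs)) {
    if (!"length_bp" %in% names(contigs))
      stop("contig table must have a length_bp column")
    contigs$length_bp
  } else if (is.numeric(contigs)) contigs
  else stop("contigs must be a data.frame or a numeric vector of lengths")
  if (any(!is.finite(lens)) || any(lens < 1))
    stop("contig lengths must be positive")
  lens
}

#' Assembly N50
#'
#' The largest contig length L such that contigs of length >= L together
#' cover at least half of the total assembly length (equivalently: walk the
#' lengths in decreasing order, cumulate, and report the length at which the
#' running sum first reaches half the total). On ties this returns the
#' common convention's value, the contig length at the crossing point.
#'
#' @param contigs A contig data.frame or numeric vector of lengths
#'   (non-empty).
#' @return N50 in bp.
#' @examples
#' n50(c(1, 2, 3, 4, 5))  # 4
#' @export
n50 <- function(contigs) {
  lens <- contig_lengths(contigs)
  if (length(lens) == 0) stop("cannot compute N50 of an empty contig set")
  s <- sort(lens, decreasing = TRUE)
  cs <- cumsum(s)
  s[which(cs >= sum(s) / 2)[1]]
}

#' Screen a GC distribution for unimodality
#'
#' Draft single-cell genomes assembled from one organism should show a
#' single mode in per-contig GC content; extra modes suggest contamination.
#' The per-contig GC fractions are kernel-smoothed (Gaussian kernel,
#' fixed bandwidth in GC-fraction units) on a fixed grid over \[0, 1\] and
#' strict local maxima of the smoothed density are counted. Maxima below 1%
#' of the peak density are ignored to suppress numerical ripples.
#'
#' @param gc_values Numeric vector of GC fractions in \[0, 1\]; at least 10
#'   values.
#' @param bandwidth Kernel bandwidth in GC-fraction units (default 0.02).
#' @return List with `n_modes` and `unimodal` (`n_modes == 1`).
#' @export
gc_unimodality <- function(gc_values, bandwidth = 0.02) {
  if (length(gc_values) < 10)
    stop("need at least 10 GC values to assess modality, got ",
         length(gc_values))
  if (!is.finite(bandwidth) || bandwidth <= 0) stop("bandwidth must be > 0")
  if (any(!is.finite(gc_values)) || any(gc_values < 0 | gc_values > 1))
    stop("gc_values must be fractions in [0, 1]")
  d <- stats::density(gc_values, bw = bandwidth, from = 0, to = 1, n = 512)
  y <- d$y
  floor_y <- 0.01 * max(y)
  inner <- 2:(length(y) - 1)
  is_mode <- y[inner] > y[inner - 1] & y[inner] > y[inner + 1] &
    y[inner] > floor_y
  n_modes <- sum(is_mode)
  list(n_modes = n_modes, unimodal = n_modes == 1L)
}

#' Construct a marker-gene survey
#'
#' Presence/absence of a set of conserved single-copy housekeeping genes in
#' a draft genome. Detection itself (homology search) is upstream; this
#' object only records the outcome.
#'
#' @param marker_ids Character vector of marker names (non-empty, unique).
#' @param present Logical vector (or named logical) of the same length:
#'   whether each marker was found.
#' @return An object of class `marker_survey`.
#' @export
marker_survey <- function(marker_ids, present) {
  if (length(marker_ids) == 0) stop("marker set must be non-empty")
  if (anyDuplicated(marker_ids)) stop("marker_ids must be unique")
  if (!is.null(names(present))) {
    if (!setequal(names(present), marker_ids))
      stop("names of 'present' do not match marker_ids")
    present <- present[marker_ids]
  }
  if (length(present) != length(marker_ids))
    stop("present must have one entry per marker")
  present <- as.logical(present)
  if (any(is.na(present))) stop("present must be TRUE/FALSE with no NA")
  structure(list(marker_ids = as.character(marker_ids),
                 present = stats::setNames(present, marker_ids)),
            class = "marker_survey")
}

#' Marker-based genome completeness
#'
#' Fraction of the single-copy marker set detected in the draft.
#'
#' @param survey A [marker_survey()].
#' @return Completeness fraction in \[0, 1\].
#' @export
completeness <- function(survey) {
  stopifnot(inherits(survey, "marker_survey"))
  sum(survey$present) / length(survey$marker_ids)
}

#' Extrapolate genome size from assembly size and completeness
#'
#' `assembly_size / completeness`, rounded to one decimal half away from
#' zero (so 3.25 reports as 3.3). The estimate assumes markers sample the
#' genome uniformly, which amplification bias in single-cell data only
#' approximately satisfies.
#'
#' @param assembly_size_mbp Assembly size, Mbp (> 0).
#' @param completeness Completeness fraction in (0, 1\].
#' @return Estimated genome size, Mbp (one decimal).
#' @examples
#' estimate_genome_size(1.3, 0.40)  # 3.3
#' @export
estimate_genome_size <- function(assembly_size_mbp, completeness) {
  if (!is.finite(assembly_size_mbp) || assembly_size_mbp <= 0)
    stop("assembly_size_mbp must be > 0")
  if (!is.finite(completeness) || completeness <= 0 || completeness > 1)
    stop("completeness must be in (0, 1]; a completeness of 0 gives an ",
         "unbounded estimate - supply a minimum detected-marker fraction")
  round_half_away(assembly_size_mbp / completeness, 1)
}

#' Full completeness report for one draft genome
#'
#' @param survey A [marker_survey()].
#' @param assembly_size_mbp Assembly size, Mbp.
#' @return An object of class `completeness_report`: list with `n_markers`,
#'   `n_found`, `completeness`, `assembly_size_mbp`,
#'   `estimated_genome_size_mbp`.
#' @export
completeness_report <- function(survey, assembly_size_mbp) {
  stopifnot(inherits(survey, "marker_survey"))
  comp <- completeness(survey)
  est <- if (comp > 0) estimate_genome_size(assembly_size_mbp, comp)
  else NA_real_
  structure(list(n_markers = length(survey$marker_ids),
                 n_found = sum(survey$present), completeness = comp,
                 assembly_size_mbp = assembly_size_mbp,
                 estimated_genome_size_mbp = est),
            class = "completeness_report")
}

#' @export
print.completeness_report <- function(x, ...) {
  cat(sprintf("<completeness_report> %d/%d markers (%.0f%%); assembly %.1f Mbp -> estimated %.1f Mbp\n",
              x$n_found, x$n_markers, 100 * x$completeness,
              x$assembly_size_mbp, x$estimated_genome_size_mbp))
  invisible(x)
}

#' Read contigs from FASTA or CSV
#'
#' FASTA input computes per-contig length and GC fraction; ambiguous bases
#' are excluded from the GC denominator (GC = (G+C)/(A+C+G+T)). CSV input
#' expects columns `contig_id`, `length_bp`, `gc_fraction`.
#'
#' @param path Path to a FASTA (`.fa`, `.fasta`, `.fna`) or CSV file.
#' @return A data.frame with columns `contig_id`, `length_bp`,
#'   `gc_fraction`.
#' @export
read_contigs <- function(path) {
  if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) {
    seqs <- Biostrings::readDNAStringSet(path)
    freq <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
    acgt <- rowSums(freq)
    gc <- ifelse(acgt > 0, (freq[, "C"] + freq[, "G"]) / acgt, NA_real_)
    data.frame(contig_id = names(seqs),
               length_bp = Biostrings::width(seqs),
               gc_fraction = as.numeric(gc), stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("contig_id", "length_bp", "gc_fraction")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("contig CSV missing columns: ",
                           paste(miss, collapse = ", "))
    df[need]
  }
}

#' Read a marker survey from a two-column CSV
#'
#' Columns `marker_id` and `present` (0/1 or TRUE/FALSE).
#'
#' @param path CSV file path.
#' @return A [marker_survey()].
#' @export
read_marker_survey <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("marker_id", "present") %in% names(df)))
    stop("marker survey CSV needs columns marker_id, present")
  marker_survey(df$marker_id, as.logical(df$present))
}

#' Write a completeness report
#'
#' @param x A [completeness_report()].
#' @param path Output file; `.json` or `.csv` by extension.
#' @return `path`, invisibly.
#' @export
write_completeness_report <- function(x, path) {
  stopifnot(inherits(x, "completeness_report"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    utils::write.csv(as.data.frame(unclass(x)), path, row.names = FALSE)
  }
  invisible(path)
}
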