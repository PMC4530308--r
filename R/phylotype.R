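# 16S rRNA phylotype analysis on pre-aligned sequences: pairwise percent
# identity and Cluster A/B assignment from the helix-38 deletion in the V6
# region.

#' Read an aligned FASTA file
#'
#' Sequences are upper-cased and U is normalized to T on load; all records
#' must share one column count. Allowed characters are A, C, G, T, N and
#' the gap character `-`.
#'
#' @param path Aligned FASTA file.
#' @return A named character vector of aligned sequences with class
#'   `aligned_seqs`.
#' @export
read_alignment <- function(path) {
  seqs <- as.character(Biostrings::readBStringSet(path))
  as_alignment(seqs)
}

#' Coerce named sequences to a checked alignment
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @return An `aligned_seqs` object.
#' @export
as_alignment <- function(seqs) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("aligned sequences must be named")
  seqs <- chartr("u", "U", toupper(seqs))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1)
    stop("all sequences in an alignment must have the same column count; got ",
         paste(unique(widths), collapse = ", "))
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("alignment contains characters outside {A,C,G,T,U,N,-}: ",
         paste(names(seqs)[bad], collapse = ", "))
  structure(seqs, class = "aligned_seqs")
}

aln_chars <- function(x) strsplit(unclass(x), "", fixed = TRUE)

#' Pairwise percent identity of two aligned sequences
#'
#' `100 * matches / comparable`, where comparable columns are by default
#' those in which both sequences are non-gap (pairwise-deletion
#' convention), and a match requires identical, unambiguous bases (N never
#' matches, including N against N). With
#' `denominator = "all_columns"` every alignment column counts.
#'
#' @param a,b Aligned sequences of equal length (character scalars or
#'   elements of an `aligned_seqs` object).
#' @param denominator `"both_nongap"` (default) or `"all_columns"`.
#' @return Percent identity (0--100). Symmetric in its arguments.
#' @examples
#' pairwise_identity("AC-GT", "ACAGT")  # 100: the gap column is excluded
#' @export
pairwise_identity <- function(a, b,
                              denominator = c("both_nongap", "all_columns")) {
  denominator <- match.arg(denominator)
  if (nchar(a) != nchar(b))
    stop("sequences are not aligned: lengths ", nchar(a), " and ", nchar(b))
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  both_nongap <- ca != "-" & cb != "-"
  match <- both_nongap & ca == cb & ca != "N"
  denom <- if (denominator == "both_nongap") sum(both_nongap) else length(ca)
  if (denom == 0)
    stop("no comparable columns between the two sequences; identity undefined")
  100 * sum(match) / denom
}

#' Pairwise identity matrix of an alignment
#'
#' @param alignment An `aligned_seqs` object (or named character vector)
#'   with at least two sequences.
#' @param denominator Passed to [pairwise_identity()].
#' @return A symmetric numeric matrix of percent identities with 100 on the
#'   diagonal, dimnames from the sequence names.
#' @export
identity_matrix <- function(alignment,
                            denominator = c("both_nongap", "all_columns")) {
  denominator <- match.arg(denominator)
  alignment <- as_alignment(alignment)
  n <- length(alignment)
  if (n < 2) stop("need at least 2 sequences for an identity matrix")
  m <- matrix(100, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <-
        pairwise_identity(alignment[[i]], alignment[[j]], denominator)
    }
  }
  m
}

#' Define an alignment region annotation
#'
#' Columns are 0-based, half-open (`start_col` inclusive, `end_col`
#' exclusive), matching the coordinate convention of the region CSV input.
#'
#' @param name Region name (e.g. `"helix38_v6"`).
#' @param start_col,end_col Region bounds, 0-based half-open.
#' @return An object of class `region_annotation`.
#' @export
region_annotation <- function(name, start_col, end_col) {
  if (!is.finite(start_col) || !is.finite(end_col) || start_col < 0 ||
      end_col <= start_col)
    stop("need 0 <= start_col < end_col")
  structure(list(name = name, start_col = as.integer(start_col),
                 end_col = as.integer(end_col)),
            class = "region_annotation")
}

#' Detect a deletion within an annotated alignment region
#'
#' A sequence is called deleted in the region (for helix 38 in the 16S V6
#' region, the diagnostic for "Cluster A" phylotypes) when the fraction of
#' gap characters in the region reaches `gap_fraction_threshold`.
#'
#' @param seq One aligned sequence (character scalar).
#' @param region A [region_annotation()] lying within the alignment.
#' @param gap_fraction_threshold Gap fraction that constitutes a deletion
#'   (default 0.5).
#' @return `TRUE` if the region is deleted.
#' @export
detect_helix38_deletion <- function(seq, region,
                                    gap_fraction_threshold = 0.5) {
  stopifnot(inherits(region, "region_annotation"))
  if (region$end_col > nchar(seq))
    stop("region ", region$name, " [", region$start_col, ", ",
         region$end_col, ") exceeds alignment length ", nchar(seq))
  sub <- substr(seq, region$start_col + 1, region$end_col)
  gap_frac <- lengths(regmatches(sub, gregexpr("-", sub, fixed = TRUE))) /
    nchar(sub)
  gap_frac >= gap_fraction_threshold
}

#' Assign a phylotype cluster from the helix-38 deletion state
#'
#' Phylotypes carrying the helix-38/V6 deletion form "Cluster A"; those
#' with helix 38 intact form "Cluster B".
#'
#' @param has_deletion Logical (vectorized).
#' @return `"A"` where deleted, `"B"` otherwise.
#' @export
assign_cluster <- function(has_deletion) {
  stopifnot(is.logical(has_deletion), !anyNA(has_deletion))
  ifelse(has_deletion, "A", "B")
}

#' Call clusters for every sequence in an alignment
#'
#' @param alignment An `aligned_seqs` object.
#' @param region A [region_annotation()] for the helix-38/V6 region.
#' @param gap_fraction_threshold Passed to [detect_helix38_deletion()].
#' @return A data.frame with columns `seq_id`, `has_deletion`, `cluster`.
#' @export
cluster_calls <- function(alignment, region, gap_fraction_threshold = 0.5) {
  alignment <- as_alignment(alignment)
  del <- vapply(unclass(alignment), detect_helix38_deletion, logical(1),
                region = region,
                gap_fraction_threshold = gap_fraction_threshold)
  data.frame(seq_id = names(alignment), has_deletion = unname(del),
             cluster = unname(assign_cluster(del)), stringsAsFactors = FALSE)
}

#' Read region annotations from CSV
#'
#' Columns `name`, `start_col`, `end_col` (0-based half-open).
#'
#' @param path CSV file path.
#' @return A named list of [region_annotation()] objects.
#' @export
read_region_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "start_col", "end_col") %in% names(df)))
    stop("region CSV needs columns name, start_col, end_col")
  out <- lapply(seq_len(nrow(df)), function(i)
    region_annotation(df$name[i], df$start_col[i], df$end_col[i]))
  names(out) <- df$name
  out
}

#' Write an identity matrix as CSV
#'
#' @param m A matrix from [identity_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_identity_matrix <- function(m, path) {
  utils::write.csv(m, path, row.names = TRUE)
  invisible(path)
}
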