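# Seeded synthetic-data generators for every input class the analysis
# consumes, each with a machine-readable ground-truth sidecar so pipeline
# stages can be tested without any external downloads. "paper"-style
# scenarios reproduce the Warm Mineral Springs field values verbatim;
# "jitter" scenarios perturb them with controlled noise.

# Run code under a local RNG state so generators are seed-deterministic
# without disturbing the caller's random stream.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

truth_sidecar <- function(generator, seed, facts, citations = list()) {
  list(schema = "achrotools-truth/1", generator = generator, seed = seed,
       facts = facts, citations = citations)
}

#' Write a ground-truth sidecar as JSON
#'
#' Every generator attaches a `truth` attribute to its output; this helper
#' serializes it next to the data file.
#'
#' @param x A generator result carrying a `truth` attribute.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(x, path) {
  truth <- attr(x, "truth")
  if (is.null(truth)) stop("object carries no truth sidecar")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Warm Mineral Springs basin surface-water reference values (two sampling
# dates) used by the "paper" scenarios and the reproduction pipeline.
wms_basin_reference <- function() {
  data.frame(
    label = c("basin-jun2012", "basin-oct2013"),
    temperature_c = c(29.6, 31.7),
    ph = c(7.03, 7.32),
    conductivity_ms_cm = c(28.9, 32.6),
    sulfide_uM = c(33.1, 0),
    bicarbonate_mM = c(2, 2),
    calcium_mM = c(11.1, 11.1),  # single ICP-AES measurement, Oct 2013
    stringsAsFactors = FALSE)
}

#' Generate water-chemistry sample tables
#'
#' `scenario = "paper-basin"` returns the two basin reference columns
#' exactly (June 2012 and October 2013 sampling dates). `"jitter"` draws
#' `n_samples` around the June basin values with small lognormal/normal
#' noise emulating between-site spread along an outflow channel.
#'
#' @param n_samples Number of rows for the jitter scenario.
#' @param scenario `"paper-basin"` or `"jitter"`.
#' @param seed Integer seed; identical seed and parameters give identical
#'   tables.
#' @return A data.frame in [read_water_samples()] column layout, with a
#'   `truth` attribute describing the generating values.
#' @export
gen_water_samples <- function(n_samples = 4,
                              scenario = c("paper-basin", "jitter"),
                              seed = 1) {
  scenario <- match.arg(scenario)
  ref <- wms_basin_reference()
  if (scenario == "paper-basin") {
    df <- ref
    attr(df, "truth") <- truth_sidecar(
      "gen_water_samples", seed,
      facts = list(scenario = scenario, values = ref),
      citations = list(
        ph = "basin field record, two sampling dates",
        bicarbonate_mM = "reported spring-water bicarbonate, ~2 mM",
        calcium_mM = "reported dissolved calcium, 11.1 mM"))
    return(df)
  }
  base <- ref[1, ]
  df <- with_local_seed(seed, {
    if (n_samples == 0) {
      out <- base[0, ]
    } else {
      out <- data.frame(
        label = sprintf("sim-%02d", seq_len(n_samples)),
        temperature_c = pmin(50, pmax(0, stats::rnorm(n_samples, base$temperature_c, 1.2))),
        ph = pmin(12, pmax(2, stats::rnorm(n_samples, base$ph, 0.08))),
        conductivity_ms_cm = base$conductivity_ms_cm *
          stats::rlnorm(n_samples, 0, 0.04),
        sulfide_uM = pmax(0, stats::rnorm(n_samples, base$sulfide_uM, 5)),
        bicarbonate_mM = base$bicarbonate_mM * stats::rlnorm(n_samples, 0, 0.05),
        calcium_mM = base$calcium_mM * stats::rlnorm(n_samples, 0, 0.03),
        stringsAsFactors = FALSE)
    }
    out
  })
  attr(df, "truth") <- truth_sidecar(
    "gen_water_samples", seed,
    facts = list(scenario = scenario, n_samples = n_samples,
                 center = base))
  df
}

#' Generate sediment sample tables
#'
#' `scenario = "paper"` returns the littoral-zone reference: porosity 0.9,
#' pore-water sulfide 30 uM, and the two measured AVS endpoints 0.3 and
#' 0.6 umol/g solid. `"jitter"` draws `n_samples` around those values with
#' porosity truncated to \[0, 1\].
#'
#' @inheritParams gen_water_samples
#' @return A data.frame in [read_sediment_samples()] column layout with a
#'   `truth` attribute.
#' @export
gen_sediment_samples <- function(n_samples = 4,
                                 scenario = c("paper", "jitter"), seed = 1) {
  scenario <- match.arg(scenario)
  ref <- data.frame(label = c("littoral-avs-low", "littoral-avs-high"),
                    porosity = 0.9, dissolved_sulfide_um = 30,
                    avs_umol_per_g = c(0.3, 0.6),
                    solid_grain_density_g_cm3 = 1.67, bulk_volume_cm3 = 1,
                    stringsAsFactors = FALSE)
  if (scenario == "paper") {
    df <- ref
    attr(df, "truth") <- truth_sidecar(
      "gen_sediment_samples", seed,
      facts = list(scenario = scenario, values = ref),
      citations = list(
        porosity = "littoral-zone porosity 0.9 (n = 2)",
        avs_umol_per_g = "AVS_solid 0.3-0.6 umol/g solid (n = 3)",
        dissolved_sulfide_um = "assumed 30 uM pore-water sulfide"))
    return(df)
  }
  df <- with_local_seed(seed, {
    if (n_samples == 0) ref[0, ]
    else data.frame(
      label = sprintf("sim-%02d", seq_len(n_samples)),
      porosity = pmin(1, pmax(0, stats::rnorm(n_samples, 0.9, 0.04))),
      dissolved_sulfide_um = pmax(0, stats::rnorm(n_samples, 30, 6)),
      avs_umol_per_g = stats::runif(n_samples, 0.3, 0.6),
      solid_grain_density_g_cm3 = 1.67, bulk_volume_cm3 = 1,
      stringsAsFactors = FALSE)
  })
  attr(df, "truth") <- truth_sidecar(
    "gen_sediment_samples", seed,
    facts = list(scenario = scenario, n_samples = n_samples))
  df
}

#' Generate a marker survey with known true completeness
#'
#' Each marker is detected independently with probability
#' `true_completeness`, emulating uniform dropout from amplification bias.
#'
#' @param true_completeness Detection probability in \[0, 1\].
#' @param n_markers Number of markers.
#' @param seed Integer seed.
#' @return A [marker_survey()] with a `truth` attribute recording
#'   `true_completeness`.
#' @export
gen_marker_survey <- function(true_completeness, n_markers = 100, seed = 1) {
  if (!is.finite(true_completeness) || true_completeness < 0 ||
      true_completeness > 1)
    stop("true_completeness must be in [0, 1]")
  if (n_markers < 1) stop("n_markers must be >= 1")
  ids <- sprintf("marker_%03d", seq_len(n_markers))
  present <- with_local_seed(seed,
    stats::runif(n_markers) < true_completeness)
  sv <- marker_survey(ids, present)
  attr(sv, "truth") <- truth_sidecar(
    "gen_marker_survey", seed,
    facts = list(true_completeness = true_completeness,
                 n_markers = n_markers))
  sv
}

#' Generate a contig set with known length and GC structure
#'
#' Contig lengths are lognormal (then rounded up to >= 1 bp); GC fractions
#' are drawn from a mixture of normal components truncated to \[0, 1\], so
#' unimodal and multimodal GC screens can be exercised with known truth.
#'
#' @param n Number of contigs.
#' @param meanlog,sdlog Lognormal length parameters (defaults give a
#'   single-cell-assembly-like spread around ~2 kb).
#' @param gc_modes List of `c(mean, sd, weight)` component triples; weights
#'   are normalized.
#' @param seed Integer seed.
#' @return A contig data.frame (`contig_id`, `length_bp`, `gc_fraction`)
#'   with a `truth` attribute recording the drawn lengths and component
#'   assignments.
#' @export
gen_contig_set <- function(n = 500, meanlog = log(2000), sdlog = 1,
                           gc_modes = list(c(0.39, 0.03, 1)), seed = 1) {
  if (n < 1) stop("n must be >= 1")
  w <- vapply(gc_modes, `[`, 0, 3)
  w <- w / sum(w)
  out <- with_local_seed(seed, {
    lens <- pmax(1, round(stats::rlnorm(n, meanlog, sdlog)))
    comp <- sample.int(length(gc_modes), n, replace = TRUE, prob = w)
    gc <- vapply(seq_len(n), function(i) {
      m <- gc_modes[[comp[i]]]
      pmin(1, pmax(0, stats::rnorm(1, m[1], m[2])))
    }, 0)
    list(lens = lens, comp = comp, gc = gc)
  })
  df <- data.frame(contig_id = sprintf("contig_%04d", seq_len(n)),
                   length_bp = out$lens, gc_fraction = out$gc,
                   stringsAsFactors = FALSE)
  attr(df, "truth") <- truth_sidecar(
    "gen_contig_set", seed,
    facts = list(n = n, lengths = out$lens, component = out$comp,
                 n_gc_modes = length(gc_modes)))
  df
}

#' Generate an aligned sequence set with exact identity structure
#'
#' Builds a random root sequence and derives the remaining sequences by
#' count-based substitution placement: per-pair substitution counts are
#' fixed by construction, not drawn, so pairwise identities hit the target
#' within one column. Substituted column sets are arranged as one block
#' shared by all non-root sequences plus disjoint private blocks, giving
#' every pair (root or not) a difference of `k = round((1 - t/100) * L)`
#' columns (`k` or `k + 1` between non-root pairs when `k` is odd).
#'
#' A deletion can be implanted in chosen sequences over an annotated
#' region: `deletion_spec = list(seq_ids =, start_col =, end_col =,
#' coverage =)` gaps out the first `coverage` fraction of the region
#' (0-based half-open columns).
#'
#' @param n_seqs Number of sequences (>= 2).
#' @param length Alignment length in columns.
#' @param target_identity Target pairwise identity, percent.
#' @param deletion_spec Optional deletion implant (see Details).
#' @param seed Integer seed.
#' @return An `aligned_seqs` object with a `truth` attribute recording the
#'   realized pairwise substitution-count matrix and any implanted
#'   deletion.
#' @export
gen_alignment <- function(n_seqs = 3, length = 1500, target_identity = 91,
                          deletion_spec = NULL, seed = 1) {
  if (n_seqs < 2) stop("n_seqs must be >= 2")
  if (target_identity < 0 || target_identity > 100)
    stop("target_identity must be a percent in [0, 100]")
  k <- round((1 - target_identity / 100) * length)
  p <- k %/% 2L          # private substitutions per non-root sequence
  cshared <- k - p       # block shared by all non-root sequences
  need <- cshared + (n_seqs - 1) * p
  if (need > length)
    stop("alignment too short for ", n_seqs, " sequences at ",
         target_identity, "% identity (need ", need, " columns)")

  rot <- c(A = "C", C = "G", G = "T", T = "A")
  built <- with_local_seed(seed, {
    root <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    cols <- sample.int(length, need)  # disjoint substitution columns
    shared_cols <- if (cshared > 0) cols[seq_len(cshared)] else integer(0)
    private <- split(cols[seq_len(need - cshared) + cshared],
                     rep(seq_len(n_seqs - 1), each = p)[seq_len(need - cshared)])
    seqs <- matrix(root, nrow = n_seqs, ncol = length, byrow = TRUE)
    for (i in seq_len(n_seqs - 1)) {
      idx <- c(shared_cols, private[[as.character(i)]])
      seqs[i + 1, idx] <- rot[seqs[i + 1, idx]]
    }
    seqs
  })

  # realized pairwise substitution counts, exact by construction
  d <- matrix(0L, n_seqs, n_seqs)
  d[1, -1] <- d[-1, 1] <- cshared + p
  if (n_seqs > 2)
    for (i in 2:(n_seqs - 1)) for (j in (i + 1):n_seqs)
      d[i, j] <- d[j, i] <- 2L * p

  ids <- sprintf("seq_%02d", seq_len(n_seqs))
  out <- stats::setNames(apply(built, 1, paste, collapse = ""), ids)
  dimnames(d) <- list(ids, ids)

  del_fact <- NULL
  if (!is.null(deletion_spec)) {
    ds <- deletion_spec
    stopifnot(all(c("seq_ids", "start_col", "end_col", "coverage") %in%
                    names(ds)))
    if (ds$end_col > length || ds$start_col < 0 ||
        ds$start_col >= ds$end_col)
      stop("deletion_spec region out of bounds")
    width <- ds$end_col - ds$start_col
    ncols <- round(ds$coverage * width)
    if (ncols > 0) {
      for (id in ds$seq_ids) {
        if (!id %in% ids) stop("unknown seq_id in deletion_spec: ", id)
        s <- strsplit(out[[id]], "")[[1]]
        s[(ds$start_col + 1):(ds$start_col + ncols)] <- "-"
        out[id] <- paste(s, collapse = "")
      }
    }
    del_fact <- list(seq_ids = ds$seq_ids, start_col = ds$start_col,
                     end_col = ds$end_col, coverage = ds$coverage,
                     gapped_columns = ncols)
  }

  aln <- as_alignment(out)
  attr(aln, "truth") <- truth_sidecar(
    "gen_alignment", seed,
    facts = list(n_seqs = n_seqs, length = length,
                 target_identity = target_identity,
                 substitutions_per_pair = d, deletion = del_fact))
  aln
}

#' Write an alignment as aligned FASTA
#'
#' @param alignment An `aligned_seqs` object.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  alignment <- as_alignment(alignment)
  lines <- as.vector(rbind(paste0(">", names(alignment)),
                           unclass(alignment)))
  writeLines(lines, path)
  invisible(path)
}
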